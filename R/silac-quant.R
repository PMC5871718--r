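#' Median-based SILAC protein ratios from peptide ratios
#'
#' Computes one heavy/light protein ratio per protein group as the median of
#' all valid quantified peptide ratios. A peptide ratio is valid when the
#' peptide passes the quantification filters: identification score > 15,
#' peptide length >= 6 residues, least-squares fit quality of the light/heavy
#' pair <= 0.1, and prior ion ratio <= 0.2. When at least one valid positive
#' ratio exists for a protein, peptides with an undetermined (`NA`) ratio are
#' excluded from the median; when no valid ratio exists the protein is
#' reported unquantified (`NA`).
#'
#' @param peptide_ratios Data frame with columns `protein_group`, `ratio`,
#'   `identification_score`, `peptide_length`, `lsq_fit_quality`,
#'   `prior_ion_ratio`.
#' @param min_score,min_length,max_lsq,max_prior_ion Filter thresholds with
#'   the defaults above.
#' @return A tibble with `protein_group`, `ratio` (median of valid ratios or
#'   `NA`), and `n_valid` (peptide ratios entering the median).
#' @export
silac_protein_ratio <- function(peptide_ratios, min_score = 15, min_length = 6,
                                max_lsq = 0.1, max_prior_ion = 0.2) {
  check_columns(
    peptide_ratios,
    c("protein_group", "ratio", "identification_score", "peptide_length",
      "lsq_fit_quality", "prior_ion_ratio"),
    "peptide ratio table"
  )
  as_tibble(peptide_ratios) |>
    filter(
      .data$identification_score > min_score,
      .data$peptide_length >= min_length,
      .data$lsq_fit_quality <= max_lsq,
      .data$prior_ion_ratio <= max_prior_ion
    ) |>
    group_by(.data$protein_group) |>
    summarise(
      n_valid = sum(is.finite(.data$ratio) & .data$ratio > 0),
      ratio = if (any(is.finite(.data$ratio) & .data$ratio > 0)) {
        median(.data$ratio[is.finite(.data$ratio)])
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    select("protein_group", "ratio", "n_valid")
}

#' Impute missing protein abundances with half the experiment-wide minimum
#'
#' Proteins robustly detected in one condition can be missing in the paired
#' condition because of strong downregulation. Such missing abundances are
#' replaced by half of the smallest detected relative abundance across the
#' whole experiment, so a fold change can still be computed and the
#' downregulation is captured. Imputed cells are flagged.
#'
#' @param protein_table Data frame with an `abundance` column; `NA` marks a
#'   missing abundance.
#' @return The table with `abundance` imputed and a logical `imputed` column.
#' @export
impute_missing_abundance <- function(protein_table) {
  check_columns(protein_table, "abundance", "protein table")
  tbl <- as_tibble(protein_table)
  detected <- tbl$abundance[is.finite(tbl$abundance)]
  if (length(detected) == 0) {
    abort("cannot impute: no detected abundance in the experiment")
  }
  proxy <- min(detected) / 2
  tbl |>
    mutate(
      imputed = !is.finite(.data$abundance),
      abundance = if_else(.data$imputed, proxy, .data$abundance)
    )
}

#' Filter proteins on between-donor consistency and spectral support
#'
#' Removes proteins whose effect differs between the two donors (replicates)
#' by more than `max_discordance`-fold in any condition, or whose
#' quantification rests on fewer than `min_ssm` quantified spectrum-sequence
#' matches in any donor x condition cell.
#'
#' @param protein_table Data frame with columns `protein_group`, `condition`,
#'   `donor`, `fold_change` (ratio scale) and `n_ssm`.
#' @param max_discordance Maximum allowed fold difference between donors
#'   (default 8).
#' @param min_ssm Minimum spectrum-sequence matches (default 3).
#' @return The table restricted to proteins passing both criteria.
#' @export
donor_consistency_filter <- function(protein_table, max_discordance = 8, min_ssm = 3) {
  check_columns(protein_table,
                c("protein_group", "condition", "donor", "fold_change", "n_ssm"),
                "protein table")
  tbl <- as_tibble(protein_table)
  bad <- tbl |>
    group_by(.data$protein_group, .data$condition) |>
    summarise(
      discordant = {
        fc <- .data$fold_change[is.finite(.data$fold_change) & .data$fold_change > 0]
        length(fc) >= 2 && max(fc) / min(fc) > max_discordance
      },
      low_support = any(.data$n_ssm < min_ssm),
      .groups = "drop"
    ) |>
    filter(.data$discordant | .data$low_support) |>
    pull("protein_group") |>
    unique()
  filter(tbl, !.data$protein_group %in% bad)
}
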