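# End-to-end orchestration: PSM table -> protein fold changes ->
# significance calls -> classification; TR table -> melting fits -> Tm-shift
# calls. Every run returns the full effective configuration alongside the
# results so thresholds are always traceable.

#' Per-protein log2 fold changes from a PSM table
#'
#' Composes the isobaric quantification steps: spectrum-quality filtering,
#' ion-area computation, optional isotope-purity correction, the
#' two-unique-peptides rule, per-channel ion-area summation per protein and
#' SILAC label, and fold changes of every non-reference channel against the
#' reference condition's channel of the same replicate. The SILAC label of a
#' spectrum determines which pool (mature or nascent) it measures for a
#' given replicate via the label-swap design.
#'
#' @param psms PSM table (see [simulate_mpdp_experiment()] for the schema).
#' @param design Design tibble with `channel`, `condition`, `replicate`,
#'   `mature_label` (see [mpdp_design()]).
#' @param reference_condition Condition used as fold-change denominator
#'   (default `"vehicle"`).
#' @param purity Optional isotope purity matrix applied to the summed areas.
#' @param apply_filters Apply [filter_psms()] first (default `TRUE`).
#' @param min_score,min_s2b,min_s2i Spectrum-quality thresholds.
#' @param min_unique_peptides Minimum unique peptide matches per protein.
#' @return A tibble with `protein_group`, `condition`, `pool`, `replicate`,
#'   `log2_fc`, `n_ssm` — the input contract of [mpdp_significance()].
#' @export
psm_fold_changes <- function(psms, design, reference_condition = "vehicle",
                             purity = NULL, apply_filters = TRUE,
                             min_score = 15, min_s2b = 4, min_s2i = 0.5,
                             min_unique_peptides = 2) {
  check_columns(design, c("channel", "condition", "replicate", "mature_label"),
                "design table")
  channels <- design$channel
  check_columns(psms, c("protein_group", "peptide_sequence", "is_unique",
                        "silac_channel", "accumulation_time", channels),
                "PSM table")
  if (!reference_condition %in% design$condition) {
    abort(sprintf("reference condition '%s' not present in the design", reference_condition))
  }
  if (apply_filters) {
    psms <- filter_psms(psms, min_score = min_score, min_s2b = min_s2b,
                        min_s2i = min_s2i)
  }
  psms <- compute_ion_areas(psms, channels)
  psms <- psms |>
    group_by(.data$protein_group) |>
    filter(n_distinct(.data$peptide_sequence[.data$is_unique]) >= min_unique_peptides) |>
    ungroup()

  sums <- psms |>
    group_by(.data$protein_group, .data$silac_channel) |>
    summarise(across(all_of(channels), sum), n_ssm = n(), .groups = "drop")
  if (!is.null(purity)) {
    sums[channels] <- correct_isotope_purity(sums[channels], purity)
  }

  long <- sums |>
    pivot_longer(all_of(channels), names_to = "channel", values_to = "area") |>
    left_join(design, by = "channel") |>
    mutate(pool = if_else(.data$silac_channel == .data$mature_label,
                          "mature", "nascent"))
  ref <- long |>
    filter(.data$condition == reference_condition) |>
    select("protein_group", "silac_channel", "replicate", ref_area = "area")
  long |>
    filter(.data$condition != reference_condition) |>
    left_join(ref, by = c("protein_group", "silac_channel", "replicate")) |>
    mutate(log2_fc = if_else(.data$ref_area > 0 & .data$area > 0,
                             log2(.data$area / .data$ref_area), NA_real_)) |>
    select("protein_group", "condition", "pool", "replicate", "log2_fc", "n_ssm") |>
    arrange(.data$condition, .data$pool, .data$replicate, .data$protein_group)
}

#' Run the full mPDP analysis on a PSM table
#'
#' PSM filtering and quantification, replicate-based significance testing,
#' and (when `time_point` is supplied) input rows for downstream dependence
#' classification. The returned `config` element records every threshold
#' applied.
#'
#' @inheritParams psm_fold_changes
#' @param fc_threshold,alpha,min_bin_size,use_mature_factors_for_nascent
#'   Passed to [mpdp_significance()].
#' @param time_point Optional time point annotation (hours) added to the
#'   significance table for multi-time-point classification.
#' @return A list with `fold_changes`, `significance`, and `config`.
#' @export
#' @examples
#' sim <- simulate_mpdp_experiment(n_proteins = 400, seed = 2)
#' res <- run_mpdp(sim$psms, sim$design)
#' sum(res$significance$significant)
run_mpdp <- function(psms, design, reference_condition = "vehicle",
                     purity = NULL, min_score = 15, min_s2b = 4, min_s2i = 0.5,
                     min_unique_peptides = 2, fc_threshold = 0.37, alpha = 0.05,
                     min_bin_size = 300, use_mature_factors_for_nascent = FALSE,
                     time_point = NULL) {
  fc <- psm_fold_changes(psms, design,
                         reference_condition = reference_condition,
                         purity = purity, min_score = min_score,
                         min_s2b = min_s2b, min_s2i = min_s2i,
                         min_unique_peptides = min_unique_peptides)
  sig <- mpdp_significance(fc, fc_threshold = fc_threshold, alpha = alpha,
                           min_bin_size = min_bin_size,
                           use_mature_factors_for_nascent = use_mature_factors_for_nascent)
  if (!is.null(time_point)) sig$time_point <- time_point
  list(
    fold_changes = fc,
    significance = sig,
    config = list(
      reference_condition = reference_condition, min_score = min_score,
      min_s2b = min_s2b, min_s2i = min_s2i,
      min_unique_peptides = min_unique_peptides,
      fc_threshold = fc_threshold, alpha = alpha, min_bin_size = min_bin_size,
      use_mature_factors_for_nascent = use_mature_factors_for_nascent
    )
  )
}

#' Run the TPP-TR analysis on a fold-change table
#'
#' Fits melting curves per protein, group and replicate and applies the
#' melting-point shift significance procedure.
#'
#' @param tr_table Input for [fit_melting_curves()].
#' @param min_bin_size,min_r2,max_vehicle_plateau,max_slope Passed to
#'   [tm_shift_significance()].
#' @return A list with `fits`, `shifts`, and `config`.
#' @export
run_thermal <- function(tr_table, min_bin_size = 300, min_r2 = 0.8,
                        max_vehicle_plateau = 0.3, max_slope = -0.06) {
  fits <- fit_melting_curves(tr_table)
  shifts <- tm_shift_significance(fits, min_bin_size = min_bin_size,
                                  min_r2 = min_r2,
                                  max_vehicle_plateau = max_vehicle_plateau,
                                  max_slope = max_slope)
  list(
    fits = fits,
    shifts = shifts,
    config = list(min_bin_size = min_bin_size, min_r2 = min_r2,
                  max_vehicle_plateau = max_vehicle_plateau,
                  max_slope = max_slope)
  )
}

#' Read and write tab-separated analysis tables
#'
#' Thin wrappers around base R's delimited-file readers for the tab-separated
#' tables the analysis functions consume and produce.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return `read_tsv_table()` returns a tibble; `write_tsv_table()` returns
#'   `x` invisibly.
#' @export
read_tsv_table <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE))
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
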