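#' Filter PSMs on spectrum quality
#'
#' Retains peptide-spectrum matches that strictly exceed all three spectrum
#' quality thresholds: identification (ion) score, precursor
#' signal-to-background, and signal-to-interference. Boundary values are
#' rejected (strict inequalities).
#'
#' @param psms A data frame of PSMs with columns `identification_score`,
#'   `precursor_s2b` and `s2i`.
#' @param min_score Minimum ion score (exclusive). Default 15.
#' @param min_s2b Minimum precursor signal-to-background (exclusive). Default 4.
#' @param min_s2i Minimum signal-to-interference (exclusive). Default 0.5.
#' @return A tibble with the retained PSM rows (possibly zero rows).
#' @export
#' @examples
#' psms <- tibble::tibble(
#'   identification_score = c(16, 15, 40),
#'   precursor_s2b = c(5, 10, 3),
#'   s2i = c(0.6, 0.9, 0.9)
#' )
#' filter_psms(psms) # keeps only the first row
filter_psms <- function(psms, min_score = 15, min_s2b = 4, min_s2i = 0.5) {
  check_columns(psms, c("identification_score", "precursor_s2b", "s2i"), "PSM table")
  as_tibble(psms) |>
    filter(
      .data$identification_score > min_score,
      .data$precursor_s2b > min_s2b,
      .data$s2i > min_s2i
    )
}

#' Convert reporter intensities to ion areas
#'
#' Multiplies each reporter-ion intensity by the spectrum's ion accumulation
#' time (milliseconds), yielding a measure proportional to the number of ions
#' ("ion area"). Records with a non-positive accumulation time are rejected
#' with a warning since their areas are undefined.
#'
#' @param psms A data frame with an `accumulation_time` column and one
#'   intensity column per reporter channel.
#' @param channels Character vector naming the reporter intensity columns.
#' @return The input tibble with the channel columns replaced by ion areas;
#'   invalid records dropped.
#' @export
compute_ion_areas <- function(psms, channels) {
  check_columns(psms, c("accumulation_time", channels), "PSM table")
  psms <- as_tibble(psms)
  bad <- !is.finite(psms$accumulation_time) | psms$accumulation_time <= 0
  if (any(bad)) {
    warn(sprintf(
      "dropping %d PSM record(s) with non-positive ion accumulation time", sum(bad)
    ))
    psms <- psms[!bad, , drop = FALSE]
  }
  mutate(psms, across(all_of(channels), ~ .x * .data$accumulation_time))
}

#' Correct ion areas for isotope impurity of the labelling reagent
#'
#' Isobaric-tag reagents spill a known fraction of their signal into
#' neighbouring reporter channels. Given the mixing (purity) matrix P with
#' `observed = P %*% true`, this solves the linear system for the true
#' per-channel areas. Negative components of the solution are clipped to zero
#' with a warning.
#'
#' @param areas A numeric matrix (rows = spectra, columns = channels) or a
#'   data frame of channel columns.
#' @param purity Square numeric mixing matrix; rows index observed channels,
#'   columns true channels, entries are fractions.
#' @return Object of the same shape as `areas` with corrected values.
#' @export
correct_isotope_purity <- function(areas, purity) {
  purity <- as.matrix(purity)
  was_df <- is.data.frame(areas)
  a <- as.matrix(areas)
  if (ncol(a) != ncol(purity)) {
    abort("purity matrix dimension does not match the number of channels")
  }
  if (any(purity < 0) || any(purity > 1)) {
    abort("purity matrix entries must be fractions in [0, 1]")
  }
  solved <- tryCatch(
    t(solve(purity, t(a))),
    error = function(e) abort("purity matrix is singular; cannot correct isotope impurity")
  )
  n_neg <- sum(solved < 0)
  if (n_neg > 0) {
    warn(sprintf("isotope purity correction produced %d negative area(s); clipped to 0", n_neg))
    solved[solved < 0] <- 0
  }
  dimnames(solved) <- dimnames(a)
  if (was_df) as_tibble(as.data.frame(solved)) else solved
}

#' Adjust a fold change for co-isolation interference
#'
#' Models the observed reporter signal in each channel as a mixture of the
#' target peptide and co-eluting background:
#' `observed = s2i * true + (1 - s2i) * background`. With the reference
#' channel normalised, the observed ratio obeys the same mixture, so the true
#' ratio is recovered as `(observed - (1 - s2i) * background) / s2i`.
#'
#' @param fold_change Observed fold change (ratio scale).
#' @param s2i Signal-to-interference fraction in (0, 1]. Records with
#'   `s2i <= 0` are undefined and return `NA` with a warning.
#' @param background_ratio Assumed fold change of the co-isolated background;
#'   defaults to 1 (unregulated background).
#' @return De-mixed fold change; `NA` where undefined or where the de-mixed
#'   value would be negative.
#' @export
adjust_interference <- function(fold_change, s2i, background_ratio = 1) {
  out <- rep(NA_real_, length(fold_change))
  ok <- is.finite(fold_change) & is.finite(s2i) & s2i > 0 & s2i <= 1
  if (any(!ok & is.finite(s2i) & s2i <= 0)) {
    warn("excluding record(s) with signal-to-interference <= 0; adjustment undefined")
  }
  out[ok] <- (fold_change[ok] - (1 - s2i[ok]) * background_ratio) / s2i[ok]
  neg <- !is.na(out) & out < 0
  if (any(neg)) {
    warn(sprintf("%d interference-adjusted ratio(s) were negative; set to NA", sum(neg)))
    out[neg] <- NA_real_
  }
  out
}

#' Sum-based protein quantification with bootstrap confidence intervals
#'
#' Aggregates filtered PSM-level ion areas to per-protein relative abundances.
#' The point estimate for each channel is the ratio of per-channel ion-area
#' sums to the reference channel sum. 95% percentile confidence intervals are
#' obtained by resampling spectra with replacement; they are reported only for
#' proteins quantified with more than three spectra. Proteins with fewer than
#' `min_unique_peptides` unique peptide matches are dropped.
#'
#' @param psms Filtered PSM table with `protein_group`, `peptide_sequence`,
#'   `is_unique`, `accumulation_time` and the reporter channel columns.
#' @param channels Character vector of reporter intensity column names.
#' @param reference_channel Name of the reference channel (must be in
#'   `channels`).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed making CI endpoints reproducible.
#' @param min_unique_peptides Minimum unique peptide matches per protein
#'   (default 2).
#' @param areas_precomputed Set `TRUE` if the channel columns already contain
#'   ion areas rather than raw intensities.
#' @return A tibble with one row per protein x channel: `fold_change`,
#'   `ci_low`/`ci_high` (NA when spectral support <= 3), `n_spectra`,
#'   `n_unique_peptides` and a `flag` column marking undefined ratios.
#' @export
bootstrap_protein_quant <- function(psms, channels, reference_channel,
                                    n_boot = 1000, seed = NULL,
                                    min_unique_peptides = 2,
                                    areas_precomputed = FALSE) {
  check_columns(psms, c("protein_group", "peptide_sequence", "is_unique", channels),
                "PSM table")
  if (!reference_channel %in% channels) {
    abort("reference_channel must be one of the supplied channels")
  }
  if (nrow(psms) == 0) abort("at least one PSM is required")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (!areas_precomputed) psms <- compute_ion_areas(psms, channels)

  keep <- as_tibble(psms) |>
    group_by(.data$protein_group) |>
    filter(n_distinct(.data$peptide_sequence[.data$is_unique]) >= min_unique_peptides) |>
    ungroup()
  if (nrow(keep) == 0) {
    return(tibble(
      protein_group = character(), channel = character(),
      fold_change = double(), ci_low = double(), ci_high = double(),
      n_spectra = integer(), n_unique_peptides = integer(), flag = character()
    ))
  }

  quant_one <- function(df) {
    a <- as.matrix(df[, channels, drop = FALSE])
    n <- nrow(a)
    sums <- colSums(a)
    ref <- sums[[reference_channel]]
    fc <- if (ref > 0) sums / ref else rep(NA_real_, length(channels))
    ci_low <- ci_high <- rep(NA_real_, length(channels))
    if (n > 3 && ref > 0) {
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
      boot <- apply(idx, 1, function(i) {
        s <- colSums(a[i, , drop = FALSE])
        s / s[[reference_channel]]
      })
      ci <- apply(boot, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      ci_low <- ci[1, ]
      ci_high <- ci[2, ]
    }
    tibble(
      channel = channels,
      fold_change = unname(fc),
      ci_low = unname(ci_low),
      ci_high = unname(ci_high),
      n_spectra = n,
      n_unique_peptides = n_distinct(df$peptide_sequence[df$is_unique]),
      flag = if (ref > 0) NA_character_ else "zero_reference_sum"
    )
  }

  keep |>
    group_by(.data$protein_group) |>
    group_modify(~ quant_one(.x)) |>
    ungroup()
}
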