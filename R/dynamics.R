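#' Median-normalize log2 fold changes
#'
#' Centres the log2 fold-change distribution of every condition x pool x
#' replicate stratum at zero by subtracting its median. When a large part of
#' the nascent proteome is genuinely regulated (so its own median is not a
#' valid null reference), set `use_mature_factors_for_nascent = TRUE` to shift
#' nascent values by the normalization factor computed from the mature pool of
#' the same condition and replicate instead of their own.
#'
#' @param fold_changes Data frame with columns `condition`, `pool`
#'   (`"mature"`/`"nascent"`), `replicate`, `log2_fc`.
#' @param use_mature_factors_for_nascent Apply mature-pool factors to nascent
#'   values (default `FALSE`).
#' @return The table with `log2_fc` normalized.
#' @export
median_normalize <- function(fold_changes, use_mature_factors_for_nascent = FALSE) {
  check_columns(fold_changes, c("condition", "pool", "replicate", "log2_fc"),
                "fold-change table")
  tbl <- as_tibble(fold_changes)
  factors <- tbl |>
    group_by(.data$condition, .data$pool, .data$replicate) |>
    summarise(.shift = median(.data$log2_fc, na.rm = TRUE), .groups = "drop")
  if (use_mature_factors_for_nascent) {
    mature <- factors |>
      filter(.data$pool == "mature") |>
      select("condition", "replicate", .mature_shift = ".shift")
    factors <- factors |>
      left_join(mature, by = c("condition", "replicate")) |>
      mutate(.shift = if_else(.data$pool == "nascent" & !is.na(.data$.mature_shift),
                              .data$.mature_shift, .data$.shift)) |>
      select(-".mature_shift")
  }
  tbl |>
    left_join(factors, by = c("condition", "pool", "replicate")) |>
    mutate(log2_fc = .data$log2_fc - .data$.shift) |>
    select(-".shift")
}

#' Bin proteins by data quality
#'
#' Sorts proteins ascending by a quality key (the number of quantified
#' spectrum-sequence matches for the dynamics framework; the melting-curve
#' slope, shallowest first, for thermal-shift testing) and forms greedy
#' consecutive bins of at least `min_bin_size` proteins. The final remainder
#' is merged into the last bin so that every bin holds at least
#' `min_bin_size` members. With fewer than `min_bin_size` proteins in total a
#' single bin is returned with a warning. Ties in the key are broken by
#' protein identifier for reproducibility.
#'
#' @param proteins Data frame with columns `protein_group` and the key column.
#' @param min_bin_size Minimum proteins per bin (default 300).
#' @param key Name of the key column (default `"n_ssm"`).
#' @param descending Sort the key descending instead of ascending (used for
#'   slope binning where the shallowest slope is the largest value).
#' @return The input with an integer `bin` column appended.
#' @export
bin_by_ssm <- function(proteins, min_bin_size = 300, key = "n_ssm",
                       descending = FALSE) {
  check_columns(proteins, c("protein_group", key), "protein table")
  tbl <- as_tibble(proteins)
  n <- nrow(tbl)
  if (n == 0) abort("cannot bin an empty protein table")
  ord <- order(if (descending) -tbl[[key]] else tbl[[key]], tbl$protein_group)
  if (n < min_bin_size) {
    warn(sprintf("only %d proteins in total; using a single bin", n))
    tbl$bin <- 1L
    return(tbl)
  }
  n_bins <- n %/% min_bin_size
  bin_sorted <- pmin(((seq_len(n) - 1L) %/% min_bin_size) + 1L, n_bins)
  tbl$bin <- NA_integer_
  tbl$bin[ord] <- bin_sorted
  tbl
}

#' Robust standard deviation from replicate disagreement
#'
#' Estimates the measurement SD of a log2 fold change from the distribution
#' of differences between biological replicates. Each difference is divided
#' by sqrt(2) (the difference of two independent measurements has sqrt(2)
#' times their SD, and it equals the shortest distance of the replicate pair
#' to the equality line). The spread is summarised robustly as half the
#' distance between the 15.87 and 84.13 percentiles (+/- 1 SD under
#' normality) of the median-centred differences, with linear interpolation
#' between order statistics.
#'
#' @param rep1,rep2 Paired log2 fold changes of the same proteins in the two
#'   replicates. Alternatively pass the precomputed scaled differences as
#'   `rep1` and leave `rep2 = NULL`.
#' @return A single robust SD estimate.
#' @export
robust_sd <- function(rep1, rep2 = NULL) {
  d <- if (is.null(rep2)) rep1 else (rep1 - rep2) / sqrt(2)
  d <- d[is.finite(d)]
  if (length(d) < 2) abort("robust_sd needs at least 2 replicate pairs")
  d <- d - median(d)
  q <- quantile(d, probs = c(0.1587, 0.8413), names = FALSE, type = 7)
  (q[2] - q[1]) / 2
}

#' Two-sided Z-test p-value
#'
#' Gaussian two-sided tail probability of a log2 fold change given a (robust)
#' standard deviation of its null distribution.
#'
#' @param log2_fc Observed log2 fold change(s), assumed centred at zero under
#'   the null.
#' @param sd Standard deviation; must be strictly positive.
#' @return p-value(s) in (0, 1].
#' @export
z_test_p <- function(log2_fc, sd) {
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    abort("z_test_p requires a strictly positive standard deviation")
  }
  2 * pnorm(-abs(log2_fc / sd))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment applied to the pooled set of
#' p-values across all data-quality bins.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(is.finite(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Dual-replicate significance call
#'
#' A protein is called significantly regulated in a condition and pool iff
#' all three hold: the adjusted p-value is <= `alpha` in both replicates, the
#' absolute log2 fold change is strictly greater than `fc_threshold` in both
#' replicates, and the change has the same sign in both replicates. The
#' default threshold 0.37 corresponds to a 30% change (log2(1.30) truncated
#' to two decimals). Proteins with a missing replicate are flagged incomplete
#' and never called significant.
#'
#' @param calls Data frame with columns `log2_fc_rep1`, `log2_fc_rep2`,
#'   `adj_p_rep1`, `adj_p_rep2`.
#' @param fc_threshold Absolute log2 fold-change cutoff (exclusive), default
#'   0.37.
#' @param alpha Adjusted p-value cutoff (inclusive), default 0.05.
#' @return The table with logical `significant`, `incomplete`, and
#'   `direction` (`"up"`, `"down"`, `"none"`) columns appended.
#' @export
call_significant <- function(calls, fc_threshold = 0.37, alpha = 0.05) {
  check_columns(calls, c("log2_fc_rep1", "log2_fc_rep2", "adj_p_rep1", "adj_p_rep2"),
                "significance table")
  as_tibble(calls) |>
    mutate(
      incomplete = !is.finite(.data$log2_fc_rep1) | !is.finite(.data$log2_fc_rep2),
      significant = !.data$incomplete &
        .data$adj_p_rep1 <= alpha & .data$adj_p_rep2 <= alpha &
        abs(.data$log2_fc_rep1) > fc_threshold & abs(.data$log2_fc_rep2) > fc_threshold &
        sign(.data$log2_fc_rep1) == sign(.data$log2_fc_rep2),
      direction = case_when(
        .data$significant & .data$log2_fc_rep1 > 0 ~ "up",
        .data$significant & .data$log2_fc_rep1 < 0 ~ "down",
        TRUE ~ "none"
      )
    )
}

#' Replicate-based significance analysis of an mPDP fold-change table
#'
#' Runs the full significance framework on per-protein log2 fold changes from
#' two biological replicates: median normalization, binning by the number of
#' quantified spectrum-sequence matches (at least `min_bin_size` proteins per
#' bin), robust per-bin SD estimation from replicate disagreement, two-sided
#' Z-tests per replicate against the bin SD, Benjamini-Hochberg adjustment
#' over the full set (per condition, pool and replicate, jointly across
#' bins), and the dual-replicate significance call.
#'
#' Each protein's binning key is the smaller of its two replicate SSM counts,
#' so data quality is judged by the weaker replicate.
#'
#' @param fold_changes Data frame with columns `protein_group`, `condition`,
#'   `pool`, `replicate` (1 or 2), `log2_fc`, `n_ssm`.
#' @param fc_threshold,alpha Passed to [call_significant()].
#' @param min_bin_size Passed to [bin_by_ssm()].
#' @param use_mature_factors_for_nascent Passed to [median_normalize()].
#' @param normalize Set `FALSE` to skip median normalization.
#' @return A tibble with one row per protein x condition x pool carrying the
#'   normalized fold changes, bin, robust SD, raw and adjusted p-values per
#'   replicate, and the significance verdict.
#' @export
#' @examples
#' sim <- simulate_mpdp_experiment(n_proteins = 400, seed = 1)
#' fc <- psm_fold_changes(sim$psms, sim$design)
#' res <- mpdp_significance(fc)
#' table(res$significant)
mpdp_significance <- function(fold_changes, fc_threshold = 0.37, alpha = 0.05,
                              min_bin_size = 300,
                              use_mature_factors_for_nascent = FALSE,
                              normalize = TRUE) {
  check_columns(fold_changes,
                c("protein_group", "condition", "pool", "replicate", "log2_fc", "n_ssm"),
                "fold-change table")
  tbl <- as_tibble(fold_changes)
  if (normalize) {
    tbl <- median_normalize(tbl, use_mature_factors_for_nascent)
  }
  wide <- tbl |>
    mutate(replicate = as.integer(.data$replicate)) |>
    pivot_wider(
      id_cols = c("protein_group", "condition", "pool"),
      names_from = "replicate",
      values_from = c("log2_fc", "n_ssm"),
      names_glue = "{.value}_rep{replicate}"
    )
  for (col in c("log2_fc_rep1", "log2_fc_rep2", "n_ssm_rep1", "n_ssm_rep2")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  complete <- wide |>
    filter(is.finite(.data$log2_fc_rep1), is.finite(.data$log2_fc_rep2)) |>
    mutate(n_ssm = pmin(.data$n_ssm_rep1, .data$n_ssm_rep2))

  tested <- complete |>
    group_by(.data$condition, .data$pool) |>
    group_modify(function(df, key) {
      df <- bin_by_ssm(df, min_bin_size = min_bin_size)
      # degenerate noiseless bins (sd = 0): a zero fold change is maximally
      # null (p = 1), any non-zero one maximally extreme (p = 0)
      z_or_degenerate <- function(fc, s) {
        out <- as.double(fc == 0)
        ok <- is.finite(s) & s > 0
        out[ok] <- 2 * pnorm(-abs(fc[ok] / s[ok]))
        out
      }
      df |>
        group_by(.data$bin) |>
        mutate(bin_sd = robust_sd(.data$log2_fc_rep1, .data$log2_fc_rep2)) |>
        ungroup() |>
        mutate(
          p_rep1 = z_or_degenerate(.data$log2_fc_rep1, .data$bin_sd),
          p_rep2 = z_or_degenerate(.data$log2_fc_rep2, .data$bin_sd),
          adj_p_rep1 = bh_adjust(.data$p_rep1),
          adj_p_rep2 = bh_adjust(.data$p_rep2)
        )
    }) |>
    ungroup()

  incomplete <- wide |>
    filter(!is.finite(.data$log2_fc_rep1) | !is.finite(.data$log2_fc_rep2))
  out <- bind_rows(tested, incomplete) |>
    call_significant(fc_threshold = fc_threshold, alpha = alpha) |>
    arrange(.data$condition, .data$pool, .data$protein_group)
  out
}
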