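#' Protein decay-rate constant from a nascent/mature ratio time course
#'
#' Under steady-state turnover the nascent/mature ratio r(t) of a protein
#' after the medium switch satisfies log(r + 1) = k * t, so the decay-rate
#' constant is the through-origin least-squares slope of log(r + 1) on t:
#' `k = sum(log(r_i + 1) * t_i) / sum(t_i^2)`. Time points with an undefined
#' ratio are dropped from both sums.
#'
#' @param time_h Time points in hours (strictly positive).
#' @param ratio Nascent/mature fold-change ratio at each time point.
#' @return Decay rate in 1/h, or `NA` when no time point has a defined ratio.
#' @export
decay_rate <- function(time_h, ratio) {
  if (length(time_h) != length(ratio)) abort("time_h and ratio lengths differ")
  if (any(is.finite(time_h) & time_h <= 0)) abort("time points must be > 0")
  ok <- is.finite(time_h) & is.finite(ratio) & ratio >= 0
  if (!any(ok)) return(NA_real_)
  t <- time_h[ok]
  y <- log(ratio[ok] + 1)
  sum(y * t) / sum(t^2)
}

#' Correct a decay rate for dilution by cell division
#'
#' In dividing cells the apparent decay rate contains a dilution component
#' log(2) / t_cc from growth with cell-cycle time t_cc; subtracting it yields
#' the true degradation rate. Values at or below zero indicate turnover at or
#' below the dilution limit.
#'
#' @param k_dp Apparent decay rate (1/h).
#' @param t_cc Cell-cycle (doubling) time in hours; must be > 0. `Inf` for
#'   non-dividing cells returns `k_dp` unchanged.
#' @return Corrected decay rate in 1/h.
#' @export
cell_cycle_correct <- function(k_dp, t_cc) {
  if (any(!is.finite(t_cc) & !is.infinite(t_cc)) || any(t_cc <= 0)) {
    abort("cell-cycle time t_cc must be > 0")
  }
  k_dp - log(2) / t_cc
}

#' Protein half-life from a decay rate
#'
#' @param rate Decay rate in 1/h.
#' @return Half-life `log(2) / rate` in hours; `NA` (flagged undefined) for
#'   rates <= 0.
#' @export
half_life <- function(rate) {
  out <- log(2) / rate
  out[!is.finite(rate) | rate <= 0] <- NA_real_
  out
}

#' QC label for a half-life time course
#'
#' Designed for four-time-point courses: `"good"` when the fold changes at
#' three or more of the four time points rest on at least three quantified
#' peptides; `"weak"` when a fold change could be determined at three or more
#' time points but the good criterion fails; `"poor"` otherwise. Good takes
#' precedence over weak.
#'
#' @param ratio Nascent/mature ratios per time point (`NA` = undetermined).
#' @param n_peptides Quantified peptides backing each time point.
#' @param n_expected Number of designed time points (default 4).
#' @return One of `"good"`, `"weak"`, `"poor"`.
#' @export
qc_label <- function(ratio, n_peptides, n_expected = 4) {
  defined <- is.finite(ratio)
  n_defined <- sum(defined)
  n_strong <- sum(defined & n_peptides >= 3)
  need <- n_expected - 1
  if (n_strong >= need) "good" else if (n_defined >= need) "weak" else "poor"
}

#' Estimate turnover for every protein in a ratio time-course table
#'
#' Applies [decay_rate()], optional cell-division correction, half-life
#' computation and QC labelling per protein. The coefficient of
#' determination is computed for the model actually fitted — the
#' through-origin linear regression of log(r + 1) on t — using the uncentred
#' definition `R^2 = 1 - RSS / sum(y^2)`.
#'
#' @param time_courses Data frame with columns `protein_group`, `time_h`,
#'   `ratio`, `n_peptides`.
#' @param t_cc Optional cell-cycle time in hours for division correction; no
#'   default is assumed.
#' @param n_expected Designed number of time points for QC (default 4).
#' @return A tibble per protein with `k_dp`, `k_corrected` (NA if `t_cc` not
#'   given), `half_life` (from the corrected rate when available),
#'   `r_squared`, `qc`, and a `below_dilution` flag for corrected rates <= 0.
#' @export
#' @examples
#' tc <- tibble::tibble(
#'   protein_group = "P1", time_h = c(1, 2, 4, 8),
#'   ratio = exp(0.1 * c(1, 2, 4, 8)) - 1, n_peptides = c(5, 4, 6, 3)
#' )
#' estimate_turnover(tc)
estimate_turnover <- function(time_courses, t_cc = NULL, n_expected = 4) {
  check_columns(time_courses, c("protein_group", "time_h", "ratio", "n_peptides"),
                "time-course table")
  as_tibble(time_courses) |>
    group_by(.data$protein_group) |>
    summarise(
      k_dp = decay_rate(.data$time_h, .data$ratio),
      r_squared = {
        ok <- is.finite(.data$time_h) & is.finite(.data$ratio) & .data$ratio >= 0
        if (sum(ok) < 2) NA_real_ else {
          y <- log(.data$ratio[ok] + 1)
          t <- .data$time_h[ok]
          k <- sum(y * t) / sum(t^2)
          if (sum(y^2) == 0) 1 else 1 - sum((y - k * t)^2) / sum(y^2)
        }
      },
      qc = qc_label(.data$ratio, .data$n_peptides, n_expected),
      .groups = "drop"
    ) |>
    mutate(
      k_corrected = if (is.null(t_cc)) NA_real_ else cell_cycle_correct(.data$k_dp, t_cc),
      below_dilution = !is.null(t_cc) & is.finite(.data$k_corrected) & .data$k_corrected <= 0,
      half_life = half_life(if (is.null(t_cc)) .data$k_dp else .data$k_corrected)
    ) |>
    select("protein_group", "k_dp", "k_corrected", "half_life",
           "r_squared", "qc", "below_dilution")
}
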