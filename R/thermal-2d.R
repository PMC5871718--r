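# 2D-TPP dose-response analysis: direction calling, 0-1 transformation,
# sigmoidal EC50 fit and pEC50 validity.

#' Classify the direction of a dose-dependent stability change
#'
#' Based on the apparent stability (fold change relative to vehicle) at the
#' highest compound concentration: `> 3/2` is potentially stabilized,
#' `< 2/3` potentially destabilized, anything in between is not considered
#' further.
#'
#' @param concentration Compound concentrations (molar); vehicle = 0.
#' @param fold_change Fold changes relative to the vehicle abundance.
#' @return `"stabilized"`, `"destabilized"` or `"none"`.
#' @export
detect_direction <- function(concentration, fold_change) {
  ok <- is.finite(concentration) & is.finite(fold_change)
  if (!any(ok)) return("none")
  top <- fold_change[ok][which.max(concentration[ok])]
  if (top > 3 / 2) "stabilized" else if (top < 2 / 3) "destabilized" else "none"
}

#' Min-max transform fold changes to the unit interval
#'
#' Rescales a concentration series of fold changes so that with increasing
#' compound concentration they range from 0 to 1 for stabilized proteins and
#' from 1 to 0 for destabilized proteins (the same min-max map serves both,
#' since destabilized series decrease). Ties (flat series) map to the vehicle
#' endpoint, 0 for stabilized and 1 for destabilized.
#'
#' @param fold_change Fold changes of one protein's concentration series.
#' @param direction `"stabilized"` or `"destabilized"`.
#' @return Transformed values in \[0, 1\].
#' @export
transform_dose_response <- function(fold_change, direction) {
  rng <- range(fold_change, finite = TRUE)
  if (diff(rng) == 0) {
    return(rep(if (direction == "destabilized") 1 else 0, length(fold_change)))
  }
  (fold_change - rng[1]) / (rng[2] - rng[1])
}

#' Evaluate the dose-response model
#'
#' `Y = 1 / (1 + 10^((logEC50 - x) * slope))` with `x = log10(concentration)`.
#'
#' @param x log10 compound concentration (molar).
#' @param logec50 log10 of the EC50 (molar).
#' @param slope Hill-type slope.
#' @return Transformed apparent stability in (0, 1).
#' @export
dose_response_curve <- function(x, logec50, slope) {
  1 / (1 + 10^((logec50 - x) * slope))
}

#' Fit a sigmoidal dose-response curve and derive the pEC50
#'
#' Transforms a protein's apparent-stability fold changes to the unit
#' interval ([transform_dose_response()]) and fits the two-parameter
#' log-logistic model by nonlinear least squares on
#' `x = log10(concentration)`, excluding the vehicle point. The fit is
#' accepted when R^2 > `min_r2`. `pec50 = -logEC50`; it is flagged invalid
#' when the derived EC50 lies below the lowest non-vehicle concentration
#' tested, i.e. the midpoint would be extrapolated below the dose range.
#'
#' @param concentration Compound concentrations in molar (vehicle = 0
#'   allowed; it anchors the transformation but not the fit).
#' @param fold_change Fold changes relative to vehicle.
#' @param direction Optional; by default determined with
#'   [detect_direction()]. `"none"` yields an unfitted result.
#' @param min_r2 Acceptance threshold for R^2 (default 0.8, exclusive).
#' @param transformed Set `TRUE` when `fold_change` is already on the 0-1
#'   scale.
#' @return An object of class `dose_response_fit` with `direction`,
#'   `logec50`, `slope`, `r_squared`, `pec50`, `pec50_valid`, `accepted`,
#'   `converged` and the data; supports [tidy()], [glance()], [autoplot()].
#' @export
#' @examples
#' conc <- c(0, 0.1, 1, 5, 20) * 1e-6
#' y <- dose_response_curve(log10(pmax(conc, 1e-12)), -6, 1)
#' y[1] <- 0
#' fit <- fit_dose_response(conc, y, direction = "stabilized", transformed = TRUE)
#' glance(fit)
fit_dose_response <- function(concentration, fold_change, direction = NULL,
                              min_r2 = 0.8, transformed = FALSE) {
  ok <- is.finite(concentration) & is.finite(fold_change)
  concentration <- concentration[ok]
  fold_change <- fold_change[ok]
  if (is.null(direction)) direction <- detect_direction(concentration, fold_change)

  empty <- function(conv) {
    out <- list(direction = direction, logec50 = NA_real_, slope = NA_real_,
                r_squared = NA_real_, pec50 = NA_real_, pec50_valid = FALSE,
                accepted = FALSE, converged = conv,
                data = tibble(concentration = concentration, y = NA_real_))
    class(out) <- "dose_response_fit"
    out
  }
  if (direction == "none") return(empty(FALSE))

  y <- if (transformed) fold_change else transform_dose_response(fold_change, direction)
  nonveh <- concentration > 0
  df <- tibble(x = log10(concentration[nonveh]), y = y[nonveh])
  if (nrow(df) < 3) return(empty(FALSE))

  # start: midpoint from the x nearest 0.5; destabilized series decrease
  # with concentration, so their slope is negative
  start_ec <- df$x[which.min(abs(df$y - 0.5))]
  start_slope <- if (direction == "destabilized") -1 else 1
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 1 / (1 + 10^((logec50 - x) * slope)),
      data = df,
      start = list(logec50 = start_ec, slope = start_slope),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10, ptol = 1e-10)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(empty(FALSE))

  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((df$y - mean(df$y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  logec50 <- unname(cf["logec50"])
  min_conc <- min(concentration[nonveh])
  out <- list(
    direction = direction,
    logec50 = logec50,
    slope = unname(cf["slope"]),
    r_squared = r2,
    pec50 = -logec50,
    pec50_valid = 10^logec50 >= min_conc,
    accepted = r2 > min_r2,
    converged = TRUE,
    data = tibble(concentration = concentration, y = y)
  )
  class(out) <- "dose_response_fit"
  out
}

#' Fit dose-response curves for a table of proteins
#'
#' @param dose_table Data frame with columns `protein_group`,
#'   `concentration` (molar, vehicle = 0), `fold_change` (relative to
#'   vehicle).
#' @param min_r2 Passed to [fit_dose_response()].
#' @return A tibble with one row per protein: direction, fitted parameters,
#'   `pec50`, `pec50_valid`, `accepted`.
#' @export
fit_dose_responses <- function(dose_table, min_r2 = 0.8) {
  check_columns(dose_table, c("protein_group", "concentration", "fold_change"),
                "dose-response table")
  as_tibble(dose_table) |>
    group_by(.data$protein_group) |>
    group_modify(function(df, key) {
      glance(fit_dose_response(df$concentration, df$fold_change, min_r2 = min_r2))
    }) |>
    ungroup()
}
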