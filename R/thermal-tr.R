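# TPP-TR melting-curve model, fitting, and melting-point shift testing.

#' Evaluate the melting-curve model
#'
#' Three-parameter sigmoid describing the fraction of non-denatured protein
#' as a function of temperature:
#' `f(T) = (1 - plateau) / (1 + exp(b - a/T)) + plateau` (the `"stable"`
#' form, decreasing with temperature). `form = "printed"` evaluates the
#' alternative exponent `exp(-(a*T - b))`, which increases with temperature
#' and is provided only for comparison.
#'
#' @param temperature Temperatures in degrees Celsius.
#' @param a,b,plateau Model constants; `plateau` is the lower asymptote.
#' @param form `"stable"` (default) or `"printed"`.
#' @return Fraction non-denatured at each temperature.
#' @export
melt_curve <- function(temperature, a, b, plateau, form = c("stable", "printed")) {
  form <- match.arg(form)
  e <- if (form == "stable") exp(b - a / temperature) else exp(-(a * temperature - b))
  (1 - plateau) / (1 + e) + plateau
}

#' Closed-form melting point of the fitted curve
#'
#' The melting point Tm is the temperature at which the melting curve equals
#' 0.5. Solving `f(T) = 0.5` for the `"stable"` form gives
#' `Tm = a / (b - log(0.5 / (0.5 - plateau)))`. Tm is undefined (NA) when the
#' plateau is >= 0.5, i.e. the curve never crosses 0.5.
#'
#' @inheritParams melt_curve
#' @return Melting point in degrees Celsius, or `NA` when undefined.
#' @export
melting_tm <- function(a, b, plateau) {
  ifelse(
    plateau >= 0.5, NA_real_,
    a / (b - log(0.5 / (0.5 - plateau)))
  )
}

#' Fit a melting curve to one protein's fold changes
#'
#' Fits the three-parameter melting-curve model to fold changes relative to
#' the lowest temperature by bounded nonlinear least squares
#' (Levenberg-Marquardt). Initialization is deterministic multi-start:
#' plateau in \{0, 0.1, 0.3\}, with `a` and `b` from a logit-linear
#' regression of the transformed fold changes on 1/T. Derived quantities are
#' the melting point Tm (curve = 0.5), the slope at the inflection (steepest)
#' point within the measured temperature range, and R^2 against the data.
#'
#' @param temperature Temperatures (>= 5 points).
#' @param fold_change Fold changes relative to the lowest temperature.
#' @return An object of class `melting_fit` with elements `a`, `b`,
#'   `plateau`, `tm`, `min_slope`, `r_squared`, `converged` and the data;
#'   supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' temps <- seq(42, 64, length.out = 12)
#' y <- melt_curve(temps, a = 550, b = 10, plateau = 0.05)
#' fit <- fit_melting_curve(temps, y)
#' glance(fit)
fit_melting_curve <- function(temperature, fold_change) {
  ok <- is.finite(temperature) & is.finite(fold_change)
  temperature <- temperature[ok]
  fold_change <- fold_change[ok]
  if (length(temperature) < 5) abort("melting-curve fit needs at least 5 temperature points")
  df <- tibble(temperature = temperature, fold_change = fold_change)

  starts <- lapply(c(0, 0.1, 0.3), function(p0) {
    # logit-linear start: logit((y - p0)/(1 - p0)) = -(b - a/T)
    y <- pmin(pmax((fold_change - p0) / (1 - p0), 1e-3), 1 - 1e-3)
    z <- log(y / (1 - y))
    cf <- stats::coef(stats::lm(z ~ I(1 / temperature)))
    list(a = unname(cf[2]), b = unname(-cf[1]), plateau = p0)
  })

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fold_change ~ (1 - plateau) / (1 + exp(b - a / temperature)) + plateau,
        data = df,
        start = list(a = s$a, b = s$b, plateau = max(s$plateau, 1e-6)),
        lower = c(a = -Inf, b = -Inf, plateau = 0),
        upper = c(a = Inf, b = Inf, plateau = 1 - 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10, ptol = 1e-10)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }

  if (is.null(best)) {
    out <- list(a = NA_real_, b = NA_real_, plateau = NA_real_, tm = NA_real_,
                min_slope = NA_real_, r_squared = NA_real_, converged = FALSE,
                data = df)
    class(out) <- "melting_fit"
    return(out)
  }
  cf <- stats::coef(best$fit)
  a <- unname(cf["a"]); b <- unname(cf["b"]); plateau <- unname(cf["plateau"])
  tss <- sum((fold_change - mean(fold_change))^2)
  r2 <- if (tss > 0) 1 - best$rss / tss else 1
  slope_fun <- function(T) {
    e <- exp(b - a / T)
    -(1 - plateau) * e * (a / T^2) / (1 + e)^2
  }
  rng <- range(temperature)
  min_slope <- stats::optimize(slope_fun, interval = rng)$objective
  min_slope <- min(min_slope, slope_fun(rng[1]), slope_fun(rng[2]))
  out <- list(a = a, b = b, plateau = plateau,
              tm = melting_tm(a, b, plateau),
              min_slope = min_slope, r_squared = r2, converged = TRUE,
              data = df)
  class(out) <- "melting_fit"
  out
}

#' Fit melting curves for a table of proteins and experiments
#'
#' @param tr_table Data frame with columns `protein_group`, `group`
#'   (e.g. `"vehicle"`/`"treatment"`), `replicate`, `temperature`,
#'   `fold_change`.
#' @return A tibble with one row per protein x group x replicate carrying the
#'   fitted parameters, `tm`, `min_slope`, `r_squared` and `converged`.
#' @export
fit_melting_curves <- function(tr_table) {
  check_columns(tr_table,
                c("protein_group", "group", "replicate", "temperature", "fold_change"),
                "TR fold-change table")
  as_tibble(tr_table) |>
    group_by(.data$protein_group, .data$group, .data$replicate) |>
    group_modify(function(df, key) {
      f <- tryCatch(fit_melting_curve(df$temperature, df$fold_change),
                    error = function(e) NULL)
      if (is.null(f)) {
        tibble(a = NA_real_, b = NA_real_, plateau = NA_real_, tm = NA_real_,
               min_slope = NA_real_, r_squared = NA_real_, converged = FALSE)
      } else {
        glance(f)
      }
    }) |>
    ungroup()
}

#' Significance of compound-induced melting-point shifts
#'
#' Implements the replicate-based TPP-TR significance procedure. Proteins
#' enter the evaluation only when the vehicle and treatment curves of both
#' replicate pairs have R^2 > `min_r2` and the vehicle plateaus are
#' < `max_vehicle_plateau`. Per replicate pair, the melting-point difference
#' dTm = Tm(treatment) - Tm(vehicle) is tested with a Z-test against a robust
#' SD estimated within bins of proteins grouped by the pair's minimum
#' melting-curve slope (shallowest slope first, at least `min_bin_size`
#' proteins per bin), followed by Benjamini-Hochberg adjustment over the full
#' set. A shift is significant iff (i) one adjusted p-value is < 0.05 and the
#' other < 0.1, (ii) both pairs shift in the same direction, (iii) both
#' |dTm| exceed the melting-point difference between the two vehicle
#' controls, and (iv) the minimum slope in each pair is < `max_slope`.
#'
#' @param fits Output of [fit_melting_curves()] for two groups
#'   (`"vehicle"`, `"treatment"`) x two replicates per protein.
#' @param min_bin_size Minimum proteins per slope bin (default 300).
#' @param min_r2 Curve-fit R^2 filter (default 0.8, exclusive).
#' @param max_vehicle_plateau Vehicle plateau filter (default 0.3, exclusive).
#' @param max_slope Required steepness of the melting curves (default -0.06).
#' @return A tibble per protein with per-pair `dtm`, p-values, adjusted
#'   p-values, the vehicle-vehicle dTm, and the `significant` flag.
#' @export
tm_shift_significance <- function(fits, min_bin_size = 300, min_r2 = 0.8,
                                  max_vehicle_plateau = 0.3, max_slope = -0.06) {
  check_columns(fits,
                c("protein_group", "group", "replicate", "tm", "plateau",
                  "min_slope", "r_squared", "converged"),
                "melting-fit table")
  wide <- as_tibble(fits) |>
    filter(.data$group %in% c("vehicle", "treatment")) |>
    mutate(replicate = as.integer(.data$replicate)) |>
    pivot_wider(
      id_cols = "protein_group",
      names_from = c("group", "replicate"),
      values_from = c("tm", "plateau", "min_slope", "r_squared", "converged"),
      names_glue = "{.value}_{group}{replicate}"
    )
  needed <- as.vector(outer(c("tm", "plateau", "min_slope", "r_squared", "converged"),
                            c("vehicle1", "vehicle2", "treatment1", "treatment2"),
                            paste, sep = "_"))
  check_columns(wide, needed, "melting-fit table (after pairing)")

  eligible <- wide |>
    filter(
      .data$converged_vehicle1, .data$converged_vehicle2,
      .data$converged_treatment1, .data$converged_treatment2,
      .data$r_squared_vehicle1 > min_r2, .data$r_squared_vehicle2 > min_r2,
      .data$r_squared_treatment1 > min_r2, .data$r_squared_treatment2 > min_r2,
      .data$plateau_vehicle1 < max_vehicle_plateau,
      .data$plateau_vehicle2 < max_vehicle_plateau,
      is.finite(.data$tm_vehicle1), is.finite(.data$tm_vehicle2),
      is.finite(.data$tm_treatment1), is.finite(.data$tm_treatment2)
    ) |>
    mutate(
      dtm_1 = .data$tm_treatment1 - .data$tm_vehicle1,
      dtm_2 = .data$tm_treatment2 - .data$tm_vehicle2,
      dtm_vehicle = .data$tm_vehicle2 - .data$tm_vehicle1,
      pair_slope_1 = pmin(.data$min_slope_vehicle1, .data$min_slope_treatment1),
      pair_slope_2 = pmin(.data$min_slope_vehicle2, .data$min_slope_treatment2)
    )
  if (nrow(eligible) == 0) {
    return(mutate(eligible, p_1 = double(), p_2 = double(),
                  adj_p_1 = double(), adj_p_2 = double(),
                  significant = logical()))
  }

  test_pair <- function(df, dtm_col, slope_col) {
    keyed <- df |>
      select("protein_group", key = all_of(slope_col), dtm = all_of(dtm_col)) |>
      bin_by_ssm(min_bin_size = min_bin_size, key = "key", descending = TRUE)
    keyed |>
      group_by(.data$bin) |>
      mutate(p = {
        centred <- .data$dtm - median(.data$dtm)
        s <- robust_sd(centred)
        if (s > 0) z_test_p(centred, s) else as.double(centred == 0)
      }) |>
      ungroup() |>
      select("protein_group", "p")
  }
  p1 <- test_pair(eligible, "dtm_1", "pair_slope_1") |> rename(p_1 = "p")
  p2 <- test_pair(eligible, "dtm_2", "pair_slope_2") |> rename(p_2 = "p")

  eligible |>
    left_join(p1, by = "protein_group") |>
    left_join(p2, by = "protein_group") |>
    mutate(
      adj_p_1 = bh_adjust(.data$p_1),
      adj_p_2 = bh_adjust(.data$p_2),
      significant =
        ((.data$adj_p_1 < 0.05 & .data$adj_p_2 < 0.1) |
           (.data$adj_p_2 < 0.05 & .data$adj_p_1 < 0.1)) &
        sign(.data$dtm_1) == sign(.data$dtm_2) &
        abs(.data$dtm_1) > abs(.data$dtm_vehicle) &
        abs(.data$dtm_2) > abs(.data$dtm_vehicle) &
        .data$pair_slope_1 < max_slope &
        .data$pair_slope_2 < max_slope
    ) |>
    select("protein_group", "dtm_1", "dtm_2", "dtm_vehicle",
           "pair_slope_1", "pair_slope_2",
           "p_1", "p_2", "adj_p_1", "adj_p_2", "significant")
}
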