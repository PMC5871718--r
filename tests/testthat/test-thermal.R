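temps12 <- seq(42, 63.9, length.out = 12)

test_that("melting-curve fit recovers noiseless model parameters", {
  a <- 1200; b <- a / 52 + log(0.5 / 0.45); plateau <- 0.05
  y <- melt_curve(temps12, a, b, plateau)
  fit <- fit_melting_curve(temps12, y)
  expect_true(fit$converged)
  expect_equal(fit$a, a, tolerance = 1e-6)
  expect_equal(fit$b, b, tolerance = 1e-6)
  expect_equal(fit$plateau, plateau, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # the fitted curve evaluated at the derived melting point is 0.5
  expect_equal(melt_curve(fit$tm, fit$a, fit$b, fit$plateau), 0.5, tolerance = 1e-9)
  # invariance to temperature-point ordering
  o <- sample(12)
  fit2 <- fit_melting_curve(temps12[o], y[o])
  expect_equal(fit2$tm, fit$tm, tolerance = 1e-8)
})

test_that("Tm closed form: a/b at zero plateau, matches numerical root-finding, NA when unreachable", {
  expect_equal(melting_tm(1100, 1100 / 52, 0), 52)
  set.seed(20)
  for (i in 1:30) {
    tm <- runif(1, 45, 60)
    pl <- runif(1, 0, 0.4)
    a <- runif(1, 600, 1500)
    b <- a / tm + log(0.5 / (0.5 - pl))
    closed <- melting_tm(a, b, pl)
    numeric_tm <- uniroot(function(T) melt_curve(T, a, b, pl) - 0.5,
                          c(20, 100), tol = 1e-10)$root
    expect_equal(closed, numeric_tm, tolerance = 1e-6)
  }
  expect_true(is.na(melting_tm(1100, 21, 0.5)))
  expect_true(is.na(melting_tm(1100, 21, 0.7)))
})

test_that("printed exponent form rises with temperature while the stable form melts", {
  y_stable <- melt_curve(temps12, 1100, 1100 / 52, 0.05)
  expect_true(all(diff(y_stable) < 0))
  y_printed <- melt_curve(temps12, 0.3, 0.3 * 52, 0.05, form = "printed")
  expect_true(all(diff(y_printed) > 0))
})

test_that("dose-response direction thresholds are 3/2 and 2/3 at the top dose", {
  conc <- c(0, 0.1, 1, 5, 20) * 1e-6
  expect_equal(detect_direction(conc, c(1, 1, 1.2, 1.6, 2.0)), "stabilized")
  expect_equal(detect_direction(conc, c(1, 1, 1.1, 1.2, 1.2)), "none")
  expect_equal(detect_direction(conc, c(1, 0.9, 0.8, 0.6, 0.5)), "destabilized")
  expect_equal(detect_direction(conc, c(1, 1, 1, 1, 1.5)), "none") # boundary
})

test_that("dose-response fit recovers noiseless parameters and its midpoint is 0.5", {
  conc <- c(0, 0.1, 1, 5, 20) * 1e-6
  x <- log10(conc[-1])
  y <- c(0, dose_response_curve(x, -6, 1))
  fit <- fit_dose_response(conc, y, direction = "stabilized", transformed = TRUE)
  expect_true(fit$converged && fit$accepted)
  expect_equal(fit$logec50, -6, tolerance = 1e-6)
  expect_equal(fit$slope, 1, tolerance = 1e-6)
  expect_equal(fit$pec50, 6, tolerance = 1e-6)
  expect_true(fit$pec50_valid)
  expect_equal(dose_response_curve(fit$logec50, fit$logec50, fit$slope), 0.5)

  # destabilized series fit with negative slope, same midpoint property
  yd <- c(1, 1 - dose_response_curve(x, -6, 1))
  fitd <- fit_dose_response(conc, yd, direction = "destabilized", transformed = TRUE)
  expect_true(fitd$converged)
  expect_lt(fitd$slope, 0)
  expect_equal(fitd$logec50, -6, tolerance = 1e-5)

  # EC50 below the lowest tested concentration is flagged invalid
  y2 <- c(0, dose_response_curve(x, -7.5, 1))
  fit2 <- fit_dose_response(conc, y2, direction = "stabilized", transformed = TRUE)
  expect_false(fit2$pec50_valid)

  # direction "none" is never fitted
  flat <- fit_dose_response(conc, c(1, 1, 1.05, 1.02, 1.1))
  expect_equal(flat$direction, "none")
  expect_false(flat$converged)
})

test_that("full 2D pipeline (direction, transform, fit) handles untransformed fold changes", {
  truth <- tibble::tibble(
    protein_group = c("stab", "destab", "null"),
    direction = c("stabilized", "destabilized", "none"),
    logec50 = c(-6, -6.3, NA), slope = c(1, 1.2, NA)
  )
  tbl <- simulate_dose_response_table(truth, noise_sd = 0, seed = 1)
  fits <- fit_dose_responses(tbl)
  expect_equal(fits$direction[match(truth$protein_group, fits$protein_group)],
               truth$direction)
  stab <- fits[fits$protein_group == "stab", ]
  expect_true(stab$accepted)
  expect_equal(stab$pec50, 6, tolerance = 0.2)
})

test_that("pEC50 recovery: median absolute error < 0.1 log units under noise", {
  set.seed(21)
  conc <- c(0, 0.1, 1, 5, 20) * 1e-6
  x <- log10(conc[-1])
  true_ec <- seq(-6.8, -5.0, length.out = 40)
  err <- vapply(seq_along(true_ec), function(i) {
    y <- c(0, dose_response_curve(x, true_ec[i], 1) + rnorm(4, 0, 0.05))
    fit <- fit_dose_response(conc, y, direction = "stabilized", transformed = TRUE)
    abs(fit$pec50 - (-true_ec[i]))
  }, numeric(1))
  expect_lt(median(err, na.rm = TRUE), 0.1)
})

test_that("Tm-shift procedure controls the null and finds injected shifts", {
  # 650 proteins, 10 with a +3 degC shift in both replicate pairs
  n <- 650
  dtm <- c(rep(3, 10), rep(0, n - 10))
  sim <- simulate_tr_experiment(n_proteins = n, seed = 22, dtm = dtm,
                                noise_sd = 0.01)
  res <- run_thermal(sim$tr_table, min_bin_size = 300)
  shifted <- sprintf("P%05d", 1:10)
  hits <- res$shifts$protein_group[res$shifts$significant]
  expect_gte(sum(shifted %in% hits), 9)
  # false positives among the nulls stay at or below 5%
  null_calls <- setdiff(hits, shifted)
  expect_lte(length(null_calls) / (n - 10), 0.05)
  # recovered shifts match the injected magnitude
  d1 <- res$shifts$dtm_1[match(shifted, res$shifts$protein_group)]
  expect_equal(median(d1, na.rm = TRUE), 3, tolerance = 0.15)
})

test_that("Tm shifts in opposite directions or identical curves are never significant", {
  n <- 400
  sim <- simulate_tr_experiment(n_proteins = n, seed = 23, dtm = 0, noise_sd = 0.005)
  fits <- fit_melting_curves(sim$tr_table)
  # identical vehicle/treatment parameters: dtm centred at 0
  suppressWarnings(res <- tm_shift_significance(fits, min_bin_size = 300))
  expect_lte(mean(res$significant), 0.05)

  # a protein shifted +3 degC in pair 1 but -3 degC in pair 2 fails the
  # same-direction criterion even though both shifts are individually extreme
  fits2 <- fits
  i1 <- fits2$protein_group == "P00001" & fits2$group == "treatment" & fits2$replicate == 1
  i2 <- fits2$protein_group == "P00001" & fits2$group == "treatment" & fits2$replicate == 2
  fits2$tm[i1] <- fits2$tm[i1] + 3
  fits2$tm[i2] <- fits2$tm[i2] - 3
  suppressWarnings(res2 <- tm_shift_significance(fits2, min_bin_size = 300))
  expect_false(res2$significant[res2$protein_group == "P00001"])
})
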