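test_that("ion areas are intensity times accumulation time, and linear", {
  psms <- make_psms(n = 2, intensities = rbind(c(2e5, 1e4), c(0, 0)), acc = 50)
  areas <- compute_ion_areas(psms, c("ch01", "ch02"))
  expect_equal(areas$ch01, c(1e7, 0))
  expect_equal(areas$ch02, c(5e5, 0))

  # scaling all intensities by c scales areas by c and preserves ratios
  psms2 <- make_psms(n = 1, intensities = rbind(c(1e4, 2e4)), acc = 100)
  a2 <- compute_ion_areas(psms2, c("ch01", "ch02"))
  expect_equal(c(a2$ch01, a2$ch02), c(1e6, 2e6))
  psms3 <- psms2 |> dplyr::mutate(ch01 = ch01 * 7, ch02 = ch02 * 7)
  a3 <- compute_ion_areas(psms3, c("ch01", "ch02"))
  expect_equal(a3$ch02 / a3$ch01, a2$ch02 / a2$ch01)

  bad <- make_psms(n = 1, acc = 0)
  expect_warning(out <- compute_ion_areas(bad, c("ch01", "ch02")),
                 "accumulation time")
  expect_equal(nrow(out), 0)
})

test_that("PSM quality filters are strict inequalities at the printed thresholds", {
  psms <- make_psms(
    n = 6,
    score = c(16, 15, 40, 40, 40, 100),
    s2b = c(5, 10, 4, 10, 10, 50),
    s2i = c(0.6, 0.9, 0.9, 0.5, 0.51, 1.0)
  )
  kept <- filter_psms(psms)
  expect_setequal(kept$psm_id, c("s001", "s005", "s006"))

  # 10 records, 4 failing exactly one criterion each -> 6 retained
  psms10 <- make_psms(
    n = 10,
    score = c(rep(30, 6), 10, 12, 30, 30),
    s2b = c(rep(10, 6), 10, 10, 2, 10),
    s2i = c(rep(0.9, 6), 0.9, 0.9, 0.9, 0.3)
  )
  expect_equal(nrow(filter_psms(psms10)), 6)
  expect_equal(nrow(filter_psms(psms10[0, ])), 0)
})

test_that("isotope purity correction inverts forward mixing", {
  # identity leaves input unchanged
  a <- matrix(c(1, 2, 3, 4), nrow = 2)
  expect_equal(correct_isotope_purity(a, diag(2)), a)

  # 2-channel, 10% spill ch1 -> ch2: observed (0.9, 1.1) from true (1, 1)
  P <- matrix(c(0.9, 0.1, 0, 1), nrow = 2)
  expect_equal(
    as.vector(correct_isotope_purity(matrix(c(0.9, 1.1), nrow = 1), P)),
    c(1, 1)
  )

  # negative solution components are clipped to zero with a warning
  obs <- as.vector(P %*% c(1, -0.1))
  expect_warning(
    out <- correct_isotope_purity(matrix(obs, nrow = 1), P),
    "negative"
  )
  expect_equal(as.vector(out), c(1, 0))

  # property: correction o forward mixing = identity on random 4x4 systems,
  # checked against an independent dense linear solve
  set.seed(41)
  for (i in 1:20) {
    P4 <- diag(4) * 0.85
    spill <- matrix(runif(16, 0, 0.04), 4, 4)
    diag(spill) <- 0
    P4 <- P4 + spill
    true <- matrix(rlnorm(8, 10, 1), nrow = 2)
    obs <- t(P4 %*% t(true))
    expect_equal(correct_isotope_purity(obs, P4), true, tolerance = 1e-10)
    expect_equal(correct_isotope_purity(obs, P4), t(qr.solve(P4, t(obs))),
                 tolerance = 1e-10)
  }

  expect_error(correct_isotope_purity(a, matrix(0.5, 2, 2)), "singular")
  expect_error(correct_isotope_purity(a, diag(3)), "dimension")
})

test_that("interference adjustment inverts the linear mixing model", {
  expect_equal(adjust_interference(2.0, 1.0), 2.0)
  expect_equal(adjust_interference(1.0, 0.42), 1.0) # fixed point at background
  # forward-mix a true ratio of 2 at s2i 0.8, background 1, then invert
  mixed <- 0.8 * 2.0 + 0.2 * 1.0
  expect_equal(adjust_interference(mixed, 0.8), 2.0)
  expect_warning(out <- adjust_interference(2.0, 0), "interference")
  expect_true(is.na(out))
})

test_that("bootstrap protein quantification: point estimates, CI rules, reproducibility", {
  ch <- c("ch01", "ch02")
  # identical spectra: estimate equals common ratio, CI width zero
  psms <- make_psms(n = 5, intensities = matrix(rep(c(1e5, 2e5), each = 5), ncol = 2))
  q <- bootstrap_protein_quant(psms, ch, "ch01", n_boot = 50, seed = 1)
  r2 <- q[q$channel == "ch02", ]
  expect_equal(r2$fold_change, 2)
  expect_equal(r2$ci_low, 2)
  expect_equal(r2$ci_high, 2)

  # exactly 3 spectra: point estimate but no CI
  psms3 <- make_psms(n = 3, intensities = matrix(rep(c(1e5, 2e5), each = 3), ncol = 2))
  q3 <- bootstrap_protein_quant(psms3, ch, "ch01", n_boot = 50, seed = 1)
  expect_equal(q3$fold_change[q3$channel == "ch02"], 2)
  expect_true(all(is.na(q3$ci_low)))

  # < 2 unique peptides: protein dropped
  psms1pep <- make_psms(n = 4, peptides = rep("P1_pep1", 4))
  expect_equal(nrow(bootstrap_protein_quant(psms1pep, ch, "ch01")), 0)

  # point estimate invariant to PSM order and seed; CI reproducible by seed
  set.seed(7)
  noisy <- make_psms(n = 20, intensities = cbind(rlnorm(20, log(1e5), 0.4),
                                                 rlnorm(20, log(3e5), 0.4)))
  qa <- bootstrap_protein_quant(noisy, ch, "ch01", n_boot = 200, seed = 5)
  qb <- bootstrap_protein_quant(noisy[sample(20), ], ch, "ch01", n_boot = 200, seed = 99)
  expect_equal(qa$fold_change, qb$fold_change)
  qc <- bootstrap_protein_quant(noisy, ch, "ch01", n_boot = 200, seed = 5)
  expect_equal(qa$ci_low, qc$ci_low)
  expect_equal(qa$ci_high, qc$ci_high)
  # CI brackets the point estimate
  expect_true(all(qa$ci_low <= qa$fold_change & qa$fold_change <= qa$ci_high))
})

test_that("bootstrap CI covers the true ratio at roughly the nominal rate", {
  ch <- c("ch01", "ch02")
  true_ratio <- 2
  set.seed(11)
  covered <- vapply(1:60, function(i) {
    ints <- cbind(rlnorm(50, log(1e5), 0.5), rlnorm(50, log(1e5 * true_ratio), 0.5))
    psms <- make_psms(n = 50, intensities = ints)
    q <- bootstrap_protein_quant(psms, ch, "ch01", n_boot = 400, seed = i)
    r <- q[q$channel == "ch02", ]
    r$ci_low <= true_ratio && true_ratio <= r$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("SILAC protein ratio is the median of valid peptide ratios", {
  base <- tibble::tibble(
    protein_group = "P1",
    identification_score = 30, peptide_length = 10,
    lsq_fit_quality = 0.05, prior_ion_ratio = 0.1
  )
  tbl <- dplyr::bind_rows(
    dplyr::mutate(base, ratio = 2), dplyr::mutate(base, ratio = 2),
    dplyr::mutate(base, ratio = 2)
  )
  expect_equal(silac_protein_ratio(tbl)$ratio, 2)

  # undetermined ratios excluded when a positive ratio exists
  tbl2 <- dplyr::bind_rows(
    dplyr::mutate(base, ratio = 1), dplyr::mutate(base, ratio = 2),
    dplyr::mutate(base, ratio = NA_real_)
  )
  expect_equal(silac_protein_ratio(tbl2)$ratio, 1.5)

  expect_equal(
    silac_protein_ratio(dplyr::bind_rows(
      dplyr::mutate(base, ratio = 0.5), dplyr::mutate(base, ratio = 1),
      dplyr::mutate(base, ratio = 4)
    ))$ratio, 1
  )

  # invariance: peptides failing any filter never change the median
  failing <- dplyr::bind_rows(
    dplyr::mutate(base, ratio = 100, identification_score = 15),
    dplyr::mutate(base, ratio = 100, peptide_length = 5),
    dplyr::mutate(base, ratio = 100, lsq_fit_quality = 0.2),
    dplyr::mutate(base, ratio = 100, prior_ion_ratio = 0.3)
  )
  expect_equal(silac_protein_ratio(dplyr::bind_rows(tbl2, failing))$ratio, 1.5)

  # only undetermined ratios -> protein unquantified
  tbl3 <- dplyr::mutate(base, ratio = NA_real_)
  expect_true(is.na(silac_protein_ratio(tbl3)$ratio))
})

test_that("missing-abundance imputation uses half the experiment-wide minimum", {
  tbl <- tibble::tibble(
    protein_group = c("A", "A", "B", "B"),
    condition = c("veh", "drug", "veh", "drug"),
    abundance = c(0.5, 0.08, 0.3, NA)
  )
  out <- impute_missing_abundance(tbl)
  expect_equal(out$abundance[4], 0.04)
  expect_equal(out$imputed, c(FALSE, FALSE, FALSE, TRUE))

  # no missing cells -> unchanged
  full <- dplyr::mutate(tbl, abundance = 1:4 / 10)
  expect_equal(impute_missing_abundance(full)$abundance, full$abundance)

  # all missing cells get the same global value
  two <- dplyr::mutate(tbl, abundance = c(0.08, NA, 0.5, NA))
  out2 <- impute_missing_abundance(two)
  expect_equal(out2$abundance[c(2, 4)], c(0.04, 0.04))

  expect_error(impute_missing_abundance(dplyr::mutate(tbl, abundance = NA_real_)),
               "no detected")
})

test_that("donor consistency filter removes discordant and low-support proteins", {
  tbl <- tibble::tibble(
    protein_group = rep(c("A", "B", "C"), each = 4),
    condition = rep(c("veh", "veh", "drug", "drug"), 3),
    donor = rep(c(1, 2), 6),
    fold_change = c(0.1, 1.0, 0.5, 0.6,    # A: 10-fold apart in veh -> removed
                    0.5, 1.0, 0.8, 0.9,    # B: within 8-fold -> kept
                    0.5, 0.6, 0.7, 0.8),   # C: low support -> removed
    n_ssm = c(rep(5, 8), 2, 5, 5, 5)
  )
  out <- donor_consistency_filter(tbl)
  expect_setequal(unique(out$protein_group), "B")
})
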