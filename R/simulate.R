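# Seeded synthetic-data generators with known ground truth. These emulate
# the pulsed-SILAC + isobaric-tag experiment design: two biological
# replicates with opposite SILAC label orientation, one reporter channel per
# condition x replicate, exponential decay of the mature pool and saturating
# accumulation of the nascent pool after the medium switch, treatment effects
# acting multiplicatively on degradation and synthesis rates, per-spectrum
# lognormal reporter noise, and long-tailed spectral-count heterogeneity.
# All generators are pure functions of (configuration, seed).

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' True mature and nascent pool abundances over time
#'
#' After the medium switch at t = 0, the pre-existing (mature) pool of a
#' protein decays exponentially, `mature(t) = M0 * exp(-k t)`, while the
#' newly synthesized (nascent) pool accumulates towards its steady state,
#' `nascent(t) = (s / k) * (1 - exp(-k t))`. Treatment multipliers on the
#' degradation rate `k` and synthesis rate `s` act from t = 0. At steady
#' state (`s = k * M0`) the nascent/mature ratio is `exp(k t) - 1`, the
#' kinetics assumed by the decay-rate estimator.
#'
#' @param k Degradation rate (1/h), > 0.
#' @param s Synthesis rate (abundance units / h).
#' @param times Times in hours (>= 0).
#' @param M0 Mature pool abundance at t = 0; defaults to the steady state
#'   `s / k`.
#' @param k_mult,s_mult Treatment multipliers on `k` and `s` (default 1).
#' @return A tibble with `time_h`, `mature`, `nascent`.
#' @export
simulate_pools <- function(k, s, times, M0 = s / k, k_mult = 1, s_mult = 1) {
  if (any(k <= 0) || any(k_mult <= 0) || any(s_mult <= 0)) {
    abort("degradation rate and treatment multipliers must be > 0")
  }
  kk <- k * k_mult
  ss <- s * s_mult
  tibble(
    time_h = times,
    mature = M0 * exp(-kk * times),
    nascent = (ss / kk) * (1 - exp(-kk * times))
  )
}

#' Experiment design for a simulated mPDP run
#'
#' One isobaric reporter channel per condition x replicate; the two
#' biological replicates carry opposite SILAC label orientations (replicate
#' 1 switches light to heavy, so its mature pool is light; replicate 2 the
#' reverse).
#'
#' @param conditions Condition names; the first is the reference (vehicle).
#' @return A tibble with `channel`, `condition`, `replicate`, `mature_label`.
#' @export
mpdp_design <- function(conditions = c("vehicle", "treated")) {
  grid <- expand_grid(replicate = 1:2, condition = conditions)
  grid |>
    mutate(
      channel = sprintf("ch%02d", seq_len(nrow(grid))),
      mature_label = if_else(.data$replicate == 1L, "light", "heavy")
    ) |>
    select("channel", "condition", "replicate", "mature_label")
}

#' Protein parameter specifications for simulation
#'
#' Degradation rates are lognormal around a median half-life of
#' `t_half_median` hours; baseline abundances are lognormal; synthesis rates
#' are set to the steady state `s = k * M0`. Spectral counts follow a
#' negative-binomial-like long-tailed distribution (shifted by 1 so every
#' protein has at least one spectrum per SILAC label).
#'
#' @param n_proteins Number of proteins.
#' @param seed Integer seed.
#' @param t_half_median Median half-life in hours (default 20).
#' @param t_half_sdlog Lognormal spread of half-lives (default 0.8).
#' @param noise_sd_log2 Per-measurement reporter noise SD on the log2 scale
#'   (default 0.25).
#' @param ssm_mu,ssm_size Negative-binomial mean and dispersion for spectral
#'   counts per protein and SILAC label (defaults 12 and 1.2).
#' @return A tibble of per-protein parameters.
#' @export
sim_protein_specs <- function(n_proteins, seed = 1, t_half_median = 20,
                              t_half_sdlog = 0.8, noise_sd_log2 = 0.25,
                              ssm_mu = 12, ssm_size = 1.2) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  t_half <- rlnorm(n_proteins, log(t_half_median), t_half_sdlog)
  k <- log(2) / t_half
  M0 <- rlnorm(n_proteins, log(1e6), 1)
  tibble(
    protein_group = sprintf("P%05d", seq_len(n_proteins)),
    k = k,
    M0 = M0,
    s = k * M0,
    noise_sd_log2 = noise_sd_log2,
    ssm_mu = ssm_mu,
    ssm_size = ssm_size
  )
}

#' Simulate a complete mPDP experiment at the PSM level
#'
#' Generates a peptide-spectrum-match table with reporter intensities for a
#' label-swap duplicate design, together with the design, the protein
#' specifications and the ground-truth fold changes. Reporter intensity of a
#' spectrum in a given channel equals the true abundance of the pool that
#' the spectrum's SILAC label represents for that channel's replicate, under
#' that channel's condition, times multiplicative lognormal noise and a
#' per-spectrum ionization scale. Quality fields (ion score,
#' signal-to-background, signal-to-interference) are drawn from long-tailed
#' distributions so that a realistic fraction (roughly a fifth) of spectra
#' fails the quantification filters. Output is deterministic given the seed.
#'
#' @param n_proteins Number of simulated proteins (default 2000).
#' @param seed Integer seed.
#' @param time_h Treatment / labelling time in hours (default 6).
#' @param conditions Condition names, reference first.
#' @param effects Optional tibble (`protein_group`, `condition`, `k_mult`,
#'   `s_mult`) of treatment effects; multipliers default to 1.
#' @param specs Optional precomputed [sim_protein_specs()] table.
#' @param noise_sd_log2,ssm_mu,ssm_size Passed to [sim_protein_specs()].
#' @return A list with `psms` (the PSM table), `design`, `specs`, and
#'   `truth` (true log2 fold change per protein x condition x pool versus
#'   the reference condition).
#' @export
#' @examples
#' sim <- simulate_mpdp_experiment(n_proteins = 50, seed = 7)
#' head(sim$psms)
simulate_mpdp_experiment <- function(n_proteins = 2000, seed = 1, time_h = 6,
                                     conditions = c("vehicle", "treated"),
                                     effects = NULL, specs = NULL,
                                     noise_sd_log2 = 0.25,
                                     ssm_mu = 12, ssm_size = 1.2) {
  if (is.null(specs)) {
    specs <- sim_protein_specs(n_proteins, seed = seed,
                               noise_sd_log2 = noise_sd_log2,
                               ssm_mu = ssm_mu, ssm_size = ssm_size)
  }
  design <- mpdp_design(conditions)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed + 1L)

  mult <- expand_grid(protein_group = specs$protein_group, condition = conditions) |>
    mutate(k_mult = 1, s_mult = 1)
  if (!is.null(effects)) {
    check_columns(effects, c("protein_group", "condition"), "effects table")
    effects <- as_tibble(effects)
    if (!"k_mult" %in% names(effects)) effects$k_mult <- 1
    if (!"s_mult" %in% names(effects)) effects$s_mult <- 1
    mult <- mult |>
      left_join(effects, by = c("protein_group", "condition"),
                suffix = c("", ".eff")) |>
      mutate(
        k_mult = coalesce(.data$k_mult.eff, .data$k_mult),
        s_mult = coalesce(.data$s_mult.eff, .data$s_mult)
      ) |>
      select(-ends_with(".eff"))
  }

  # true pool abundances per protein x condition
  abund <- mult |>
    left_join(specs, by = "protein_group") |>
    mutate(
      mature = .data$M0 * exp(-.data$k * .data$k_mult * time_h),
      nascent = (.data$s * .data$s_mult / (.data$k * .data$k_mult)) *
        (1 - exp(-.data$k * .data$k_mult * time_h))
    ) |>
    select("protein_group", "condition", "mature", "nascent") |>
    pivot_longer(c("mature", "nascent"), names_to = "pool", values_to = "abundance")
  abund_key <- setNames(abund$abundance,
                        paste(abund$protein_group, abund$condition, abund$pool))

  # spectra: one block per protein x SILAC label
  n_ssm <- rnbinom(2 * nrow(specs), mu = specs$ssm_mu, size = specs$ssm_size) + 1L
  spec_idx <- rep(rep(seq_len(nrow(specs)), 2), n_ssm)
  psms <- tibble(
    protein_group = specs$protein_group[spec_idx],
    silac_channel = rep(rep(c("light", "heavy"), each = nrow(specs)), n_ssm)
  )
  n_psm <- nrow(psms)
  psms <- psms |>
    mutate(
      psm_id = sprintf("psm%07d", seq_len(n_psm)),
      peptide_sequence = sprintf("%s_pep%02d", .data$protein_group,
                                 sample.int(8, n_psm, replace = TRUE)),
      is_unique = runif(n_psm) < 0.9,
      identification_score = rgamma(n_psm, shape = 2.2, scale = 13),
      precursor_s2b = rlnorm(n_psm, log(10), 0.7),
      s2i = rbeta(n_psm, 8, 2),
      accumulation_time = runif(n_psm, 20, 100),
      peptide_length = sample(6:30, n_psm, replace = TRUE)
    )

  scale <- rlnorm(n_psm, 0, 0.5)
  noise_sd <- specs$noise_sd_log2[match(psms$protein_group, specs$protein_group)]
  for (i in seq_len(nrow(design))) {
    ch <- design$channel[i]
    pool <- if_else(psms$silac_channel == design$mature_label[i], "mature", "nascent")
    true_ab <- abund_key[paste(psms$protein_group, design$condition[i], pool)]
    noise <- if (all(noise_sd == 0)) 1 else 2^rnorm(n_psm, 0, noise_sd)
    psms[[ch]] <- unname(true_ab) * scale * noise
  }

  reference <- conditions[1]
  truth <- abund |>
    left_join(filter(abund, .data$condition == reference) |>
                select("protein_group", "pool", ref_abundance = "abundance"),
              by = c("protein_group", "pool")) |>
    mutate(true_log2_fc = log2(.data$abundance / .data$ref_abundance)) |>
    filter(.data$condition != reference) |>
    select("protein_group", "condition", "pool", "true_log2_fc")

  list(psms = psms, design = design, specs = specs, truth = truth)
}

#' Simulate nascent/mature ratio time courses for turnover estimation
#'
#' Courses follow the steady-state kinetics `r(t) = exp(k t) - 1` with
#' optional multiplicative lognormal noise applied to `r + 1` (so the
#' decay-rate estimator is unbiased in log space).
#'
#' @param specs A [sim_protein_specs()] table (uses `k`).
#' @param times Time points in hours (default `c(2, 6, 12, 24)`).
#' @param noise_sdlog SD of the lognormal noise on `r + 1` (default 0).
#' @param seed Integer seed.
#' @return A list with `courses` (`protein_group`, `time_h`, `ratio`,
#'   `n_peptides`) and `truth` (`protein_group`, `k`).
#' @export
simulate_turnover_courses <- function(specs, times = c(2, 6, 12, 24),
                                      noise_sdlog = 0, seed = 1) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  courses <- expand_grid(protein_group = specs$protein_group, time_h = times) |>
    left_join(select(specs, "protein_group", "k"), by = "protein_group") |>
    mutate(
      ratio = (exp(.data$k * .data$time_h) - 1 + 1) *
        exp(rnorm(n(), 0, noise_sdlog)) - 1,
      ratio = pmax(.data$ratio, 0),
      n_peptides = rnbinom(n(), mu = 6, size = 2) + 1L
    ) |>
    select(-"k")
  list(courses = courses, truth = select(specs, "protein_group", "k"))
}

#' Simulate a TPP-TR melting experiment
#'
#' Draws per-protein melting-curve parameters (melting points around 52 °C,
#' curve steepness passing the slope filter, small lower plateaus), applies
#' an optional treatment-induced melting-point shift, and emits fold changes
#' from the melting model plus Gaussian noise for a vehicle x treatment,
#' two-replicate design over 12 temperatures spanning 42.0-63.9 °C.
#'
#' @param n_proteins Number of proteins (default 1000).
#' @param seed Integer seed.
#' @param temperatures Temperatures in degrees Celsius.
#' @param dtm Per-protein true melting-point shift of the treatment curves in
#'   degrees Celsius; recycled (default 0, the null experiment).
#' @param noise_sd Gaussian noise SD on fold changes (default 0.01).
#' @return A list with `tr_table` (input for [fit_melting_curves()]) and
#'   `truth` (per-protein true parameters and Tm per group).
#' @export
simulate_tr_experiment <- function(n_proteins = 1000, seed = 1,
                                   temperatures = seq(42, 63.9, length.out = 12),
                                   dtm = 0, noise_sd = 0.01) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  dtm <- rep_len(dtm, n_proteins)
  truth <- tibble(
    protein_group = sprintf("P%05d", seq_len(n_proteins)),
    tm_vehicle = rnorm(n_proteins, 52, 2.5),
    a = runif(n_proteins, 800, 1500),
    plateau = runif(n_proteins, 0, 0.12),
    dtm = dtm
  ) |>
    mutate(
      b = .data$a / .data$tm_vehicle + log(0.5 / (0.5 - .data$plateau)),
      tm_treatment = .data$tm_vehicle + .data$dtm,
      b_treatment = .data$a / .data$tm_treatment + log(0.5 / (0.5 - .data$plateau))
    )

  grid <- expand_grid(
    protein_group = truth$protein_group,
    group = c("vehicle", "treatment"),
    replicate = 1:2,
    temperature = temperatures
  ) |>
    left_join(truth, by = "protein_group") |>
    mutate(
      fold_change = melt_curve(
        .data$temperature, .data$a,
        if_else(.data$group == "treatment", .data$b_treatment, .data$b),
        .data$plateau
      ) + rnorm(n(), 0, noise_sd)
    ) |>
    select("protein_group", "group", "replicate", "temperature", "fold_change")

  list(tr_table = grid, truth = truth)
}

#' Simulate 2D-TPP apparent-stability fold changes
#'
#' Per protein, apparent-stability fold changes versus compound
#' concentration are generated from the log-logistic dose-response model:
#' stabilized proteins rise from 1 at vehicle towards `fc_max`, destabilized
#' proteins fall towards `fc_min`, unaffected proteins stay flat; Gaussian
#' noise is added on the fold-change scale.
#'
#' @param truth A tibble with `protein_group`, `direction`
#'   (`"stabilized"`, `"destabilized"`, `"none"`), `logec50`, `slope`.
#' @param concentrations Non-vehicle concentrations in molar (default
#'   0.1, 1, 5, 20 micromolar); vehicle (0) is prepended automatically.
#' @param fc_max,fc_min Asymptotic fold changes (defaults 3 and 1/3).
#' @param noise_sd Gaussian noise SD (default 0.02).
#' @param seed Integer seed.
#' @return A tibble (`protein_group`, `concentration`, `fold_change`)
#'   suitable for [fit_dose_responses()].
#' @export
simulate_dose_response_table <- function(truth,
                                         concentrations = c(0.1, 1, 5, 20) * 1e-6,
                                         fc_max = 3, fc_min = 1 / 3,
                                         noise_sd = 0.02, seed = 1) {
  check_columns(truth, c("protein_group", "direction", "logec50", "slope"),
                "dose-response truth table")
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  expand_grid(protein_group = truth$protein_group,
              concentration = c(0, concentrations)) |>
    left_join(as_tibble(truth), by = "protein_group") |>
    mutate(
      y = if_else(.data$concentration > 0,
                  dose_response_curve(log10(.data$concentration),
                                      .data$logec50, .data$slope),
                  0),
      fold_change = case_when(
        .data$direction == "stabilized" ~ 1 + (fc_max - 1) * .data$y,
        .data$direction == "destabilized" ~ 1 - (1 - fc_min) * .data$y,
        TRUE ~ 1
      ) + rnorm(n(), 0, noise_sd)
    ) |>
    select("protein_group", "concentration", "fold_change")
}
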