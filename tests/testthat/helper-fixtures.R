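# fixture builders used across test files

# minimal PSM table with controllable quality fields and channel intensities
make_psms <- function(n = 4, protein = "P1", channels = c("ch01", "ch02"),
                      intensities = NULL, score = 30, s2b = 10, s2i = 0.9,
                      acc = 50, peptides = NULL, silac = "light") {
  psms <- tibble::tibble(
    psm_id = sprintf("s%03d", seq_len(n)),
    protein_group = protein,
    peptide_sequence = if (is.null(peptides)) {
      sprintf("%s_pep%d", protein, ((seq_len(n) - 1) %% 3) + 1)
    } else {
      peptides
    },
    is_unique = TRUE,
    silac_channel = silac,
    identification_score = score,
    precursor_s2b = s2b,
    s2i = s2i,
    accumulation_time = acc,
    peptide_length = 12
  )
  if (is.null(intensities)) {
    intensities <- matrix(1e5, nrow = n, ncol = length(channels))
  }
  for (j in seq_along(channels)) psms[[channels[j]]] <- intensities[, j]
  psms
}

# independent brute-force step-up oracle for BH adjustment
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# exhaustive hypergeometric enumeration for the two-sided Fisher p
fisher_oracle <- function(a, b, c_, d) {
  m <- a + c_       # annotated total
  n <- b + d        # not annotated
  k <- a + b        # class size
  x_range <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(x_range, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force through-origin least squares slope of y on t
origin_slope_oracle <- function(t, y) {
  unname(stats::coef(stats::lm(y ~ 0 + t))[1])
}
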