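# shared fixtures and helpers for the test suite

# a small valid TPM matrix whose columns sum to exactly 1e6
toy_tpm <- function(n_genes = 4, n_cells = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rexp(n_genes * n_cells), n_genes, n_cells)
  m <- sweep(m, 2, colSums(m), "/") * 1e6
  dimnames(m) <- list(sprintf("g%02d", seq_len(n_genes)),
                      sprintf("c%02d", seq_len(n_cells)))
  m
}

# simulation with the intron machinery switched off (faster where introns
# are irrelevant)
sim_no_introns <- function(seed, config = default_config()) {
  config$sim$n_nri <- 0L
  config$sim$n_background_introns <- 0L
  suppressMessages(simulate_experiment(config, seed = seed))
}

# full default simulation, messages silenced
sim_default <- function(seed, config = default_config()) {
  suppressMessages(simulate_experiment(config, seed = seed))
}

# run the in silico normalization, tolerating occasional marker dropout
# warnings (a marker can sample zero counts in one fraction of one cell at
# shallow depth; the mean-over-usable-markers path covers it)
insilico_quiet <- function(sim) {
  suppressWarnings(insilico_normalize(sim$cyt, sim$nuc, sim$qpcr))
}

# brute-force Pearson correlation straight from the definition
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - sum(x) / n) * (y - sum(y) / n))
  sxx <- sum((x - sum(x) / n)^2)
  syy <- sum((y - sum(y) / n)^2)
  sxy / sqrt(sxx * syy)
}

# sample sequences around a consensus (test-local copy, independent of the
# generator's sampler)
sample_splice_sites_for_test <- function(consensus, n, match_p) {
  cons <- strsplit(consensus, "")[[1]]
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    paste0(vapply(cons, function(b) {
      if (stats::runif(1) < match_p) b else sample(setdiff(bases, b), 1)
    }, ""), collapse = "")
  }, "")
}

# brute-force Mann-Whitney U statistic (pair counting with ties as 1/2)
u_oracle <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}
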