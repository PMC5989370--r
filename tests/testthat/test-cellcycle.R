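# expression whose log10(TPM + 1) equals a cosine of the cell's phase, so
# antiphase pairs correlate at exactly -1 after the transform
cosine_matrix <- function(theta, g1, g2, amp = 0.4, offset = 1) {
  vals <- lapply(c(stats::setNames(rep(0, length(g1)), g1),
                   stats::setNames(rep(pi, length(g2)), g2)),
                 function(ph) 10^(offset + amp * cos(theta + ph)) - 1)
  m <- do.call(rbind, vals)
  colnames(m) <- sprintf("c%02d", seq_along(theta))
  m
}

test_that("noise-free antiphase cosines give exact in/out-of-phase structure", {
  theta <- seq(0, 2 * pi, length.out = 13)[-13]
  m <- cosine_matrix(theta, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  pcm <- phase_correlation_matrix(m, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  expect_equal(pcm$mean_in_phase, 1, tolerance = 1e-12)
  expect_equal(pcm$mean_out_of_phase, -1, tolerance = 1e-12)
  expect_equal(unname(diag(pcm$matrix)), rep(1, 6), tolerance = 1e-12)
  expect_equal(pcm$matrix, t(pcm$matrix))
})

test_that("constant genes are excluded as NA without breaking the summary", {
  theta <- seq(0, 2 * pi, length.out = 9)[-9]
  m <- cosine_matrix(theta, c("a1", "a2"), c("b1", "b2"))
  m <- rbind(m, a3 = rep(10, ncol(m)))
  pcm <- phase_correlation_matrix(m, c("a1", "a2", "a3"), c("b1", "b2"))
  expect_true(all(is.na(pcm$matrix["a3", ])))
  expect_false(is.na(pcm$mean_in_phase))
  expect_error(phase_correlation_matrix(m[, 1:2], c("a1", "a2"), c("b1", "b2")),
               "3 cells")
  expect_error(phase_correlation_matrix(m, c("a1"), c("b1", "b2")), "at least 2 genes")
})

test_that("planted oscillation shows positive in-phase and negative out-of-phase means", {
  sim <- sim_no_introns(seed = 6)
  tr <- sim$truth
  for (mat in list(sim$cyt, sim$nuc)) {
    pcm <- phase_correlation_matrix(mat, tr$g1_genes, tr$g2_genes)
    expect_gt(pcm$mean_in_phase, 0)
    expect_lt(pcm$mean_out_of_phase, 0)
  }
})

test_that("compartment comparison matches a brute-force U oracle and detects shifts", {
  # 4 vs 4 toy: the statistic equals exhaustive pair counting
  x <- c(0.9, 0.1, 0.4, 0.35)
  y <- c(0.2, 0.3, 0.5, 0.05)
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(unname(wt$statistic), u_oracle(x, y))

  theta <- seq(0, 2 * pi, length.out = 13)[-13]
  g1 <- paste0("a", 1:4); g2 <- paste0("b", 1:4)
  set.seed(2)
  noisy <- function(shift = 0) {
    m <- cosine_matrix(theta, g1, g2)
    m * 10^matrix(stats::rnorm(length(m), 0, 0.05), nrow(m)) + shift
  }
  pcm1 <- phase_correlation_matrix(noisy(), g1, g2)
  cmp_null <- compare_compartments(pcm1, pcm1)
  expect_gt(cmp_null$p, 0.99)

  # push the nuclear out-of-phase values down by 0.2: stochastically smaller
  pcm2 <- pcm1
  g1n <- names(pcm2$phase)[pcm2$phase == "G1"]
  g2n <- names(pcm2$phase)[pcm2$phase == "G2"]
  pcm2$matrix[g1n, g2n] <- pcm2$matrix[g1n, g2n] - 0.2
  pcm2$matrix[g2n, g1n] <- t(pcm2$matrix[g1n, g2n])
  cmp <- compare_compartments(pcm1, pcm2, which = "out_of_phase")
  expect_lt(cmp$p, 0.01)
  expect_gt(mean(cmp$cyt_values), mean(cmp$nuc_values))
})

test_that("the cross-compartment matrix reduces to the within matrix on duplicates", {
  theta <- seq(0, 2 * pi, length.out = 11)[-11]
  g1 <- paste0("a", 1:3); g2 <- paste0("b", 1:3)
  set.seed(4)
  m <- cosine_matrix(theta, g1, g2) * 10^matrix(stats::rnorm(60, 0, 0.1), 6)
  within <- phase_correlation_matrix(m, g1, g2)
  cross <- cross_compartment_cellcycle_matrix(m, m, g1, g2)
  expect_equal(cross$matrix, within$matrix, tolerance = 1e-12)
  expect_error(cross_compartment_cellcycle_matrix(m[, 1, drop = FALSE],
                                                  m[, 1, drop = FALSE], g1, g2),
               "3 shared cells")
})

test_that("planted data give a positive in-phase and negative cross-phase block structure", {
  sim <- sim_no_introns(seed = 14)
  tr <- sim$truth
  x <- cross_compartment_cellcycle_matrix(sim$cyt, sim$nuc, tr$g1_genes, tr$g2_genes)
  expect_gt(x$mean_in_phase, x$mean_cross_phase)
  expect_gt(x$mean_in_phase, 0)
  expect_lt(x$mean_cross_phase, 0)
  # cross-compartment matrix need not be symmetric
  expect_false(isTRUE(all.equal(x$matrix, t(x$matrix))))
})

test_that("the phase score separates the planted poles and tracks the phase", {
  sim <- sim_no_introns(seed = 25)
  tr <- sim$truth
  ps <- phase_score(sim$nuc, tr$g1_genes, tr$g2_genes)
  # monotone in the cosine distance from the G2 pole (theta = pi)
  expect_gt(stats::cor(ps, -cos(tr$theta[names(ps)]), method = "spearman"), 0.8)
  # the cell nearest the G1 pole scores negative, nearest G2 positive
  expect_lt(ps[which.max(cos(tr$theta))], 0)
  expect_gt(ps[which.min(cos(tr$theta))], 0)
})

test_that("the phase score is zero at the symmetric phase and balanced overall", {
  theta <- seq(0, 2 * pi, length.out = 9)[-9]  # includes pi/2 and 3*pi/2
  m <- cosine_matrix(theta, c("a1", "a2"), c("b1", "b2"))
  s <- phase_score(m, c("a1", "a2"), c("b1", "b2"))
  # cells at theta = pi/2 and 3*pi/2 sit between the poles: score ~ 0
  sym <- which(abs(cos(theta)) < 1e-12)
  expect_equal(unname(s[sym]), rep(0, length(sym)), tolerance = 1e-12)
  # scores at the two poles are opposite and equal in magnitude
  expect_equal(unname(s[which.max(cos(theta))]),
               -unname(s[which.min(cos(theta))]), tolerance = 1e-12)
})
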