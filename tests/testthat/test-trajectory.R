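test_that("duplicating the compartments reproduces conventional PCA scaled by sqrt(2)", {
  set.seed(4)
  x <- matrix(10^stats::rnorm(20 * 12, 1, 0.5), 20, 12,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:12)))
  pc <- conventional_pca(x)
  lp <- lpca(x, x, rownames(x))
  expect_equal(lp$explained_variance, pc$explained_variance, tolerance = 1e-10)
  for (j in 1:5) {
    s <- sign(sum(pc$scores[, j] * lp$scores[, j]))
    expect_equal(lp$scores[, j] * s, sqrt(2) * pc$scores[, j], tolerance = 1e-8)
  }
})

test_that("explained variance ratios sum to one and are non-increasing", {
  sim <- sim_no_introns(seed = 2)
  lp <- suppressWarnings(lpca(sim$cyt, sim$nuc, rownames(sim$cyt)[1:100]))
  expect_equal(sum(lp$explained_variance), 1, tolerance = 1e-12)
  expect_true(all(diff(lp$explained_variance) <= 1e-12))
})

test_that("orthogonal compartment signals are captured by the first two PCs", {
  set.seed(4)
  m <- 40
  t1 <- seq(-1, 1, length.out = m)
  t2 <- rep(c(-1, 1), length.out = m)
  cyt <- outer(stats::rexp(15), t1) + matrix(stats::rnorm(15 * m, 0, 0.01), 15)
  nuc <- outer(stats::rexp(15), t2) + matrix(stats::rnorm(15 * m, 0, 0.01), 15)
  dimnames(cyt) <- dimnames(nuc) <- list(sprintf("g%02d", 1:15), sprintf("c%02d", 1:m))
  lp <- lpca(cyt, nuc, rownames(cyt), log = FALSE)
  cors <- abs(stats::cor(cbind(t1, t2), lp$scores[, 1:2]))
  # each signal is tracked by exactly one of the first two PCs
  expect_gt(max(cors["t1", ]), 0.95)
  expect_gt(max(cors["t2", ]), 0.95)
  expect_false(which.max(cors["t1", ]) == which.max(cors["t2", ]))
})

test_that("PCA agrees with a direct eigen-decomposition of the covariance", {
  set.seed(6)
  x <- matrix(stats::rexp(10 * 8, 0.1), 10, 8,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("c%d", 1:8)))
  pc <- conventional_pca(x)
  lx <- log10(t(x) + 1)
  ev <- eigen(stats::cov(lx))
  scores <- scale(lx, center = TRUE, scale = FALSE) %*% ev$vectors
  k <- min(ncol(pc$scores), 7)
  for (j in 1:k) {
    s <- sign(sum(scores[, j] * pc$scores[, j]))
    expect_equal(pc$scores[, j], s * scores[, j], tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("degenerate PCA inputs error or drop constant features", {
  x <- matrix(5, 4, 6, dimnames = list(letters[1:4], sprintf("c%d", 1:6)))
  expect_error(conventional_pca(x), "constant")
  expect_error(conventional_pca(x[, 1:2]), "3 cells")
  y <- toy_tpm(4, 6)
  y[1, ] <- 7
  expect_warning(pc <- conventional_pca(y), "constant feature")
  expect_false("g01" %in% pc$features)
  expect_error(lpca(y, y, rownames(y)[1]), "2 genes")
})

test_that("fallback pseudotime recovers a planted trajectory and reverses exactly", {
  cfg <- default_config()
  cfg$sim$trajectory <- TRUE
  sim <- sim_no_introns(seed = 11, cfg)
  res <- suppressWarnings(insilico_normalize(sim$cyt, sim$nuc, sim$qpcr))
  ref <- names(sim$truth$day)[sim$truth$day == 0]
  # ordered along the trajectory-informative genes, as in real use
  pt <- fallback_pseudotime(res$tpm_insilico, genes = sim$truth$degs$gene_id,
                            reference_cells = ref)
  rho <- stats::cor(pt$pseudotime, sim$truth$tau[pt$cell_id], method = "spearman")
  expect_gte(rho, 0.8)
  # reference cells anchor the origin
  expect_lt(mean(pt$rank[pt$cell_id %in% ref]), mean(pt$rank))
  rev <- fallback_pseudotime(res$tpm_insilico, genes = sim$truth$degs$gene_id,
                             reference_cells = ref, reverse = TRUE)
  expect_identical(rev$rank, max(pt$rank) - pt$rank)
  expect_setequal(pt$rank, seq_len(nrow(pt)) - 1L)
})

test_that("cell cross-correlation matches hand-computed Pearson on a 3-cell toy", {
  genes <- c("g1", "g2", "g3", "g4")
  nuc <- matrix(c(1, 5, 20, 3,
                  9, 2, 14, 8,
                  4, 4, 4, 30), 4, 3,
                dimnames = list(genes, c("x", "y", "z")))
  cyt <- matrix(c(2, 6, 18, 2,
                  10, 1, 16, 6,
                  5, 3, 6, 28), 4, 3,
                dimnames = list(genes, c("x", "y", "z")))
  ord <- data.frame(cell_id = c("x", "y", "z"), rank = 0:2)
  ccm <- cell_cross_correlation(nuc, cyt, genes, ord)
  for (i in 1:3) for (j in 1:3) {
    want <- pearson_oracle(log10(nuc[, i] + 1), log10(cyt[, j] + 1))
    expect_equal(ccm[i, j], want, tolerance = 1e-12)
  }
  # identical matrices: unit diagonal
  ccm2 <- cell_cross_correlation(nuc, nuc, genes, ord)
  expect_equal(unname(diag(ccm2)), rep(1, 3), tolerance = 1e-12)
  expect_error(cell_cross_correlation(nuc, cyt, genes[1:2], ord), "3 genes")
})

test_that("permuting the ordering permutes rows and columns together", {
  sim <- sim_no_introns(seed = 3)
  genes <- rownames(sim$nuc)[1:50]
  ord <- sim$pseudotime
  ccm <- cell_cross_correlation(sim$nuc, sim$cyt, genes, ord)
  set.seed(1)
  perm <- sample(nrow(ord))
  ord2 <- ord
  ord2$rank <- order(perm) - 1L  # reassign ranks arbitrarily
  ccm2 <- cell_cross_correlation(sim$nuc, sim$cyt, genes, ord2)
  cells2 <- rownames(ccm2)
  expect_equal(ccm2, ccm[cells2, cells2], ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("pseudotime binning follows the remainder-to-last rule", {
  ccm <- matrix(1, 10, 10)
  expect_identical(bin_and_summarize(ccm, 5)$sizes, rep(2L, 5))
  ccm <- matrix(1, 11, 11)
  bs <- bin_and_summarize(ccm, 5)
  expect_identical(bs$sizes, c(2L, 2L, 2L, 2L, 3L))
  # constant matrix: all block means equal
  expect_true(all(bs$grid == 1))
  expect_error(bin_and_summarize(ccm, 12), "invalid number of bins")
})

test_that("corner asymmetry is zero on symmetric matrices and errors for k = 1", {
  set.seed(2)
  a <- matrix(stats::runif(100), 10, 10)
  sym <- (a + t(a)) / 2
  ca <- corner_asymmetry(sym, k = 5, n_bootstrap = 50, seed = 1)
  expect_equal(ca$difference, 0, tolerance = 1e-12)
  expect_error(corner_asymmetry(sym, k = 1), "2 bins")
  # bootstrap is reproducible under a fixed seed
  ca2 <- corner_asymmetry(sym, k = 5, n_bootstrap = 50, seed = 1)
  expect_identical(ca$bootstrap, ca2$bootstrap)
  expect_identical(ca$p, ca2$p)
})

test_that("correlation decline requires at least 3 bins", {
  sim <- sim_no_introns(seed = 3)
  expect_error(correlation_decline(sim$nuc, sim$cyt, rownames(sim$nuc)[1:10],
                                   NULL, sim$pseudotime, k = 2), "3 bins")
})

test_that("an externally supplied ordering is honoured end to end", {
  sim <- sim_no_introns(seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(cell_id = colnames(sim$nuc),
                                pseudotime = seq_len(ncol(sim$nuc))),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  ord <- read_pseudotime(path)
  ccm <- cell_cross_correlation(sim$nuc, sim$cyt, rownames(sim$nuc)[1:20], ord)
  expect_identical(rownames(ccm), colnames(sim$nuc))
})
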