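test_that("intron FPKM follows the per-kilobase per-million definition", {
  expect_equal(intron_fpkm(10, 1000, 1e6), 10)
  expect_equal(intron_fpkm(0, 700, 3e6), 0)
  expect_equal(intron_fpkm(5, 500, 2e6), 5)
})

test_that("classification applies the retained/spliced/discard thresholds exactly", {
  cases <- data.frame(
    fpkm      = c(0.15, 0.005, 0.15, 0.10, 0.01,  0.15,  0.15,  0.005, 0.005, 0.15, 0.099, 0.005) * 5,
    icov      = c(0.96, 0.10,  0.96, 0.96, 0.10,  0.95,  0.949, 0.10,  0.10,  0.96, 0.96,  0.10),
    exon_expr = c(5,    5,     5,    5,    5,     5,     5,     5,     0,     0,    5,     5),
    exon_cov  = c(0.8,  0.60,  0.8,  0.8,  0.60,  0.8,   0.8,   0.50,  0.49,  0.8,  0.8,   0.8),
    gene_tpm  = c(5,    5,     1.5,  5,    5,     5,     5,     2,     5,     5,    5,     5)
  )
  want <- c("retained",   # the canonical retained observation
            "spliced",    # the canonical spliced observation
            "discarded",  # host gene under 2 TPM discards everything
            "retained",   # ratio exactly at the 10% bound (inclusive)
            "discarded",  # ratio exactly 1%: not spliced (strict <)
            "retained",   # intron coverage exactly 95% (inclusive)
            "discarded",  # intron coverage just below 95%
            "spliced",    # gene at exactly 2 TPM is assessable; exon cov at bound
            "discarded",  # exon coverage below 50%: not spliced
            "discarded",  # zero adjacent-exon expression blocks retained
            "discarded",  # ratio between 1% and 10%: neither rule
            "spliced")
  # note: fpkm is ratio * gene_tpm except where gene_tpm differs; recompute
  cases$fpkm <- c(0.15, 0.005, 0.15, 0.10, 0.01, 0.15, 0.15, 0.005, 0.005, 0.15, 0.099, 0.005) *
    cases$gene_tpm
  got <- classify_intron(cases$fpkm, cases$icov, cases$exon_expr,
                         cases$exon_cov, cases$gene_tpm)
  expect_identical(got, want)
  expect_error(classify_intron(1, 0.9, 1, 0.5, NA_real_, gene_id = "GENEX"), "GENEX")
})

test_that("raising intron FPKM never moves a call from retained to spliced", {
  set.seed(12)
  for (i in 1:200) {
    icov <- stats::runif(1)
    exon_expr <- sample(c(0, stats::runif(1, 0, 10)), 1)
    exon_cov <- stats::runif(1)
    gene <- stats::runif(1, 0, 10)
    f <- sort(stats::runif(2, 0, 2 * gene))
    s_lo <- classify_intron(f[1], icov, exon_expr, exon_cov, gene)
    s_hi <- classify_intron(f[2], icov, exon_expr, exon_cov, gene)
    expect_false(s_lo == "retained" && s_hi == "spliced")
    expect_false(s_lo == "retained" && s_hi == "discarded" && gene >= 2)
  }
})

test_that("retention probability uses the assessable-cell denominator", {
  calls <- data.frame(
    intron_id = "i1",
    cell_id = sprintf("c%02d", 1:10),
    compartment = "nuc",
    state = c(rep("retained", 6), rep("spliced", 4))
  )
  expect_equal(retention_probability(calls)$p_nuc, 0.6)

  calls$state <- c(rep("retained", 3), rep("spliced", 2), rep("discarded", 5))
  expect_equal(retention_probability(calls)$p_nuc, 0.6)
  expect_equal(retention_probability(calls, denominator = "all")$p_nuc, 0.3)

  calls$state <- rep("discarded", 10)
  expect_true(is.na(retention_probability(calls)$p_nuc))
})

test_that("NRI/CRI calling is inclusive at the 0.25 boundary", {
  expect_identical(call_nri_cri(0.8, 0.4), "NRI")
  expect_identical(call_nri_cri(0.5, 0.4), "neither")
  expect_identical(call_nri_cri(0.65, 0.40), "NRI")
  expect_identical(call_nri_cri(0.40, 0.65), "CRI")
  expect_identical(call_nri_cri(c(0.9, NA), c(0.1, 0.5)), c("NRI", NA))
})

test_that("overlap filtering keeps the longest intron and resolves chains greedily", {
  nris <- data.frame(
    intron_id = c("A", "B"),
    chrom = "chr1", strand = "+",
    start = c(100, 150), end = c(500, 300)
  )
  got <- filter_unique(nris)
  expect_identical(got$unique, c(TRUE, FALSE))

  # non-overlapping introns both survive
  nris$start <- c(100, 600); nris$end <- c(500, 900)
  expect_true(all(filter_unique(nris)$unique))

  # chain: A overlaps B, B overlaps C, A and C disjoint, len A > C > B
  chain <- data.frame(
    intron_id = c("A", "B", "C"),
    chrom = "chr1", strand = "+",
    start = c(100, 480, 550), end = c(500, 560, 700)
  )
  got <- filter_unique(chain)
  expect_identical(got$unique, c(TRUE, FALSE, TRUE))

  # different strand or chromosome never conflicts
  chain$strand <- c("+", "-", "+")
  got <- filter_unique(chain)
  expect_identical(got$unique[got$intron_id == "B"], TRUE)
})

test_that("overlap filtering is invariant to input order", {
  set.seed(3)
  nris <- data.frame(
    intron_id = sprintf("i%02d", 1:30),
    chrom = sample(c("chr1", "chr2"), 30, TRUE),
    strand = sample(c("+", "-"), 30, TRUE),
    start = sample(1:2000, 30)
  )
  nris$end <- nris$start + sample(50:800, 30)
  ref <- filter_unique(nris)
  ref <- ref[order(ref$intron_id), ]
  for (i in 1:5) {
    perm <- nris[sample(nrow(nris)), ]
    got <- filter_unique(perm)
    got <- got[order(got$intron_id), ]
    expect_identical(got$unique, ref$unique)
  }
})

test_that("the full NRI pipeline recovers planted introns from a simulation", {
  sim <- sim_default(seed = 13)
  calls <- classify_table(sim$intron_quant, sim$cyt, sim$nuc)
  nri <- suppressMessages(nri_table(calls, sim$intron_annotation))
  m <- merge(nri, sim$truth$introns[, c("intron_id", "class")],
             by = "intron_id", suffixes = c("", ".true"))
  called <- !is.na(m$class) & m$class == "NRI"
  truth <- m$class.true == "NRI"
  expect_gte(sum(called & truth) / sum(truth), 0.85)
  expect_gte(sum(called & truth) / sum(called), 0.85)
})

test_that("NRI-expression coupling is recovered in the nucleus and absent in the cytoplasm", {
  # aggregate over a few generated experiments: the cytoplasmic side is a
  # planted null, so its correlation fluctuates around zero
  r_nuc <- r_cyt <- p_nuc <- numeric(3)
  for (i in 1:3) {
    sim <- sim_default(seed = i)
    calls <- classify_table(sim$intron_quant, sim$cyt, sim$nuc)
    nri <- suppressMessages(nri_table(calls, sim$intron_annotation))
    nn <- suppressMessages(nri_expression_correlation(calls, sim$nuc, nri, "nuc"))
    nc <- suppressMessages(nri_expression_correlation(calls, sim$cyt, nri, "cyt"))
    r_nuc[i] <- nn$r; p_nuc[i] <- nn$p; r_cyt[i] <- nc$r
  }
  expect_true(all(r_nuc > 0))
  expect_true(all(p_nuc < 0.05))
  expect_lt(mean(abs(r_cyt)), 0.15)
  expect_lt(mean(abs(r_cyt)), mean(r_nuc))
})

test_that("a single usable intron cannot be correlated", {
  calls <- data.frame(
    intron_id = "i1", cell_id = sprintf("c%d", 1:8), compartment = "nuc",
    state = rep(c("retained", "spliced"), each = 4)
  )
  expr <- matrix(10, 1, 8, dimnames = list("gA", sprintf("c%d", 1:8)))
  nris <- data.frame(intron_id = "i1", gene_id = "gA", class = "NRI",
                     p_nuc = 0.5, p_cyt = 0.1)
  expect_error(suppressMessages(nri_expression_correlation(calls, expr, nris, "nuc")),
               "at least 2 introns")
})
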