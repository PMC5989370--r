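## resolve phase gene sets against a matrix: genes missing from the matrix
## are dropped with a warning; fewer than 2 genes left in a set is an error
resolve_phase_sets <- function(mat, g1_genes, g2_genes) {
  if (length(intersect(g1_genes, g2_genes)) > 0)
    stop("G1 and G2 gene sets must be disjoint", call. = FALSE)
  miss <- setdiff(c(g1_genes, g2_genes), rownames(mat))
  if (length(miss) > 0)
    warning("dropping ", length(miss), " phase gene(s) absent from the matrix: ",
            paste(utils::head(miss, 5), collapse = ", "),
            if (length(miss) > 5) ", ..." else "", call. = FALSE)
  g1 <- intersect(g1_genes, rownames(mat))
  g2 <- intersect(g2_genes, rownames(mat))
  if (length(g1) < 2 || length(g2) < 2)
    stop("each phase set needs at least 2 genes present in the matrix", call. = FALSE)
  list(g1 = g1, g2 = g2)
}

#' Within-compartment cell-cycle correlation matrix
#'
#' Pearson correlation across cells, on `log10(TPM + 1)`, for every pair of
#' cell-cycle genes (G1 and G2 sets). In-phase pairs are G1-G1 and G2-G2,
#' out-of-phase pairs G1-G2; coherent cell-cycle progression shows as
#' positive in-phase and negative out-of-phase correlation. Constant genes
#' yield `NA` rows/columns and are excluded from the summary means.
#'
#' @param mat Gene-by-cell TPM matrix (at least 3 cells).
#' @param g1_genes,g2_genes Phase gene sets.
#' @return A list with the correlation `matrix`, the per-gene `phase`
#'   labels, and `mean_in_phase` / `mean_out_of_phase` summaries over
#'   off-diagonal pairs.
#' @export
phase_correlation_matrix <- function(mat, g1_genes, g2_genes) {
  if (ncol(mat) < 3) stop("need at least 3 cells", call. = FALSE)
  sets <- resolve_phase_sets(mat, g1_genes, g2_genes)
  genes <- c(sets$g1, sets$g2)
  phase <- stats::setNames(rep(c("G1", "G2"), c(length(sets$g1), length(sets$g2))), genes)
  lm <- log_transform(unclass(mat)[genes, , drop = FALSE])

  centred <- lm - rowMeans(lm)
  norms <- sqrt(rowSums(centred^2))
  cmat <- tcrossprod(centred / ifelse(norms == 0, NA_real_, norms))
  cmat <- pmin(pmax(cmat, -1), 1)
  dimnames(cmat) <- list(genes, genes)

  same <- outer(phase, phase, `==`)
  off <- !diag(length(genes))
  list(
    matrix = cmat, phase = phase,
    mean_in_phase = mean(cmat[same & off], na.rm = TRUE),
    mean_out_of_phase = mean(cmat[!same], na.rm = TRUE)
  )
}

## extract each unordered pair once: in-phase pairs from the upper triangles
## of the two within-phase blocks, out-of-phase values from the G1 x G2 block
phase_pair_values <- function(pcm, which = c("out_of_phase", "in_phase")) {
  which <- match.arg(which)
  g1 <- names(pcm$phase)[pcm$phase == "G1"]
  g2 <- names(pcm$phase)[pcm$phase == "G2"]
  m <- pcm$matrix
  if (which == "out_of_phase") {
    vals <- as.vector(m[g1, g2])
  } else {
    b1 <- m[g1, g1]
    b2 <- m[g2, g2]
    vals <- c(b1[upper.tri(b1)], b2[upper.tri(b2)])
  }
  vals[!is.na(vals)]
}

#' Compare cell-cycle correlation structure between compartments
#'
#' Two-sided Mann-Whitney U test on the pairwise correlation values (each
#' unordered gene pair counted once) of the chosen phase relation, between
#' the cytoplasmic and nuclear fractions — e.g. whether out-of-phase
#' anticorrelation is stronger in the nucleus.
#'
#' @param pcm_cyt,pcm_nuc Results of [phase_correlation_matrix()] on the two
#'   fractions.
#' @param which `"out_of_phase"` (default) or `"in_phase"`.
#' @return A list with `U` (the Mann-Whitney statistic for the cytoplasmic
#'   sample), `p`, and the two value vectors.
#' @export
compare_compartments <- function(pcm_cyt, pcm_nuc,
                                 which = c("out_of_phase", "in_phase")) {
  which <- match.arg(which)
  x <- phase_pair_values(pcm_cyt, which)
  y <- phase_pair_values(pcm_nuc, which)
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  list(U = unname(wt$statistic), p = wt$p.value, cyt_values = x, nuc_values = y)
}

#' Cross-compartment cell-cycle correlation matrix
#'
#' Entry (i, j) is the Pearson correlation across cells between the nuclear
#' expression of cell-cycle gene i and the cytoplasmic expression of gene j
#' (log10(TPM + 1)). Synchronized oscillation in the two fractions shows as
#' positive in-phase blocks (G1 nuc x G1 cyt, G2 nuc x G2 cyt) and negative
#' cross blocks. Unlike the within-compartment matrix this one need not be
#' symmetric.
#'
#' @param cyt,nuc TPM matrices on the same cells.
#' @param g1_genes,g2_genes Phase gene sets.
#' @return A list with the `matrix` (rows = nuclear genes, columns =
#'   cytoplasmic genes), `phase` labels, and block means `mean_in_phase`,
#'   `mean_cross_phase`.
#' @export
cross_compartment_cellcycle_matrix <- function(cyt, nuc, g1_genes, g2_genes) {
  cells <- intersect(colnames(cyt), colnames(nuc))
  if (length(cells) < 3) stop("need at least 3 shared cells", call. = FALSE)
  sets <- resolve_phase_sets(cyt, g1_genes, g2_genes)
  sets_n <- resolve_phase_sets(nuc, g1_genes, g2_genes)
  g1 <- intersect(sets$g1, sets_n$g1)
  g2 <- intersect(sets$g2, sets_n$g2)
  genes <- c(g1, g2)
  phase <- stats::setNames(rep(c("G1", "G2"), c(length(g1), length(g2))), genes)

  ln <- log_transform(unclass(nuc)[genes, cells, drop = FALSE])
  lc <- log_transform(unclass(cyt)[genes, cells, drop = FALSE])
  cn <- ln - rowMeans(ln)
  cc <- lc - rowMeans(lc)
  nn <- sqrt(rowSums(cn^2))
  nc <- sqrt(rowSums(cc^2))
  m <- tcrossprod(cn / ifelse(nn == 0, NA_real_, nn),
                  cc / ifelse(nc == 0, NA_real_, nc))
  m <- pmin(pmax(m, -1), 1)
  dimnames(m) <- list(genes, genes)

  same <- outer(phase, phase, `==`)
  list(
    matrix = m, phase = phase,
    mean_in_phase = mean(m[same], na.rm = TRUE),
    mean_cross_phase = mean(m[!same], na.rm = TRUE)
  )
}

#' Per-cell cell-cycle phase score
#'
#' For each cell, the mean (across genes) z-scored log expression of the G2
#' genes minus that of the G1 genes, where z-scoring is per gene across
#' cells. Cells at the G1 pole of the cycle score negative, cells at the G2
#' pole positive. This is a simple two-set surrogate for published
#' phase-score schemes.
#'
#' @param mat Gene-by-cell TPM matrix.
#' @param g1_genes,g2_genes Phase gene sets.
#' @return Named numeric vector of per-cell scores.
#' @export
phase_score <- function(mat, g1_genes, g2_genes) {
  if (ncol(mat) < 3) stop("need at least 3 cells", call. = FALSE)
  sets <- resolve_phase_sets(mat, g1_genes, g2_genes)
  lm <- log_transform(unclass(mat)[c(sets$g1, sets$g2), , drop = FALSE])
  mu <- rowMeans(lm)
  sdv <- sqrt(rowSums((lm - mu)^2) / (ncol(lm) - 1))
  z <- (lm - mu) / ifelse(sdv == 0, NA_real_, sdv)
  colMeans(z[sets$g2, , drop = FALSE], na.rm = TRUE) -
    colMeans(z[sets$g1, , drop = FALSE], na.rm = TRUE)
}
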