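## shared PCA core: features x cells in, centred (optionally scaled) rows,
## SVD via prcomp on the transposed matrix
pca_core <- function(feat, scale. = FALSE) {
  if (ncol(feat) < 3) stop("need at least 3 cells", call. = FALSE)
  constant <- apply(feat, 1, function(x) max(x) == min(x))
  if (all(constant)) stop("all features are constant", call. = FALSE)
  if (any(constant)) {
    warning("dropping ", sum(constant), " constant feature(s)", call. = FALSE)
    feat <- feat[!constant, , drop = FALSE]
  }
  pr <- stats::prcomp(t(feat), center = TRUE, scale. = scale.)
  ev <- pr$sdev^2
  list(scores = pr$x, rotation = pr$rotation,
       explained_variance = ev / sum(ev), features = rownames(feat))
}

#' Localization-embedded PCA (L-PCA)
#'
#' PCA on the stacked `(2n x m)` feature matrix in which each of the n
#' selected genes contributes two features — its cytoplasmic and its nuclear
#' log expression — so a cell is represented with double dimension and the
#' two fractions can pull the embedding apart. Features are centred across
#' cells; no unit-variance scaling by default. Principal components are
#' computed by singular value decomposition.
#'
#' @param cyt,nuc TPM matrices on the same cells.
#' @param genes Genes to embed (at least 2).
#' @param log Apply `log10(TPM + 1)` first (default).
#' @param scale. Scale features to unit variance.
#' @return A list with `scores` (cells x PCs), `rotation`,
#'   `explained_variance` (ratios summing to 1, non-increasing), and the
#'   stacked `features` (named `<gene>|cyt`, `<gene>|nuc`).
#' @export
lpca <- function(cyt, nuc, genes, log = TRUE, scale. = FALSE) {
  if (length(genes) < 2) stop("need at least 2 genes", call. = FALSE)
  cells <- intersect(colnames(cyt), colnames(nuc))
  xc <- unclass(cyt)[genes, cells, drop = FALSE]
  xn <- unclass(nuc)[genes, cells, drop = FALSE]
  if (log) {
    xc <- log_transform(xc)
    xn <- log_transform(xn)
  }
  rownames(xc) <- paste0(genes, "|cyt")
  rownames(xn) <- paste0(genes, "|nuc")
  pca_core(rbind(xc, xn), scale. = scale.)
}

#' Conventional PCA on a single expression matrix
#'
#' Same centring/SVD contract as [lpca()], on the `(n x m)` matrix of a
#' single profile per cell (typically the in silico single-cell matrix).
#'
#' @param mat Gene-by-cell TPM matrix.
#' @param genes Genes to embed; default all.
#' @param log Apply `log10(TPM + 1)` first.
#' @param scale. Scale features to unit variance.
#' @return As [lpca()].
#' @export
conventional_pca <- function(mat, genes = rownames(mat), log = TRUE, scale. = FALSE) {
  x <- unclass(mat)[genes, , drop = FALSE]
  if (log) x <- log_transform(x)
  pca_core(x, scale. = scale.)
}

#' Fallback pseudotime from the first principal component
#'
#' When no externally computed pseudotime is supplied, cells are ordered by
#' their score along the first conventional PC, sign-oriented so that the
#' designated reference cells (e.g. the untreated group) sit at the origin
#' of the ordering.
#'
#' @param mat Gene-by-cell TPM matrix (typically in silico single cells).
#' @param genes Genes used for the PCA.
#' @param reference_cells Cells anchoring the start of the trajectory; the
#'   PC1 sign is flipped so their mean score is below the overall mean.
#' @param reverse Reverse the final ordering.
#' @return A data frame `cell_id`, `pseudotime` (oriented PC1 score),
#'   `rank` (0-based).
#' @export
fallback_pseudotime <- function(mat, genes = rownames(mat),
                                reference_cells = NULL, reverse = FALSE) {
  pc <- conventional_pca(mat, genes)
  s <- pc$scores[, 1]
  if (!is.null(reference_cells)) {
    ref <- intersect(reference_cells, names(s))
    if (length(ref) == 0) stop("no reference cell found in the matrix", call. = FALSE)
    if (mean(s[ref]) > mean(s)) s <- -s
  }
  if (reverse) s <- -s
  data.frame(cell_id = names(s), pseudotime = unname(s),
             rank = rank(s, ties.method = "first") - 1L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cell-by-cell cross-compartment correlation matrix
#'
#' Entry (i, j) is the Pearson correlation, over the selected genes'
#' log-transformed expression, between the nuclear profile of cell i and the
#' cytoplasmic profile of cell j. Rows and columns are ordered by
#' pseudotime. The matrix is not symmetric in general; its diagonal holds
#' each cell's own nucleus-cytoplasm agreement.
#'
#' @param nuc,cyt TPM matrices on the same cells.
#' @param genes Genes entering the profile vectors (at least 3).
#' @param ordering Pseudotime data frame (`cell_id`, `rank`), e.g. from
#'   [fallback_pseudotime()] or [read_pseudotime()].
#' @return A matrix with `ordering` attached as attribute `"ordering"`.
#' @export
cell_cross_correlation <- function(nuc, cyt, genes, ordering) {
  if (length(genes) < 3) stop("need at least 3 genes", call. = FALSE)
  ord <- ordering[order(ordering$rank), , drop = FALSE]
  cells <- ord$cell_id
  if (!all(cells %in% colnames(nuc)) || !all(cells %in% colnames(cyt)))
    stop("ordering contains cells absent from the matrices", call. = FALSE)
  ln <- log_transform(unclass(nuc)[genes, cells, drop = FALSE])
  lc <- log_transform(unclass(cyt)[genes, cells, drop = FALSE])
  m <- stats::cor(ln, lc)
  dimnames(m) <- list(cells, cells)
  attr(m, "ordering") <- ord
  m
}

## contiguous equal-size bins along an ordering of m cells: the remainder
## goes to the last bins, e.g. 11 cells in 5 bins -> sizes 2,2,2,2,3
pseudotime_bins <- function(m, k) {
  if (k < 1 || k > m) stop("invalid number of bins", call. = FALSE)
  base <- m %/% k
  rem <- m %% k
  sizes <- c(rep(base, k - rem), rep(base + 1, rem))
  rep(seq_len(k), times = sizes)
}

#' Bin a cross-correlation matrix along pseudotime
#'
#' Divides the ordered cells into `k` contiguous groups (equal sizes, any
#' remainder assigned to the last bins) and averages the cross-correlation
#' within each (nuclear bin, cytoplasmic bin) block.
#'
#' @param ccm Matrix from [cell_cross_correlation()].
#' @param k Number of pseudotime groups.
#' @return A list with `grid` (k x k block means), `dispersion` (block SDs),
#'   `bins` (per-cell bin index), `sizes`.
#' @export
bin_and_summarize <- function(ccm, k = 5) {
  m <- nrow(ccm)
  bins <- pseudotime_bins(m, k)
  grid <- matrix(NA_real_, k, k)
  disp <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      block <- ccm[bins == i, bins == j, drop = FALSE]
      grid[i, j] <- mean(block)
      disp[i, j] <- stats::sd(block)
    }
  }
  list(grid = grid, dispersion = disp, bins = bins,
       sizes = as.integer(table(bins)))
}

#' Corner asymmetry of the pseudotime cross-correlation grid
#'
#' Compares the late-nucleus/early-cytoplasm corner (top right: last nuclear
#' bin against first cytoplasmic bin) with the early-nucleus/late-cytoplasm
#' corner (bottom left). A lower top-right corner means late nuclear
#' profiles resemble early cytoplasmic profiles less than the reverse —
#' evidence that the nucleus leads the divergence. Significance is assessed
#' by bootstrap: cells are resampled with replacement within each pseudotime
#' bin and the corner difference recomputed.
#'
#' @param ccm Matrix from [cell_cross_correlation()].
#' @param k Number of pseudotime bins (at least 2).
#' @param n_bootstrap Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return A list: `mean_topright`, `mean_bottomleft`, `difference`
#'   (bottom-left minus top-right), two-sided bootstrap `p`, and the
#'   bootstrap draws.
#' @export
corner_asymmetry <- function(ccm, k = 5, n_bootstrap = 1000, seed = 1L) {
  if (k < 2) stop("corner asymmetry needs at least 2 bins", call. = FALSE)
  m <- nrow(ccm)
  bins <- pseudotime_bins(m, k)
  first <- which(bins == 1)
  last <- which(bins == k)
  corner <- function(idx_row, idx_col) mean(ccm[idx_row, idx_col, drop = FALSE])
  tr <- corner(last, first)
  bl <- corner(first, last)
  diff_obs <- bl - tr

  set.seed(seed)
  boot <- vapply(seq_len(n_bootstrap), function(b) {
    rf <- sample(first, length(first), replace = TRUE)
    rl <- sample(last, length(last), replace = TRUE)
    corner(rf, rl) - corner(rl, rf)
  }, numeric(1))
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0)) + 1 / n_bootstrap
  list(mean_topright = tr, mean_bottomleft = bl, difference = diff_obs,
       p = min(1, p), bootstrap = boot)
}

#' Decline of same-cell cross-compartment correlation along pseudotime
#'
#' Takes each cell's own nucleus-cytoplasm correlation (the diagonal of the
#' cell-by-cell cross-correlation matrix restricted to a gene set) and tests
#' its Spearman trend against the cell's pseudotime bin index, separately
#' for a gene set of interest (typically the DEGs) and a size-matched
#' control set. Diverging compartments show a negative trend for the DEGs
#' and a weaker one for the controls.
#'
#' @param nuc,cyt TPM matrices.
#' @param deg_genes,control_genes Gene sets (control defaults to `NULL` =
#'   skip).
#' @param ordering Pseudotime ordering data frame.
#' @param k Number of bins (at least 3 for a trend).
#' @return A list with per-set results (`rho`, `p`, per-cell values) under
#'   `deg` and `control`.
#' @export
correlation_decline <- function(nuc, cyt, deg_genes, control_genes = NULL,
                                ordering, k = 5) {
  if (k < 3) stop("need at least 3 bins for a trend", call. = FALSE)
  one <- function(genes) {
    ccm <- cell_cross_correlation(nuc, cyt, genes, ordering)
    d <- diag(ccm)
    bins <- pseudotime_bins(length(d), k)
    ct <- suppressWarnings(stats::cor.test(d, bins, method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value, diagonal = d, bins = bins)
  }
  out <- list(deg = one(deg_genes))
  if (!is.null(control_genes)) out$control <- one(control_genes)
  out
}

#' Select trajectory DEGs per compartment and take the union
#'
#' Runs the negative-binomial exact test within each fraction, comparing all
#' non-reference cells against the reference (origin) cells, and returns the
#' union of significant genes across the two fractions.
#'
#' @param cyt,nuc Count-scale matrices (see [tpm_to_pseudocounts()]).
#' @param reference_cells The origin group (e.g. untreated day-0 cells).
#' @param config Configuration (significance rule).
#' @return A list with the per-compartment DE tables (`de_cyt`, `de_nuc`)
#'   and the union `genes`.
#' @export
select_trajectory_degs <- function(cyt, nuc, reference_cells,
                                   config = default_config()) {
  cells <- colnames(cyt)
  ref <- intersect(reference_cells, cells)
  other <- setdiff(cells, ref)
  if (length(ref) < 2 || length(other) < 2)
    stop("need at least 2 reference and 2 non-reference cells", call. = FALSE)
  de_c <- nb_de_test(unclass(cyt)[, other, drop = FALSE],
                     unclass(cyt)[, ref, drop = FALSE],
                     config$de_max_p, config$de_min_lfc, config$dispersion_floor)
  de_n <- nb_de_test(unclass(nuc)[, other, drop = FALSE],
                     unclass(nuc)[, ref, drop = FALSE],
                     config$de_max_p, config$de_min_lfc, config$dispersion_floor)
  list(de_cyt = de_c, de_nuc = de_n,
       genes = union(de_c$gene[de_c$significant], de_n$gene[de_n$significant]))
}

#' Convert TPM to count-scale pseudo-counts
#'
#' Rescales TPM to the sequencing depth and rounds, for use with the exact
#' count tests.
#'
#' @param tpm TPM matrix.
#' @param depth Reads per library.
#' @return Integer-valued matrix.
#' @export
tpm_to_pseudocounts <- function(tpm, depth = 2e5) {
  round(unclass(tpm) * depth / 1e6)
}

#' Heatmap of a cell-by-cell cross-correlation matrix
#'
#' @param ccm Matrix from [cell_cross_correlation()].
#' @param ... Passed to [graphics::image()].
#' @export
plot_cross_correlation <- function(ccm, ...) {
  m <- nrow(ccm)
  graphics::image(seq_len(m), seq_len(m), t(ccm[m:1, , drop = FALSE]),
                  xlab = "cytoplasm, cells by pseudotime",
                  ylab = "nucleus, cells by pseudotime (late at bottom)",
                  ...)
}
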