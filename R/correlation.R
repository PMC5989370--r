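#' Log-transform an expression matrix
#'
#' Elementwise `log10(x + 1)`, the transform used throughout the correlation
#' analyses.
#'
#' @param x Numeric matrix or vector of TPM values.
#' @return Transformed values.
#' @export
log_transform <- function(x) {
  log10(unclass(x) + 1)
}

## rowwise Pearson correlation between two aligned matrices; rows with zero
## variance in either matrix give NA
row_correlations <- function(a, b) {
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  na <- rowSums(ac^2)
  nb <- rowSums(bc^2)
  r <- rowSums(ac * bc) / sqrt(na * nb)
  r[na == 0 | nb == 0] <- NA_real_
  ## numerical guard: |r| can exceed 1 by epsilon
  pmin(pmax(r, -1), 1)
}

## two-sided p-value for a Pearson/Spearman coefficient via the t
## approximation with n - 2 degrees of freedom
correlation_p_value <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  t_stat <- abs(r[ok]) * sqrt((n - 2) / pmax(1 - r[ok]^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(t_stat, df = n - 2, lower.tail = FALSE)
  p[ok][abs(r[ok]) == 1] <- 0
  p
}

#' Per-gene nucleus-cytoplasm correlation landscape
#'
#' For every gene expressed in enough cells in both fractions, computes the
#' correlation across cells between its log-transformed cytoplasmic and
#' nuclear expression, a two-sided p-value from the t approximation
#' `t = r sqrt((n-2)/(1-r^2))`, a BH-adjusted q-value, and the gene's rank
#' and quantile position when sorted by the coefficient. Genes with zero
#' variance in either fraction get `r = NA` and are excluded from ranking.
#'
#' @param cyt,nuc Gene-by-cell TPM matrices on the same cells (matched by
#'   name; fewer than 3 shared cells is an error).
#' @param min_cells_expressed A gene enters the landscape when its TPM
#'   exceeds `detection_tpm` in at least this many cells in both fractions.
#' @param detection_tpm Expression threshold for the admission filter
#'   (strict inequality).
#' @param method `"pearson"` or `"spearman"`.
#' @return A data frame (`gene`, `r`, `p`, `q`, `rank`, `quantile`) sorted
#'   by increasing `r`, with a `summary` attribute holding the counts of
#'   positively/negatively correlated genes at p < 0.05.
#' @export
gene_landscape <- function(cyt, nuc, min_cells_expressed = 5, detection_tpm = 1,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(rownames(cyt), rownames(nuc)))
    stop("matrices must share the same genes in the same order", call. = FALSE)
  cells <- intersect(colnames(cyt), colnames(nuc))
  if (length(cells) < 3) stop("fewer than 3 shared cells", call. = FALSE)
  cyt <- unclass(cyt)[, cells, drop = FALSE]
  nuc <- unclass(nuc)[, cells, drop = FALSE]
  n <- length(cells)

  keep <- rowSums(cyt > detection_tpm) >= min_cells_expressed &
          rowSums(nuc > detection_tpm) >= min_cells_expressed
  message(sprintf("landscape: %d of %d genes expressed (TPM > %g) in >= %d cells in both fractions",
                  sum(keep), nrow(cyt), detection_tpm, min_cells_expressed))
  lc <- log_transform(cyt[keep, , drop = FALSE])
  ln <- log_transform(nuc[keep, , drop = FALSE])
  if (method == "spearman") {
    lc <- t(apply(lc, 1, rank))
    ln <- t(apply(ln, 1, rank))
  }
  r <- row_correlations(lc, ln)
  p <- correlation_p_value(r, n)
  q <- stats::p.adjust(p, method = "BH")

  tab <- data.frame(gene = rownames(lc), r = r, p = p, q = q,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$r, tab$gene, na.last = TRUE), , drop = FALSE]
  ranked <- !is.na(tab$r)
  tab$rank <- NA_integer_
  tab$rank[ranked] <- seq_len(sum(ranked))
  tab$quantile <- tab$rank / sum(ranked)
  rownames(tab) <- NULL

  attr(tab, "summary") <- list(
    n_tested = sum(ranked),
    n_positive = sum(ranked & tab$r > 0 & tab$p < 0.05, na.rm = TRUE),
    n_negative = sum(ranked & tab$r < 0 & tab$p < 0.05, na.rm = TRUE),
    n_cells = n, method = method
  )
  message(sprintf("landscape: %d positively and %d negatively correlated genes at p < 0.05",
                  attr(tab, "summary")$n_positive, attr(tab, "summary")$n_negative))
  tab
}

#' Correlation between two expression profiles
#'
#' Pearson correlation over genes between two (optionally log-transformed)
#' expression profiles — e.g. a nuclear profile against its own in silico
#' single cell, or an in silico cell against a conventional whole-cell
#' profile.
#'
#' @param profile_a,profile_b Numeric vectors over the same genes.
#' @param log Apply `log10(x + 1)` first (default).
#' @return Pearson correlation coefficient.
#' @export
sample_correlation <- function(profile_a, profile_b, log = TRUE) {
  stopifnot(length(profile_a) == length(profile_b))
  if (log) {
    profile_a <- log_transform(profile_a)
    profile_b <- log_transform(profile_b)
  }
  stats::cor(profile_a, profile_b)
}

#' Quantile plot of the correlation landscape
#'
#' The monotone step curve of sorted correlation coefficients against their
#' quantile position.
#'
#' @param tab Landscape table from [gene_landscape()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_quantile_landscape <- function(tab, ...) {
  ok <- !is.na(tab$r)
  graphics::plot(tab$quantile[ok], tab$r[ok], type = "s",
                 xlab = "gene quantile", ylab = "nucleus-cytoplasm correlation r",
                 ...)
  graphics::abline(h = 0, lty = 2)
}
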