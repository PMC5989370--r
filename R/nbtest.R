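#' Negative-binomial exact test for differential expression
#'
#' Per-gene two-sample test for count matrices under a negative-binomial
#' model, in the style of exact-test DE callers for small numbers of
#' replicates:
#'
#' * library sizes are the column totals; counts are normalized to the
#'   geometric-mean library size;
#' * a per-gene dispersion is estimated by the method of moments within each
#'   group and pooled across groups weighted by degrees of freedom, floored
#'   at `dispersion_floor`;
#' * when the floor is hit the model degenerates to Poisson and the exact
#'   conditional test is used: given the total count of the gene, the group-A
#'   sum is binomial with probability proportional to the group's total
#'   library size (two-sided by summing outcome probabilities no larger than
#'   the observed one);
#' * otherwise group sums are quantile-matched to equal library sizes and an
#'   exact conditional NB test is performed on the pair of sums (two-sided by
#'   likelihood ordering of the partitions of the total).
#'
#' The log2 fold change is computed from normalized group means with a
#' pseudo-count of 1 (positive = higher in group A). Significance follows the
#' p < 0.001 and |log2 FC| > 1 rule; q-values are BH-adjusted.
#'
#' Counts are expected on an integer scale; non-integer input (e.g. rescaled
#' TPM pseudo-counts) is rounded for the exact tests.
#'
#' @param counts_a,counts_b Gene-by-cell count matrices with identical gene
#'   ordering; at least 2 cells per group.
#' @param de_max_p,de_min_lfc Significance rule.
#' @param dispersion_floor Lower bound on the pooled dispersion; at or below
#'   it the Poisson limit is used.
#' @return A data frame with columns `gene`, `log2fc`, `p`, `q`,
#'   `significant`, `dispersion`, `method`.
#' @export
nb_de_test <- function(counts_a, counts_b, de_max_p = 0.001, de_min_lfc = 1,
                       dispersion_floor = 1e-8) {
  if (!identical(rownames(counts_a), rownames(counts_b)))
    stop("count matrices must share the same genes in the same order", call. = FALSE)
  counts_a <- unclass(counts_a)
  counts_b <- unclass(counts_b)
  na <- ncol(counts_a)
  nb <- ncol(counts_b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 cells", call. = FALSE)
  lib_a <- colSums(counts_a)
  lib_b <- colSums(counts_b)
  if (any(c(lib_a, lib_b) == 0))
    stop("cell with all-zero library size", call. = FALSE)

  N0 <- exp(mean(log(c(lib_a, lib_b))))
  za <- sweep(counts_a, 2, lib_a / N0, `/`)
  zb <- sweep(counts_b, 2, lib_b / N0, `/`)

  ma <- rowMeans(za)
  mb <- rowMeans(zb)
  row_var <- function(z, m) rowSums((z - m)^2) / (ncol(z) - 1)
  va <- row_var(za, ma)
  vb <- row_var(zb, mb)
  mom <- function(v, m) ifelse(m > 0, (v - m) / m^2, NA_real_)
  phi_a <- mom(va, ma)
  phi_b <- mom(vb, mb)
  wa <- ifelse(is.na(phi_a), 0, na - 1)
  wb <- ifelse(is.na(phi_b), 0, nb - 1)
  phi <- (wa * ifelse(is.na(phi_a), 0, phi_a) + wb * ifelse(is.na(phi_b), 0, phi_b)) /
    pmax(wa + wb, 1)
  phi <- pmax(phi, dispersion_floor)

  ya <- round(rowSums(counts_a))
  yb <- round(rowSums(counts_b))
  Sa <- sum(lib_a)
  Sb <- sum(lib_b)

  G <- nrow(counts_a)
  p <- numeric(G)
  method <- character(G)
  for (g in seq_len(G)) {
    s <- ya[g] + yb[g]
    if (s == 0) {
      p[g] <- 1
      method[g] <- "none"
    } else if (phi[g] <= dispersion_floor) {
      p[g] <- binomial_exact_p(ya[g], s, Sa / (Sa + Sb))
      method[g] <- "poisson"
    } else {
      p[g] <- nb_exact_p(ya[g], yb[g], na, nb, phi[g],
                         Sa / na / N0, Sb / nb / N0)
      method[g] <- "nb"
    }
  }

  log2fc <- log2((ma + 1) / (mb + 1))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(
    gene = rownames(counts_a),
    log2fc = log2fc, p = p, q = q,
    significant = p < de_max_p & abs(log2fc) > de_min_lfc,
    dispersion = phi, method = method,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

## two-sided exact binomial p-value by likelihood ordering (the standard
## small-sample convention: sum all outcome probabilities not exceeding the
## observed one, with a 1 + 1e-7 relative guard)
binomial_exact_p <- function(x, n, prob) {
  d <- stats::dbinom(0:n, n, prob)
  min(1, sum(d[d <= d[x + 1] * (1 + 1e-7)]))
}

## exact conditional NB test on group sums. The observed sums are first
## quantile-matched (mid-p) from their actual mean library sizes to the
## common normalized library size, then all partitions (y, s - y) of the
## total are enumerated under NB(size n/phi) with the conditional null mean,
## and the two-sided p-value sums partition probabilities no larger than the
## observed one. For large totals the enumeration is restricted to a window
## of +-12 SD around each group's expectation (the excluded tail mass is
## negligible at double precision).
nb_exact_p <- function(ya, yb, na, nb, phi, sbar_a, sbar_b) {
  size_a <- na / phi
  size_b <- nb / phi

  ## quantile match each group's sum to equal per-cell library sizes
  q2q <- function(y, size, mu_obs, mu_ref) {
    if (abs(mu_obs - mu_ref) / mu_ref < 1e-12) return(y)
    pr <- stats::pnbinom(y, size = size, mu = mu_obs) -
      0.5 * stats::dnbinom(y, size = size, mu = mu_obs)
    stats::qnbinom(min(max(pr, 1e-15), 1 - 1e-15), size = size, mu = mu_ref)
  }
  mu_hat <- (ya / sbar_a + yb / sbar_b) / (na + nb)  # rough per-cell mean for matching
  ya <- q2q(ya, size_a, mu_hat * na * sbar_a, mu_hat * na)
  yb <- q2q(yb, size_b, mu_hat * nb * sbar_b, mu_hat * nb)

  s <- ya + yb
  if (s == 0) return(1)
  mu0 <- s / (na + nb)   # conditional null mean per cell
  Ma <- na * mu0
  Mb <- nb * mu0

  if (s <= 20000) {
    y <- 0:s
  } else {
    sd_a <- sqrt(Ma + phi * Ma^2 / na)
    sd_b <- sqrt(Mb + phi * Mb^2 / nb)
    lo <- max(0, floor(min(Ma - 12 * sd_a, s - Mb - 12 * sd_b)))
    hi <- min(s, ceiling(max(Ma + 12 * sd_a, s - Mb + 12 * sd_b)))
    y <- lo:hi
    if (!(ya >= lo && ya <= hi)) return(0)  # observed far outside the window
  }
  d <- stats::dnbinom(y, size = size_a, mu = Ma) *
       stats::dnbinom(s - y, size = size_b, mu = Mb)
  d_obs <- stats::dnbinom(ya, size = size_a, mu = Ma) *
           stats::dnbinom(s - ya, size = size_b, mu = Mb)
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]) / sum(d))
}
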