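#' Cytoplasmic weight from one qPCR marker
#'
#' Converts a marker gene's qPCR delta-Ct (`Ct_nuc - Ct_cyt`) and its raw
#' TPM in the two fractions into the per-cell cytoplasmic normalization
#' weight
#' \deqn{\alpha = \frac{2^{\Delta Ct}}{TPM^*_{cyt}/TPM^*_{nuc} + 2^{\Delta Ct}}.}
#' `alpha` is the fraction of the cell's transcripts that are cytoplasmic;
#' the complementary nuclear weight is `beta = 1 - alpha`.
#'
#' A marker with zero raw TPM in the nucleus leaves the ratio undefined; the
#' marker is unusable and `NA` is returned with a warning (callers average
#' over the usable markers). This path is degenerate for the intended
#' high-expression markers.
#'
#' @param delta_ct Delta-Ct in cycles (`Ct_nuc - Ct_cyt`).
#' @param raw_tpm_cyt,raw_tpm_nuc Raw TPM of the marker in the cytoplasmic
#'   and nuclear libraries.
#' @return Cytoplasmic weight in (0, 1), or `NA_real_` if unusable.
#' @export
#' @examples
#' alpha_for_marker(0, 100, 100)   # 0.5
#' alpha_for_marker(2, 100, 100)   # 0.8
alpha_for_marker <- function(delta_ct, raw_tpm_cyt, raw_tpm_nuc) {
  stopifnot(length(delta_ct) == 1, is.finite(delta_ct))
  if (raw_tpm_nuc <= 0 || raw_tpm_cyt <= 0) {
    warning("marker with zero raw TPM in one fraction is unusable", call. = FALSE)
    return(NA_real_)
  }
  ratio <- raw_tpm_cyt / raw_tpm_nuc
  2^delta_ct / (ratio + 2^delta_ct)
}

## resolve a qPCR marker to matrix rows: an exact rowname match, else the sum
## of numbered paralogue rows (e.g. HBG -> HBG1 + HBG2)
marker_tpm_value <- function(marker, mat, cell) {
  if (marker %in% rownames(mat)) return(mat[marker, cell])
  paralogues <- grep(paste0("^", marker, "[0-9]+$"), rownames(mat), value = TRUE)
  if (length(paralogues) == 0) return(NA_real_)
  sum(mat[paralogues, cell])
}

#' Cytoplasmic weight for one cell from all its qPCR markers
#'
#' Computes [alpha_for_marker()] for every qPCR record of the cell and
#' returns the arithmetic mean of the per-marker weights (the weights are
#' averaged, not the delta-Ct values). A marker absent from the matrices is
#' resolved as the sum of its numbered paralogue rows (HBG uses HBG1 + HBG2);
#' unusable markers are skipped with a warning, and a cell with no usable
#' marker is an error naming the cell.
#'
#' @param qpcr Data frame of qPCR records (`cell_id`, `marker_gene`,
#'   `delta_ct`); rows for other cells are ignored.
#' @param cyt,nuc Raw TPM matrices for the two fractions.
#' @param cell Cell identifier.
#' @return The mean cytoplasmic weight for the cell.
#' @export
cell_alpha <- function(qpcr, cyt, nuc, cell) {
  rec <- qpcr[qpcr$cell_id == cell, , drop = FALSE]
  if (nrow(rec) == 0) stop("no qPCR records for cell '", cell, "'", call. = FALSE)
  if (!cell %in% colnames(cyt) || !cell %in% colnames(nuc))
    stop("cell '", cell, "' missing from the expression matrices", call. = FALSE)
  alphas <- vapply(seq_len(nrow(rec)), function(i) {
    marker <- rec$marker_gene[i]
    tc <- marker_tpm_value(marker, cyt, cell)
    tn <- marker_tpm_value(marker, nuc, cell)
    if (is.na(tc) || is.na(tn)) {
      warning("marker '", marker, "' not found in the expression matrices", call. = FALSE)
      return(NA_real_)
    }
    alpha_for_marker(rec$delta_ct[i], tc, tn)
  }, numeric(1))
  usable <- alphas[!is.na(alphas)]
  if (length(usable) == 0)
    stop("no usable qPCR marker for cell '", cell, "'", call. = FALSE)
  mean(usable)
}

#' Combine one cell's compartment profiles into an in silico column
#'
#' Returns `alpha * raw_cyt + (1 - alpha) * raw_nuc`. If both raw columns
#' sum to one million, so does the result, which is the defining property of
#' the in silico single-cell profile.
#'
#' @param raw_cyt,raw_nuc Raw TPM vectors for one cell.
#' @param alpha Cytoplasmic weight in `[0, 1]`.
#' @return The combined TPM vector.
#' @export
combine_columns <- function(raw_cyt, raw_nuc, alpha) {
  stopifnot(length(raw_cyt) == length(raw_nuc))
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]", call. = FALSE)
  alpha * raw_cyt + (1 - alpha) * raw_nuc
}

#' In silico single-cell normalization
#'
#' Recombines the raw cytoplasmic and nuclear TPM matrices of the same cells
#' into whole-cell ("in silico single cell") profiles: per cell, a
#' cytoplasmic weight `alpha` is estimated from the cell's qPCR markers
#' ([cell_alpha()]), the nuclear weight is `beta = 1 - alpha`, and the
#' combined profile is `alpha * TPM*_cyt + beta * TPM*_nuc`, which again
#' sums to one million per cell. `alpha` and `beta` equal the cell's
#' cytoplasmic and nuclear fractions of transcripts, so the weighted
#' sub-matrices are directly comparable across compartments within a cell.
#'
#' @param cyt,nuc Raw TPM matrices (same genes; cells are matched by name).
#' @param qpcr qPCR records covering every shared cell.
#' @return An object of class `insilico_result`: list with `alpha`, `beta`
#'   (named per-cell vectors), `tpm_insilico`, `tpm_cyt_scaled`,
#'   `tpm_nuc_scaled` (gene-by-cell matrices).
#' @export
insilico_normalize <- function(cyt, nuc, qpcr) {
  if (!identical(rownames(cyt), rownames(nuc)))
    stop("cyt and nuc matrices must share the same genes in the same order", call. = FALSE)
  cells <- intersect(colnames(cyt), colnames(nuc))
  if (length(cells) == 0) stop("no shared cells between the matrices", call. = FALSE)
  cyt <- unclass(cyt)[, cells, drop = FALSE]
  nuc <- unclass(nuc)[, cells, drop = FALSE]
  alpha <- vapply(cells, function(cl) cell_alpha(qpcr, cyt, nuc, cl), numeric(1))
  beta <- 1 - alpha
  cyt_scaled <- sweep(cyt, 2, alpha, `*`)
  nuc_scaled <- sweep(nuc, 2, beta, `*`)
  structure(list(
    alpha = alpha, beta = beta,
    tpm_insilico = cyt_scaled + nuc_scaled,
    tpm_cyt_scaled = cyt_scaled,
    tpm_nuc_scaled = nuc_scaled
  ), class = "insilico_result")
}

#' @export
print.insilico_result <- function(x, ...) {
  cat(sprintf("insilico_result: %d genes x %d cells\n",
              nrow(x$tpm_insilico), ncol(x$tpm_insilico)))
  cat(sprintf("  cytoplasmic weight alpha: mean %.3f (sd %.3f)\n",
              mean(x$alpha), stats::sd(x$alpha)))
  invisible(x)
}

#' Summary of the cytoplasmic transcript fraction
#'
#' Reports the per-cell cytoplasmic weights, their mean and SD, and the
#' pooled estimate (total weighted cytoplasmic TPM over total TPM), both as
#' fractions and percent.
#'
#' @param result An `insilico_result`.
#' @return A list with `per_cell`, `mean`, `sd`, `percent_cyt`,
#'   `pooled_fraction`.
#' @export
cytoplasmic_abundance_summary <- function(result) {
  if (!inherits(result, "insilico_result") || length(result$alpha) == 0)
    stop("empty in silico result", call. = FALSE)
  a <- result$alpha
  pooled <- sum(result$tpm_cyt_scaled) / sum(result$tpm_insilico)
  list(per_cell = a, mean = mean(a), sd = stats::sd(a),
       percent_cyt = 100 * mean(a), pooled_fraction = pooled)
}

#' Detected genes per cell
#'
#' A gene is detected in a cell when its TPM is strictly greater than the
#' threshold (default 1 TPM; a gene at exactly the threshold is not
#' detected).
#'
#' @param mat Gene-by-cell TPM matrix.
#' @param threshold Detection threshold.
#' @return Named integer vector of detected genes per cell.
#' @export
count_detected <- function(mat, threshold = 1) {
  colSums(unclass(mat) > threshold)
}

#' Per-cell detection Venn between compartments
#'
#' For every cell, counts genes detected only in the cytoplasmic fraction,
#' only in the nuclear fraction, and in both, then averages across cells
#' (the mean-count Venn layout used for paired-fraction experiments).
#'
#' @param cyt,nuc TPM matrices sharing genes and cells.
#' @param threshold Detection threshold (strict).
#' @return A list with `per_cell` (3 x cells matrix) and `mean` (named
#'   vector: `cyt_only`, `nuc_only`, `both`).
#' @export
detection_venn <- function(cyt, nuc, threshold = 1) {
  stopifnot(identical(dim(cyt), dim(nuc)),
            identical(rownames(cyt), rownames(nuc)),
            identical(colnames(cyt), colnames(nuc)))
  dc <- unclass(cyt) > threshold
  dn <- unclass(nuc) > threshold
  per_cell <- rbind(
    cyt_only = colSums(dc & !dn),
    nuc_only = colSums(!dc & dn),
    both     = colSums(dc & dn)
  )
  list(per_cell = per_cell, mean = rowMeans(per_cell))
}
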