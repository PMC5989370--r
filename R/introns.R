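#' Intron FPKM
#'
#' Fragments per kilobase of intron per million mapped fragments:
#' `count / ((length_nt / 1e3) * (total / 1e6))`.
#'
#' @param fragment_count Fragments mapped to the intron.
#' @param length_nt Intron length in nucleotides.
#' @param total_mapped_fragments Library total of mapped fragments.
#' @return FPKM value(s).
#' @export
#' @examples
#' intron_fpkm(10, 1000, 1e6)  # 10
intron_fpkm <- function(fragment_count, length_nt, total_mapped_fragments) {
  stopifnot(all(length_nt > 0), all(total_mapped_fragments > 0))
  fragment_count / ((length_nt / 1e3) * (total_mapped_fragments / 1e6))
}

#' Classify an intron observation as retained, spliced, or discarded
#'
#' Applies the three-way rule per (intron, cell, compartment) observation:
#'
#' * the host gene must have at least `gene_min_tpm` TPM (default 2) in that
#'   cell and compartment, otherwise the observation is **discarded**
#'   regardless of the other fields;
#' * **retained**: intron expression at least `ri_min_ratio` (10%) of the
#'   gene, intron-body coverage at least `ri_min_intron_cov` (95%), and
#'   non-zero adjacent-exon expression;
#' * **spliced**: intron expression below `spliced_max_ratio` (1%) of the
#'   gene and adjacent-exon coverage at least `spliced_min_exon_cov` (50%);
#' * anything else is **discarded**.
#'
#' The expression ratio is intron FPKM over the host gene's expression on a
#' common per-kilobase, per-million scale (under unit gene length the gene's
#' TPM serves directly); raising the intron FPKM with everything else fixed
#' can never move an observation from retained to spliced.
#'
#' @param fpkm Intron FPKM (vectorized over observations).
#' @param intron_cov_frac Fraction of the intron body covered.
#' @param adj_exon_expr Adjacent-exon expression.
#' @param adj_exon_cov_frac Adjacent-exon coverage fraction.
#' @param gene_tpm Host-gene expression in the same cell/compartment; `NA`
#'   is an error naming the gene.
#' @param gene_id Gene identifiers, used in error messages.
#' @param config Configuration list supplying the thresholds.
#' @return Character vector in `{"retained", "spliced", "discarded"}`.
#' @export
classify_intron <- function(fpkm, intron_cov_frac, adj_exon_expr,
                            adj_exon_cov_frac, gene_tpm,
                            gene_id = NULL, config = default_config()) {
  if (anyNA(gene_tpm)) {
    bad <- which(is.na(gene_tpm))[1]
    stop("missing gene TPM for gene '",
         if (!is.null(gene_id)) gene_id[bad] else bad, "'", call. = FALSE)
  }
  n <- length(fpkm)
  stopifnot(length(intron_cov_frac) == n, length(adj_exon_expr) == n,
            length(adj_exon_cov_frac) == n, length(gene_tpm) == n)
  ratio <- ifelse(gene_tpm > 0, fpkm / gene_tpm, Inf)
  state <- rep("discarded", n)
  retained <- ratio >= config$ri_min_ratio &
    intron_cov_frac >= config$ri_min_intron_cov &
    adj_exon_expr > 0
  spliced <- ratio < config$spliced_max_ratio &
    adj_exon_cov_frac >= config$spliced_min_exon_cov
  state[spliced] <- "spliced"
  state[retained] <- "retained"
  state[gene_tpm < config$gene_min_tpm] <- "discarded"
  state
}

#' Classify a full intron quantification table
#'
#' Looks up the host gene's TPM for every (intron, cell, compartment) row
#' from the raw compartment matrices and applies [classify_intron()].
#'
#' @param quant Intron quantification table (see [read_intron_quant()]).
#' @param cyt,nuc Raw TPM matrices.
#' @param config Configuration list.
#' @return The `quant` table with `gene_tpm` and `state` columns appended.
#' @export
classify_table <- function(quant, cyt, nuc, config = default_config()) {
  get_tpm <- function(mat, genes, cells) {
    missing_g <- setdiff(unique(genes), rownames(mat))
    if (length(missing_g) > 0)
      stop("missing gene TPM for gene '", missing_g[1], "'", call. = FALSE)
    unclass(mat)[cbind(genes, cells)]
  }
  gt <- numeric(nrow(quant))
  is_cyt <- quant$compartment == "cyt"
  gt[is_cyt] <- get_tpm(cyt, quant$gene_id[is_cyt], quant$cell_id[is_cyt])
  gt[!is_cyt] <- get_tpm(nuc, quant$gene_id[!is_cyt], quant$cell_id[!is_cyt])
  quant$gene_tpm <- gt
  quant$state <- classify_intron(quant$fpkm, quant$intron_cov_frac,
                                 quant$adj_exon_expr, quant$adj_exon_cov_frac,
                                 gt, quant$gene_id, config)
  quant
}

#' Retention probability per intron and compartment
#'
#' The proportion of cells in which the intron is retained. By default the
#' denominator is the assessable cells (retained + spliced; discarded cells
#' carry no information); set `denominator = "all"` to divide by every cell
#' with an observation. `NA` when the denominator is zero.
#'
#' @param calls Classified table from [classify_table()] (needs `intron_id`,
#'   `compartment`, `state`).
#' @param denominator `"assessable"` or `"all"`.
#' @return Data frame with one row per intron: `intron_id`, `p_nuc`,
#'   `p_cyt`, `n_nuc`, `n_cyt` (denominator sizes).
#' @export
retention_probability <- function(calls, denominator = c("assessable", "all")) {
  denominator <- match.arg(denominator)
  one <- function(comp) {
    k <- calls[calls$compartment == comp, , drop = FALSE]
    if (nrow(k) == 0) {
      return(data.frame(intron_id = character(0), p = numeric(0),
                        n = numeric(0), stringsAsFactors = FALSE))
    }
    ret <- tapply(k$state == "retained", k$intron_id, sum)
    den <- if (denominator == "assessable") {
      tapply(k$state != "discarded", k$intron_id, sum)
    } else {
      tapply(rep(TRUE, nrow(k)), k$intron_id, sum)
    }
    p <- ifelse(den > 0, ret / den, NA_real_)
    data.frame(intron_id = names(p), p = as.numeric(p), n = as.numeric(den),
               stringsAsFactors = FALSE)
  }
  pn <- one("nuc")
  pc <- one("cyt")
  out <- merge(pn, pc, by = "intron_id", all = TRUE, suffixes = c("_nuc", "_cyt"))
  names(out) <- c("intron_id", "p_nuc", "n_nuc", "p_cyt", "n_cyt")
  out[, c("intron_id", "p_nuc", "p_cyt", "n_nuc", "n_cyt")]
}

#' Call nuclear- and cytoplasmic-retained introns
#'
#' An intron whose retention probability is at least `delta` (default 0.25)
#' higher in the nuclear fraction is an NRI; at least `delta` higher in the
#' cytoplasmic fraction, a CRI; otherwise neither. The threshold is
#' inclusive. `NA` probabilities give `NA`.
#'
#' @param p_nuc,p_cyt Retention probabilities (vectorized).
#' @param delta Calling threshold.
#' @return Character vector in `{"NRI", "CRI", "neither"}` (or `NA`).
#' @export
call_nri_cri <- function(p_nuc, p_cyt, delta = 0.25) {
  d <- p_nuc - p_cyt
  out <- ifelse(d >= delta, "NRI", ifelse(-d >= delta, "CRI", "neither"))
  out[is.na(d)] <- NA_character_
  out
}

#' Keep only the longest intron among overlapping calls
#'
#' Among introns on the same chromosome and strand whose half-open intervals
#' overlap, only the longest is flagged unique; shorter overlapping introns
#' are discarded greedily (ties broken by leftmost start, then lexicographic
#' id). Transitive chains resolve greedily by length, and the result is
#' independent of input order.
#'
#' @param nris Data frame with columns `intron_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @return The input with a logical `unique` column appended.
#' @export
filter_unique <- function(nris) {
  need <- c("intron_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(nris))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  len <- nris$end - nris$start
  ord <- order(-len, nris$start, nris$intron_id)
  keep <- logical(nrow(nris))
  for (grp in split(ord, paste(nris$chrom[ord], nris$strand[ord]))) {
    kept_idx <- integer(0)
    for (i in grp) {
      overlaps <- any(nris$start[i] < nris$end[kept_idx] &
                      nris$start[kept_idx] < nris$end[i])
      if (!overlaps) kept_idx <- c(kept_idx, i)
    }
    keep[kept_idx] <- TRUE
  }
  nris$unique <- keep
  nris
}

#' Build the NRI/CRI table from classified calls
#'
#' Combines [retention_probability()], [call_nri_cri()] and
#' [filter_unique()] (the unique flag is resolved among NRIs and among CRIs
#' separately).
#'
#' @param calls Classified table from [classify_table()].
#' @param annotation Intron annotation (for coordinates).
#' @param config Configuration list.
#' @return Data frame: `intron_id`, `gene_id`, coordinates, `p_nuc`,
#'   `p_cyt`, `delta`, `class`, `unique`.
#' @export
nri_table <- function(calls, annotation, config = default_config()) {
  probs <- retention_probability(calls, config$retention_denominator)
  tab <- merge(annotation, probs, by = "intron_id")
  tab$delta <- tab$p_nuc - tab$p_cyt
  tab$class <- call_nri_cri(tab$p_nuc, tab$p_cyt, config$nri_min_delta)
  tab$unique <- FALSE
  for (cls in c("NRI", "CRI")) {
    sel <- which(!is.na(tab$class) & tab$class == cls)
    if (length(sel) > 0) {
      tab$unique[sel] <- filter_unique(tab[sel, , drop = FALSE])$unique
    }
  }
  tab[order(tab$intron_id), , drop = FALSE]
}

#' Correlation between NRI probability and retention-linked expression change
#'
#' For each called NRI, cells (in the stated compartment) are split into
#' those where the intron is retained and those where it is spliced; the
#' log2 fold change of host-gene expression between the two groups is
#' computed, and the Pearson correlation across introns between the
#' retention probability and that fold change is returned with a
#' t-approximation p-value. Introns with fewer than 2 cells in either group
#' are excluded and reported.
#'
#' The fold change is the geometric-mean fold change, i.e. the difference in
#' mean `log2(TPM + 1)` between the two cell groups. Because the retention
#' probability controls the group sizes, a ratio of arithmetic group means
#' is biased downward more strongly in the smaller group (Jensen's
#' inequality on the noisy mean of skewed expression), which by itself
#' induces a spurious probability-vs-fold-change correlation; the mean of
#' per-cell log expression has the same expectation in both groups under the
#' null whatever their sizes, so the geometric-mean fold change is free of
#' that artifact while preserving real expression shifts.
#'
#' @param calls Classified table from [classify_table()].
#' @param expr Gene-by-cell TPM matrix of the compartment under study.
#' @param nris NRI table ([nri_table()]); rows with `class == "NRI"` are
#'   used (pass a pre-filtered table to study CRIs).
#' @param compartment `"nuc"` or `"cyt"`.
#' @return A list with `table` (per-intron probability and fold change),
#'   `r`, `p`, `n_used`, `n_excluded`.
#' @export
nri_expression_correlation <- function(calls, expr, nris,
                                       compartment = c("nuc", "cyt")) {
  compartment <- match.arg(compartment)
  sel <- nris[!is.na(nris$class) & nris$class == "NRI", , drop = FALSE]
  k <- calls[calls$compartment == compartment, , drop = FALSE]
  expr <- unclass(expr)

  rows <- lapply(seq_len(nrow(sel)), function(i) {
    ki <- k[k$intron_id == sel$intron_id[i], , drop = FALSE]
    gene <- sel$gene_id[i]
    ret_cells <- ki$cell_id[ki$state == "retained"]
    spl_cells <- ki$cell_id[ki$state == "spliced"]
    if (length(ret_cells) < 2 || length(spl_cells) < 2) return(NULL)
    lfc <- mean(log2(expr[gene, ret_cells] + 1)) -
           mean(log2(expr[gene, spl_cells] + 1))
    pr <- if (compartment == "nuc") sel$p_nuc[i] else sel$p_cyt[i]
    data.frame(intron_id = sel$intron_id[i], gene_id = gene,
               probability = pr, log2fc = lfc, stringsAsFactors = FALSE)
  })
  used <- do.call(rbind, rows)
  n_excluded <- nrow(sel) - if (is.null(used)) 0 else nrow(used)
  if (n_excluded > 0)
    message(n_excluded, " intron(s) excluded (fewer than 2 retained or spliced cells)")
  if (is.null(used) || nrow(used) < 2)
    stop("need at least 2 introns with both cell groups to correlate", call. = FALSE)
  r <- stats::cor(used$probability, used$log2fc)
  p <- correlation_p_value(r, nrow(used))
  list(table = used, r = r, p = p, n_used = nrow(used), n_excluded = n_excluded)
}
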