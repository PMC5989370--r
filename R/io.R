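#' Construct a compartment expression matrix
#'
#' A compartment matrix holds gene-by-cell TPM values for one subcellular
#' fraction (cytoplasm or nucleus) of a set of cells. Values must be
#' non-negative and finite, and gene/cell identifiers unique. For raw TPM
#' input every column should sum to one million; deviations beyond the
#' relative tolerance produce a warning, not an error, because rescaled
#' sub-matrices (alpha/beta-weighted) legitimately sum to a fraction of 1e6.
#'
#' @param values Numeric matrix, genes in rows, cells in columns, with
#'   dimnames set.
#' @param compartment `"cyt"` or `"nuc"`.
#' @param tol Relative tolerance for the column-sum diagnostic.
#' @param check_sums Whether to run the column-sum diagnostic.
#' @return The matrix with class `compartment_matrix` and a `compartment`
#'   attribute.
#' @export
compartment_matrix <- function(values, compartment = c("cyt", "nuc"),
                               tol = 1e-3, check_sums = TRUE) {
  compartment <- match.arg(compartment)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("gene (row) and cell (column) identifiers are required", call. = FALSE)
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g) > 0)
    stop("duplicated gene identifier(s): ", paste(dup_g, collapse = ", "), call. = FALSE)
  dup_c <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_c) > 0)
    stop("duplicated cell identifier(s): ", paste(dup_c, collapse = ", "), call. = FALSE)
  if (any(!is.finite(values)))
    stop("non-finite expression values", call. = FALSE)
  if (any(values < 0))
    stop("negative expression values", call. = FALSE)
  if (check_sums) {
    cs <- colSums(values)
    off <- abs(cs - 1e6) > 1e6 * tol
    if (any(off)) {
      warning(sprintf("%d of %d columns deviate from a 1e6 TPM sum (range %.4g-%.4g)",
                      sum(off), length(cs), min(cs), max(cs)), call. = FALSE)
    }
  }
  structure(values, compartment = compartment,
            class = c("compartment_matrix", "matrix", "array"))
}

#' @export
print.compartment_matrix <- function(x, ...) {
  cat(sprintf("compartment_matrix [%s]: %d genes x %d cells\n",
              attr(x, "compartment"), nrow(x), ncol(x)))
  cat(sprintf("  column sums: %.4g - %.4g\n", min(colSums(x)), max(colSums(x))))
  invisible(x)
}

#' Read a gene-by-cell expression matrix
#'
#' Expects a tab-separated file with gene identifiers in the first column
#' and a header row of cell identifiers. Duplicate identifiers, negative
#' values and non-numeric cells are hard errors; the offending row/column is
#' reported.
#'
#' @param path Path to a TSV file.
#' @param compartment `"cyt"` or `"nuc"`.
#' @param tol Relative tolerance for the column-sum diagnostic.
#' @return A [compartment_matrix()].
#' @export
read_compartment_matrix <- function(path, compartment = c("cyt", "nuc"), tol = 1e-3) {
  compartment <- match.arg(compartment)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("expected a gene-id column plus at least one cell column", call. = FALSE)
  genes <- df[[1]]
  vals <- df[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(vals) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, colnames(vals)))
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric value at row %d (gene '%s'), column '%s'",
                 bad[1, 1], genes[bad[1, 1]], colnames(vals)[bad[1, 2]]), call. = FALSE)
  }
  if (anyNA(num)) stop("missing expression values", call. = FALSE)
  rownames(num) <- genes
  m <- compartment_matrix(num, compartment, tol = tol)
  message(sprintf("read %d genes x %d cells [%s] from %s (column sums %.4g-%.4g)",
                  nrow(m), ncol(m), compartment, path,
                  min(colSums(m)), max(colSums(m))))
  m
}

#' Write an expression matrix as TSV
#'
#' @param mat Gene-by-cell matrix with dimnames.
#' @param path Output path.
#' @export
write_compartment_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat),
                   formatC(unclass(mat), digits = 17, format = "g"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an intron annotation in BED6 format
#'
#' The name field must be `<intron_id>|<gene_id>`. Coordinates are 0-based
#' half-open (BED convention). Introns whose length is not strictly greater
#' than `min_length` are dropped, and the number dropped is reported.
#'
#' @param path Path to a BED6 file (no header).
#' @param min_length Minimum intron length in nt (strict inequality).
#' @return A data frame with columns `intron_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `length_nt`.
#' @export
read_intron_annotation <- function(path, min_length = 50L) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("expected BED6 (chrom, start, end, name, score, strand)", call. = FALSE)
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  parts <- strsplit(df$name, "|", fixed = TRUE)
  ok <- lengths(parts) >= 2
  if (any(!ok)) {
    stop("malformed name field (expected '<intron_id>|<gene_id>'): ",
         df$name[which(!ok)[1]], call. = FALSE)
  }
  ann <- data.frame(
    intron_id = vapply(parts, `[[`, "", 1),
    gene_id   = vapply(parts, `[[`, "", 2),
    chrom     = df$chrom,
    start     = as.integer(df$start),
    end       = as.integer(df$end),
    strand    = df$strand,
    stringsAsFactors = FALSE
  )
  if (any(ann$start >= ann$end))
    stop("intron with start >= end: ", ann$intron_id[which(ann$start >= ann$end)[1]],
         call. = FALSE)
  dup <- unique(ann$intron_id[duplicated(ann$intron_id)])
  if (length(dup) > 0)
    stop("duplicated intron identifier(s): ", paste(dup, collapse = ", "), call. = FALSE)
  ann$length_nt <- ann$end - ann$start
  short <- ann$length_nt <= min_length
  if (any(short)) {
    message(sprintf("dropped %d intron(s) with length <= %d nt", sum(short), min_length))
  }
  ann[!short, , drop = FALSE]
}

#' Write an intron annotation as BED6
#'
#' @param ann Data frame as returned by [read_intron_annotation()].
#' @param path Output path.
#' @export
write_intron_annotation <- function(ann, path) {
  bed <- data.frame(ann$chrom, ann$start, ann$end,
                    paste(ann$intron_id, ann$gene_id, sep = "|"),
                    0L, ann$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-intron quantification table
#'
#' TSV with one row per (intron, cell, compartment) and columns `intron_id`,
#' `gene_id`, `cell_id`, `compartment`, `fpkm`, `intron_cov_frac`,
#' `adj_exon_expr`, `adj_exon_cov_frac`.
#'
#' @param path Input path.
#' @return A validated data frame.
#' @export
read_intron_quant <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("intron_id", "gene_id", "cell_id", "compartment", "fpkm",
            "intron_cov_frac", "adj_exon_expr", "adj_exon_cov_frac")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("intron quantification table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(df$compartment %in% c("cyt", "nuc")))
    stop("compartment must be 'cyt' or 'nuc'", call. = FALSE)
  if (any(df$fpkm < 0) || any(df$adj_exon_expr < 0))
    stop("negative expression in intron quantification table", call. = FALSE)
  if (any(df$intron_cov_frac < 0 | df$intron_cov_frac > 1) ||
      any(df$adj_exon_cov_frac < 0 | df$adj_exon_cov_frac > 1))
    stop("coverage fractions must lie in [0, 1]", call. = FALSE)
  df
}

#' Read per-cell qPCR delta-Ct records
#'
#' TSV with columns `cell_id`, `marker_gene`, `delta_ct`, where
#' `delta_ct = Ct_nuc - Ct_cyt` for the marker in that cell.
#'
#' @param path Input path.
#' @return A data frame.
#' @export
read_qpcr <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "marker_gene", "delta_ct")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("qPCR table is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$delta_ct)))
    stop("non-finite delta_ct values", call. = FALSE)
  df
}

#' Read a pseudotime ordering
#'
#' TSV with columns `cell_id` and `pseudotime` (for example an ordering
#' exported from an external trajectory tool). Ranks are recomputed from the
#' pseudotime values, 0-based.
#'
#' @param path Input path.
#' @return A data frame with columns `cell_id`, `pseudotime`, `rank`.
#' @export
read_pseudotime <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "pseudotime")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("pseudotime table is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$cell_id))
    stop("duplicated cell identifiers in pseudotime table", call. = FALSE)
  df$rank <- rank(df$pseudotime, ties.method = "first") - 1L
  df
}

#' Read a cell-cycle phase gene-set file
#'
#' Two-column TSV (`gene_id`, `phase`) with phase in `{G1, G2}`.
#'
#' @param path Input path.
#' @return A list with elements `g1_genes` and `g2_genes`.
#' @export
read_phase_gene_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "phase")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("gene-set table is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!all(df$phase %in% c("G1", "G2")))
    stop("phase must be 'G1' or 'G2'", call. = FALSE)
  sets <- list(g1_genes = df$gene_id[df$phase == "G1"],
               g2_genes = df$gene_id[df$phase == "G2"])
  if (length(intersect(sets$g1_genes, sets$g2_genes)) > 0)
    stop("G1 and G2 gene sets must be disjoint", call. = FALSE)
  sets
}

#' Read splice-site sequences from FASTA
#'
#' One record per intron end with identifiers `<intron_id>|5p` (9 nt:
#' exonic 3-mer + intronic 6-mer around the donor site) or `<intron_id>|3p`
#' (23 nt: intronic 20-mer + exonic 3-mer around the acceptor site). Records
#' of the wrong length are an error naming the record.
#'
#' @param path FASTA path.
#' @return A data frame with columns `intron_id`, `site`, `seq`.
#' @export
read_splice_sites <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- names(ss)
  parts <- strsplit(ids, "|", fixed = TRUE)
  ok <- lengths(parts) == 2 & vapply(parts, function(p) p[2] %in% c("5p", "3p"), TRUE)
  if (any(!ok))
    stop("malformed splice-site record id (expected '<intron_id>|5p' or '|3p'): ",
         ids[which(!ok)[1]], call. = FALSE)
  site <- vapply(parts, `[[`, "", 2)
  expected <- ifelse(site == "5p", 9L, 23L)
  wrong <- Biostrings::width(ss) != expected
  if (any(wrong))
    stop(sprintf("splice-site record '%s' has length %d, expected %d",
                 ids[which(wrong)[1]], Biostrings::width(ss)[which(wrong)[1]],
                 expected[which(wrong)[1]]), call. = FALSE)
  data.frame(intron_id = vapply(parts, `[[`, "", 1),
             site = site,
             seq = as.character(ss),
             stringsAsFactors = FALSE)
}

#' Write splice-site sequences as FASTA
#'
#' @param sites Data frame with columns `intron_id`, `site`, `seq`.
#' @param path Output path.
#' @export
write_splice_sites <- function(sites, path) {
  ss <- Biostrings::DNAStringSet(sites$seq)
  names(ss) <- paste(sites$intron_id, sites$site, sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Serialize / restore the planted ground truth of a simulated experiment
#'
#' Structured JSON so that tests and scripts can assert recovery against the
#' generator's planted values.
#'
#' @param truth Ground-truth list from [simulate_experiment()].
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
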