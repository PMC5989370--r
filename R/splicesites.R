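#' Build a position-weight matrix from training sequences
#'
#' Per-position base frequencies with a pseudocount (default 0.5 per base
#' per position), expressed as log2-odds against a uniform background. All
#' training sequences must share one length; a deviating record is an error
#' naming it.
#'
#' @param seqs Character vector of equal-length DNA sequences.
#' @param pseudocount Added to every base count at every position.
#' @return A 4 x width numeric matrix (rows A, C, G, T) of log2-odds scores,
#'   with class `splice_pwm`.
#' @export
build_pwm <- function(seqs, pseudocount = 0.5) {
  if (length(seqs) == 0) stop("no training sequences", call. = FALSE)
  w <- nchar(seqs[1])
  bad <- which(nchar(seqs) != w)
  if (length(bad) > 0)
    stop(sprintf("training sequence %d has length %d, expected %d",
                 bad[1], nchar(seqs[bad[1]]), w), call. = FALSE)
  bases <- c("A", "C", "G", "T")
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  counts <- vapply(seq_len(w), function(j) {
    tab <- table(factor(chars[, j], levels = bases))
    as.numeric(tab)
  }, numeric(4))
  freq <- (counts + pseudocount) / (length(seqs) + 4 * pseudocount)
  pwm <- log2(freq / 0.25)
  dimnames(pwm) <- list(bases, NULL)
  structure(pwm, class = c("splice_pwm", "matrix", "array"))
}

#' Score sequences against a position-weight matrix
#'
#' Sum of per-position log2-odds. A sequence whose length does not match the
#' PWM width is an error naming the record.
#'
#' @param pwm A `splice_pwm` from [build_pwm()].
#' @param seqs Character vector of sequences.
#' @param ids Optional record names for error messages.
#' @return Numeric vector of scores.
#' @export
score_sequences <- function(pwm, seqs, ids = NULL) {
  w <- ncol(pwm)
  bad <- which(nchar(seqs) != w)
  if (length(bad) > 0) {
    nm <- if (!is.null(ids)) ids[bad[1]] else as.character(bad[1])
    stop(sprintf("sequence record '%s' has length %d, expected %d",
                 nm, nchar(seqs[bad[1]]), w), call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  idx_base <- match(chars, rownames(pwm))
  if (anyNA(idx_base)) stop("non-ACGT character in sequence", call. = FALSE)
  scores <- matrix(pwm[cbind(as.vector(idx_base),
                             rep(seq_len(w), each = length(seqs)))],
                   nrow = length(seqs))
  rowSums(scores)
}

#' Splice-site strength scores for all introns
#'
#' Trains a donor (5', 9-mer) and an acceptor (3', 23-mer) PWM on the
#' splice-site sequences of the training introns (normally the fully spliced
#' set) and scores every intron against both.
#'
#' @param sites Splice-site table (`intron_id`, `site`, `seq`), see
#'   [read_splice_sites()].
#' @param training_ids Intron ids whose sequences train the PWMs.
#' @param pseudocount PWM pseudocount.
#' @return A list with `scores` (data frame `intron_id`, `score5`, `score3`)
#'   and the two PWMs (`pwm5`, `pwm3`).
#' @export
splice_site_scores <- function(sites, training_ids, pseudocount = 0.5) {
  s5 <- sites[sites$site == "5p", , drop = FALSE]
  s3 <- sites[sites$site == "3p", , drop = FALSE]
  bad5 <- which(nchar(s5$seq) != 9)
  if (length(bad5) > 0)
    stop(sprintf("splice-site record '%s|5p' has length %d, expected 9",
                 s5$intron_id[bad5[1]], nchar(s5$seq[bad5[1]])), call. = FALSE)
  bad3 <- which(nchar(s3$seq) != 23)
  if (length(bad3) > 0)
    stop(sprintf("splice-site record '%s|3p' has length %d, expected 23",
                 s3$intron_id[bad3[1]], nchar(s3$seq[bad3[1]])), call. = FALSE)
  tr5 <- s5$seq[s5$intron_id %in% training_ids]
  tr3 <- s3$seq[s3$intron_id %in% training_ids]
  if (length(tr5) == 0 || length(tr3) == 0)
    stop("no training sequences among the supplied intron ids", call. = FALSE)
  pwm5 <- build_pwm(tr5, pseudocount)
  pwm3 <- build_pwm(tr3, pseudocount)
  sc5 <- data.frame(intron_id = s5$intron_id,
                    score5 = score_sequences(pwm5, s5$seq, s5$intron_id),
                    stringsAsFactors = FALSE)
  sc3 <- data.frame(intron_id = s3$intron_id,
                    score3 = score_sequences(pwm3, s3$seq, s3$intron_id),
                    stringsAsFactors = FALSE)
  list(scores = merge(sc5, sc3, by = "intron_id"), pwm5 = pwm5, pwm3 = pwm3)
}

#' Compare splice-site strength between retained and spliced introns
#'
#' One-sided Mann-Whitney U test of the hypothesis that retained introns
#' have lower splice-site scores than fully spliced introns, separately for
#' the donor and acceptor scores.
#'
#' @param scores Score table from [splice_site_scores()] (`$scores`).
#' @param ri_ids,spliced_ids Intron id sets to compare.
#' @return A list with elements `five_prime` and `three_prime`, each holding
#'   `U` and `p`.
#' @export
compare_splice_scores <- function(scores, ri_ids, spliced_ids) {
  one <- function(col) {
    x <- scores[[col]][scores$intron_id %in% ri_ids]
    y <- scores[[col]][scores$intron_id %in% spliced_ids]
    if (length(x) == 0 || length(y) == 0)
      stop("empty group in splice-score comparison", call. = FALSE)
    wt <- stats::wilcox.test(x, y, alternative = "less", exact = FALSE)
    list(U = unname(wt$statistic), p = wt$p.value,
         n_ri = length(x), n_spliced = length(y))
  }
  list(five_prime = one("score5"), three_prime = one("score3"))
}
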