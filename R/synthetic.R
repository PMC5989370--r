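#' Simulate a paired nuclear/cytoplasmic single-cell RNA-seq experiment
#'
#' Generates the complete set of inputs the pipeline consumes — cytoplasmic
#' and nuclear TPM matrices for the same cells, per-cell qPCR delta-Ct
#' records for marker genes, a per-intron quantification table with BED-style
#' coordinates, splice-site sequences, and a true pseudotime ordering —
#' together with the planted ground truth, so that every downstream stage has
#' a recoverable target.
#'
#' The generative model, in order:
#' 1. Per-gene log10 mean abundance `mu_g ~ Normal(mu_mean, mu_sd)`; the
#'    marker genes (GAPDH, HBG1, HBG2) are pinned near their configured
#'    abundance so the qPCR-based weighting has high-count anchors in both
#'    fractions, as it does for real housekeeping/globin markers.
#' 2. Latent nuclear transcription
#'    `t_gc = mu_g + a_g cos(theta_c + phase_g) + b_g tau_c + Normal(0, sigma_t)`,
#'    where the cosine term applies to the planted G1/G2 cell-cycle genes
#'    (G2 genes in antiphase) and the trajectory term to planted DEGs.
#' 3. Nuclear abundance `n_gc = 10^t_gc * eps`, cytoplasmic abundance
#'    `c_gc = 10^(mu_g + s(|rho_g| d_gc + (1-|rho_g|) u_gc) + b'_g (tau_c - lag)) * kappa_c * eps`,
#'    where `d_gc` is the nuclear deviation from `mu_g`, `u_gc` an
#'    independent latent of comparable marginal, `s = sign(rho_g)` (negative
#'    coupling negates the shared latent), and `kappa_c` is set so that the
#'    cell's true cytoplasmic fraction of transcripts equals `f_c`.
#' 4. Sequencing counts are multinomial with `reads_per_compartment` draws
#'    per compartment per cell from the abundance simplex; TPM is
#'    `count / reads * 1e6` under a unit gene length (gene lengths cancel in
#'    every downstream formula here).
#' 5. qPCR `delta_Ct` per marker is `log2(absolute cyt marker abundance /
#'    absolute nuc marker abundance) + Normal(0, sigma_ct)`. Defining
#'    delta-Ct on absolute abundance makes the qPCR-derived cytoplasmic
#'    weight a consistent estimator of `f_c`, which is exactly the property
#'    the in silico normalization assumes of its markers.
#' 6. Introns: planted NRIs get nuclear/cytoplasmic retention probabilities
#'    with `p_nuc - p_cyt` at least the call threshold plus a margin;
#'    background introns are retained with equal probability in both
#'    fractions. Per cell per compartment retention is Bernoulli; a retained
#'    intron gets FPKM between 10% and 50% of the gene with near-complete
#'    intron-body coverage, a spliced one gets under 1% with adequate
#'    adjacent-exon coverage. Retention of a planted NRI additionally boosts
#'    the gene's nuclear expression in that cell, in proportion to the
#'    intron's retention probability, planting the positive
#'    retention-vs-expression relationship in the nucleus (and none in the
#'    cytoplasm).
#' 7. Splice sites: background (spliced) introns are sampled from a strong
#'    consensus position-weight matrix (GT..AG cores), planted NRIs from a
#'    weakened one.
#'
#' All distributions are generator design choices: the model emulates the
#' statistical structure the pipeline targets (compartment coupling,
#' cell-cycle oscillation, nuclear intron retention, compartment-divergent
#' differentiation), not the mechanistic kinetics of transcription or export.
#'
#' @param config Configuration list; the `sim` sub-list holds the generator
#'   parameters (see [default_config()]).
#' @param seed Integer seed; the single source of randomness for the run.
#' @return A list with elements `cyt`, `nuc` ([compartment_matrix()]),
#'   `qpcr`, `intron_annotation`, `intron_quant`, `splice_sites`,
#'   `pseudotime` (data frames) and `truth` (planted ground-truth list).
#' @export
simulate_experiment <- function(config = default_config(), seed = config$seed) {
  p <- config$sim
  set.seed(seed)
  G <- as.integer(p$n_genes)
  M <- as.integer(p$n_cells)
  L <- p$reads_per_compartment
  markers <- names(p$marker_tpm)
  if (G < length(markers) + p$n_g1 + p$n_g2 + 10)
    stop("n_genes too small for the requested gene sets", call. = FALSE)

  genes <- c(markers, sprintf("gene%04d", seq_len(G - length(markers))))
  cells <- sprintf("cell%03d", seq_len(M))

  f_c <- rep(p$cytoplasmic_fraction, M)
  names(f_c) <- cells
  if (any(f_c <= 0 | f_c >= 1))
    stop("cytoplasmic fraction must lie strictly inside (0, 1)", call. = FALSE)

  ## (1) per-gene log10 means; markers pinned to their configured scale
  mu <- stats::rnorm(G, p$mu_mean, p$mu_sd)
  names(mu) <- genes
  mu[markers] <- log10(p$marker_tpm / 3.55)  # approximate TPM -> latent scale

  ## gene roles -----------------------------------------------------------
  nonmarker <- setdiff(genes, markers)
  cc_pool <- sample(nonmarker, p$n_g1 + p$n_g2)
  g1_genes <- cc_pool[seq_len(p$n_g1)]
  g2_genes <- cc_pool[p$n_g1 + seq_len(p$n_g2)]
  if (length(intersect(g1_genes, g2_genes)) > 0)
    stop("G1 and G2 gene sets overlap", call. = FALSE)

  ## nucleus-cytoplasm coupling rho: mixture over non-marker genes
  rho <- numeric(G)
  names(rho) <- genes
  rho[markers] <- 1
  n_non <- length(nonmarker)
  n_high <- round(p$rho_high_frac * n_non)
  n_mid  <- round(p$rho_mid_frac * n_non)
  n_low  <- round(p$rho_low_frac * n_non)
  n_neg  <- round(p$rho_neg_frac * n_non)
  shuffled <- sample(nonmarker)
  idx <- 0
  take <- function(n) {
    out <- shuffled[idx + seq_len(n)]
    idx <<- idx + n
    out
  }
  rho[take(n_high)] <- stats::runif(n_high, 0.8, 1.0)
  rho[take(n_mid)]  <- stats::runif(n_mid, 0.3, 0.8)
  rho[take(n_low)]  <- stats::runif(n_low, 0.0, 0.3)
  rho[take(n_neg)]  <- stats::runif(n_neg, -0.8, -0.2)
  ## cell-cycle genes oscillate coherently in both compartments
  rho[c(g1_genes, g2_genes)] <- stats::runif(p$n_g1 + p$n_g2, 0.8, 1.0)

  ## trajectory -----------------------------------------------------------
  trajectory <- isTRUE(p$trajectory)
  if (trajectory) {
    day <- sort(rep(seq_len(p$n_days) - 1L, length.out = M))
    tau <- (day + stats::runif(M, 0.05, 0.95)) / p$n_days
    deg_pool <- setdiff(nonmarker, c(g1_genes, g2_genes))
    deg_genes <- sample(deg_pool, p$n_deg)
    draw_effect <- function(n) {
      sample(c(-1, 1), n, replace = TRUE) *
        stats::runif(n, p$deg_effect_min, p$deg_effect_max)
    }
    ## compartment-divergent effects: equal marginal size, partial sharing,
    ## so the two fractions respond to the perturbation along largely
    ## different gene programs
    b_nuc <- draw_effect(p$n_deg)
    b_cyt <- p$deg_shared_cor * b_nuc +
      sqrt(1 - p$deg_shared_cor^2) * draw_effect(p$n_deg)
  } else {
    day <- rep(0L, M)
    tau <- rep(0, M)
    deg_genes <- character(0)
    b_nuc <- b_cyt <- numeric(0)
  }
  names(tau) <- names(day) <- cells

  ## (2) latent transcription ---------------------------------------------
  theta <- stats::runif(M, 0, 2 * pi)
  names(theta) <- cells
  amp <- numeric(G)
  names(amp) <- genes
  amp[c(g1_genes, g2_genes)] <- p$cellcycle_amplitude
  phase <- numeric(G)
  names(phase) <- genes
  phase[g2_genes] <- pi

  osc <- amp * cos(outer(phase, theta, `+`))            # G x M
  dev_n <- osc + matrix(stats::rnorm(G * M, 0, p$sigma_t), G, M)
  b_nuc_full <- b_cyt_full <- numeric(G)
  names(b_nuc_full) <- names(b_cyt_full) <- genes
  if (trajectory) {
    b_nuc_full[deg_genes] <- b_nuc
    b_cyt_full[deg_genes] <- b_cyt
  }

  ## independent latent with a comparable marginal, for the uncoupled part
  dev_u <- matrix(stats::rnorm(G * M, 0, sqrt(amp^2 / 2 + p$sigma_t^2)), G, M)

  s_rho <- sign(rho)
  s_rho[s_rho == 0] <- 1
  dev_c <- s_rho * (abs(rho) * dev_n + (1 - abs(rho)) * dev_u)

  t_c <- mu + dev_c + outer(b_cyt_full, pmax(tau - p$cyt_lag * trajectory, 0))
  t_n <- mu + dev_n + outer(b_nuc_full, tau)

  ## (6a) intron retention draws (needed now: retention boosts nuclear
  ## expression of planted NRI genes) --------------------------------------
  n_nri <- as.integer(p$n_nri)
  n_bg <- as.integer(p$n_background_introns)
  n_int <- n_nri + n_bg
  if (n_int > 0) {
    ## intron hosts: well-expressed genes outside the marker/cell-cycle/DEG
    ## sets; hosts are drawn from the weakly coupled pool, mirroring the
    ## observation that retention-regulated genes are the less
    ## compartment-correlated ones
    eligible <- setdiff(nonmarker, c(g1_genes, g2_genes, deg_genes))
    eligible <- eligible[mu[eligible] >= 1 & rho[eligible] < 0.8]
    if (length(eligible) < n_int)
      stop(sprintf("only %d genes eligible to host introns, %d requested",
                   length(eligible), n_int), call. = FALSE)
    host <- sample(eligible, n_int)
    intron_id <- sprintf("intron%04d", seq_len(n_int))
    is_nri <- c(rep(TRUE, n_nri), rep(FALSE, n_bg))

    delta <- stats::runif(n_int, p$nri_delta_min, p$nri_delta_max)
    p_cyt_i <- stats::runif(n_int, 0.05, pmax(0.05, 0.95 - delta))
    p_nuc_i <- pmin(p_cyt_i + delta, 0.99)
    p_bg <- stats::runif(n_int, p$background_p_min, p$background_p_max)
    p_nuc_i[!is_nri] <- p_bg[!is_nri]
    p_cyt_i[!is_nri] <- p_bg[!is_nri]

    ret_nuc <- matrix(stats::rbinom(n_int * M, 1, rep(p_nuc_i, M)), n_int, M)
    ret_cyt <- matrix(stats::rbinom(n_int * M, 1, rep(p_cyt_i, M)), n_int, M)
    rownames(ret_nuc) <- rownames(ret_cyt) <- intron_id

    ## nuclear expression boost for retained planted NRIs, scaled by the
    ## intron's retention probability
    if (p$nri_expr_coupling != 0 && n_nri > 0) {
      boost <- p$nri_expr_coupling * p_nuc_i[is_nri]
      t_n[host[is_nri], ] <- t_n[host[is_nri], ] + boost * ret_nuc[is_nri, , drop = FALSE]
    }
  }

  ## (3) abundances with multiplicative technical noise ---------------------
  eps_n <- matrix(10^stats::rnorm(G * M, 0, p$sigma_eps), G, M)
  eps_c <- matrix(10^stats::rnorm(G * M, 0, p$sigma_eps), G, M)
  n_ab <- 10^t_n * eps_n
  c_rel <- 10^t_c * eps_c
  kappa <- f_c / (1 - f_c) * colSums(n_ab) / colSums(c_rel)
  c_ab <- sweep(c_rel, 2, kappa, `*`)
  dimnames(n_ab) <- dimnames(c_ab) <- list(genes, cells)

  ## (4) multinomial sequencing and TPM -------------------------------------
  draw_tpm <- function(ab) {
    counts <- vapply(seq_len(M), function(j) {
      stats::rmultinom(1, L, ab[, j])[, 1]
    }, numeric(G))
    dimnames(counts) <- list(genes, cells)
    counts / L * 1e6
  }
  tpm_cyt <- draw_tpm(c_ab)
  tpm_nuc <- draw_tpm(n_ab)

  ## (5) qPCR delta-Ct on absolute marker abundance -------------------------
  dct_gapdh <- log2(c_ab["GAPDH", ] / n_ab["GAPDH", ]) +
    stats::rnorm(M, 0, p$sigma_ct)
  dct_hbg <- log2((c_ab["HBG1", ] + c_ab["HBG2", ]) /
                  (n_ab["HBG1", ] + n_ab["HBG2", ])) +
    stats::rnorm(M, 0, p$sigma_ct)
  qpcr <- data.frame(
    cell_id = rep(cells, 2),
    marker_gene = rep(c("GAPDH", "HBG"), each = M),
    delta_ct = c(dct_gapdh, dct_hbg),
    stringsAsFactors = FALSE
  )

  ## (6b) intron annotation, quantification table, splice sites -------------
  if (n_int > 0) {
    ilen <- sample(200:1500, n_int, replace = TRUE)
    istart <- cumsum(c(1000, utils::head(ilen, -1) + 500))
    ann <- data.frame(
      intron_id = intron_id, gene_id = host, chrom = "chr1",
      start = istart, end = istart + ilen,
      strand = sample(c("+", "-"), n_int, replace = TRUE),
      length_nt = ilen, stringsAsFactors = FALSE
    )

    quant_one <- function(comp, tpm, ret) {
      gt <- tpm[host, , drop = FALSE]           # host-gene TPM, introns x cells
      r <- as.vector(ret) == 1
      n <- n_int * M
      ratio <- numeric(n)
      ratio[r] <- stats::runif(sum(r), 0.10, 0.50)  # retained-intron FPKM ratio
      ratio[!r] <- stats::runif(sum(!r), 0, 0.01)
      icov <- numeric(n)
      icov[r] <- stats::runif(sum(r), 0.95, 1.0)
      icov[!r] <- stats::runif(sum(!r), 0, 0.2)
      data.frame(
        intron_id = rep(intron_id, M),
        gene_id = rep(host, M),
        cell_id = rep(cells, each = n_int),
        compartment = comp,
        fpkm = ratio * as.vector(gt),
        intron_cov_frac = icov,
        adj_exon_expr = as.vector(gt),
        adj_exon_cov_frac = stats::runif(n, 0.5, 1.0),
        stringsAsFactors = FALSE
      )
    }
    quant <- rbind(quant_one("cyt", tpm_cyt, ret_cyt),
                   quant_one("nuc", tpm_nuc, ret_nuc))

    sites <- rbind(
      data.frame(intron_id = intron_id, site = "5p",
                 seq = sample_splice_sites(splice_consensus("5p"), n_int,
                        ifelse(is_nri, p$pwm_weak_match, p$pwm_strong_match)),
                 stringsAsFactors = FALSE),
      data.frame(intron_id = intron_id, site = "3p",
                 seq = sample_splice_sites(splice_consensus("3p"), n_int,
                        ifelse(is_nri, p$pwm_weak_match, p$pwm_strong_match)),
                 stringsAsFactors = FALSE)
    )
    introns_truth <- data.frame(
      intron_id = intron_id, gene_id = host,
      class = ifelse(is_nri, "NRI", "background"),
      p_nuc = p_nuc_i, p_cyt = p_cyt_i, stringsAsFactors = FALSE
    )
  } else {
    ann <- quant <- sites <- introns_truth <- NULL
  }

  pseudotime <- data.frame(
    cell_id = cells, pseudotime = tau,
    rank = rank(tau, ties.method = "first") - 1L,
    stringsAsFactors = FALSE, row.names = NULL
  )

  truth <- list(
    f_c = f_c, rho = rho, g1_genes = g1_genes, g2_genes = g2_genes,
    theta = theta, tau = tau, day = day,
    introns = introns_truth,
    degs = if (trajectory) data.frame(gene_id = deg_genes, b_nuc = b_nuc,
                                      b_cyt = b_cyt, stringsAsFactors = FALSE) else NULL,
    markers = markers, cyt_lag = if (trajectory) p$cyt_lag else 0
  )

  list(
    cyt = compartment_matrix(tpm_cyt, "cyt"),
    nuc = compartment_matrix(tpm_nuc, "nuc"),
    qpcr = qpcr,
    intron_annotation = ann,
    intron_quant = quant,
    splice_sites = sites,
    pseudotime = pseudotime,
    truth = truth
  )
}

#' Splice-site consensus sequences used by the generator
#'
#' The donor 9-mer is exonic 3-mer + intronic 6-mer (GT core); the acceptor
#' 23-mer is intronic 20-mer (polypyrimidine tract, AG core) + exonic 3-mer.
#'
#' @param site `"5p"` or `"3p"`.
#' @return A character scalar.
#' @export
splice_consensus <- function(site = c("5p", "3p")) {
  site <- match.arg(site)
  if (site == "5p") "CAGGTAAGT" else "CTTTTTTTTTTTTTTTTCAGGTC"
}

## sample n sequences around a consensus: each position is the consensus base
## with probability match_p (recycled over sequences), otherwise uniform over
## the other three bases
sample_splice_sites <- function(consensus, n, match_p) {
  bases <- c("A", "C", "G", "T")
  cons <- strsplit(consensus, "")[[1]]
  w <- length(cons)
  match_p <- rep_len(match_p, n)
  out <- matrix("", n, w)
  for (j in seq_len(w)) {
    hit <- stats::runif(n) < match_p
    alt <- sample(setdiff(bases, cons[j]), n, replace = TRUE)
    out[, j] <- ifelse(hit, cons[j], alt)
  }
  apply(out, 1, paste0, collapse = "")
}
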