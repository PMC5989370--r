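#' Default run configuration
#'
#' Returns the full list of tunable parameters used across the pipeline,
#' with their default values. Every threshold used by any stage of the
#' analysis lives here, so that a single configuration object documents a
#' run completely. `read_config()` merges a user-supplied YAML file over
#' these defaults and rejects unknown keys.
#'
#' Top-level entries control the analysis stages; the `sim` sub-list
#' controls the synthetic-data generator (see [simulate_experiment()]).
#'
#' @return A named list of parameters.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$nri_min_delta
default_config <- function() {
  list(
    ## global
    seed = 1L,

    ## detection and correlation landscape
    detection_tpm        = 1,      # strict ">" threshold for a detected gene
    min_cells_expressed  = 5L,     # landscape admission: TPM > detection_tpm in >= this many cells, both fractions
    correlation_method   = "pearson",   # or "spearman"
    landscape_scale      = "insilico",  # or "raw": which TPM scale feeds the landscape
    tpm_sum_tol          = 1e-3,   # relative tolerance for the per-cell TPM column-sum check

    ## differential expression (negative-binomial exact test)
    de_max_p         = 0.001,
    de_min_lfc       = 1,
    dispersion_floor = 1e-8,

    ## intron retention calling
    ri_min_ratio        = 0.10,  # retained: intron expression >= 10% of the gene
    ri_min_intron_cov   = 0.95,  # retained: breadth of coverage over the intron body
    spliced_max_ratio   = 0.01,  # fully spliced: intron expression < 1% of the gene
    spliced_min_exon_cov = 0.50, # fully spliced: adjacent-exon coverage
    gene_min_tpm        = 2,     # introns on genes below this TPM are discarded outright
    nri_min_delta       = 0.25,  # |p_nuc - p_cyt| needed to call an NRI / CRI
    retention_denominator = "assessable",  # or "all": cells counted in the retention probability
    min_intron_length   = 50L,   # introns must be strictly longer than this (nt)
    pwm_pseudocount     = 0.5,   # per base per position, splice-site PWM

    ## trajectory dynamics
    n_pseudotime_bins = 5L,
    n_bootstrap       = 1000L,
    pca_scale         = FALSE,   # centre only by default; set TRUE for unit-variance features

    ## synthetic-data generator
    sim = list(
      n_genes = 2000L,
      n_cells = 60L,
      reads_per_compartment = 2e5,
      mu_mean  = 1,     # per-gene log10 mean abundance ~ Normal(mu_mean, mu_sd)
      mu_sd    = 1,
      sigma_t  = 0.5,   # per-cell biological variability of the latent, log10 scale
      sigma_eps = 0.1,  # multiplicative technical noise, log10 scale
      cytoplasmic_fraction = 0.84,  # true per-cell fraction of transcripts in the cytoplasm
      sigma_ct = 0.1,   # qPCR delta-Ct measurement noise, cycles
      marker_tpm = c(GAPDH = 3000, HBG1 = 400, HBG2 = 600),  # target marker abundance, TPM scale

      ## nucleus-cytoplasm coupling mixture (fractions of genes; remainder rho = 0)
      rho_high_frac = 0.25,  # rho ~ U(0.8, 1.0)
      rho_mid_frac  = 0.15,  # rho ~ U(0.3, 0.8)
      rho_low_frac  = 0.10,  # rho ~ U(0.0, 0.3)
      rho_neg_frac  = 0.10,  # rho ~ U(-0.8, -0.2)

      ## cell cycle
      n_g1 = 30L,
      n_g2 = 30L,
      cellcycle_amplitude = 0.5,  # log10 amplitude of the phase oscillation

      ## planted introns
      n_nri = 100L,
      n_background_introns = 200L,
      nri_delta_min = 0.40,   # planted p_nuc - p_cyt range (>= call threshold + margin)
      nri_delta_max = 0.60,
      background_p_min = 0.05,
      background_p_max = 0.50,
      nri_expr_coupling = 0.8,  # log10 nuclear expression boost at retention probability 1
      pwm_strong_match = 0.85,  # consensus-base probability, spliced splice sites
      pwm_weak_match   = 0.40,  # consensus-base probability, planted NRI splice sites

      ## differentiation trajectory (disabled by default: unperturbed culture)
      trajectory = FALSE,
      n_days = 5L,
      n_deg = 100L,
      deg_effect_min = 1,     # |b|, log10 change over the full trajectory
      deg_effect_max = 2,
      deg_shared_cor = 0.4,   # correlation between a gene's nuclear and cytoplasmic effects
      cyt_lag = 0.3           # pseudotime lag of the cytoplasm behind the nucleus (tau units)
    )
  )
}

#' Read a run configuration from YAML
#'
#' Loads a YAML file and merges it over [default_config()]. Keys absent from
#' the file keep their defaults; a key not present in the defaults is an
#' error (listing the valid keys), so typos cannot silently fall back to a
#' default. If the file does not set `seed`, the default seed is applied and
#' reported.
#'
#' @param path Path to a YAML configuration file.
#' @return The merged configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- default_config()

  check_keys <- function(supplied, known, where) {
    bad <- setdiff(names(supplied), names(known))
    if (length(bad) > 0) {
      stop(sprintf("unknown config key%s %s in '%s'; valid keys: %s",
                   if (length(bad) > 1) "s" else "",
                   paste(sQuote(bad), collapse = ", "), where,
                   paste(names(known), collapse = ", ")), call. = FALSE)
    }
  }
  check_keys(user, cfg, "config")
  if (!is.null(user$sim)) check_keys(user$sim, cfg$sim, "config$sim")

  if (is.null(user$seed)) {
    message("config: no seed supplied, using default seed ", cfg$seed)
  }
  out <- utils::modifyList(cfg, user)
  # YAML named lists arrive as lists; marker_tpm must be a named numeric vector
  if (is.list(out$sim$marker_tpm)) {
    out$sim$marker_tpm <- unlist(out$sim$marker_tpm)
  }
  out$seed <- as.integer(out$seed)
  out
}

#' Write a result table to a tab-separated file
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip reproduces double-precision values exactly.
#'
#' @param x A data frame.
#' @param path Output path.
#' @export
write_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  y <- x
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) y[[j]] <- formatC(y[[j]], digits = 17, format = "g")
  }
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path Input path.
#' @return A data frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
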