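# Two-trait GWAS summary-statistics simulator with known pleiotropic
# architecture, plus an LD-blocked genotype reference panel generator.
# Ground-truth labels allow empirical FDR/power evaluation downstream.

#' Simulation configuration
#'
#' Each SNP belongs to one of four mixture components: null, causal for trait
#' A only, causal for trait B only, or pleiotropic (causal for both). Causal
#' z-scores are drawn as Normal(s * mu, 1) with a random sign `s`; null
#' z-scores are standard normal. Two-sided p-values are `2 * pnorm(-|z|)`.
#'
#' @param seed Integer RNG seed (required; there is no default so every run
#'   is explicitly reproducible).
#' @param m_snps Total number of SNPs.
#' @param pi_null,pi_a,pi_b,pi_ab Mixture proportions (must sum to 1).
#' @param mu_a,mu_b Mean absolute non-centrality of causal z-scores.
#' @param n_samples Reference-panel sample count.
#' @param block_size SNPs per LD block in the panel.
#' @param rho Within-block latent correlation in \[0, 1).
#' @param maf_range Interval within (0, 0.5] from which per-SNP minor allele
#'   frequencies are drawn uniformly.
#' @param n_chrom Number of chromosomes the SNPs are laid out on (default
#'   22; small fixtures may use 1 so LD blocks stay contiguous).
#' @param independent_labels If `TRUE`, trait-A and trait-B causal status are
#'   assigned independently at marginal rates `pi_a + pi_ab` and
#'   `pi_b + pi_ab` (the negative-control design); `pi_ab` must then be 0.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed, m_snps = 20000,
                       pi_null = 0.90, pi_a = 0.04, pi_b = 0.04, pi_ab = 0.02,
                       mu_a = 3.0, mu_b = 3.0,
                       n_samples = 500, block_size = 10, rho = 0.9,
                       maf_range = c(0.05, 0.5), n_chrom = 22L,
                       independent_labels = FALSE) {
  if (missing(seed)) stop("sim_config: an explicit integer seed is required")
  pis <- c(pi_null, pi_a, pi_b, pi_ab)
  if (any(pis < 0) || abs(sum(pis) - 1) > 1e-12) {
    stop("mixture proportions must be non-negative and sum to 1")
  }
  if (independent_labels && pi_ab != 0) {
    stop("independent_labels requires pi_ab = 0")
  }
  stopifnot(m_snps >= 1, mu_a >= 0, mu_b >= 0, n_samples >= 2,
            block_size >= 1, rho >= 0, rho < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], n_chrom >= 1)
  structure(list(seed = as.integer(seed), m_snps = as.integer(m_snps),
                 pi_null = pi_null, pi_a = pi_a, pi_b = pi_b, pi_ab = pi_ab,
                 mu_a = mu_a, mu_b = mu_b, n_samples = as.integer(n_samples),
                 block_size = as.integer(block_size), rho = rho,
                 maf_range = maf_range, n_chrom = as.integer(n_chrom),
                 independent_labels = independent_labels),
            class = "sim_config")
}

#' Negative-control configuration
#'
#' Matched control design: the same marginal causal rates per trait as the
#' corresponding pleiotropic configuration, but trait-A and trait-B causal
#' labels assigned independently (no built-in pleiotropic component). Mirrors
#' conditioning on a genetically unrelated trait.
#'
#' @inheritParams sim_config
#' @param marginal_a,marginal_b Marginal causal proportion per trait
#'   (defaults equal the default pleiotropic design, 0.04 + 0.02).
#' @param ... Passed through to [sim_config()].
#' @export
negative_control_config <- function(seed, m_snps = 20000,
                                    marginal_a = 0.06, marginal_b = 0.06,
                                    ...) {
  sim_config(seed = seed, m_snps = m_snps,
             pi_null = 1 - marginal_a - marginal_b,
             pi_a = marginal_a, pi_b = marginal_b, pi_ab = 0,
             independent_labels = TRUE, ...)
}

#' Simulate paired GWAS summary statistics for two traits
#'
#' @param config A [sim_config()].
#' @return List with `stats_a`, `stats_b` (summary-statistics tables as from
#'   [read_summary_stats()]) and `truth` (`data.table`: `snp_id`,
#'   `component` in {null, a_only, b_only, pleiotropic}, `z_a`, `z_b`).
#' @export
simulate_two_trait_stats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$m_snps
  if (config$independent_labels) {
    causal_a <- stats::runif(m) < (config$pi_a + config$pi_ab)
    causal_b <- stats::runif(m) < (config$pi_b + config$pi_ab)
  } else {
    comp <- sample(4L, m, replace = TRUE,
                   prob = c(config$pi_null, config$pi_a, config$pi_b,
                            config$pi_ab))
    causal_a <- comp %in% c(2L, 4L)
    causal_b <- comp %in% c(3L, 4L)
  }
  component <- ifelse(causal_a & causal_b, "pleiotropic",
                      ifelse(causal_a, "a_only",
                             ifelse(causal_b, "b_only", "null")))
  sign_a <- sample(c(-1, 1), m, replace = TRUE)
  sign_b <- sample(c(-1, 1), m, replace = TRUE)
  z_a <- stats::rnorm(m) + ifelse(causal_a, sign_a * config$mu_a, 0)
  z_b <- stats::rnorm(m) + ifelse(causal_b, sign_b * config$mu_b, 0)
  map <- snp_map(m, config$n_chrom)
  mk <- function(z) {
    data.table::data.table(snp_id = map$snp_id, chrom = map$chrom,
                           pos = map$pos, pvalue = 2 * stats::pnorm(-abs(z)))
  }
  list(stats_a = mk(z_a), stats_b = mk(z_b),
       truth = data.table::data.table(snp_id = map$snp_id,
                                      component = component,
                                      z_a = z_a, z_b = z_b))
}

# rs1..rsM laid out on n_chrom chromosomes in contiguous chunks, 10 kb apart
snp_map <- function(m, n_chrom = 22L) {
  chrom <- as.character(ceiling(seq_len(m) * n_chrom / m))
  pos <- integer(m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- seq_along(idx) * 10000L
  }
  data.table::data.table(snp_id = paste0("rs", seq_len(m)),
                         chrom = chrom, pos = pos)
}

#' Simulate an LD-blocked genotype reference panel
#'
#' Within each block of `block_size` consecutive SNPs (blocks never straddle
#' a chromosome boundary), two haplotypes per sample are generated from a
#' Gaussian copula with exchangeable correlation `rho` and thresholded at the
#' quantile implied by the SNP's allele frequency, then summed to a 0/1/2
#' dosage. SNPs in different blocks are independent. Uses the RNG stream
#' seeded at `config$seed + 1` so panel and statistics draws do not interact.
#'
#' @param config A [sim_config()].
#' @return A `ref_panel` (see [read_reference_panel()]).
#' @export
simulate_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  m <- config$m_snps
  n <- config$n_samples
  map <- snp_map(m, config$n_chrom)
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  thr <- stats::qnorm(maf)
  dos <- matrix(0, nrow = m, ncol = n)
  sr <- sqrt(config$rho)
  se <- sqrt(1 - config$rho)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    blocks <- split(idx, ceiling(seq_along(idx) / config$block_size))
    for (blk in blocks) {
      k <- length(blk)
      for (hap in 1:2) {
        common <- stats::rnorm(n)
        latent <- sr * matrix(common, nrow = k, ncol = n, byrow = TRUE) +
          se * matrix(stats::rnorm(k * n), nrow = k)
        dos[blk, ] <- dos[blk, ] + (latent < thr[blk])
      }
    }
  }
  new_ref_panel(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                dosages = dos)
}

#' Empirical FDR and power of a set of called SNPs against simulation truth
#'
#' @param truth Truth table from [simulate_two_trait_stats()].
#' @param called Character vector of called SNP ids (subset of the truth).
#' @param direction One of `"A|B"` (relevant causal set: causal for A),
#'   `"B|A"` (causal for B), `"conjunction"` (pleiotropic only).
#' @return Named numeric: `empirical_fdr` (fraction of calls whose component
#'   is non-causal for the direction's target) and `power` (fraction of
#'   relevant causal SNPs called). Both 0 for an empty call set, by
#'   convention.
#' @export
evaluate_detection <- function(truth, called,
                               direction = c("A|B", "B|A", "conjunction")) {
  direction <- match.arg(direction)
  unknown <- setdiff(called, truth$snp_id)
  if (length(unknown) > 0) {
    stop("called SNP id(s) absent from truth: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  relevant <- switch(direction,
    "A|B" = truth$component %in% c("a_only", "pleiotropic"),
    "B|A" = truth$component %in% c("b_only", "pleiotropic"),
    "conjunction" = truth$component == "pleiotropic")
  if (length(called) == 0) {
    message("evaluate_detection: empty call set; returning (0, 0)")
    return(c(empirical_fdr = 0, power = 0))
  }
  is_called <- truth$snp_id %in% called
  c(empirical_fdr = sum(is_called & !relevant) / sum(is_called),
    power = if (sum(relevant) == 0) 0 else
      sum(is_called & relevant) / sum(relevant))
}
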