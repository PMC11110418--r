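#' Simulation configuration for two-sample MR summary statistics
#'
#' Collects the ground-truth parameters of the summary-statistic generator.
#' Defaults emulate the study conditions the package targets: a plasma-pQTL
#' exposure panel of ~7,200 European participants instrumenting a protein,
#' and a large biobank case-control outcome GWAS (~450,000 individuals).
#'
#' @param theta true causal effect of the exposure on the outcome (log-OR per
#'   SD of protein level).
#' @param n_instruments number of independent instruments J.
#' @param gamma_sd SD of the true instrument effects gamma_j (SD units of the
#'   protein per allele).
#' @param gamma_mean mean absolute instrument effect; `NULL` (default) sets it
#'   so the expected exposure z-statistic clears the genome-wide threshold
#'   (|z| ~ 8) at the least-informative allele frequency in `eaf_range`.
#' @param eaf_range effect-allele frequency range, drawn uniformly.
#' @param n_exposure,n_outcome exposure and outcome GWAS sample sizes.
#' @param pleiotropy_frac fraction of instruments with a direct (invalid)
#'   pleiotropic path to the outcome.
#' @param alpha_mean,alpha_sd mean and SD of the pleiotropic effects alpha_j
#'   on the invalid instruments (directional when `alpha_mean != 0`).
#' @param n_cohorts number of replication cohorts K for [simulate_cohorts()].
#' @param tau between-cohort SD of the cohort-specific causal effects.
#' @param seed integer seed; every generator is a pure function of its config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(theta = 0, n_instruments = 50, gamma_sd = 0.05,
                       gamma_mean = NULL, eaf_range = c(0.1, 0.9),
                       n_exposure = 7213, n_outcome = 449500,
                       pleiotropy_frac = 0, alpha_mean = 0, alpha_sd = 0,
                       n_cohorts = 4, tau = 0, seed = 1) {
  stopifnot(n_instruments >= 1, pleiotropy_frac >= 0, pleiotropy_frac <= 1,
            gamma_sd >= 0, alpha_sd >= 0, tau >= 0,
            length(eaf_range) == 2, eaf_range[1] > 0, eaf_range[2] < 1,
            eaf_range[1] <= eaf_range[2], n_exposure > 0, n_outcome > 0)
  if (is.null(gamma_mean)) {
    f_min <- eaf_range[which.max(abs(eaf_range - 0.5))]
    sx_max <- 1 / sqrt(2 * f_min * (1 - f_min) * n_exposure)
    gamma_mean <- 8 * sx_max
  }
  structure(list(theta = theta, n_instruments = n_instruments,
                 gamma_sd = gamma_sd, gamma_mean = gamma_mean,
                 eaf_range = eaf_range, n_exposure = n_exposure,
                 n_outcome = n_outcome, pleiotropy_frac = pleiotropy_frac,
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 n_cohorts = n_cohorts, tau = tau, seed = seed),
            class = "sim_config")
}

# per-allele standard error of a GWAS effect at allele frequency f;
# binary traits carry the balanced-design variance factor phi*(1-phi)=0.25
.gwas_se <- function(f, n, binary = FALSE) {
  v <- if (binary) 0.25 else 1
  1 / sqrt(2 * f * (1 - f) * n * v)
}

.assoc_records <- function(id, chrom, pos, ea, oa, eaf, beta, se, n) {
  data.frame(variant_id = id, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se,
             pvalue = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300),
             n = n, stringsAsFactors = FALSE)
}

# shared truth draw: instrument positions, frequencies and true effects
.draw_instrument_truth <- function(config, chrom = "1",
                                   pos_start = 1e6, pos_end = 3e6) {
  J <- config$n_instruments
  eaf <- stats::runif(J, config$eaf_range[1], config$eaf_range[2])
  gamma <- sample(c(-1, 1), J, replace = TRUE) *
    abs(stats::rnorm(J, config$gamma_mean, config$gamma_sd))
  n_invalid <- round(config$pleiotropy_frac * J)
  invalid <- if (n_invalid > 0) sort(sample.int(J, n_invalid)) else integer(0)
  alpha <- numeric(J)
  if (n_invalid > 0)
    alpha[invalid] <- stats::rnorm(n_invalid, config$alpha_mean, config$alpha_sd)
  alleles <- t(replicate(J, sample(c("A", "C", "G", "T"), 2)))
  list(variant_id = sprintf("rs%05d", seq_len(J)), chrom = chrom,
       pos = sort(round(stats::runif(J, pos_start, pos_end))),
       ea = alleles[, 1], oa = alleles[, 2],
       eaf = eaf, gamma = gamma, alpha = alpha, invalid = invalid)
}

.observe_pair <- function(tr, theta, config, trait_id, exposure_label,
                          outcome_label) {
  sx <- .gwas_se(tr$eaf, config$n_exposure)
  sy <- .gwas_se(tr$eaf, config$n_outcome, binary = TRUE)
  bx <- stats::rnorm(length(tr$gamma), tr$gamma, sx)
  # pleiotropic shifts act along the exposure-increasing allele, so a
  # non-zero alpha_mean is directional in the oriented (Egger) frame
  by <- stats::rnorm(length(tr$gamma),
                     theta * tr$gamma + sign(tr$gamma) * tr$alpha, sy)
  exposure <- summary_dataset(
    .assoc_records(tr$variant_id, tr$chrom, tr$pos, tr$ea, tr$oa, tr$eaf,
                   bx, sx, config$n_exposure),
    trait_id = trait_id, trait_type = "quantitative",
    cohort_label = exposure_label, n = config$n_exposure, validate = FALSE)
  outcome <- summary_dataset(
    .assoc_records(tr$variant_id, tr$chrom, tr$pos, tr$ea, tr$oa, tr$eaf,
                   by, sy, config$n_outcome),
    trait_id = paste0(trait_id, "_outcome"), trait_type = "binary",
    cohort_label = outcome_label, n = config$n_outcome, validate = FALSE)
  list(exposure = exposure, outcome = outcome)
}

#' Simulate exposure/outcome summary statistics for one protein
#'
#' Generates matched cis-pQTL exposure and disease outcome summary statistics
#' under a linear causal model `by_j ~ N(theta * gamma_j + alpha_j, sy_j^2)`,
#' with a configurable fraction of invalid (pleiotropic) instruments.
#' Standard errors scale with sample size and allele frequency as in a GWAS:
#' `1/sqrt(2 f (1-f) n)` for the quantitative exposure and
#' `1/sqrt(2 f (1-f) n * 0.25)` for the binary outcome.
#'
#' @param config a [sim_config()].
#' @return List with `exposure` and `outcome` (`summary_dataset`s over the
#'   same variants) and `truth` (theta, per-instrument gamma/alpha, ids of
#'   invalid instruments).
#' @export
simulate_instruments <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tr <- .draw_instrument_truth(config)
  pair <- .observe_pair(tr, config$theta, config, "protein", "exposure_cohort",
                        "outcome_cohort")
  list(exposure = pair$exposure, outcome = pair$outcome,
       truth = list(theta_true = config$theta, gamma = tr$gamma,
                    alpha = tr$alpha,
                    invalid_instrument_ids = tr$variant_id[tr$invalid]))
}

#' Simulate a multi-cohort replication series
#'
#' Cohort k receives its own causal effect `theta_k ~ N(theta, tau^2)`
#' (between-cohort heterogeneity) while the true instrument effects gamma_j
#' are shared; measurement noise is independent across cohorts.
#'
#' @param config a [sim_config()]; `n_cohorts` and `tau` control the series.
#' @return List with `cohorts` (list of `list(exposure, outcome)` pairs) and
#'   `truth` (theta, tau, per-cohort theta_k).
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$n_cohorts >= 1)
  set.seed(config$seed)
  tr <- .draw_instrument_truth(config)
  theta_k <- stats::rnorm(config$n_cohorts, config$theta, config$tau)
  cohorts <- lapply(seq_len(config$n_cohorts), function(k)
    .observe_pair(tr, theta_k[k], config, "protein",
                  sprintf("exposure_%d", k), sprintf("outcome_%d", k)))
  list(cohorts = cohorts,
       truth = list(theta_true = config$theta, tau = config$tau,
                    theta_per_cohort = theta_k,
                    invalid_instrument_ids = tr$variant_id[tr$invalid]))
}

#' Simulate a regional dataset pair for colocalization
#'
#' Builds an AR(1) LD matrix `Sigma_ij = ld_rho^|i-j|` over `n_snps_region`
#' variants and draws marginal z-vectors `z ~ MVN(Sigma lambda, Sigma)`,
#' where `lambda` places `causal_z` at the causal index of each trait:
#' the same index under H4, distinct indices under H3, one trait only under
#' H1/H2, and none under H0. Betas are `z * se` with `se = 1/sqrt(n)`.
#'
#' @param scenario one of `"H0".."H4"`.
#' @param n_snps_region number of variants M in the region (>= 2 for H3).
#' @param causal_z signal size at the causal variant(s).
#' @param ld_rho AR(1) correlation in `[0, 1)`.
#' @param n1,n2 sample sizes of the two traits.
#' @param seed integer seed.
#' @return List with `ds1`, `ds2` (`summary_dataset`s; trait 1 quantitative,
#'   trait 2 binary) and `truth` (scenario and causal indices).
#' @export
simulate_coloc_region <- function(scenario = c("H4", "H0", "H1", "H2", "H3"),
                                  n_snps_region = 100, causal_z = 8,
                                  ld_rho = 0, n1 = 10000, n2 = 10000,
                                  seed = 1) {
  scenario <- match.arg(scenario)
  M <- n_snps_region
  stopifnot(M >= 1, causal_z >= 0, ld_rho >= 0, ld_rho < 1)
  if (scenario == "H3" && M < 2) stop("H3 requires at least 2 SNPs")
  set.seed(seed)
  Sigma <- ld_rho ^ abs(outer(seq_len(M), seq_len(M), "-"))
  idx <- sample.int(M, if (scenario == "H3") 2 else min(1, M))
  causal1 <- switch(scenario, H0 = NA, H1 = idx[1], H2 = NA,
                    H3 = idx[1], H4 = idx[1])
  causal2 <- switch(scenario, H0 = NA, H1 = NA, H2 = idx[1],
                    H3 = idx[2], H4 = idx[1])
  lam <- function(ci) {
    l <- numeric(M)
    if (!is.na(ci)) l[ci] <- causal_z
    l
  }
  draw_z <- function(ci) MASS::mvrnorm(1, Sigma %*% lam(ci), Sigma)
  z1 <- draw_z(causal1)
  z2 <- draw_z(causal2)
  mk <- function(z, n, type, label) {
    se <- rep(1 / sqrt(n), M)
    summary_dataset(
      .assoc_records(sprintf("rs%05d", seq_len(M)), "1", seq_len(M) * 1000L,
                     rep("A", M), rep("G", M), rep(0.5, M), z * se, se, n),
      trait_id = label, trait_type = type, cohort_label = label, n = n,
      validate = FALSE)
  }
  list(ds1 = mk(z1, n1, "quantitative", "trait1"),
       ds2 = mk(z2, n2, "binary", "trait2"),
       truth = list(scenario = scenario, causal_snp_trait1 = causal1,
                    causal_snp_trait2 = causal2))
}

#' Simulate TWAS prediction weights and matched GWAS z-scores
#'
#' Emulates a pre-computed expression/protein weight panel: a sparse weight
#' vector over M variants, an AR(1) LD matrix, and a GWAS z-vector drawn as
#' `z ~ MVN(LD w eta, LD)`. Under `causal = TRUE` the scale `eta` is set so
#' the weighted-score association statistic has expectation
#' `6 * sqrt(h2 / 0.1)`; under `causal = FALSE` the mean is zero, so the
#' statistic is standard normal.
#'
#' @param M number of variants.
#' @param h2 nominal cis-heritability of the predicted trait; scales the
#'   causal signal.
#' @param causal does the predicted trait affect the GWAS phenotype?
#' @param seed integer seed.
#' @param n_nonzero number of non-zero weights (default `min(5, M)`).
#' @param ld_rho AR(1) LD parameter.
#' @return List with `weights`, `gwas_z`, `ld`.
#' @export
simulate_twas_weights <- function(M, h2 = 0.1, causal = FALSE, seed = 1,
                                  n_nonzero = min(5, M), ld_rho = 0.3) {
  stopifnot(M >= 1, h2 >= 0, n_nonzero >= 1, n_nonzero <= M)
  set.seed(seed)
  ld <- ld_rho ^ abs(outer(seq_len(M), seq_len(M), "-"))
  w <- numeric(M)
  w[sample.int(M, n_nonzero)] <- stats::rnorm(n_nonzero)
  qf <- drop(t(w) %*% ld %*% w)
  eta <- if (causal) 6 * sqrt(h2 / 0.1) / sqrt(qf) else 0
  z <- MASS::mvrnorm(1, ld %*% w * eta, ld)
  list(weights = w, gwas_z = as.numeric(z), ld = ld)
}

#' Simulate a scored protein-protein interaction edge list
#'
#' Erdos-Renyi graph over `n_nodes` proteins, the first `n_drug_targets` of
#' which are flagged as known drug targets; each realized edge carries an
#' interaction score drawn uniformly from `score_range`.
#'
#' @param n_nodes total proteins.
#' @param n_drug_targets how many nodes are known drug targets.
#' @param edge_density edge probability in `[0, 1]`.
#' @param seed integer seed.
#' @param score_range interval for the uniform edge scores.
#' @return List with `edges` (data.frame `node1`, `node2`, `score`) and
#'   `drug_targets` (character vector of target node ids).
#' @export
simulate_ppi_graph <- function(n_nodes, n_drug_targets, edge_density = 0.1,
                               seed = 1, score_range = c(0, 1)) {
  stopifnot(n_nodes >= n_drug_targets, edge_density >= 0, edge_density <= 1)
  set.seed(seed)
  nodes <- sprintf("P%03d", seq_len(n_nodes))
  pairs <- utils::combn(nodes, 2)
  present <- stats::runif(ncol(pairs)) < edge_density
  edges <- data.frame(node1 = pairs[1, present], node2 = pairs[2, present],
                      score = stats::runif(sum(present), score_range[1],
                                           score_range[2]),
                      stringsAsFactors = FALSE)
  list(edges = edges, drug_targets = nodes[seq_len(n_drug_targets)])
}
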