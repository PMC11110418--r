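#' Colocalization priors and effect-size hyperparameters
#'
#' Per-SNP prior probabilities of association with trait 1 only (`p1`),
#' trait 2 only (`p2`), and both (`p12`), plus the prior SD of true effects
#' entering the Wakefield approximate Bayes factor — 0.15 for quantitative
#' traits (SD units) and 0.2 for binary traits (log-OR), the conventional
#' defaults.
#'
#' @param p1,p2,p12 per-SNP priors; `p12 <= min(p1, p2)` required.
#' @param prior_sd_quant,prior_sd_binary prior effect SDs by trait type.
#' @return List of class `coloc_config`.
#' @export
coloc_config <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         prior_sd_quant = 0.15, prior_sd_binary = 0.2) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, p12 > 0, p12 < 1,
            p12 <= min(p1, p2))
  structure(list(p1 = p1, p2 = p2, p12 = p12,
                 prior_sd_quant = prior_sd_quant,
                 prior_sd_binary = prior_sd_binary),
            class = "coloc_config")
}

#' Log approximate Bayes factor for one association
#'
#' Wakefield's asymptotic Bayes factor against the null, on the log scale:
#' with `V = se^2`, `W = prior_sd^2`, `z = beta/se`,
#' `log ABF = 0.5 log(V/(V+W)) + z^2 W / (2 (V+W))`.
#'
#' @param beta,se association estimate and standard error (`se > 0`).
#' @param prior_sd prior SD of the true effect.
#' @return Log Bayes factor (vectorized).
#' @export
abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("se must be positive")
  V <- se^2
  W <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * log(V / (V + W)) + z2 * W / (2 * (V + W))
}

.logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf when equal within tolerance
.logdiffexp <- function(a, b) {
  if (b == -Inf) return(a)
  d <- b - a
  if (d >= 0) return(-Inf)
  a + log1p(-exp(d))
}

#' Single-causal-variant Bayesian colocalization
#'
#' Enumerates the five hypotheses about a region shared by two traits —
#' H0 no causal variant, H1/H2 a causal variant for one trait only, H3
#' distinct causal variants, H4 a shared causal variant — assuming at most
#' one causal variant per trait. Per-SNP Wakefield log-ABFs are combined in
#' log space (log-sum-exp throughout, so extreme z-scores do not overflow):
#' `S1 = p1 sum B1_j`, `S2 = p2 sum B2_j`, `S4 = p12 sum B1_j B2_j`,
#' `S3 = p1 p2 (sum B1 sum B2 - sum B1_j B2_j)`, `S0 = 1`, and posteriors
#' are the normalized S's.
#'
#' @param ds1,ds2 `summary_dataset`s over the same region; only variants
#'   present in both enter. The prior effect SD follows each dataset's
#'   `trait_type`.
#' @param config a [coloc_config()].
#' @return Object of class `coloc_result`: `pp` (named numeric `pp0..pp4`),
#'   `n_snps`, `log_s` (log hypothesis sums).
#' @export
coloc_abf <- function(ds1, ds2, config = coloc_config()) {
  stopifnot(inherits(ds1, "summary_dataset"),
            inherits(ds2, "summary_dataset"),
            inherits(config, "coloc_config"))
  shared <- intersect(ds1$records$variant_id, ds2$records$variant_id)
  if (length(shared) < 1) stop("no shared variants between the two datasets")
  r1 <- ds1$records[match(shared, ds1$records$variant_id), ]
  r2 <- ds2$records[match(shared, ds2$records$variant_id), ]
  sd1 <- if (ds1$study$trait_type == "binary") config$prior_sd_binary else config$prior_sd_quant
  sd2 <- if (ds2$study$trait_type == "binary") config$prior_sd_binary else config$prior_sd_quant
  lb1 <- abf(r1$beta, r1$se, sd1)
  lb2 <- abf(r2$beta, r2$se, sd2)
  lsum1 <- .logsumexp(lb1)
  lsum2 <- .logsumexp(lb2)
  lsum12 <- .logsumexp(lb1 + lb2)
  log_s <- c(
    h0 = 0,
    h1 = log(config$p1) + lsum1,
    h2 = log(config$p2) + lsum2,
    h3 = if (length(shared) < 2) -Inf
         else log(config$p1) + log(config$p2) +
           .logdiffexp(lsum1 + lsum2, lsum12),
    h4 = log(config$p12) + lsum12)
  denom <- .logsumexp(log_s)
  pp <- exp(log_s - denom)
  names(pp) <- paste0("pp", 0:4)
  structure(list(pp = pp, n_snps = length(shared), log_s = log_s),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc over %d shared SNP(s):\n", x$n_snps))
  print(round(x$pp, 4))
  cat(sprintf("PPH4 = %.1f%% -> %s\n", 100 * x$pp["pp4"],
              if (coloc_pass(x)) "colocalizes" else "no colocalization"))
  invisible(x)
}

#' Colocalization decision
#'
#' Shared-causal-variant evidence is called when the posterior probability of
#' H4 strictly exceeds the threshold (default 0.8).
#'
#' @param result a `coloc_result` (or a bare PPH4 number).
#' @param threshold decision threshold, default 0.8.
#' @return Logical.
#' @export
coloc_pass <- function(result, threshold = 0.8) {
  pp4 <- if (inherits(result, "coloc_result")) unname(result$pp["pp4"])
         else result
  pp4 > threshold
}
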