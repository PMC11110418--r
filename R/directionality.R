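#' Variance explained by a single variant from its z-statistic
#'
#' `r^2 = z^2 / (z^2 + n - 2)` with `z = beta/se` — valid for binary and
#' quantitative traits alike since it needs no allele frequency.
#'
#' @param beta,se association estimate and standard error.
#' @param n study sample size, > 2.
#' @return Variance explained in `[0, 1)`.
#' @export
snp_r2 <- function(beta, se, n) {
  if (any(n <= 2)) stop("snp_r2 requires n > 2")
  if (any(se <= 0)) stop("se must be positive")
  z2 <- (beta / se)^2
  z2 / (z2 + n - 2)
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure with the
#' variance they explain in the outcome. Correlations `r = sqrt(r^2)` are
#' Fisher-z transformed and compared with the independent-samples statistic
#' `z = (z_exp - z_out) / sqrt(1/(n_exp - 3) + 1/(n_out - 3))`. The causal
#' direction exposure -> outcome is supported (`direction_ok`) when the
#' exposure r-squared is larger and the test is significant.
#'
#' @param r2_exp,r2_out summed instrument r-squared for exposure and outcome,
#'   in `[0, 1)`.
#' @param n_exp,n_out sample sizes, > 3.
#' @param alpha significance level, default 0.05.
#' @return List of class `steiger_result`: `r2_exposure`, `r2_outcome`,
#'   `z_stat`, `pvalue`, `direction_ok`.
#' @export
steiger_test <- function(r2_exp, r2_out, n_exp, n_out, alpha = 0.05) {
  stopifnot(r2_exp >= 0, r2_exp < 1, r2_out >= 0, r2_out < 1)
  if (n_exp <= 3 || n_out <= 3) stop("steiger_test requires n > 3")
  z_exp <- atanh(sqrt(r2_exp))
  z_out <- atanh(sqrt(r2_out))
  z_stat <- (z_exp - z_out) / sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  pvalue <- 2 * stats::pnorm(-abs(z_stat))
  structure(list(r2_exposure = r2_exp, r2_outcome = r2_out, z_stat = z_stat,
                 pvalue = pvalue,
                 direction_ok = (r2_exp > r2_out) && (pvalue < alpha)),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("Steiger: r2_exp = %.3g, r2_out = %.3g, z = %.3f, p = %.3g -> %s\n",
              x$r2_exposure, x$r2_outcome, x$z_stat, x$pvalue,
              if (x$direction_ok) "direction supported" else "direction NOT supported"))
  invisible(x)
}

#' Steiger test from an MR fit's inputs
#'
#' Convenience wrapper: sums per-instrument [snp_r2()] over the (clumped,
#' hence approximately independent) instruments on both sides and runs
#' [steiger_test()].
#'
#' @param instr `harmonized_instruments`.
#' @param n_exp,n_out study sample sizes.
#' @param alpha significance level.
#' @return A `steiger_result`.
#' @export
steiger_from_instruments <- function(instr, n_exp, n_out, alpha = 0.05) {
  r2e <- min(sum(snp_r2(instr$bx, instr$sx, n_exp)), 1 - 1e-12)
  r2o <- min(sum(snp_r2(instr$by, instr$sy, n_out)), 1 - 1e-12)
  steiger_test(r2e, r2o, n_exp, n_out, alpha)
}

#' Reverse-direction MR
#'
#' Runs the full estimator suite with the disease as exposure and the
#' protein as outcome, instrumenting on genome-wide-significant disease
#' variants. A stringent corrected threshold (`p < 0.01`) guards the
#' reverse-causation call against multiplicity.
#'
#' @param outcome_as_exposure disease `summary_dataset` (new exposure).
#' @param protein_as_outcome protein `summary_dataset` (new outcome).
#' @param p_max instrument significance threshold, default `5e-8`.
#' @param p_significant reverse-significance threshold, default 0.01.
#' @param ... passed to [mr_fit()].
#' @return List of class `reverse_mr_result`: `fit` (`mr_fit` or `NULL`),
#'   `significant` (logical), `status` (`"tested"` or `"untestable"`).
#' @export
reverse_mr <- function(outcome_as_exposure, protein_as_outcome,
                       p_max = 5e-8, p_significant = 0.01, ...) {
  sig <- outcome_as_exposure
  sig$records <- sig$records[sig$records$pvalue < p_max, , drop = FALSE]
  if (nrow(sig$records) == 0)
    return(structure(list(fit = NULL, significant = FALSE,
                          status = "untestable"),
                     class = "reverse_mr_result"))
  instr <- harmonize(sig, protein_as_outcome)
  if (nrow(instr) == 0)
    return(structure(list(fit = NULL, significant = FALSE,
                          status = "untestable"),
                     class = "reverse_mr_result"))
  fit <- mr_fit(instr, ...)
  structure(list(fit = fit,
                 significant = is.finite(fit$selected$pvalue) &&
                   fit$selected$pvalue < p_significant,
                 status = "tested"),
            class = "reverse_mr_result")
}

#' Reverse-causality exclusion rule
#'
#' A protein-outcome pair is excluded only when both alarms fire: the
#' Steiger test does not support the forward direction AND reverse MR is
#' significant at the corrected threshold.
#'
#' @param steiger a `steiger_result` (or any list with `direction_ok`).
#' @param reverse_significant logical from [reverse_mr()].
#' @return `"keep"` or `"excluded"`.
#' @export
exclusion_rule <- function(steiger, reverse_significant) {
  if (!steiger$direction_ok && isTRUE(reverse_significant)) "excluded"
  else "keep"
}
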