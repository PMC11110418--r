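#' Cohort estimates for meta-analysis
#'
#' Builds the per-cohort `(beta, se)` input table, reconstructing log-scale
#' values from printed odds-ratio confidence intervals via [se_from_ci()]
#' when raw estimates are unavailable.
#'
#' @param cohort_label character vector of cohort names.
#' @param beta,se log-OR estimates and SEs; omit when supplying OR/CI.
#' @param or,lower,upper odds ratio and CI bounds (used when `beta` absent).
#' @param level CI level of the printed intervals.
#' @return data.frame with `cohort_label`, `beta`, `se`.
#' @export
cohort_estimates <- function(cohort_label, beta = NULL, se = NULL,
                             or = NULL, lower = NULL, upper = NULL,
                             level = 0.95) {
  if (is.null(beta)) {
    stopifnot(!is.null(or), !is.null(lower), !is.null(upper))
    beta <- log(or)
    se <- se_from_ci(lower, upper, level)
  }
  stopifnot(all(se > 0), length(beta) == length(se),
            length(cohort_label) == length(beta))
  data.frame(cohort_label = cohort_label, beta = beta, se = se,
             stringsAsFactors = FALSE)
}

.meta_result <- function(pooled_beta, pooled_se, q, df, tau2, model, k) {
  i2 <- if (df >= 1) i_squared(q, df) else 0
  structure(list(pooled_beta = pooled_beta, pooled_se = pooled_se,
                 pvalue = 2 * stats::pnorm(-abs(pooled_beta / pooled_se)),
                 q_stat = q, df = df, i2 = i2, tau2 = tau2, model = model,
                 k = k),
            class = "meta_result")
}

#' Fixed-effect (inverse-variance) meta-analysis
#'
#' `w_k = 1/se_k^2`; pooled beta is the weighted mean, pooled SE
#' `1/sqrt(sum w)`; Cochran's Q and I-squared reported.
#'
#' @param estimates data.frame from [cohort_estimates()] (columns `beta`,
#'   `se`).
#' @return Object of class `meta_result`.
#' @export
meta_fixed <- function(estimates) {
  stopifnot(nrow(estimates) >= 1)
  w <- 1 / estimates$se^2
  pooled <- sum(w * estimates$beta) / sum(w)
  q <- sum(w * (estimates$beta - pooled)^2)
  .meta_result(pooled, 1 / sqrt(sum(w)), q, nrow(estimates) - 1L, 0,
               "fixed", nrow(estimates))
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Moment estimator of the between-cohort variance,
#' `tau^2 = max(0, (Q - df) / (sum w - sum w^2 / sum w))` with fixed-effect
#' weights, then inverse-variance pooling with `w*_k = 1/(se_k^2 + tau^2)`.
#'
#' @inheritParams meta_fixed
#' @return Object of class `meta_result` (`model = "random"`; equals the
#'   fixed-effect result when `Q <= df`).
#' @export
meta_random_dl <- function(estimates) {
  stopifnot(nrow(estimates) >= 2)
  w <- 1 / estimates$se^2
  fixed <- meta_fixed(estimates)
  tau2 <- max(0, (fixed$q_stat - fixed$df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (estimates$se^2 + tau2)
  pooled <- sum(ws * estimates$beta) / sum(ws)
  .meta_result(pooled, 1 / sqrt(sum(ws)), fixed$q_stat, fixed$df, tau2,
               "random", nrow(estimates))
}

#' I-squared heterogeneity statistic
#'
#' `max(0, (Q - df)/Q) * 100` percent.
#'
#' @param q_stat Cochran's Q.
#' @param df degrees of freedom (cohorts minus one), >= 1.
#' @return Percent heterogeneity in `[0, 100)`.
#' @export
i_squared <- function(q_stat, df) {
  stopifnot(df >= 1)
  if (q_stat <= 0) return(0)
  max(0, (q_stat - df) / q_stat) * 100
}

#' Heterogeneity-driven model choice
#'
#' Random effects iff I-squared exceeds 50% (strictly).
#'
#' @param i2 I-squared percent.
#' @return `"fixed"` or `"random"`.
#' @export
select_model <- function(i2) {
  stopifnot(i2 >= 0, i2 < 100 + 1e-9)
  if (i2 > 50) "random" else "fixed"
}

#' Meta-analyze a protein's replication series
#'
#' Pools the per-cohort estimates, choosing fixed vs random effects by the
#' I-squared rule ([select_model()]).
#'
#' @inheritParams meta_fixed
#' @return A `meta_result` with the model actually applied.
#' @export
meta_analyze <- function(estimates) {
  if (nrow(estimates) == 1)
    return(.meta_result(estimates$beta, estimates$se, 0, 0L, 0, "fixed", 1L))
  fixed <- meta_fixed(estimates)
  if (select_model(fixed$i2) == "random") meta_random_dl(estimates) else fixed
}

#' @export
print.meta_result <- function(x, ...) {
  ci <- ci_from_beta(x$pooled_beta, x$pooled_se)
  cat(sprintf("%s-effect meta-analysis of %d cohort(s)\n", x$model, x$k))
  cat(sprintf("  pooled OR = %.4f (%.4f, %.4f), p = %.3g\n",
              ci["or"], ci["lower_or"], ci["upper_or"], x$pvalue))
  cat(sprintf("  Q = %.3f (df %d), I2 = %.2f%%, tau2 = %.4g\n",
              x$q_stat, x$df, x$i2, x$tau2))
  invisible(x)
}

#' Replication verdict for a discovered association
#'
#' Pass iff the pooled meta-analysis is significant and its direction agrees
#' with the discovery estimate.
#'
#' @param meta a `meta_result`.
#' @param discovery the discovery `mr_estimate` (or any list with `beta`).
#' @param alpha significance threshold, default 0.05.
#' @return `"pass"` or `"fail"`.
#' @export
replication_verdict <- function(meta, discovery, alpha = 0.05) {
  if (meta$pvalue < alpha && sign(meta$pooled_beta) == sign(discovery$beta))
    "pass" else "fail"
}
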