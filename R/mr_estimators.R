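#' @keywords internal
.mr_estimate <- function(method, beta, se, n_snp, ...) {
  extra <- list(...)
  est <- c(list(method = method, beta = beta, se = se,
                pvalue = if (is.finite(se) && se > 0)
                  2 * stats::pnorm(-abs(beta / se)) else NA_real_,
                or = exp(beta), n_snp = n_snp), extra)
  class(est) <- "mr_estimate"
  est
}

#' @export
print.mr_estimate <- function(x, ...) {
  ci <- ci_from_beta(x$beta, max(x$se, .Machine$double.eps))
  cat(sprintf("%s: beta = %.4f (se %.4f), OR = %.4f (%.4f, %.4f), p = %.3g, %d SNP(s)\n",
              x$method, x$beta, x$se, ci["or"], ci["lower_or"], ci["upper_or"],
              x$pvalue, x$n_snp))
  invisible(x)
}

#' Wald ratio estimate from a single instrument
#'
#' `beta = by / bx` with the first-order standard error `sy / |bx|` (the
#' exposure uncertainty is ignored, standard practice for strong
#' instruments); `second_order = TRUE` adds the delta-method term in
#' `sx`.
#'
#' @param inst one-row `harmonized_instruments` data.frame (or any list with
#'   `bx`, `sx`, `by`, `sy`).
#' @param second_order use the second-order delta-method SE.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(inst, second_order = FALSE) {
  if (inst$bx[1] == 0) stop("Wald ratio undefined for bx = 0")
  beta <- inst$by[1] / inst$bx[1]
  se <- if (second_order) {
    sqrt(inst$sy[1]^2 / inst$bx[1]^2 +
           inst$by[1]^2 * inst$sx[1]^2 / inst$bx[1]^4)
  } else {
    inst$sy[1] / abs(inst$bx[1])
  }
  .mr_estimate("wald_ratio", beta, se, 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of the outcome effects on the exposure effects
#' through the origin with weights `1/sy^2`:
#' `beta = sum(bx by w) / sum(bx^2 w)`, `se = 1/sqrt(sum(bx^2 w))`.
#' With `scale_overdispersion = TRUE` (default) the SE is inflated by
#' `max(1, sqrt(Q/(J-1)))` — the multiplicative random-effects model with a
#' fixed-effect floor. Cochran's Q and its chi-square p-value are reported.
#'
#' @param instr `harmonized_instruments` with >= 2 rows.
#' @param scale_overdispersion inflate the SE when Q exceeds its df?
#' @return An `mr_estimate` with `q_stat`, `q_df`, `q_pvalue`.
#' @export
ivw <- function(instr, scale_overdispersion = TRUE) {
  J <- nrow(instr)
  if (J < 2) stop("IVW needs >= 2 instruments; use wald_ratio()")
  w <- 1 / instr$sy^2
  beta <- sum(instr$bx * instr$by * w) / sum(instr$bx^2 * w)
  se <- 1 / sqrt(sum(instr$bx^2 * w))
  q <- sum(w * (instr$by - beta * instr$bx)^2)
  if (scale_overdispersion) se <- se * max(1, sqrt(q / (J - 1)))
  .mr_estimate("ivw", beta, se, J, q_stat = q, q_df = J - 1L,
               q_pvalue = stats::pchisq(q, J - 1, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted least-squares regression `by = a + b bx` with weights `1/sy^2`
#' after orienting every instrument to `bx >= 0` (both signs flipped). The
#' slope `b` is the pleiotropy-adjusted causal estimate; a non-zero intercept
#' `a` indicates directional pleiotropy. SEs carry the same multiplicative
#' overdispersion floor as [ivw()].
#'
#' @param instr `harmonized_instruments` with >= 3 rows.
#' @return An `mr_estimate` with `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_p`.
#' @export
egger <- function(instr) {
  J <- nrow(instr)
  if (J < 3) stop("MR-Egger needs >= 3 instruments")
  flip <- sign(instr$bx)
  flip[flip == 0] <- 1
  bx <- instr$bx * flip
  by <- instr$by * flip
  w <- 1 / instr$sy^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, X * w)
  fit <- solve(XtWX, crossprod(X, by * w))
  resid <- by - X %*% fit
  sigma2 <- max(1, sum(w * resid^2) / (J - 2))
  vc <- sigma2 * solve(XtWX)
  a <- fit[1]; b <- fit[2]
  se_a <- sqrt(vc[1, 1]); se_b <- sqrt(vc[2, 2])
  .mr_estimate("egger", b, se_b, J,
               egger_intercept = a, egger_intercept_se = se_a,
               egger_intercept_p = 2 * stats::pt(-abs(a / se_a), J - 2))
}

#' Weighted-median estimate
#'
#' Robust to up to 50% invalid instruments (by weight): per-instrument Wald
#' ratios are ordered and the median of the weighted empirical distribution
#' (weights `bx^2/sy^2`, midpoint-standardized cumulative weights
#' `(S_j - w_j/2)/S_J`) is interpolated at 0.5. The SE comes from a seeded
#' parametric bootstrap resampling `bx` and `by` from their sampling
#' distributions.
#'
#' @param instr `harmonized_instruments` with >= 3 rows.
#' @param n_boot bootstrap replicates for the SE (default 1000; 0 skips the
#'   bootstrap and returns `se = NA`).
#' @param seed bootstrap seed.
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(instr, n_boot = 1000, seed = 1) {
  J <- nrow(instr)
  if (J < 3) stop("weighted median needs >= 3 instruments")
  wm <- function(ratio, w) {
    ord <- order(ratio)
    ratio <- ratio[ord]; w <- w[ord]
    p <- (cumsum(w) - w / 2) / sum(w)
    stats::approx(p, ratio, xout = 0.5, rule = 2)$y
  }
  beta <- wm(instr$by / instr$bx, instr$bx^2 / instr$sy^2)
  se <- NA_real_
  if (n_boot > 0) {
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(J, instr$bx, instr$sx)
      by <- stats::rnorm(J, instr$by, instr$sy)
      wm(by / bx, bx^2 / instr$sy^2)
    }, numeric(1))
    se <- stats::sd(reps)
  }
  .mr_estimate("weighted_median", beta, se, J)
}

# leave-one-out IVW predictions (fixed-effect weights) for an instrument set;
# vectorized over the columns of by/bx matrices for the simulation null
.loo_predictions <- function(bx, by, w) {
  Sxx <- sum(w * bx^2)
  Sxy <- sum(w * bx * by)
  beta_loo <- (Sxy - w * bx * by) / (Sxx - w * bx^2)
  beta_loo * bx
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Compares the observed weighted residual sum of squares about
#' leave-one-out IVW predictions with a seeded parametric null
#' (`by* ~ N(yhat_j, sy^2)`, `bx* ~ N(bx, sx^2)`, residuals recomputed about
#' each simulated set's own leave-one-out predictions). The global p-value is
#' `(1 + #(RSS* >= RSS_obs)) / (n_sim + 1)`; per-instrument p-values are
#' computed from each instrument's simulated residual distribution,
#' Bonferroni-corrected, and instruments below `outlier_alpha` are removed
#' before the IVW re-estimate.
#'
#' @param instr `harmonized_instruments` with >= 4 rows.
#' @param n_sim parametric draws (default 1000).
#' @param seed simulation seed.
#' @param outlier_alpha significance level for the corrected per-instrument
#'   test.
#' @return An `mr_estimate` (the outlier-corrected IVW when outliers are
#'   found, otherwise the plain IVW) with `presso_global_p`, `outlier_ids`,
#'   `presso_rss`.
#' @export
mr_presso <- function(instr, n_sim = 1000, seed = 1, outlier_alpha = 0.05) {
  J <- nrow(instr)
  if (J < 4) stop("MR-PRESSO needs >= 4 instruments")
  if (n_sim < 1) stop("n_sim must be a positive integer")
  w <- 1 / instr$sy^2
  yhat <- .loo_predictions(instr$bx, instr$by, w)
  res_obs <- w * (instr$by - yhat)^2
  rss_obs <- sum(res_obs)
  set.seed(seed)
  res_sim <- matrix(0, n_sim, J)
  for (s in seq_len(n_sim)) {
    bxs <- stats::rnorm(J, instr$bx, instr$sx)
    bys <- stats::rnorm(J, yhat, instr$sy)
    yhs <- .loo_predictions(bxs, bys, w)
    res_sim[s, ] <- w * (bys - yhs)^2
  }
  global_p <- (1 + sum(rowSums(res_sim) >= rss_obs)) / (n_sim + 1)
  p_snp <- (1 + colSums(res_sim >= rep(res_obs, each = n_sim))) / (n_sim + 1)
  p_snp_adj <- pmin(1, p_snp * J)
  outliers <- which(p_snp_adj < outlier_alpha)
  if (length(outliers) >= J - 1)
    stop("MR-PRESSO flagged (almost) every instrument; set unusable")
  if (length(outliers) > 0 && global_p < outlier_alpha) {
    est <- ivw(instr[-outliers, , drop = FALSE])
    est$method <- "mr_presso_corrected"
  } else {
    est <- ivw(instr)
    est$method <- "mr_presso"
  }
  est$presso_global_p <- global_p
  est$presso_rss <- rss_obs
  est$outlier_ids <- instr$variant_id[outliers]
  est
}

#' Robust adjusted profile score estimate
#'
#' Solves the profile-score estimating equation
#' `sum_j (by_j - theta bx_j) bx_j / (sy_j^2 + theta^2 sx_j^2) = 0`
#' for `theta` by root bracketing on `[-10, 10]`, which accounts for
#' exposure measurement error (weak instruments) unlike IVW. The SE is the
#' profile-score information `1/sqrt(sum bx^2/(sy^2 + theta^2 sx^2))`,
#' which reduces to the fixed-effect IVW SE when `sx = 0`.
#'
#' @param instr `harmonized_instruments` with >= 2 rows.
#' @param bracket search interval for theta.
#' @return An `mr_estimate`.
#' @export
mr_raps <- function(instr, bracket = c(-10, 10)) {
  if (nrow(instr) < 2) stop("profile-score estimate needs >= 2 instruments")
  score <- function(theta)
    sum((instr$by - theta * instr$bx) * instr$bx /
          (instr$sy^2 + theta^2 * instr$sx^2))
  if (score(bracket[1]) * score(bracket[2]) > 0)
    stop("profile score has no sign change on the bracket; estimation failed")
  theta <- stats::uniroot(score, bracket, tol = 1e-12)$root
  se <- 1 / sqrt(sum(instr$bx^2 / (instr$sy^2 + theta^2 * instr$sx^2)))
  .mr_estimate("mr_raps", theta, se, nrow(instr))
}

#' Estimator-preference policy
#'
#' Selects the reported estimate from the fitted suite: IVW by default;
#' MR-Egger when the Egger intercept test detects directional pleiotropy
#' (`egger_intercept_p < alpha`); the MR-PRESSO outlier-corrected estimate
#' takes precedence when the global test is significant and outliers were
#' identified.
#'
#' @param candidates named list of `mr_estimate`s; `ivw` required, `egger`
#'   and `mr_presso` consulted when present.
#' @param alpha significance level for both diagnostics, default 0.05.
#' @return The chosen `mr_estimate` with a `selection_reason` element.
#' @export
choose_estimate <- function(candidates, alpha = 0.05) {
  if (is.null(candidates$ivw)) stop("candidates must include an 'ivw' estimate")
  presso <- candidates$mr_presso
  if (!is.null(presso) && !is.null(presso$presso_global_p) &&
      presso$presso_global_p < alpha && length(presso$outlier_ids) > 0) {
    presso$selection_reason <-
      sprintf("MR-PRESSO global p = %.3g with %d outlier(s); corrected estimate preferred",
              presso$presso_global_p, length(presso$outlier_ids))
    return(presso)
  }
  eg <- candidates$egger
  if (!is.null(eg) && !is.null(eg$egger_intercept_p) &&
      is.finite(eg$egger_intercept_p) && eg$egger_intercept_p < alpha) {
    eg$selection_reason <-
      sprintf("Egger intercept p = %.3g indicates directional pleiotropy; Egger slope preferred",
              eg$egger_intercept_p)
    return(eg)
  }
  out <- candidates$ivw
  out$selection_reason <- "no pleiotropy detected; IVW preferred by default"
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, `q_i = min_{j >= i} m p_(j) / j`.
#'
#' @param pvalues numeric vector in (0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  stats::p.adjust(pvalues, method = "BH")
}

#' Express an estimate as an odds ratio with 95% CI
#'
#' @param estimate an `mr_estimate`.
#' @param level CI level.
#' @return Named vector `c(or, lower_or, upper_or)`.
#' @export
beta_to_or <- function(estimate, level = 0.95) {
  ci_from_beta(estimate$beta, estimate$se, level)
}
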