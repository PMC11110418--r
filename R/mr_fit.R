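#' Fit the two-sample MR estimator suite for one exposure-outcome pair
#'
#' The package's central fitting function. Given harmonized instruments (or
#' an exposure/outcome `summary_dataset` pair, harmonized internally), it
#' fits every estimator the instrument count admits — Wald ratio (1 SNP),
#' IVW (>= 2), profile score (>= 2), MR-Egger and weighted median (>= 3),
#' MR-PRESSO (>= 4) — and applies the estimator-preference policy
#' ([choose_estimate()]) to nominate the reported estimate.
#'
#' @param exposure either a `harmonized_instruments` data.frame or an
#'   exposure `summary_dataset`.
#' @param outcome outcome `summary_dataset`; ignored when `exposure` is
#'   already harmonized.
#' @param alpha significance level of the preference policy diagnostics.
#' @param n_boot weighted-median bootstrap replicates.
#' @param n_sim MR-PRESSO parametric draws.
#' @param seed seed for the bootstrap and MR-PRESSO null.
#' @param scale_overdispersion IVW/Egger multiplicative overdispersion floor.
#' @return Object of class `mr_fit`: list with `instruments` (the harmonized
#'   data.frame), `estimates` (named list of `mr_estimate`s), `selected`
#'   (the policy choice), `alpha`, `seed`.
#' @seealso [summary.mr_fit()], [coef.mr_fit()], [confint.mr_fit()],
#'   [plot.mr_fit()]
#' @export
#' @examples
#' sim <- simulate_instruments(sim_config(theta = 0.3, seed = 7))
#' fit <- mr_fit(sim$exposure, sim$outcome, seed = 7)
#' fit
#' coef(fit)
mr_fit <- function(exposure, outcome = NULL, alpha = 0.05, n_boot = 1000,
                   n_sim = 1000, seed = 1, scale_overdispersion = TRUE) {
  instr <- if (inherits(exposure, "harmonized_instruments")) {
    exposure
  } else {
    if (is.null(outcome))
      stop("outcome dataset required when exposure is not harmonized")
    harmonize(exposure, outcome)
  }
  J <- nrow(instr)
  if (J < 1) stop("no instruments available after harmonization")
  estimates <- list()
  if (J == 1) {
    estimates$wald_ratio <- wald_ratio(instr)
    selected <- estimates$wald_ratio
    selected$selection_reason <- "single instrument; Wald ratio"
  } else {
    estimates$ivw <- ivw(instr, scale_overdispersion)
    estimates$mr_raps <- tryCatch(mr_raps(instr), error = function(e) NULL)
    if (J >= 3) {
      estimates$egger <- egger(instr)
      estimates$weighted_median <- weighted_median(instr, n_boot, seed)
    }
    if (J >= 4)
      estimates$mr_presso <- tryCatch(mr_presso(instr, n_sim, seed, alpha),
                                      error = function(e) NULL)
    estimates <- Filter(Negate(is.null), estimates)
    selected <- choose_estimate(estimates, alpha)
  }
  structure(list(instruments = instr, estimates = estimates,
                 selected = selected, alpha = alpha, seed = seed),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("Two-sample MR fit: %d instrument(s)\n", nrow(x$instruments)))
  cat("Selected estimate (", x$selected$selection_reason, "):\n", sep = "")
  print(x$selected)
  invisible(x)
}

#' Summarize an MR fit
#'
#' @param object an `mr_fit`.
#' @param ... unused.
#' @return Object of class `summary.mr_fit` wrapping a per-method table.
#' @export
summary.mr_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$estimates, function(e)
    data.frame(method = e$method, beta = e$beta, se = e$se, or = e$or,
               pvalue = e$pvalue, n_snp = e$n_snp,
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  structure(list(table = tab, selected = object$selected,
                 diagnostics = list(
                   q_stat = object$estimates$ivw$q_stat,
                   q_pvalue = object$estimates$ivw$q_pvalue,
                   egger_intercept = object$estimates$egger$egger_intercept,
                   egger_intercept_p = object$estimates$egger$egger_intercept_p,
                   presso_global_p = object$estimates$mr_presso$presso_global_p,
                   outlier_ids = object$estimates$mr_presso$outlier_ids)),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  cat("Estimator suite:\n")
  print(x$table, digits = 4)
  d <- x$diagnostics
  if (!is.null(d$q_stat))
    cat(sprintf("Cochran Q = %.3f (p = %.3g)\n", d$q_stat, d$q_pvalue))
  if (!is.null(d$egger_intercept))
    cat(sprintf("Egger intercept = %.4f (p = %.3g)\n",
                d$egger_intercept, d$egger_intercept_p))
  if (!is.null(d$presso_global_p))
    cat(sprintf("MR-PRESSO global p = %.3g; %d outlier(s)\n",
                d$presso_global_p, length(d$outlier_ids)))
  cat("Selected: ", x$selected$method, " (", x$selected$selection_reason,
      ")\n", sep = "")
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, `[[`, numeric(1), "beta")
}

#' @export
confint.mr_fit <- function(object, parm = NULL, level = 0.95, ...) {
  ests <- object$estimates
  if (!is.null(parm)) ests <- ests[parm]
  out <- t(vapply(ests, function(e)
    ci_from_beta(e$beta, e$se, level)[2:3], numeric(2)))
  colnames(out) <- paste0(c("lower_", "upper_"),
                          format(100 * level, trim = TRUE), "%")
  out
}

#' Scatter plot of an MR fit
#'
#' Instrument outcome effects against exposure effects (oriented to
#' `bx >= 0`) with per-instrument error bars, the IVW line through the
#' origin, and the Egger line when fitted.
#'
#' @param x an `mr_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  instr <- x$instruments
  flip <- ifelse(instr$bx < 0, -1, 1)
  bx <- instr$bx * flip
  by <- instr$by * flip
  graphics::plot(bx, by, xlab = "SNP effect on exposure (SD/allele)",
                 ylab = "SNP effect on outcome (log-OR/allele)",
                 pch = 19, ...)
  graphics::segments(bx, by - 1.96 * instr$sy, bx, by + 1.96 * instr$sy,
                     col = "grey60")
  if (!is.null(x$estimates$ivw))
    graphics::abline(0, x$estimates$ivw$beta, col = "firebrick", lwd = 2)
  if (!is.null(x$estimates$egger))
    graphics::abline(x$estimates$egger$egger_intercept,
                     x$estimates$egger$beta, col = "steelblue",
                     lwd = 2, lty = 2)
  invisible(x)
}
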