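#' Simulate a multi-protein discovery panel
#'
#' Builds a proteome-style discovery input: each protein owns a locus on its
#' own chromosome with `n_instruments` cis-pQTLs, a subset of proteins carry
#' a true causal effect on the (binary) outcome, the rest are null. The
#' exposure and outcome datasets share variants, so the panel can be fed
#' straight to [run_discovery()].
#'
#' @param n_proteins panel size.
#' @param causal_ids indices (or names `"protein_001"`-style) of causal
#'   proteins.
#' @param theta causal log-OR per SD for the causal proteins.
#' @param n_instruments instruments per protein.
#' @param seed integer seed.
#' @param ... further arguments to [sim_config()] (sample sizes etc.).
#' @return List with `exposure`, `outcome` (`summary_dataset`s over all
#'   proteins' variants), `loci` (list of [gene_locus()]), `truth`
#'   (per-protein theta).
#' @export
simulate_panel <- function(n_proteins = 20, causal_ids = integer(0),
                           theta = 0.4, n_instruments = 10, seed = 1, ...) {
  if (is.character(causal_ids))
    causal_ids <- match(causal_ids, sprintf("protein_%03d", seq_len(n_proteins)))
  proteins <- sprintf("protein_%03d", seq_len(n_proteins))
  ex_list <- list()
  ou_list <- list()
  loci <- list()
  theta_true <- ifelse(seq_len(n_proteins) %in% causal_ids, theta, 0)
  for (i in seq_len(n_proteins)) {
    cfg <- sim_config(theta = theta_true[i], n_instruments = n_instruments,
                      seed = seed + i * 131, ...)
    sim <- simulate_instruments(cfg)
    rename <- function(ds) {
      ds$records$variant_id <- paste0(proteins[i], "_", ds$records$variant_id)
      ds$records$chrom <- as.character(i)
      ds
    }
    ex_list[[i]] <- rename(sim$exposure)$records
    ou_list[[i]] <- rename(sim$outcome)$records
    # instrument positions span [1e6, 3e6]; a 2 Mb gene body keeps them cis
    loci[[i]] <- gene_locus(proteins[i], as.character(i), 1e6, 3e6)
  }
  names(loci) <- proteins
  n_exp <- ex_list[[1]]$n[1]
  n_out <- ou_list[[1]]$n[1]
  list(exposure = summary_dataset(do.call(rbind, ex_list), "proteins",
                                  "quantitative", "exposure_cohort",
                                  n = n_exp, validate = FALSE),
       outcome = summary_dataset(do.call(rbind, ou_list), "disease",
                                 "binary", "outcome_cohort",
                                 n = n_out, validate = FALSE),
       loci = loci,
       truth = data.frame(protein_id = proteins, theta_true = theta_true,
                          stringsAsFactors = FALSE))
}

#' Proteome-wide MR discovery scan
#'
#' For every locus: select cis instruments, clump, harmonize against the
#' outcome, fit the estimator suite, apply the preference policy, and FDR-
#' correct the selected p-values across proteins (within the one outcome).
#'
#' @param exposure pQTL `summary_dataset` covering all proteins.
#' @param outcome disease `summary_dataset`.
#' @param loci list of [gene_locus()] objects, one per protein.
#' @param ld optional LD matrix for [ld_clump()]; `NULL` skips clumping.
#' @param p_max,cis_window,mhc instrument-selection parameters
#'   ([select_instruments()]).
#' @param fdr_max discovery significance threshold on the q-value.
#' @param seed seed passed to the stochastic estimators.
#' @param n_boot,n_sim weighted-median / MR-PRESSO effort; the discovery
#'   scan defaults them low since only the policy-selected estimate is kept.
#' @return List of class `mr_discovery`: `results` (one row per protein with
#'   instruments: method, beta, se, or, pvalue, fdr_q, significant, q/Egger/
#'   PRESSO diagnostics), `fits` (named list of `mr_fit`s), `skipped`
#'   (proteins without instruments, with reasons).
#' @export
run_discovery <- function(exposure, outcome, loci, ld = NULL,
                          p_max = 5e-8, cis_window = 1e6,
                          mhc = list("6", 26e6, 34e6), fdr_max = 0.05,
                          seed = 1, n_boot = 200, n_sim = 500) {
  rows <- list()
  fits <- list()
  skipped <- character(0)
  for (locus in loci) {
    sel <- select_instruments(exposure, locus, p_max, cis_window, mhc)
    sel <- ld_clump(sel, ld)
    if (nrow(sel$records) == 0) {
      skipped <- c(skipped, locus$gene_id)
      next
    }
    instr <- harmonize(sel, outcome)
    if (nrow(instr) == 0) {
      skipped <- c(skipped, locus$gene_id)
      next
    }
    fit <- mr_fit(instr, n_boot = n_boot, n_sim = n_sim, seed = seed)
    sel_est <- fit$selected
    fits[[locus$gene_id]] <- fit
    rows[[locus$gene_id]] <- data.frame(
      protein_id = locus$gene_id, n_snp = nrow(instr),
      method = sel_est$method, beta = sel_est$beta, se = sel_est$se,
      or = sel_est$or, pvalue = sel_est$pvalue,
      q_stat = sel_est$q_stat %||% NA_real_,
      egger_intercept_p = fit$estimates$egger$egger_intercept_p %||% NA_real_,
      presso_global_p = fit$estimates$mr_presso$presso_global_p %||% NA_real_,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  if (is.null(results)) {
    warning("no protein had usable instruments", call. = FALSE)
    results <- data.frame()
  } else {
    results$fdr_q <- bh_fdr(results$pvalue)
    results$significant <- results$fdr_q < fdr_max
    rownames(results) <- NULL
  }
  structure(list(results = results, fits = fits, skipped = skipped),
            class = "mr_discovery")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mr_discovery <- function(x, ...) {
  cat(sprintf("MR discovery scan: %d protein(s) tested, %d significant (FDR), %d skipped\n",
              nrow(x$results), sum(x$results$significant %||% FALSE),
              length(x$skipped)))
  invisible(x)
}

#' End-to-end drug-target triage
#'
#' Composes the full evidence chain for every FDR-significant discovery
#' protein: Steiger directionality + reverse MR (exclusion rule), multi-
#' cohort replication meta-analysis with the I-squared model switch,
#' Bayesian colocalization, TWAS/PWAS external validation, PPI drug-target
#' linkage, and the four-tier grading.
#'
#' @param discovery list with `exposure`, `outcome`, `loci` as for
#'   [run_discovery()] (a [simulate_panel()] output works directly).
#' @param replication named list: `protein_id` -> list of
#'   `list(exposure, outcome)` cohort pairs.
#' @param coloc_regions named list: `protein_id` -> `list(ds1, ds2)` regional
#'   datasets.
#' @param external data.frame with `protein_id`, `twas_q`, `pwas_q` (`NA`
#'   for proteins absent from a panel).
#' @param ppi list with `edges` and `drug_targets`
#'   ([simulate_ppi_graph()]-shaped).
#' @param seed seed for the stochastic estimators.
#' @param fdr_max discovery threshold.
#' @param pph4_threshold colocalization threshold.
#' @param ... further arguments to [run_discovery()].
#' @return List of class `mr_triage`: `discovery` (the scan), `profiles`
#'   (evidence data.frame), `tiers` (profiles with the `tier` column),
#'   `meta` (per-protein `meta_result`s).
#' @export
run_full <- function(discovery, replication = list(), coloc_regions = list(),
                     external = NULL, ppi = NULL, seed = 1, fdr_max = 0.05,
                     pph4_threshold = 0.8, ...) {
  scan <- run_discovery(discovery$exposure, discovery$outcome,
                        discovery$loci, seed = seed, fdr_max = fdr_max, ...)
  hits <- scan$results[scan$results$significant, , drop = FALSE]
  profiles <- list()
  metas <- list()
  for (pid in hits$protein_id) {
    fit <- scan$fits[[pid]]
    instr <- fit$instruments
    n_exp <- discovery$exposure$study$n
    n_out <- discovery$outcome$study$n
    st <- steiger_from_instruments(instr, n_exp, n_out)
    rev <- reverse_mr(discovery$outcome, discovery$exposure, seed = seed,
                      n_boot = 0, n_sim = 500)
    keep <- exclusion_rule(st, rev$significant) == "keep"
    rep_verdict <- "fail"
    if (!is.null(replication[[pid]]) && length(replication[[pid]]) > 0) {
      cohorts <- lapply(replication[[pid]], function(pair) {
        f <- mr_fit(pair$exposure, pair$outcome, seed = seed,
                    n_boot = 0, n_sim = 500)
        c(beta = f$selected$beta, se = f$selected$se)
      })
      est <- cohort_estimates(
        cohort_label = sprintf("cohort_%d", seq_along(cohorts)),
        beta = vapply(cohorts, `[[`, numeric(1), "beta"),
        se = vapply(cohorts, `[[`, numeric(1), "se"))
      metas[[pid]] <- meta_analyze(est)
      rep_verdict <- replication_verdict(metas[[pid]], fit$selected)
    }
    pph4 <- 0
    if (!is.null(coloc_regions[[pid]])) {
      cres <- coloc_abf(coloc_regions[[pid]]$ds1, coloc_regions[[pid]]$ds2)
      pph4 <- unname(cres$pp["pp4"])
    }
    ext <- "fail"
    if (!is.null(external) && pid %in% external$protein_id) {
      row <- external[external$protein_id == pid, ][1, ]
      ext <- external_validation_verdict(twas_q = row$twas_q,
                                         pwas_q = row$pwas_q)
    }
    linked <- FALSE
    if (!is.null(ppi))
      linked <- suppressWarnings(
        ppi_linked(ppi$edges, pid, ppi$drug_targets))
    profiles[[pid]] <- data.frame(
      protein_id = pid, outcome_id = discovery$outcome$study$trait_id,
      beta = fit$selected$beta, fdr_q = hits$fdr_q[hits$protein_id == pid],
      steiger_keep = keep, replication = rep_verdict, coloc_pph4 = pph4,
      external = ext, ppi = linked, stringsAsFactors = FALSE)
  }
  profiles <- if (length(profiles) > 0) do.call(rbind, profiles)
    else data.frame()
  rownames(profiles) <- NULL
  tiers <- if (nrow(profiles) > 0) assign_tiers(profiles, pph4_threshold)
    else profiles
  structure(list(discovery = scan, profiles = profiles, tiers = tiers,
                 meta = metas),
            class = "mr_triage")
}

#' @export
print.mr_triage <- function(x, ...) {
  print(x$discovery)
  if (nrow(x$tiers) > 0) {
    cat("Tier assignments:\n")
    print(x$tiers[, c("protein_id", "coloc_pph4", "replication", "external",
                      "ppi", "tier")], digits = 3)
  }
  invisible(x)
}
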