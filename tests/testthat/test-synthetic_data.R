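test_that("generators are pure functions of their config", {
  cfg <- sim_config(theta = 0.2, pleiotropy_frac = 0.3, alpha_mean = 0.02,
                    alpha_sd = 0.01, seed = 123)
  a <- simulate_instruments(cfg)
  b <- simulate_instruments(cfg)
  expect_identical(a, b)
  expect_identical(simulate_cohorts(cfg), simulate_cohorts(cfg))
  expect_identical(simulate_coloc_region("H4", seed = 5),
                   simulate_coloc_region("H4", seed = 5))
  expect_identical(simulate_ppi_graph(20, 3, 0.2, seed = 9),
                   simulate_ppi_graph(20, 3, 0.2, seed = 9))
})

test_that("generated records satisfy the summary-statistic invariants", {
  sim <- simulate_instruments(sim_config(theta = 0.3, seed = 77))
  for (ds in list(sim$exposure, sim$outcome)) {
    rec <- ds$records
    expect_true(all(rec$se > 0))
    expect_true(all(rec$eaf > 0 & rec$eaf < 1))
    expect_true(all(rec$pvalue > 0 & rec$pvalue <= 1))
    expect_true(all(rec$effect_allele != rec$other_allele))
    expect_false(any(duplicated(rec$variant_id)))
    # p consistent with the z statistic by construction
    expect_equal(rec$pvalue,
                 pmax(2 * pnorm(-abs(rec$beta / rec$se)), 1e-300))
  }
})

test_that("instruments are strong and the causal effect is recoverable", {
  # exposure associations clear genome-wide significance in expectation
  sim <- simulate_instruments(sim_config(seed = 8))
  expect_gt(mean(sim$exposure$records$pvalue < 5e-8), 0.9)

  cfg <- sim_config(theta = 0.3, n_instruments = 100, n_exposure = 1e5,
                    n_outcome = 1e5, seed = 31)
  s <- simulate_instruments(cfg)
  est <- ivw(harmonize(s$exposure, s$outcome))
  expect_lt(abs(est$beta - 0.3), 3 * est$se)
})

test_that("the null model is unbiased over seeds", {
  ests <- vapply(1:200, function(s) {
    sim <- simulate_instruments(sim_config(theta = 0, seed = s))
    ivw(harmonize(sim$exposure, sim$outcome))$beta
  }, numeric(1))
  expect_lt(abs(mean(ests)), 2 * sd(ests) / sqrt(length(ests)))
})

test_that("outcome noise shrinks with sample size and pleiotropy moves the Egger intercept", {
  small <- simulate_instruments(sim_config(n_outcome = 1e4, seed = 3))
  big <- simulate_instruments(sim_config(n_outcome = 1e6, seed = 3))
  expect_gt(median(small$outcome$records$se),
            median(big$outcome$records$se))

  intercepts <- function(alpha_mean) {
    vapply(1:60, function(s) {
      sim <- simulate_instruments(
        sim_config(theta = 0.1, pleiotropy_frac = 1,
                   alpha_mean = alpha_mean, alpha_sd = 0.005, seed = s))
      egger(harmonize(sim$exposure, sim$outcome))$egger_intercept
    }, numeric(1))
  }
  expect_gt(mean(intercepts(0.05)), mean(intercepts(0)) + 0.02)
})

test_that("cohort generator shares instruments and spreads effects by tau", {
  cfg0 <- sim_config(theta = 0.3, n_cohorts = 4, tau = 0, seed = 5)
  hom <- simulate_cohorts(cfg0)
  expect_length(hom$cohorts, 4)
  expect_equal(hom$truth$theta_per_cohort, rep(0.3, 4))
  ids <- lapply(hom$cohorts, function(p) p$exposure$records$variant_id)
  expect_true(all(vapply(ids, identical, TRUE, ids[[1]])))

  cfg1 <- sim_config(theta = 0.3, n_cohorts = 4, tau = 0.2, seed = 5)
  het <- simulate_cohorts(cfg1)
  expect_gt(sd(het$truth$theta_per_cohort), 0)
})

test_that("K = 1 cohort series meta-analyzes to the single estimate", {
  cfg <- sim_config(theta = 0.2, n_cohorts = 1, seed = 6)
  sim <- simulate_cohorts(cfg)
  f <- mr_fit(sim$cohorts[[1]]$exposure, sim$cohorts[[1]]$outcome,
              n_boot = 0, n_sim = 200)
  est <- cohort_estimates("only", beta = f$selected$beta, se = f$selected$se)
  m <- meta_analyze(est)
  expect_equal(m$pooled_beta, f$selected$beta)
  expect_equal(m$pooled_se, f$selected$se)
})

test_that("coloc scenarios separate H3 from H4 and respect their truth labels", {
  h4 <- simulate_coloc_region("H4", n_snps_region = 50, causal_z = 8,
                              seed = 21)
  expect_equal(h4$truth$causal_snp_trait1, h4$truth$causal_snp_trait2)
  h3 <- simulate_coloc_region("H3", n_snps_region = 50, causal_z = 8,
                              seed = 21)
  expect_false(h3$truth$causal_snp_trait1 == h3$truth$causal_snp_trait2)
  expect_error(simulate_coloc_region("H3", n_snps_region = 1), "H3")

  res3 <- coloc_abf(h3$ds1, h3$ds2)
  expect_gt(res3$pp["pp3"], res3$pp["pp4"])
})

test_that("TWAS generator: degenerate weights error, causal signal detectable", {
  tw <- simulate_twas_weights(M = 50, h2 = 0.1, causal = TRUE, seed = 2)
  z <- twas_assoc(tw$weights, tw$gwas_z, tw$ld)
  expect_gt(abs(z$z), 1.96)
  expect_error(twas_assoc(numeric(50), tw$gwas_z, tw$ld), "degenerate")
})

test_that("PPI generator spans the density extremes", {
  none <- simulate_ppi_graph(10, 2, edge_density = 0, seed = 1)
  expect_equal(nrow(none$edges), 0)
  expect_warning(linked <- ppi_linked(none$edges, "P005", none$drug_targets),
                 "absent")
  expect_false(linked)

  full <- simulate_ppi_graph(6, 2, edge_density = 1, seed = 1,
                             score_range = c(1, 1))
  for (node in setdiff(sprintf("P%03d", 1:6), full$drug_targets))
    expect_true(ppi_linked(full$edges, node, full$drug_targets))
  expect_true(all(full$edges$score >= 0 & full$edges$score <= 1))
})
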