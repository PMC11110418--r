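test_that("Wald ratio arithmetic, error case and delta-method agreement", {
  est <- wald_ratio(make_instruments(bx = 0.5, by = 0.25, sy = 0.05))
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
  expect_equal(wald_ratio(make_instruments(bx = 1, by = 0.37))$beta, 0.37)
  expect_error(wald_ratio(make_instruments(bx = 0, by = 1)), "bx = 0")

  # strong instruments: first- and second-order SEs within 10%
  set.seed(2)
  for (i in 1:20) {
    bx <- runif(1, 0.5, 2)
    inst <- make_instruments(bx = bx, by = runif(1, -1, 1),
                             sx = 0.05 * bx, sy = 0.1)
    s1 <- wald_ratio(inst)$se
    s2 <- wald_ratio(inst, second_order = TRUE)$se
    expect_lt(abs(s2 - s1) / s1, 0.1)
  }
})

test_that("IVW matches the hand-computed two-instrument case and edge cases", {
  inst <- make_instruments(bx = c(1, 1), by = c(0.4, 0.6), sy = 0.1)
  est <- ivw(inst)
  expect_equal(est$beta, 0.5)
  expect_equal(est$q_stat, 2.0)
  expect_equal(est$se, sqrt(2) / sqrt(200))  # overdispersion-scaled

  same <- make_instruments(bx = rep(0.5, 4), by = rep(0.2, 4), sy = 0.1)
  est2 <- ivw(same)
  expect_equal(est2$beta, 0.4)
  expect_equal(est2$q_stat, 0)
  expect_error(ivw(make_instruments(1, 1)), ">= 2")
})

test_that("fixed-effect IVW is the no-overdispersion limit", {
  set.seed(3)
  inst <- make_instruments(bx = runif(5, 0.5, 1), by = rnorm(5, 0.2, 0.2),
                           sy = runif(5, 0.05, 0.2))
  fe <- ivw(inst, scale_overdispersion = FALSE)
  re <- ivw(inst, scale_overdispersion = TRUE)
  expect_equal(fe$beta, re$beta)
  expect_gte(re$se, fe$se)
})

test_that("Egger reproduces collinear data and the WLS normal equations", {
  inst <- make_instruments(bx = 1:3, by = 1:3, sy = 0.1)
  est <- egger(inst)
  expect_equal(est$beta, 1)
  expect_equal(est$egger_intercept, 0, tolerance = 1e-12)

  set.seed(7)
  inst2 <- make_instruments(bx = runif(5, 0.2, 1.5),
                            by = rnorm(5, 0.3, 0.3),
                            sy = runif(5, 0.05, 0.3))
  fit <- lm(by ~ bx, data = inst2, weights = 1 / inst2$sy^2)
  est2 <- egger(inst2)
  expect_equal(est2$beta, unname(coef(fit)[2]))
  expect_equal(est2$egger_intercept, unname(coef(fit)[1]))
  if (summary(fit)$sigma > 1) {
    expect_equal(est2$se, summary(fit)$coefficients[2, 2])
    expect_equal(est2$egger_intercept_se, summary(fit)$coefficients[1, 2])
  }
  expect_error(egger(make_instruments(1:2, 1:2)), ">= 3")
})

test_that("Egger orients instruments to non-negative exposure effects", {
  set.seed(8)
  bx <- runif(6, 0.2, 1)
  by <- 0.05 + 0.4 * bx + rnorm(6, 0, 0.05)
  flip <- c(1, -1, 1, -1, 1, -1)
  a <- egger(make_instruments(bx, by, sy = 0.1))
  b <- egger(make_instruments(bx * flip, by * flip, sy = 0.1))
  expect_equal(a$beta, b$beta)
  expect_equal(a$egger_intercept, b$egger_intercept)
})

test_that("weighted median interpolates the weighted ratio distribution", {
  inst <- make_instruments(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.3), sy = 0.1)
  expect_equal(weighted_median(inst, n_boot = 0)$beta, 0.2)

  # splitting an instrument into two half-weight copies leaves the
  # interpolated median unchanged (shown away from the median atom)
  set.seed(4)
  inst2 <- make_instruments(bx = runif(7, 0.5, 1.5), by = rnorm(7, 0.3, 0.2),
                            sy = 0.1)
  k <- which.max(inst2$by / inst2$bx)
  dup <- rbind(inst2, inst2[k, ], inst2[k, ])
  dup$sy[c(k, 8, 9)] <- dup$sy[c(k, 8, 9)] * sqrt(2)  # w = bx^2/sy^2 halves
  dup <- dup[-k, ]
  class(dup) <- class(inst2)
  expect_equal(weighted_median(dup, n_boot = 0)$beta,
               weighted_median(inst2, n_boot = 0)$beta)

  # seeded bootstrap SE is reproducible
  s1 <- weighted_median(inst2, n_boot = 200, seed = 99)$se
  s2 <- weighted_median(inst2, n_boot = 200, seed = 99)$se
  expect_identical(s1, s2)
})

test_that("MR-PRESSO flags a planted outlier and corrects toward the truth", {
  set.seed(21)
  theta <- 0.3
  J <- 20
  bx <- rnorm(J, 1, 0.1)
  sy <- rep(0.05, J)
  by <- rnorm(J, theta * bx, sy)
  by[7] <- by[7] + 10 * sy[7]
  inst <- make_instruments(bx, by, sx = 0.02, sy = sy)
  est <- mr_presso(inst, n_sim = 500, seed = 5)
  expect_true("rs007" %in% est$outlier_ids)
  expect_lt(est$presso_global_p, 0.05)
  uncorrected <- ivw(inst)
  expect_lt(abs(est$beta - theta), abs(uncorrected$beta - theta))
  expect_error(mr_presso(inst, n_sim = 0), "n_sim")
  expect_error(mr_presso(inst[1:3, ]), ">= 4")
})

test_that("profile score equals IVW at sx = 0 and the single-ratio closed form", {
  set.seed(6)
  inst <- make_instruments(bx = runif(6, 0.5, 1.5), by = rnorm(6, 0.25, 0.1),
                           sx = 0, sy = runif(6, 0.05, 0.2))
  raps <- mr_raps(inst)
  fe <- ivw(inst, scale_overdispersion = FALSE)
  expect_equal(raps$beta, fe$beta, tolerance = 1e-8)
  expect_equal(raps$se, fe$se, tolerance = 1e-8)

  one_pair <- make_instruments(bx = c(0.5, 0.5), by = c(0.2, 0.2),
                               sx = 0.01, sy = 0.1)
  expect_equal(mr_raps(one_pair)$beta, 0.4, tolerance = 1e-8)
})

test_that("estimator preference policy follows the diagnostics", {
  ivw_est <- ivw(make_instruments(bx = c(1, 1), by = c(0.4, 0.6), sy = 0.1))
  mk_egger <- function(p) {
    e <- ivw_est
    e$method <- "egger"; e$egger_intercept_p <- p
    e
  }
  mk_presso <- function(p, outliers) {
    e <- ivw_est
    e$method <- "mr_presso_corrected"
    e$presso_global_p <- p; e$outlier_ids <- outliers
    e
  }
  cands <- list(ivw = ivw_est, egger = mk_egger(0.30),
                mr_presso = mk_presso(0.40, character(0)))
  expect_equal(choose_estimate(cands)$method, "ivw")
  cands$egger <- mk_egger(0.01)
  expect_equal(choose_estimate(cands)$method, "egger")
  cands$mr_presso <- mk_presso(0.001, "rs001")
  expect_equal(choose_estimate(cands)$method, "mr_presso_corrected")
  expect_error(choose_estimate(list(egger = mk_egger(1))), "ivw")
})

test_that("BH q-values equal the definition-based computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(13)
  for (m in 1:8) {
    for (rep in 1:5) {
      p <- runif(m)^2
      q <- bh_fdr(p)
      expect_equal(q, bh_brute(p))
      expect_true(all(q <= 1))
      expect_true(all(diff(q[order(p)]) >= -1e-12))
    }
  }
})

test_that("odds-ratio transform agrees with ci_from_beta", {
  est <- ivw(make_instruments(bx = c(1, 1), by = c(0.4, 0.6), sy = 0.1))
  expect_equal(beta_to_or(est), ci_from_beta(est$beta, est$se))
  expect_equal(unname(beta_to_or(list(beta = 0, se = 1))["or"]), 1)
  expect_equal(unname(beta_to_or(list(beta = log(2), se = 1))["or"]), 2)
})
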