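# shared fixture builders; everything is generated in code

make_records <- function(n, seed = 1, chrom = "1", pos = NULL) {
  set.seed(seed)
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, n, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), "")
  beta <- rnorm(n, 0, 0.1)
  se <- runif(n, 0.01, 0.05)
  data.frame(variant_id = sprintf("rs%04d", seq_len(n)), chrom = chrom,
             pos = if (is.null(pos)) sort(sample.int(1e6, n)) else pos,
             effect_allele = ea, other_allele = unname(oa),
             eaf = runif(n, 0.05, 0.95), beta = beta, se = se,
             pvalue = 2 * pnorm(-abs(beta / se)), n = 10000,
             stringsAsFactors = FALSE)
}

make_instruments <- function(bx, by, sx = 0.01, sy = 0.1,
                             id = sprintf("rs%03d", seq_along(bx))) {
  out <- data.frame(variant_id = id, bx = bx, sx = sx, by = by, sy = sy,
                    eaf = 0.3, effect_allele = "A", other_allele = "G",
                    flipped = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("harmonized_instruments", "data.frame")
  out
}

# definition-based BH step-up, independent of stats::p.adjust
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(vapply(i:m, function(j) m * p[ord][j] / j, 0), 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# exhaustive single-causal-variant enumeration in linear space: every
# configuration (i, j) of causal indices (0 = none) weighted by priors
coloc_enumerate <- function(ds1, ds2, config = coloc_config()) {
  shared <- intersect(ds1$records$variant_id, ds2$records$variant_id)
  r1 <- ds1$records[match(shared, ds1$records$variant_id), ]
  r2 <- ds2$records[match(shared, ds2$records$variant_id), ]
  sd1 <- if (ds1$study$trait_type == "binary") config$prior_sd_binary else config$prior_sd_quant
  sd2 <- if (ds2$study$trait_type == "binary") config$prior_sd_binary else config$prior_sd_quant
  B1 <- exp(abf(r1$beta, r1$se, sd1))
  B2 <- exp(abf(r2$beta, r2$se, sd2))
  M <- length(shared)
  s <- c(h0 = 0, h1 = 0, h2 = 0, h3 = 0, h4 = 0)
  for (i in 0:M) {
    for (j in 0:M) {
      if (i == 0 && j == 0) s["h0"] <- s["h0"] + 1
      else if (j == 0) s["h1"] <- s["h1"] + config$p1 * B1[i]
      else if (i == 0) s["h2"] <- s["h2"] + config$p2 * B2[j]
      else if (i == j) s["h4"] <- s["h4"] + config$p12 * B1[i] * B2[i]
      else s["h3"] <- s["h3"] + config$p1 * config$p2 * B1[i] * B2[j]
    }
  }
  s / sum(s)
}
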