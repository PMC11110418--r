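toy_pqtl <- function() {
  # protein on chr6, gene body 29.5-29.6 Mb: 2 trans, 1 underpowered,
  # 1 inside the MHC, 1 clean survivor
  rec <- data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    chrom = c("1", "6", "6", "6", "6"),
    pos = c(1e6, 50e6, 29.55e6, 30e6, 28.9e6),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = 0.2, se = 0.02, pvalue = c(1e-20, 1e-20, 1e-6, 1e-20, 1e-20),
    n = 7000, stringsAsFactors = FALSE)
  summary_dataset(rec, validate = FALSE)
}

test_that("instrument filters drop trans, weak and MHC variants in order", {
  ds <- toy_pqtl()
  locus <- gene_locus("GENE", "6", 29.5e6, 29.6e6)
  # MHC upper bound 29 Mb here so rs5 is inside it but rs3/rs4 are not
  out <- select_instruments(ds, locus, mhc = list("6", 26e6, 29e6))
  expect_equal(out$records$variant_id, "rs4")
  expect_equal(unname(attr(out, "audit")), c(2, 1, 1))
})

test_that("cis window is a closed interval", {
  rec <- make_records(1, pos = 2e6 - 1e6)  # exactly start - window
  ds <- summary_dataset(rec, validate = FALSE)
  ds$records$pvalue <- 1e-20
  out <- select_instruments(ds, gene_locus("G", "1", 2e6, 2.1e6))
  expect_equal(nrow(out$records), 1)
  ds$records$pos <- 1e6 - 1
  out2 <- select_instruments(ds, gene_locus("G", "1", 2e6, 2.1e6))
  expect_equal(nrow(out2$records), 0)
})

test_that("empty dataset selects to empty with zero audit", {
  ds <- summary_dataset(make_records(1)[0, ], validate = FALSE)
  out <- select_instruments(ds, gene_locus("G", "1", 1e6, 2e6))
  expect_equal(nrow(out$records), 0)
  expect_equal(sum(attr(out, "audit")), 0)
})

test_that("LD clumping keeps the best of a correlated pair and all of an identity block", {
  rec <- make_records(2)
  rec$pvalue <- c(1e-10, 1e-9)
  ds <- summary_dataset(rec, validate = FALSE)
  ld <- matrix(c(1, 0.5, 0.5, 1), 2,
               dimnames = list(rec$variant_id, rec$variant_id))
  out <- ld_clump(ds, ld)
  expect_equal(out$records$variant_id, rec$variant_id[1])

  ld_id <- diag(2)
  dimnames(ld_id) <- list(rec$variant_id, rec$variant_id)
  expect_equal(nrow(ld_clump(ds, ld_id)$records), 2)
  expect_error(ld_clump(ds, ld[1, 1, drop = FALSE]), "missing")
})

test_that("clumping equals greedy maximal-by-p selection and ignores row order", {
  set.seed(5)
  for (case in 1:5) {
    rec <- make_records(20, seed = case)
    ds <- summary_dataset(rec, validate = FALSE)
    r <- matrix(runif(400, 0, 0.9), 20)
    r2 <- (r + t(r)) / 2
    diag(r2) <- 1
    thr <- 0.3
    dimnames(r2) <- list(rec$variant_id, rec$variant_id)
    out <- ld_clump(ds, r2, r2_max = thr)$records$variant_id
    # oracle: walk the p-order, keep iff compatible with everything kept
    ord <- order(rec$pvalue, rec$variant_id)
    kept <- character(0)
    for (i in ord)
      if (all(r2[rec$variant_id[i], kept] < thr))
        kept <- c(kept, rec$variant_id[i])
    expect_setequal(out, kept)
    # pairwise independence of the output
    if (length(out) > 1)
      expect_true(max(r2[out, out][upper.tri(diag(length(out)))]) < thr)
    # input order irrelevant
    shuf <- ds
    shuf$records <- shuf$records[sample(20), ]
    expect_setequal(ld_clump(shuf, r2, r2_max = thr)$records$variant_id, kept)
  }
})

test_that("harmonization flips swapped alleles and drops ambiguous palindromes", {
  ex <- make_records(1)
  ex$effect_allele <- "A"; ex$other_allele <- "G"; ex$beta <- 0.1
  ou <- ex
  ou$effect_allele <- "G"; ou$other_allele <- "A"; ou$beta <- -0.05
  ou$eaf <- 1 - ex$eaf
  h <- harmonize(summary_dataset(ex, validate = FALSE),
                 summary_dataset(ou, validate = FALSE))
  expect_equal(h$by, 0.05)
  expect_true(h$flipped)

  pal <- ex
  pal$effect_allele <- "A"; pal$other_allele <- "T"; pal$eaf <- 0.5
  h2 <- harmonize(summary_dataset(pal, validate = FALSE),
                  summary_dataset(pal, validate = FALSE))
  expect_equal(nrow(h2), 0)
  expect_equal(unname(attr(h2, "audit")["palindromic_ambiguous"]), 1L)

  pal$eaf <- 0.1  # unambiguous palindrome is retained
  h3 <- harmonize(summary_dataset(pal, validate = FALSE),
                  summary_dataset(pal, validate = FALSE))
  expect_equal(nrow(h3), 1)
})

test_that("self-harmonization is the identity and harmonization is idempotent", {
  rec <- make_records(30, seed = 9)
  rec$eaf <- ifelse(rec$eaf > 0.42 & rec$eaf < 0.58, 0.2, rec$eaf)
  ds <- summary_dataset(rec, validate = FALSE)
  h <- harmonize(ds, ds)
  expect_equal(h$by, h$bx)
  expect_false(any(h$flipped))

  # pushing an aligned pair through again changes nothing
  sim <- simulate_instruments(sim_config(seed = 3))
  h1 <- harmonize(sim$exposure, sim$outcome)
  aligned_out <- sim$outcome
  keep <- match(h1$variant_id, aligned_out$records$variant_id)
  aligned_out$records <- aligned_out$records[keep, ]
  aligned_out$records$beta <- h1$by
  aligned_ex <- sim$exposure
  aligned_ex$records <- aligned_ex$records[
    match(h1$variant_id, aligned_ex$records$variant_id), ]
  h2 <- harmonize(aligned_ex, aligned_out)
  expect_equal(h2$by, h1$by)
  expect_equal(h2$bx, h1$bx)
})

test_that("BED loci convert to 1-based inclusive coordinates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("6\t29499999\t29600000\tGENE", path)
  loci <- read_loci_bed(path)
  expect_equal(loci$GENE$start, 29.5e6)
  expect_equal(loci$GENE$end, 29.6e6)
})
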