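#' Gene locus annotation
#'
#' @param gene_id gene/protein identifier.
#' @param chrom chromosome label (matched as a string against the dataset).
#' @param start,end 1-based inclusive gene-body coordinates, `start <= end`.
#' @return A list of class `gene_locus`.
#' @export
gene_locus <- function(gene_id, chrom, start, end) {
  stopifnot(start >= 1, start <= end)
  structure(list(gene_id = gene_id, chrom = as.character(chrom),
                 start = start, end = end), class = "gene_locus")
}

#' Read BED-like gene loci
#'
#' Three-plus-column TSV (`chrom`, `start`, `end`, `gene_id`) with 0-based
#' half-open coordinates, converted to the package's 1-based inclusive
#' convention on read.
#'
#' @param path TSV path, no header.
#' @return List of [gene_locus()] objects named by `gene_id`.
#' @export
read_loci_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  loci <- lapply(seq_len(nrow(tab)), function(i)
    gene_locus(tab[i, 4], tab[i, 1], tab[i, 2] + 1, tab[i, 3]))
  stats::setNames(loci, vapply(loci, `[[`, "", "gene_id"))
}

#' Select cis-pQTL instruments for a protein
#'
#' Applies the three positional/statistical filters used to nominate
#' instruments from a pQTL scan, in order:
#' \enumerate{
#'   \item cis: position within `cis_window` bp of the gene body (closed
#'     interval `[start - cis_window, end + cis_window]`, same chromosome);
#'   \item genome-wide significance: `pvalue < p_max`;
#'   \item outside the extended MHC region (default chr6:26-34 Mb, closed).
#' }
#' LD pruning is a separate step ([ld_clump()]).
#'
#' @param ds a `summary_dataset` of pQTL associations.
#' @param locus a [gene_locus()] for the encoded protein.
#' @param p_max genome-wide significance threshold, default `5e-8`.
#' @param cis_window cis distance in bp, default 1 Mb.
#' @param mhc list/vector `(chrom, start, end)` of the exclusion region;
#'   default `list("6", 26e6, 34e6)`.
#' @return The filtered `summary_dataset`, with an `audit` attribute counting
#'   removals per filter (`trans`, `not_significant`, `mhc`).
#' @export
select_instruments <- function(ds, locus, p_max = 5e-8, cis_window = 1e6,
                               mhc = list("6", 26e6, 34e6)) {
  stopifnot(inherits(ds, "summary_dataset"), inherits(locus, "gene_locus"))
  rec <- ds$records
  cis_ok <- rec$chrom == locus$chrom &
    rec$pos >= locus$start - cis_window & rec$pos <= locus$end + cis_window
  n_trans <- sum(!cis_ok)
  rec <- rec[cis_ok, , drop = FALSE]
  sig_ok <- rec$pvalue < p_max
  n_nonsig <- sum(!sig_ok)
  rec <- rec[sig_ok, , drop = FALSE]
  in_mhc <- rec$chrom == as.character(mhc[[1]]) &
    rec$pos >= mhc[[2]] & rec$pos <= mhc[[3]]
  n_mhc <- sum(in_mhc)
  rec <- rec[!in_mhc, , drop = FALSE]
  out <- ds
  out$records <- rec
  rownames(out$records) <- NULL
  attr(out, "audit") <- c(trans = n_trans, not_significant = n_nonsig,
                          mhc = n_mhc)
  out
}

#' Greedy LD clumping
#'
#' Keeps an independent instrument set: variants are visited in ascending
#' p-value order (ties broken lexicographically on `variant_id`) and accepted
#' iff their squared correlation with every previously accepted variant is
#' below `r2_max`. The result is invariant to input row order.
#'
#' @param ds a `summary_dataset` (typically the [select_instruments()]
#'   output).
#' @param ld square correlation (r) or squared-correlation matrix with
#'   dimnames covering all variants in `ds`; entries are squared internally
#'   if any `|value| >` 1 is absent and the matrix has negative entries.
#'   Pass `NULL` to skip clumping (instruments already independent).
#' @param r2_max clumping threshold, default 0.001.
#' @return The clumped `summary_dataset`.
#' @export
ld_clump <- function(ds, ld, r2_max = 0.001) {
  stopifnot(inherits(ds, "summary_dataset"))
  if (is.null(ld) || nrow(ds$records) <= 1) return(ds)
  rec <- ds$records
  missing <- setdiff(rec$variant_id, rownames(ld))
  if (length(missing) > 0)
    stop("variant(s) missing from LD matrix: ",
         paste(missing, collapse = ", "))
  r2 <- ld[rec$variant_id, rec$variant_id, drop = FALSE]
  if (any(r2 < 0)) r2 <- r2^2  # given as signed r
  ord <- order(rec$pvalue, rec$variant_id)
  accepted <- integer(0)
  for (i in ord) {
    if (all(r2[i, accepted] < r2_max)) accepted <- c(accepted, i)
  }
  out <- ds
  out$records <- rec[sort(accepted), , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(ea, oa) .complement[ea] == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome effect to the exposure effect allele, variant by
#' variant. Alleles matching after swap (outcome effect allele equals the
#' exposure other allele) have `by` sign-flipped and `eaf` reflected; strand
#' flips (A<->T, C<->G complements) are resolved the same way. Palindromic
#' variants (A/T or C/G pairs) are kept only when their allele frequency is
#' informative about strand, i.e. `eaf` outside
#' `(palindrome_eaf_margin, 1 - palindrome_eaf_margin)`; kept palindromes are
#' strand-aligned by frequency concordance. Unmatched or irreconcilable
#' variants are dropped and counted.
#'
#' @param exposure,outcome `summary_dataset`s sharing variant ids.
#' @param palindrome_eaf_margin ambiguity margin, default 0.42: palindromes
#'   with `eaf` in (0.42, 0.58) are dropped.
#' @return data.frame of class `harmonized_instruments` with columns
#'   `variant_id`, `bx`, `sx`, `by`, `sy`, `eaf`, `effect_allele`,
#'   `other_allele`, `flipped`; `audit` attribute counts drops by reason.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_margin = 0.42) {
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(outcome, "summary_dataset"))
  ex <- exposure$records
  ou <- outcome$records
  m <- match(ex$variant_id, ou$variant_id)
  n_unmatched <- sum(is.na(m))
  keep <- !is.na(m)
  ex <- ex[keep, , drop = FALSE]
  ou <- ou[m[keep], , drop = FALSE]
  ea_x <- ex$effect_allele; oa_x <- ex$other_allele
  ea_y <- ou$effect_allele; oa_y <- ou$other_allele
  eaf_x <- ex$eaf; eaf_y <- ou$eaf
  pal <- .complement[ea_x] == oa_x
  same_set <- (ea_y == ea_x & oa_y == oa_x) | (ea_y == oa_x & oa_y == ea_x)
  comp_set <- (ea_y == .complement[ea_x] & oa_y == .complement[oa_x]) |
    (ea_y == .complement[oa_x] & oa_y == .complement[ea_x])
  # for palindromes allele codes cannot distinguish strands; frequency
  # concordance decides, and mid-range frequencies are unresolvable
  mid <- function(f) is.na(f) |
    (f > palindrome_eaf_margin & f < 1 - palindrome_eaf_margin)
  ambiguous <- pal & (mid(eaf_x) | mid(eaf_y))
  irrec <- ifelse(pal, !same_set, !(same_set | comp_set))
  flipped <- ifelse(pal,
                    !is.na(eaf_x) & !is.na(eaf_y) &
                      ((eaf_x > 0.5) != (eaf_y > 0.5)),
                    (ea_y == oa_x & oa_y == ea_x) |
                      (ea_y == .complement[oa_x] & oa_y == .complement[ea_x]))
  ok <- !irrec & !ambiguous
  n_irrec <- sum(irrec)
  n_pal_dropped <- sum(ambiguous & !irrec)
  flipped <- flipped[ok]
  out <- data.frame(
    variant_id = ex$variant_id[ok], bx = ex$beta[ok], sx = ex$se[ok],
    by = ifelse(flipped, -ou$beta[ok], ou$beta[ok]), sy = ou$se[ok],
    eaf = ifelse(is.na(eaf_x[ok]),
                 ifelse(flipped, 1 - eaf_y[ok], eaf_y[ok]), eaf_x[ok]),
    effect_allele = ea_x[ok], other_allele = oa_x[ok], flipped = flipped,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("harmonized_instruments", "data.frame")
  attr(out, "audit") <- c(unmatched = n_unmatched,
                          palindromic_ambiguous = n_pal_dropped,
                          irreconcilable = n_irrec)
  out
}
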