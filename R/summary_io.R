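#' Summary-statistic datasets
#'
#' A `summary_dataset` bundles one trait's GWAS summary statistics (one row
#' per variant) with minimal study metadata. It is the common currency of the
#' package: instrument selection, harmonization, every MR estimator and the
#' colocalization routine all consume it.
#'
#' @param records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`
#'   (missing `eaf`/`n` are allowed as `NA`).
#' @param trait_id trait identifier, e.g. a protein or disease name.
#' @param trait_type `"quantitative"` (protein levels, SD units) or
#'   `"binary"` (disease, log-odds). Determines the colocalization prior SD.
#' @param cohort_label free-text cohort label.
#' @param n overall study sample size (used where per-variant `n` is absent).
#' @param validate drop rows violating the record invariants (default `TRUE`);
#'   the number dropped per rule is kept in the `audit` attribute.
#'
#' @return An object of class `summary_dataset`: a list with elements
#'   `study` (list: `trait_id`, `trait_type`, `cohort_label`, `n`) and
#'   `records` (the validated data.frame), plus an `audit` attribute.
#' @export
summary_dataset <- function(records, trait_id = "trait",
                            trait_type = c("quantitative", "binary"),
                            cohort_label = "cohort", n = NA_integer_,
                            validate = TRUE) {
  trait_type <- match.arg(trait_type)
  required <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pvalue", "n")
  for (col in setdiff(required, names(records))) {
    if (col %in% c("eaf", "n")) records[[col]] <- NA_real_
    else stop("records is missing required column '", col, "'")
  }
  records <- records[required]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  audit <- c(bad_se = 0L, bad_eaf = 0L, bad_pos = 0L, bad_allele = 0L,
             bad_pvalue = 0L, duplicate_id = 0L)
  if (validate && nrow(records) > 0) {
    keep_rule <- function(ok, rule) {
      ok[is.na(ok)] <- FALSE
      audit[rule] <<- audit[rule] + sum(!ok)
      records <<- records[ok, , drop = FALSE]
    }
    keep_rule(is.finite(records$se) & records$se > 0, "bad_se")
    keep_rule(is.na(records$eaf) | (records$eaf >= 0 & records$eaf <= 1), "bad_eaf")
    keep_rule(is.finite(records$pos) & records$pos >= 1, "bad_pos")
    acgt <- c("A", "C", "G", "T")
    keep_rule(records$effect_allele %in% acgt & records$other_allele %in% acgt &
                records$effect_allele != records$other_allele, "bad_allele")
    keep_rule(is.finite(records$pvalue) & records$pvalue > 0 &
                records$pvalue <= 1, "bad_pvalue")
    keep_rule(!duplicated(records$variant_id), "duplicate_id")
    # published tables round, so p vs |beta/se| mismatch warns rather than drops
    p_expect <- 2 * stats::pnorm(-abs(records$beta / records$se))
    off <- which(p_expect > 0 &
                   abs(records$pvalue - p_expect) > 1e-6 * pmax(p_expect, 1e-300))
    if (length(off) > 0)
      warning(length(off), " record(s) have p-values inconsistent with beta/se",
              call. = FALSE)
  }
  rownames(records) <- NULL
  out <- structure(
    list(study = list(trait_id = trait_id, trait_type = trait_type,
                      cohort_label = cohort_label, n = n),
         records = records),
    class = "summary_dataset")
  attr(out, "audit") <- audit
  out
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("summary_dataset: %s (%s, %s), %d variant(s)\n",
              x$study$trait_id, x$study$trait_type, x$study$cohort_label,
              nrow(x$records)))
  dropped <- sum(attr(x, "audit"))
  if (!is.na(dropped) && dropped > 0)
    cat(sprintf("  %d record(s) dropped on ingest\n", dropped))
  invisible(x)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a TSV with a header into a [summary_dataset()]. Column names are
#' translated through `column_map` (package name -> file name), so tables in
#' any dialect can be ingested without rewriting. Rows violating the record
#' invariants (non-positive SE, allele codes outside A/C/G/T, p outside
#' (0,1], ...) are dropped and counted in the `audit` attribute.
#'
#' @param path TSV path.
#' @param column_map named character vector mapping the canonical column names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`) to the file's column names. Unmapped
#'   canonical names are looked up verbatim; `eaf` and `n` may be absent.
#' @inheritParams summary_dataset
#' @return A `summary_dataset`.
#' @export
read_summary_table <- function(path, column_map = character(),
                               trait_id = "trait",
                               trait_type = c("quantitative", "binary"),
                               cohort_label = "cohort", n = NA_integer_) {
  trait_type <- match.arg(trait_type)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pvalue", "n")
  if (nrow(tab) == 0) {
    warning("empty summary table: ", path, call. = FALSE)
    empty <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(canonical)), canonical))
    return(summary_dataset(empty, trait_id, trait_type, cohort_label, n,
                           validate = FALSE))
  }
  records <- data.frame(row.names = seq_len(nrow(tab)))
  for (col in canonical) {
    src <- if (col %in% names(column_map)) column_map[[col]] else col
    if (src %in% names(tab)) {
      records[[col]] <- tab[[src]]
    } else if (col %in% c("eaf", "n")) {
      records[[col]] <- NA_real_
    } else {
      stop("mapped column '", src, "' for '", col, "' not found in ", path)
    }
  }
  summary_dataset(records, trait_id, trait_type, cohort_label, n)
}

#' Write a summary dataset as TSV
#'
#' Inverse of [read_summary_table()]: numeric fields are written with full
#' double precision (17 significant digits) so that a read/write round trip
#' is lossless.
#'
#' @param ds a `summary_dataset`.
#' @param path output path.
#' @export
write_summary_table <- function(ds, path) {
  stopifnot(inherits(ds, "summary_dataset"))
  rec <- ds$records
  for (col in c("eaf", "beta", "se", "pvalue", "n"))
    rec[[col]] <- formatC(rec[[col]], digits = 17, format = "g")
  rec[rec == "NA"] <- "NA"
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a column mapping from a YAML config
#'
#' Convenience loader for [read_summary_table()]'s `column_map`: a YAML file
#' with a flat `columns:` mapping of canonical names to file column names.
#'
#' @param path YAML path.
#' @return Named character vector.
#' @export
read_column_map <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  cfg <- yaml::read_yaml(path)
  unlist(cfg$columns %||% cfg)
}

#' Convert an odds-ratio confidence interval to a log-OR standard error
#'
#' Published association tables often print only "OR (95% CI)"; the meta
#' module reconstructs the log-scale standard error from those bounds as
#' `se = (log(upper) - log(lower)) / (2 * z)` with `z` the normal quantile
#' for the interval level (1.959964 at 95%).
#'
#' @param lower_or,upper_or positive CI bounds on the OR scale.
#' @param level CI level, default 0.95.
#' @return Standard error of the log-OR.
#' @export
#' @examples
#' se_from_ci(0.6363, 0.8211) # ~0.065
se_from_ci <- function(lower_or, upper_or, level = 0.95) {
  if (any(lower_or <= 0) || any(upper_or <= 0))
    stop("CI bounds must be positive")
  if (any(upper_or < lower_or)) stop("upper_or must be >= lower_or")
  if (any(level <= 0.5) || any(level >= 1)) stop("level must be in (0.5, 1)")
  z <- stats::qnorm((1 + level) / 2)
  (log(upper_or) - log(lower_or)) / (2 * z)
}

#' Odds ratio with confidence interval from a log-OR estimate
#'
#' @param beta log-OR point estimate.
#' @param se standard error, > 0.
#' @param level CI level, default 0.95.
#' @return Named numeric vector `c(or, lower_or, upper_or)`.
#' @export
ci_from_beta <- function(beta, se, level = 0.95) {
  if (any(se <= 0)) stop("se must be positive")
  z <- stats::qnorm((1 + level) / 2)
  c(or = exp(beta), lower_or = exp(beta - z * se), upper_or = exp(beta + z * se))
}
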