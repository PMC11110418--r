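#' Weighted-score (TWAS/PWAS-style) association statistic
#'
#' Association between a GWAS phenotype and a genetically predicted
#' expression/protein trait from summary statistics:
#' `z = w'z_gwas / sqrt(w' LD w)` with `w` the prediction weights.
#'
#' @param weights numeric weight vector.
#' @param gwas_z GWAS z-scores, same length.
#' @param ld LD (correlation) matrix.
#' @return List with `z` and `pvalue`.
#' @export
twas_assoc <- function(weights, gwas_z, ld) {
  stopifnot(length(weights) == length(gwas_z),
            nrow(ld) == length(weights), ncol(ld) == length(weights))
  denom2 <- drop(t(weights) %*% ld %*% weights)
  if (denom2 <= 0) stop("degenerate weights: w' LD w must be positive")
  z <- sum(weights * gwas_z) / sqrt(denom2)
  list(z = z, pvalue = 2 * stats::pnorm(-abs(z)))
}

#' External-validation verdict from TWAS/PWAS evidence
#'
#' Pass iff either study is significant at the FDR threshold; an absent
#' study fails its branch. Direction concordance with the discovery
#' estimate can optionally be required.
#'
#' @param twas_q,pwas_q FDR q-values (`NA` when the protein is absent from
#'   the reference panel).
#' @param direction_concordant_twas,direction_concordant_pwas logical
#'   concordance flags, consulted only when `require_direction = TRUE`.
#' @param q_max significance threshold, default 0.05.
#' @param require_direction require sign concordance as well (default
#'   `FALSE`).
#' @return `"pass"` or `"fail"`.
#' @export
external_validation_verdict <- function(twas_q = NA, pwas_q = NA,
                                        direction_concordant_twas = NA,
                                        direction_concordant_pwas = NA,
                                        q_max = 0.05,
                                        require_direction = FALSE) {
  branch <- function(q, conc) {
    !is.na(q) && q < q_max &&
      (!require_direction || isTRUE(conc))
  }
  if (branch(twas_q, direction_concordant_twas) ||
      branch(pwas_q, direction_concordant_pwas)) "pass" else "fail"
}

#' Direct drug-target linkage in a PPI network
#'
#' `TRUE` iff some edge with interaction score at or above `min_score`
#' directly connects the protein to a known drug-target node (two-hop paths
#' do not count).
#'
#' @param edges data.frame with `node1`, `node2`, `score` in `[0, 1]`.
#' @param protein_id node to test.
#' @param drug_targets character vector of drug-target node ids.
#' @param min_score interaction-score threshold, default 0.4.
#' @return Logical.
#' @export
ppi_linked <- function(edges, protein_id, drug_targets, min_score = 0.4) {
  nodes <- unique(c(edges$node1, edges$node2))
  if (!protein_id %in% nodes) {
    warning("protein '", protein_id, "' absent from the PPI graph",
            call. = FALSE)
    return(FALSE)
  }
  touch <- (edges$node1 == protein_id & edges$node2 %in% drug_targets) |
    (edges$node2 == protein_id & edges$node1 %in% drug_targets)
  any(touch & edges$score >= min_score)
}

#' Evidence profile for one protein-outcome pair
#'
#' The complete dossier the tier assignment consumes. Missing evidence must
#' be encoded explicitly (`"fail"` / `FALSE` / `NA` q-values), never left
#' out.
#'
#' @param protein_id,outcome_id identifiers.
#' @param steiger_keep `TRUE` unless the reverse-causality exclusion rule
#'   fired.
#' @param replication `"pass"` or `"fail"` ([replication_verdict()]).
#' @param coloc_pph4 posterior probability of a shared causal variant.
#' @param external `"pass"` or `"fail"` ([external_validation_verdict()]).
#' @param ppi logical ([ppi_linked()]).
#' @return List of class `evidence_profile`.
#' @export
evidence_profile <- function(protein_id, outcome_id, steiger_keep,
                             replication, coloc_pph4, external, ppi) {
  args <- list(protein_id = protein_id, outcome_id = outcome_id,
               steiger_keep = steiger_keep, replication = replication,
               coloc_pph4 = coloc_pph4, external = external, ppi = ppi)
  missing <- names(args)[vapply(args, function(a) is.null(a) || anyNA(a), TRUE)]
  if (length(missing) > 0)
    stop("incomplete evidence profile; missing: ",
         paste(missing, collapse = ", "))
  stopifnot(replication %in% c("pass", "fail"),
            external %in% c("pass", "fail"),
            is.logical(steiger_keep), is.logical(ppi),
            coloc_pph4 >= 0, coloc_pph4 <= 1)
  structure(args, class = "evidence_profile")
}

#' Four-tier evidence grading of a candidate drug target
#'
#' Rules evaluated in order, first match wins:
#' \describe{
#'   \item{Excluded}{the directionality exclusion rule fired
#'     (`steiger_keep = FALSE`).}
#'   \item{Tier 1}{colocalization (PPH4 > threshold) AND replication pass
#'     AND external (TWAS/PWAS) pass.}
#'   \item{Tier 2}{direct PPI drug-target linkage AND (replication pass OR
#'     external pass).}
#'   \item{Tier 3}{colocalization AND (replication pass OR external pass OR
#'     PPI linkage).}
#'   \item{Tier 4}{everything else.}
#' }
#'
#' @param profile an [evidence_profile()].
#' @param pph4_threshold colocalization threshold, default 0.8 (strict).
#' @return List of class `tier_assignment`: `tier` (one of `"excluded"`,
#'   `1:4`) and `rationale` (named logical vector of every clause outcome).
#' @export
assign_tier <- function(profile, pph4_threshold = 0.8) {
  stopifnot(inherits(profile, "evidence_profile"))
  coloc_ok <- profile$coloc_pph4 > pph4_threshold
  rep_ok <- profile$replication == "pass"
  ext_ok <- profile$external == "pass"
  ppi_ok <- isTRUE(profile$ppi)
  rationale <- c(steiger_keep = profile$steiger_keep, coloc = coloc_ok,
                 replication = rep_ok, external = ext_ok, ppi = ppi_ok)
  tier <- if (!profile$steiger_keep) "excluded"
  else if (coloc_ok && rep_ok && ext_ok) "1"
  else if (ppi_ok && (rep_ok || ext_ok)) "2"
  else if (coloc_ok && (rep_ok || ext_ok || ppi_ok)) "3"
  else "4"
  structure(list(protein_id = profile$protein_id,
                 outcome_id = profile$outcome_id,
                 tier = tier, rationale = rationale),
            class = "tier_assignment")
}

#' @export
print.tier_assignment <- function(x, ...) {
  label <- if (x$tier == "excluded") "Excluded" else paste("Tier", x$tier)
  cat(sprintf("%s / %s: %s [%s]\n", x$protein_id, x$outcome_id, label,
              paste(names(x$rationale)[x$rationale], collapse = ", ")))
  invisible(x)
}

#' Grade a table of evidence profiles
#'
#' @param profiles data.frame with the [evidence_profile()] columns
#'   (`protein_id`, `outcome_id`, `steiger_keep`, `replication`,
#'   `coloc_pph4`, `external`, `ppi`).
#' @param pph4_threshold colocalization threshold.
#' @return The input with a `tier` column appended.
#' @export
assign_tiers <- function(profiles, pph4_threshold = 0.8) {
  profiles$tier <- vapply(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    assign_tier(evidence_profile(p$protein_id, p$outcome_id, p$steiger_keep,
                                 p$replication, p$coloc_pph4, p$external,
                                 p$ppi),
                pph4_threshold)$tier
  }, character(1))
  profiles
}
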