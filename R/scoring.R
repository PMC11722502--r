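# Integrative 0-8 candidate-gene score and per-signal ranking.
#
# Scheme: significant eQTL colocalization or TWAS evidence contributes a
# block of 6 points and pre-empts the chromatin ladder and methylation
# points; otherwise the score accumulates the 4-level nested chromatin
# ladder (linked; + regulatory variant; + MPRA-significant; + marginal eQTL)
# plus 2 points for meQTL colocalization or MWAS. Driver-gene points
# (+1 melanoma, +1 pan-cancer) apply to all nominated genes, capping the
# total at 8.

#' Score one or more evidence records
#'
#' Enforces the ladder nesting invariant
#' (`var_marginal_eqtl => var_mpra_sig => var_regulatory => linked`) and
#' rejects violating records rather than rescoring them.
#'
#' @param record EvidenceRecord data.frame (one or more rows) with logical
#'   columns `linked`, `var_regulatory`, `var_mpra_sig`, `var_marginal_eqtl`,
#'   `eqtl_or_twas`, `meqtl_or_mwas`, `driver_melanoma`, `driver_pancancer`.
#' @return GeneScore data.frame: identifier columns carried through plus
#'   component columns `comp_eqtl_twas` (0 or 6), `comp_ladder` (0-4),
#'   `comp_meqtl_mwas` (0 or 2), `comp_driver_melanoma`,
#'   `comp_driver_pancancer` (0 or 1 each), and integer `total` in `[0, 8]`.
#' @examples
#' r <- data.frame(linked = TRUE, var_regulatory = TRUE, var_mpra_sig = FALSE,
#'                 var_marginal_eqtl = FALSE, eqtl_or_twas = FALSE,
#'                 meqtl_or_mwas = FALSE, driver_melanoma = TRUE,
#'                 driver_pancancer = TRUE)
#' score_gene(r)$total # 4
#' @export
score_gene <- function(record) {
  need <- c("linked", "var_regulatory", "var_mpra_sig", "var_marginal_eqtl",
            "eqtl_or_twas", "meqtl_or_mwas", "driver_melanoma",
            "driver_pancancer")
  missing <- setdiff(need, names(record))
  if (length(missing) > 0L)
    stop("evidence record lacks columns: ", paste(missing, collapse = ", "))
  ok <- (!record$var_marginal_eqtl | record$var_mpra_sig) &
        (!record$var_mpra_sig | record$var_regulatory) &
        (!record$var_regulatory | record$linked)
  if (!all(ok))
    stop("ladder nesting violated in record(s) ",
         paste(which(!ok), collapse = ", "),
         "; records must come from build_evidence_records()")
  ladder <- record$linked + record$var_regulatory + record$var_mpra_sig +
    record$var_marginal_eqtl
  comp_eqtl <- ifelse(record$eqtl_or_twas, 6L, 0L)
  comp_ladder <- ifelse(record$eqtl_or_twas, 0L, as.integer(ladder))
  comp_meqtl <- ifelse(record$eqtl_or_twas, 0L,
                       ifelse(record$meqtl_or_mwas, 2L, 0L))
  comp_dm <- as.integer(record$driver_melanoma)
  comp_dp <- as.integer(record$driver_pancancer)
  id_cols <- intersect(c("signal_id", "gene_id", "best_variant_id",
                         "protein_coding_nomination"), names(record))
  out <- record[, id_cols, drop = FALSE]
  out$comp_eqtl_twas <- comp_eqtl
  out$comp_ladder <- comp_ladder
  out$comp_meqtl_mwas <- comp_meqtl
  out$comp_driver_melanoma <- comp_dm
  out$comp_driver_pancancer <- comp_dp
  out$total <- comp_eqtl + comp_ladder + comp_meqtl + comp_dm + comp_dp
  rownames(out) <- NULL
  out
}

#' Enumerate every valid evidence combination
#'
#' All records satisfying the nesting invariants: the eQTL/TWAS flag, the
#' 4-level nested chromatin ladder (encoded as depth 0-4), the meQTL/MWAS
#' flag, and the two driver flags. Used to audit the score's range by
#' exhaustive enumeration.
#'
#' @return data.frame of all valid evidence records.
#' @export
enumerate_evidence_lattice <- function() {
  grid <- expand.grid(eqtl_or_twas = c(FALSE, TRUE), ladder = 0:4,
                      meqtl_or_mwas = c(FALSE, TRUE),
                      driver_melanoma = c(FALSE, TRUE),
                      driver_pancancer = c(FALSE, TRUE))
  data.frame(linked = grid$ladder >= 1L,
             var_regulatory = grid$ladder >= 2L,
             var_mpra_sig = grid$ladder >= 3L,
             var_marginal_eqtl = grid$ladder >= 4L,
             eqtl_or_twas = grid$eqtl_or_twas,
             meqtl_or_mwas = grid$meqtl_or_mwas,
             driver_melanoma = grid$driver_melanoma,
             driver_pancancer = grid$driver_pancancer)
}

#' Rank scored genes per signal
#'
#' Genes are ordered by total score (descending), ties broken by gene id.
#' The per-signal maximum and the counts of signals whose best gene reaches
#' the conventional reporting thresholds (>= 7, >= 6, >= 4) are attached.
#'
#' @param scores GeneScore data.frame from [score_gene()] with `signal_id`
#'   and `gene_id`.
#' @return Ordered data.frame with a per-gene `rank` within each signal;
#'   attributes `per_signal_max` (data.frame) and `threshold_counts` (named
#'   vector for >= 7 / >= 6 / >= 4).
#' @export
rank_genes <- function(scores) {
  ord <- order(scores$signal_id, -scores$total, scores$gene_id)
  out <- scores[ord, , drop = FALSE]
  out$rank <- stats::ave(out$total, out$signal_id,
                         FUN = function(x) seq_along(x))
  per_max <- stats::aggregate(total ~ signal_id, data = out, FUN = max)
  names(per_max)[2] <- "max_score"
  counts <- c(ge7 = sum(per_max$max_score >= 7),
              ge6 = sum(per_max$max_score >= 6),
              ge4 = sum(per_max$max_score >= 4))
  rownames(out) <- NULL
  attr(out, "per_signal_max") <- per_max
  attr(out, "threshold_counts") <- counts
  out
}
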