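# Fine-mapping of GWAS risk signals from summary statistics: the credible
# causal variant (CCV) set per signal is the inclusive union of an LLR-based
# filter, LD expansion around the lead, and externally supplied Bayesian
# credible-set membership.

#' Likelihood ratio of a variant against the lead variant
#'
#' Asymptotic single-causal approximation from summary statistics:
#' `LR_i = exp((z_i^2 - z_lead^2) / 2)`. Equals 1 when `z_i = z_lead`; below
#' 1 for any variant less associated than the lead.
#'
#' @param z_i,z_lead Z-scores (`beta / se`), finite.
#' @return The likelihood ratio(s), vectorised over `z_i`.
#' @export
likelihood_ratio_vs_lead <- function(z_i, z_lead) {
  stopifnot(all(is.finite(z_i)), all(is.finite(z_lead)))
  exp((z_i^2 - z_lead^2) / 2)
}

#' Select the LLR-credible set for one signal
#'
#' Keeps variants whose likelihood ratio versus the lead is at least
#' `threshold` (default 1/100, inclusive boundary). The lead variant is
#' always a member.
#'
#' @param records Summary-statistic data.frame with columns `variant_id` and
#'   either `z` or `beta`/`se`.
#' @param lead Lead variant id (must be present).
#' @param threshold Likelihood-ratio cutoff (kept set is `LR >= threshold`).
#' @return Character vector of variant ids.
#' @export
select_llr_set <- function(records, lead, threshold = 0.01) {
  if (nrow(records) == 0L) stop("empty summary-statistic input")
  z <- if ("z" %in% names(records)) records$z else records$beta / records$se
  li <- match(lead, records$variant_id)
  if (is.na(li)) stop(sprintf("lead variant %s absent from summary stats", lead))
  lr <- likelihood_ratio_vs_lead(z, z[li])
  unique(c(lead, records$variant_id[lr >= threshold]))
}

#' Expand a lead variant by linkage disequilibrium
#'
#' Returns the lead plus all variants with `r2 > r2_threshold` to the lead
#' (strict inequality). The LD table is treated as symmetric.
#'
#' @param lead Lead variant id.
#' @param ld data.frame with columns `id_a`, `id_b`, `r2`.
#' @param r2_threshold Strict lower bound on r-squared (default 0.8).
#' @param restrict_to Optional id set to intersect the expansion with (the
#'   lead is kept regardless).
#' @return Character vector of variant ids.
#' @export
ld_expand <- function(lead, ld, r2_threshold = 0.8, restrict_to = NULL) {
  in_tab <- lead %in% ld$id_a || lead %in% ld$id_b
  if (!in_tab) stop(sprintf("lead variant %s absent from LD table", lead))
  partner <- c(ld$id_b[ld$id_a == lead & ld$r2 > r2_threshold],
               ld$id_a[ld$id_b == lead & ld$r2 > r2_threshold])
  partner <- setdiff(unique(partner), lead)
  if (!is.null(restrict_to)) partner <- intersect(partner, restrict_to)
  unique(c(lead, partner))
}

#' Union the per-approach credible sets into CCV records
#'
#' All variants fine-mapped by at least one approach become credible causal
#' variants, with per-variant provenance flags. Cardinalities obey
#' inclusion-exclusion exactly.
#'
#' @param llr_set,ld_set,bayes_set Character vectors of variant ids (any may
#'   be empty).
#' @param signal_id Signal identifier stamped on each record.
#' @param stats Optional summary-statistic data.frame used to back-fill
#'   `lr_vs_lead` (requires `lead` too).
#' @param ld Optional LD table used to back-fill `r2_to_lead`.
#' @param lead Optional lead variant id.
#' @return data.frame with columns `variant_id`, `signal_id`, `sources`
#'   (comma string over LLR/LD/BAYES), `lr_vs_lead`, `r2_to_lead`.
#' @export
union_credible <- function(llr_set, ld_set, bayes_set = character(0),
                           signal_id = NA_integer_, stats = NULL, ld = NULL,
                           lead = NULL) {
  ids <- unique(c(llr_set, ld_set, bayes_set))
  src <- vapply(ids, function(v) {
    paste(c("LLR", "LD", "BAYES")[c(v %in% llr_set, v %in% ld_set,
                                    v %in% bayes_set)], collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  lr <- rep(NA_real_, length(ids)); r2 <- rep(NA_real_, length(ids))
  if (!is.null(stats) && !is.null(lead)) {
    z <- if ("z" %in% names(stats)) stats$z else stats$beta / stats$se
    zl <- z[match(lead, stats$variant_id)]
    m <- match(ids, stats$variant_id)
    if (length(zl) == 1L && !is.na(zl))
      lr[!is.na(m)] <- likelihood_ratio_vs_lead(z[m[!is.na(m)]], zl)
  }
  if (!is.null(ld) && !is.null(lead)) {
    for (i in seq_along(ids)) {
      hit <- (ld$id_a == lead & ld$id_b == ids[i]) |
             (ld$id_b == lead & ld$id_a == ids[i])
      if (any(hit)) r2[i] <- max(ld$r2[hit])
      else if (identical(ids[i], lead)) r2[i] <- 1
    }
  }
  data.frame(variant_id = ids, signal_id = signal_id, sources = src,
             lr_vs_lead = lr, r2_to_lead = r2, stringsAsFactors = FALSE)
}

#' Fine-map every risk signal
#'
#' Primary signals use the LLR filter on summary statistics plus LD
#' expansion restricted to variants missing from the summary data ("not
#' genotyped"); secondary signals (identified by conditional analysis) use
#' LD expansion only. Bayesian credible-set membership, when supplied, is
#' unioned in per signal.
#'
#' @param stats Summary statistics data.frame (`variant_id`, `chrom`, `pos`,
#'   `beta`, `se`, `p`).
#' @param ld LD table (`id_a`, `id_b`, `r2`).
#' @param signals data.frame with `signal_id`, `lead_variant_id`,
#'   `is_secondary`, and optionally a fine-mapping window per signal
#'   (`chrom`, `region_start`, `region_end`, 1-based inclusive). Window
#'   boundaries are inputs, not derived here; when present, the LLR filter
#'   is evaluated only over summary records inside the window (the
#'   likelihood-ratio criterion is relative to the lead *of that locus* and
#'   is meaningless across loci).
#' @param bayes Optional membership data.frame (`variant_id`, `signal_id`).
#' @param llr_threshold,r2_threshold Cutoffs (defaults 1/100 and 0.8).
#' @return CCV data.frame (one row per variant x signal) as from
#'   [union_credible()].
#' @export
fine_map_signals <- function(stats, ld, signals, bayes = NULL,
                             llr_threshold = 0.01, r2_threshold = 0.8) {
  out <- vector("list", nrow(signals))
  for (i in seq_len(nrow(signals))) {
    sid <- signals$signal_id[i]
    lead <- signals$lead_variant_id[i]
    bayes_set <- if (is.null(bayes)) character(0) else
      unique(bayes$variant_id[bayes$signal_id == sid])
    sstats <- stats
    if (all(c("region_start", "region_end") %in% names(signals)) &&
        !is.na(signals$region_start[i])) {
      sstats <- stats[stats$chrom == signals$chrom[i] &
                      stats$pos >= signals$region_start[i] &
                      stats$pos <= signals$region_end[i], , drop = FALSE]
    }
    if (isTRUE(signals$is_secondary[i])) {
      llr_set <- character(0)
      ld_set <- ld_expand(lead, ld, r2_threshold)
    } else {
      llr_set <- select_llr_set(sstats, lead, llr_threshold)
      not_genotyped <- setdiff(unique(c(ld$id_a, ld$id_b)), stats$variant_id)
      ld_set <- tryCatch(
        ld_expand(lead, ld, r2_threshold, restrict_to = not_genotyped),
        error = function(e) lead)
    }
    out[[i]] <- union_credible(llr_set, ld_set, bayes_set, signal_id = sid,
                               stats = stats, ld = ld, lead = lead)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Variants altering protein-coding sequence
#'
#' Consumes a variant-effect consequence table (VEP is not run) and returns
#' the variants whose consequence set intersects the protein-altering
#' classes (missense or frameshift). Variants absent from the table are
#' treated as non-altering.
#'
#' @param consequence_table data.frame with columns `variant_id` and
#'   `consequence` (comma-separated consequence strings).
#' @param altering Consequence classes counted as protein-altering.
#' @return Character vector of protein-altering variant ids.
#' @export
classify_protein_altering <- function(consequence_table,
                                      altering = c("missense_variant",
                                                   "frameshift_variant")) {
  if (is.null(consequence_table) || nrow(consequence_table) == 0L)
    return(character(0))
  hit <- vapply(consequence_table$consequence, function(s) {
    any(.uncollapse(s) %in% altering)
  }, logical(1), USE.NAMES = FALSE)
  unique(consequence_table$variant_id[hit])
}
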