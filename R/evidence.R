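# Evidence overlay: regulatory-region annotation of variants, marginal eQTL
# regression, expression filtering, and per-(signal, gene) evidence records
# feeding the integrative score and the high-confidence set.

#' Annotate variants with regulatory-region overlap
#'
#' Point-in-interval overlap of each variant with ATAC peaks and ChromHMM
#' segments, per cell context. The ChromHMM flag is true iff a covering
#' segment's label is in that context's enhancer-or-promoter (regulatory)
#' list. `any_regulatory` is the inclusive OR of the four flags (the
#' paper-style "either ATAC-seq or ChromHMM" definition);
#' `both_datasets` is the stricter ATAC-and-ChromHMM intersection.
#'
#' @param variants data.frame with `variant_id`, `chrom`, `pos` (1-based).
#' @param atac Named list of ATAC peak data.frames (1-based closed `chrom`,
#'   `start`, `end`) with elements `melanocyte` and/or `melanoma`.
#' @param chromhmm data.frame of segments (`chrom`, `start`, `end`,
#'   `state_label`, `cell_context`).
#' @param vocab Vocabulary registry (see [chromhmm_vocab()]).
#' @return RegulatoryAnnotation data.frame: per-variant flags
#'   `atac_melanocyte`, `atac_melanoma`, `chromhmm_regulatory_melanocyte`,
#'   `chromhmm_regulatory_melanoma`, `any_regulatory`, `both_datasets`.
#' @export
annotate_regulatory <- function(variants, atac = list(), chromhmm = NULL,
                                vocab = chromhmm_vocab()) {
  n <- nrow(variants)
  point_in <- function(iv) {
    if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, n))
    vapply(seq_len(n), function(i) {
      any(iv$chrom == variants$chrom[i] & iv$start <= variants$pos[i] &
          iv$end >= variants$pos[i])
    }, logical(1))
  }
  out <- data.frame(variant_id = variants$variant_id,
                    stringsAsFactors = FALSE)
  out$atac_melanocyte <- point_in(atac$melanocyte)
  out$atac_melanoma <- point_in(atac$melanoma)
  for (ctx in c("melanocyte", "melanoma")) {
    seg <- NULL
    if (!is.null(chromhmm) && nrow(chromhmm) > 0L) {
      seg <- chromhmm[chromhmm$cell_context == ctx &
                      chromhmm$state_label %in% .regulatory_labels(ctx, vocab),
                      , drop = FALSE]
    }
    out[[paste0("chromhmm_regulatory_", ctx)]] <- point_in(seg)
  }
  out$any_regulatory <- out$atac_melanocyte | out$atac_melanoma |
    out$chromhmm_regulatory_melanocyte | out$chromhmm_regulatory_melanoma
  out$both_datasets <- (out$atac_melanocyte | out$atac_melanoma) &
    (out$chromhmm_regulatory_melanocyte | out$chromhmm_regulatory_melanoma)
  out
}

#' Marginal eQTL test by linear regression
#'
#' Ordinary least squares of expression on genotype dosage plus covariates
#' and an intercept; returns the dosage coefficient and its two-sided
#' t-test p-value. Used for nominal eQTL assessment of interacting
#' variant-gene pairs outside the standard cis window.
#'
#' @param dosage Per-sample genotype dosages in `[0, 2]`.
#' @param expression Per-sample expression values.
#' @param covariates Optional per-sample covariate matrix (e.g. genotyping
#'   PCs and PEER factors).
#' @return list with `beta`, `se`, `p`, `n`, `tested`. A constant dosage is
#'   untestable: `tested = FALSE` with `NA` estimates.
#' @export
marginal_eqtl_test <- function(dosage, expression, covariates = NULL) {
  n <- length(dosage)
  stopifnot(length(expression) == n)
  p_cov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= p_cov + 2L)
    stop("need more samples than covariates + 2")
  if (stats::var(dosage) == 0)
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, n = n,
                tested = FALSE))
  X <- if (is.null(covariates)) data.frame(dosage = dosage)
       else data.frame(dosage = dosage, as.matrix(covariates))
  fit <- stats::lm(expression ~ ., data = X)
  co <- summary(fit)$coefficients["dosage", ]
  list(beta = unname(co["Estimate"]), se = unname(co["Std. Error"]),
       p = unname(co["Pr(>|t|)"]), n = n, tested = TRUE)
}

#' Filter genes by expression and compute median expression percentile
#'
#' A gene is dropped iff the fraction of samples with expression below
#' `threshold` strictly exceeds `max_low_fraction` (exactly 20% low samples
#' is retained). For retained genes, each gene's within-sample percentile
#' rank (0-100, among retained genes) is computed and the median across
#' samples reported.
#'
#' @param mat Numeric matrix, genes x samples, non-negative (e.g. RSEM).
#' @param threshold Low-expression cutoff (default 0.1).
#' @param max_low_fraction Maximum tolerated low-sample fraction
#'   (default 0.20, strict).
#' @return data.frame with `gene_id`, `retained`, `median_percentile` (NA
#'   for dropped genes).
#' @export
expression_filter <- function(mat, threshold = 0.1, max_low_fraction = 0.20) {
  stopifnot(!is.null(rownames(mat)), all(mat >= 0))
  low_frac <- rowMeans(mat < threshold)
  retained <- low_frac <= max_low_fraction
  med_pct <- rep(NA_real_, nrow(mat))
  if (any(retained)) {
    sub <- mat[retained, , drop = FALSE]
    pct <- vapply(seq_len(ncol(sub)), function(j)
      rank(sub[, j], ties.method = "average") / nrow(sub) * 100,
      numeric(nrow(sub)))
    pct <- matrix(pct, nrow = nrow(sub))
    med_pct[retained] <- apply(pct, 1L, stats::median)
  }
  data.frame(gene_id = rownames(mat), retained = retained,
             median_percentile = med_pct, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Build per-(signal, gene) evidence records
#'
#' Aggregates linking, regulatory, MPRA, marginal-eQTL, QTL/TWAS/MWAS,
#' driver, and expression evidence. The chromatin ladder is evaluated over
#' the *same* linking variant: a variant contributes the MPRA level only if
#' it is also regulatory, and the marginal-eQTL level only if additionally
#' MPRA-significant with eQTL `p < marginal_p`. `best_variant_id` is the
#' variant achieving the deepest ladder level (ties broken by lowest GWAS
#' p-value, then lexicographic id). Missing MPRA rows mean "untested" and
#' are never imputed significant.
#'
#' @param links Link table from [link_variants_to_genes()].
#' @param regulatory Per-variant annotation from [annotate_regulatory()].
#' @param mpra data.frame (`variant_id`, `fdr_sig_mc`, `fdr_sig_mel`) or
#'   `NULL` (all untested).
#' @param qtl data.frame (`signal_id`, `gene_id`, `eqtl_or_twas`,
#'   `meqtl_or_mwas`) or `NULL`.
#' @param drivers data.frame (`gene_id`, `melanoma_driver`,
#'   `pancancer_driver`) or `NULL`.
#' @param eqtl_p Optional data.frame (`variant_id`, `gene_id`, `p`) of
#'   marginal eQTL p-values.
#' @param expression Optional named list of [expression_filter()] reports
#'   (`melanocyte`, `melanoma`).
#' @param gwas_p Optional data.frame (`variant_id`, `p`) for tie-breaking.
#' @param marginal_p Marginal eQTL significance cutoff (default 0.05).
#' @return EvidenceRecord data.frame, one row per (signal, gene), with the
#'   per-variant ladder table in attribute `variant_ladder`.
#' @export
build_evidence_records <- function(links, regulatory, mpra = NULL, qtl = NULL,
                                   drivers = NULL, eqtl_p = NULL,
                                   expression = NULL, gwas_p = NULL,
                                   marginal_p = 0.05) {
  pairs <- unique(links[, c("signal_id", "gene_id")])
  if (nrow(pairs) > 0L) pairs <- pairs[order(pairs$signal_id, pairs$gene_id), ,
                                       drop = FALSE]
  reg_of <- function(v) {
    i <- match(v, regulatory$variant_id)
    !is.na(i) & regulatory$any_regulatory[i]
  }
  mpra_of <- function(v) {
    if (is.null(mpra)) return(rep(FALSE, length(v)))
    i <- match(v, mpra$variant_id)
    ok <- !is.na(i)
    res <- rep(FALSE, length(v))
    res[ok] <- mpra$fdr_sig_mc[i[ok]] | mpra$fdr_sig_mel[i[ok]]
    res
  }
  eqtlp_of <- function(v, g) {
    if (is.null(eqtl_p)) return(rep(NA_real_, length(v)))
    key <- paste(eqtl_p$variant_id, eqtl_p$gene_id)
    eqtl_p$p[match(paste(v, g), key)]
  }
  gwasp_of <- function(v) {
    if (is.null(gwas_p)) return(rep(NA_real_, length(v)))
    gwas_p$p[match(v, gwas_p$variant_id)]
  }
  ladders <- list()
  recs <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sid <- pairs$signal_id[i]; g <- pairs$gene_id[i]
    vs <- unique(links$variant_id[links$signal_id == sid &
                                  links$gene_id == g])
    reg <- reg_of(vs)
    mp <- reg & mpra_of(vs)
    ep <- eqtlp_of(vs, g)
    meq <- mp & !is.na(ep) & ep < marginal_p
    depth <- 1L + reg + mp + meq
    ladders[[i]] <- data.frame(signal_id = sid, gene_id = g, variant_id = vs,
                               ladder_depth = depth, gwas_p = gwasp_of(vs),
                               stringsAsFactors = FALSE)
    ord <- order(-depth, gwasp_of(vs), vs)
    best <- vs[ord[1L]]
    qi <- if (is.null(qtl)) integer(0) else
      which(qtl$signal_id == sid & qtl$gene_id == g)
    di <- if (is.null(drivers)) integer(0) else
      which(drivers$gene_id == g)
    expr_flag <- function(ctx) {
      if (is.null(expression) || is.null(expression[[ctx]])) return(NA)
      r <- expression[[ctx]]
      j <- match(g, r$gene_id)
      if (is.na(j)) NA else r$retained[j]
    }
    recs[[i]] <- data.frame(
      signal_id = sid, gene_id = g, linked = TRUE,
      best_variant_id = best,
      var_regulatory = any(reg), var_mpra_sig = any(mp),
      var_marginal_eqtl = any(meq),
      eqtl_or_twas = length(qi) > 0L && any(qtl$eqtl_or_twas[qi]),
      meqtl_or_mwas = length(qi) > 0L && any(qtl$meqtl_or_mwas[qi]),
      driver_melanoma = length(di) > 0L && any(drivers$melanoma_driver[di]),
      driver_pancancer = length(di) > 0L && any(drivers$pancancer_driver[di]),
      expressed_melanocyte = expr_flag("melanocyte"),
      expressed_melanoma = expr_flag("melanoma"),
      protein_coding_nomination = FALSE,
      stringsAsFactors = FALSE)
  }
  out <- if (length(recs) == 0L) {
    data.frame(signal_id = integer(0), gene_id = character(0),
               linked = logical(0), best_variant_id = character(0),
               var_regulatory = logical(0), var_mpra_sig = logical(0),
               var_marginal_eqtl = logical(0), eqtl_or_twas = logical(0),
               meqtl_or_mwas = logical(0), driver_melanoma = logical(0),
               driver_pancancer = logical(0),
               expressed_melanocyte = logical(0),
               expressed_melanoma = logical(0),
               protein_coding_nomination = logical(0))
  } else do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "variant_ladder") <- if (length(ladders) == 0L) NULL else
    do.call(rbind, ladders)
  out
}

#' High-confidence variant / gene / signal sets
#'
#' The high-confidence gene set comprises genes linked by a regulatory,
#' MPRA-significant variant (ladder depth >= 3). Companion sets of the
#' qualifying variants and their signals are returned.
#'
#' @param records Evidence records from [build_evidence_records()] (the
#'   `variant_ladder` attribute is used for the variant set).
#' @return list with `variants`, `genes`, `signals`.
#' @export
high_confidence_set <- function(records) {
  hc <- records[records$var_mpra_sig, , drop = FALSE]
  ladder <- attr(records, "variant_ladder")
  variants <- character(0)
  if (!is.null(ladder) && nrow(hc) > 0L) {
    key <- paste(ladder$signal_id, ladder$gene_id)
    keep <- key %in% paste(hc$signal_id, hc$gene_id) & ladder$ladder_depth >= 3L
    variants <- sort(unique(ladder$variant_id[keep]))
  }
  list(variants = variants,
       genes = sort(unique(hc$gene_id)),
       signals = sort(unique(hc$signal_id)))
}
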