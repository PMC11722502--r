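# Synthetic-data generator: a self-consistent toy universe (genome, genes,
# restriction fragments, GWAS signals, loops, epigenome, MPRA, QTL flags)
# with a planted-truth ledger, so the whole analysis runs and is validated
# at desk scale without external data.
#
# One master seed fans out to per-component sub-seeds through derive_seed(),
# so adding an output never reshuffles existing ones. Variant positions are
# sampled on restriction fragments and never on cut-site motifs, avoiding
# any interaction between digestion and variant placement.

#' Configuration of the synthetic universe
#'
#' Defaults describe the stated desk-scale world: one 600 kb chromosome
#' hosting 10 well-separated genes, 10 risk signals with one planted
#' enhancer-gene regulatory link each, tight LD blocks around each causal
#' variant, genome-wide-significant causal effects, every causal inside a
#' regulatory element, and no decoy loops.
#'
#' @param seed Master seed (all randomness derives from it).
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bases.
#' @param n_genes Total genes (0 allowed: empty transcript set).
#' @param n_signals Number of risk signals (one planted causal each).
#' @param n_variants_per_signal Variants per signal (including the causal).
#' @param causal_effect_lambda Non-centrality of each planted causal's
#'   Z-score.
#' @param ld_decay_rate Per-base exponential decay of the signed LD
#'   correlation r.
#' @param fraction_regulatory Proportion of planted causals placed inside a
#'   regulatory (enhancer) element.
#' @param loop_true_score_range CHiCAGO-score interval for planted loops.
#' @param loop_noise_rate Decoy loops per true loop (0.5 adds one decoy per
#'   two true loops).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 42L, n_chromosomes = 1L,
                             chrom_length = 600000L, n_genes = 10L,
                             n_signals = 10L, n_variants_per_signal = 15L,
                             causal_effect_lambda = 6,
                             ld_decay_rate = 2e-4, fraction_regulatory = 1,
                             loop_true_score_range = c(5, 15),
                             loop_noise_rate = 0) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes), n_signals = as.integer(n_signals),
              n_variants_per_signal = as.integer(n_variants_per_signal),
              causal_effect_lambda = causal_effect_lambda,
              ld_decay_rate = ld_decay_rate,
              fraction_regulatory = fraction_regulatory,
              loop_true_score_range = loop_true_score_range,
              loop_noise_rate = loop_noise_rate)
  stopifnot(cfg$n_chromosomes >= 1L, cfg$chrom_length >= 1L,
            cfg$n_genes >= 0L, cfg$n_signals >= 1L,
            cfg$n_variants_per_signal >= 1L,
            cfg$fraction_regulatory >= 0, cfg$fraction_regulatory <= 1,
            cfg$loop_noise_rate >= 0,
            length(cfg$loop_true_score_range) == 2L,
            cfg$loop_true_score_range[1] >= 0,
            diff(cfg$loop_true_score_range) >= 0,
            cfg$ld_decay_rate >= 0)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate the toy genome and transcript models
#'
#' Each chromosome is a uniform random A/C/G/T string of the configured
#' length. Genes (2-4 kb, random strand) are placed non-overlapping in
#' equal-width slots with generous margins, round-robin across chromosomes;
#' the TSS is the transcript start on `+` and end on `-`. All transcripts
#' are protein-coding.
#'
#' @param config A [synthetic_config()].
#' @return list with `sequences` (named `DNAStringSet`) and `transcripts`
#'   (data.frame as from [load_transcripts()]).
#' @export
generate_genome <- function(config) {
  set.seed(derive_seed(config$seed, "genome"))
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  seqs <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1))
  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- chroms
  if (config$n_genes == 0L) {
    transcripts <- data.frame(gene_id = character(0), gene_name = character(0),
                              transcript_id = character(0), chrom = character(0),
                              strand = character(0), start = integer(0),
                              end = integer(0), tss = integer(0),
                              biotype = character(0))
    return(list(sequences = sequences, transcripts = transcripts,
                config = config))
  }
  chrom_of <- chroms[((seq_len(config$n_genes) - 1L) %% length(chroms)) + 1L]
  margin <- 10000L
  rows <- vector("list", config$n_genes)
  for (ch in chroms) {
    gi <- which(chrom_of == ch)
    g <- length(gi)
    if (g == 0L) next
    usable <- config$chrom_length - 2L * margin
    slot <- usable %/% g
    if (slot < 8000L)
      stop("chromosome too short to host requested genes")
    for (k in seq_along(gi)) {
      i <- gi[k]
      glen <- sample(2000:4000, 1L)
      lo <- margin + (k - 1L) * slot + 1000L
      hi <- margin + k * slot - glen - 1000L
      gstart <- sample(lo:hi, 1L)
      gend <- gstart + glen - 1L
      strand <- sample(c("+", "-"), 1L)
      rows[[i]] <- data.frame(
        gene_id = sprintf("G%03d", i), gene_name = sprintf("G%03d", i),
        transcript_id = sprintf("T%03d", i), chrom = ch, strand = strand,
        start = gstart, end = gend,
        tss = if (strand == "-") gend else gstart,
        biotype = "protein_coding", stringsAsFactors = FALSE)
    }
  }
  list(sequences = sequences, transcripts = do.call(rbind, rows),
       config = config)
}

#' Write transcript models as a GTF file
#'
#' @param transcripts Transcript table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- character(0)
  if (nrow(transcripts) > 0L) {
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_name "%s"; transcript_biotype "%s";',
      transcripts$gene_id, transcripts$transcript_id, transcripts$gene_name,
      transcripts$biotype)
    lines <- paste(transcripts$chrom, "synthetic", "transcript",
                   transcripts$start, transcripts$end, ".",
                   transcripts$strand, ".", attrs, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

# 0-based positions covered by a cut-site motif on one sequence.
.motif_cover <- function(seq, motifs = restriction_motifs()) {
  cov <- IRanges::IRanges()
  for (i in seq_len(nrow(motifs))) {
    hits <- Biostrings::matchPattern(motifs$motif[i], seq, fixed = "subject")
    if (length(hits) > 0L)
      cov <- c(cov, IRanges::IRanges(BiocGenerics::start(hits),
                                     BiocGenerics::end(hits)))
  }
  IRanges::reduce(cov)
}

#' Simulate GWAS summary statistics with LD-correlated Z-scores
#'
#' Per signal, Z-scores are drawn from a multivariate normal with mean
#' `r[i, causal] * lambda` and correlation matrix equal to the signed LD
#' table; a non-positive-definite correlation is repaired by diagonal
#' loading (logged). `beta` is back-filled as `z * se` with `se` fixed at
#' 0.02 (only `z` matters downstream) and `p` is the two-sided normal
#' p-value.
#'
#' @param signal_spec data.frame with `variant_id`, `signal_id`, `chrom`,
#'   `pos`, `is_causal`, `lambda` (non-centrality of each causal).
#' @param ld data.frame with `id_a`, `id_b` and signed `r` (falls back to
#'   `sqrt(r2)` when only `r2` is present).
#' @param seed Integer seed.
#' @param se Fixed standard error used to back-fill `beta`.
#' @return Summary-statistic data.frame (`variant_id`, `chrom`, `pos`,
#'   `beta`, `se`, `p`, `z`).
#' @export
simulate_summary_stats <- function(signal_spec, ld, seed, se = 0.02) {
  if (!"r" %in% names(ld)) {
    stopifnot("r2" %in% names(ld))
    ld$r <- sqrt(ld$r2)
  }
  stopifnot(all(abs(ld$r) <= 1))
  set.seed(derive_seed(seed, "summary_stats"))
  out <- vector("list", 0L)
  for (sid in unique(signal_spec$signal_id)) {
    sv <- signal_spec[signal_spec$signal_id == sid, , drop = FALSE]
    ids <- sv$variant_id
    n <- length(ids)
    R <- diag(n)
    sub <- ld[ld$id_a %in% ids & ld$id_b %in% ids, , drop = FALSE]
    ia <- match(sub$id_a, ids); ib <- match(sub$id_b, ids)
    R[cbind(ia, ib)] <- sub$r
    R[cbind(ib, ia)] <- sub$r
    causal_idx <- which(sv$is_causal)
    if (length(causal_idx) == 0L)
      stop(sprintf("signal %s has no causal variant in spec", sid))
    mu <- as.vector(R[, causal_idx, drop = FALSE] %*%
                      sv$lambda[causal_idx])
    U <- NULL; eps <- 0
    repeat {
      U <- tryCatch(chol(R + diag(eps, n)), error = function(e) NULL)
      if (!is.null(U)) break
      eps <- if (eps == 0) 1e-8 else eps * 10
      if (eps > 1) stop("correlation matrix could not be repaired")
    }
    if (eps > 0)
      message(sprintf(
        "simulate_summary_stats: signal %s correlation repaired by diagonal loading (eps=%g)",
        sid, eps))
    z <- mu + as.vector(t(U) %*% stats::rnorm(n))
    out[[length(out) + 1L]] <- data.frame(
      variant_id = ids, chrom = sv$chrom, pos = sv$pos,
      beta = z * se, se = se, p = 2 * stats::pnorm(-abs(z)), z = z,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plant the regulatory architecture of the universe
#'
#' For each signal: a target gene, an enhancer-hosting restriction fragment
#' 20-80 kb from the target TSS (and at least 6 kb from every TSS so no
#' planted causal accidentally sits in a promoter), a causal variant at the
#' fragment midpoint with an LD cloud of companion variants within 2 kb,
#' enhancer-state ChromHMM segments and ATAC peaks over the causal (for the
#' regulatory fraction of signals), promoter-state segments over every gene
#' TSS, a chromatin loop from the causal's bin to the target promoter's bin
#' with score inside the configured range, and an MPRA-significant record
#' for the causal. Decoy loops connect a causal's bin to the promoter bin of
#' a *non-target* gene (never a true causal's bin to its true gene), at
#' `loop_noise_rate` decoys per true loop. A link whose enhancer and target
#' promoter would share a bin is re-planted at greater distance (logged).
#'
#' @param bundle Genome bundle from [generate_genome()].
#' @param config The [synthetic_config()].
#' @param fragments Fragment table from [digest_genome()].
#' @param bins Bin table from [make_bins()].
#' @return list of universe components: `variants`, `signals`, `chromhmm`,
#'   `atac`, `loops`, `mpra`, `qtl`, `drivers`, `bayes`, `eqtl_p`,
#'   `target_regions`, and the planted-truth ledger `truth`.
#' @export
plant_architecture <- function(bundle, config, fragments, bins) {
  set.seed(derive_seed(config$seed, "architecture"))
  tx <- bundle$transcripts
  if (nrow(tx) == 0L) stop("cannot plant signals without genes")
  vocab <- chromhmm_vocab()
  motif_cov <- lapply(bundle$sequences, .motif_cover)

  in_motif <- function(chrom, pos) {
    cov <- motif_cov[[chrom]]
    length(cov) > 0L &&
      any(BiocGenerics::start(cov) <= pos & BiocGenerics::end(cov) >= pos)
  }
  bin_of_pos <- function(chrom, pos) {
    fi <- which(fragments$chrom == chrom & fragments$start <= pos - 1L &
                fragments$end > pos - 1L)
    .bin_of_fragment(bins, fragments$frag_id[fi[1L]])
  }

  # promoter-state segments over every TSS, both contexts
  chromhmm <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    data.frame(chrom = tx$chrom[i], start = max(tx$tss[i] - 1000L, 1L),
               end = tx$tss[i] + 1000L,
               state_label = c("TssA", "1_TssA"),
               cell_context = c("melanocyte", "melanoma"),
               sample_id = "S1", stringsAsFactors = FALSE)
  }))

  n_sig <- config$n_signals
  n_reg <- round(config$fraction_regulatory * n_sig)
  target_gene <- tx$gene_id[((seq_len(n_sig) - 1L) %% nrow(tx)) + 1L]
  variants <- list(); loops <- list(); enh_segments <- list()
  atac_peaks <- list(); regions <- list()
  true_links <- list(); causal_ids <- character(n_sig)
  replant_log <- character(0)
  # keep signals spatially disjoint so no variant cloud shares (or neighbours)
  # another signal's loop anchor bins
  placed <- data.frame(chrom = character(0), mid = integer(0))
  min_signal_sep <- 12000L

  for (s in seq_len(n_sig)) {
    g <- target_gene[s]
    gi <- which(tx$gene_id == g)[1L]
    chrom <- tx$chrom[gi]; tss <- tx$tss[gi]
    prom_bin <- bin_of_pos(chrom, tss)
    fr <- fragments[fragments$chrom == chrom, , drop = FALSE]
    mid <- (fr$start + fr$end) %/% 2L + 1L # 1-based midpoints
    d_target <- abs(mid - tss)
    min_tss_d <- vapply(mid, function(m)
      min(abs(m - tx$tss[tx$chrom == chrom])), numeric(1))
    width_ok <- (fr$end - fr$start) >= 60L
    prior <- placed$mid[placed$chrom == chrom]
    sep_ok <- if (length(prior) == 0L) rep(TRUE, length(mid)) else
      vapply(mid, function(m) all(abs(m - prior) >= min_signal_sep),
             logical(1))
    for (dmax in c(80000L, 160000L, 320000L)) {
      cand <- which(d_target >= 20000L & d_target <= dmax &
                    min_tss_d >= 6000L & width_ok & sep_ok)
      cand <- cand[vapply(cand, function(i)
        !identical(.bin_of_fragment(bins, fr$frag_id[i]), prom_bin),
        logical(1))]
      if (length(cand) > 0L) break
      replant_log <- c(replant_log, sprintf(
        "signal %d: link re-planted at greater distance (dmax=%d)", s, dmax))
    }
    if (length(cand) == 0L)
      stop(sprintf("signal %d: no eligible enhancer fragment", s))
    ei <- cand[sample.int(length(cand), 1L)]
    cpos <- mid[ei]
    placed <- rbind(placed, data.frame(chrom = chrom, mid = cpos))
    while (in_motif(chrom, cpos)) cpos <- cpos + 1L
    causal_id <- sprintf("v_s%02d_causal", s)
    causal_ids[s] <- causal_id
    # companion variants within +/- 2 kb, off cut-site motifs, unique
    others <- integer(0)
    while (length(others) < config$n_variants_per_signal - 1L) {
      p <- cpos + sample(-2000:2000, 1L)
      if (p < 1L || p > config$chrom_length || p == cpos ||
          p %in% others || in_motif(chrom, p)) next
      others <- c(others, p)
    }
    pos <- c(cpos, sort(others))
    ids <- c(causal_id,
             sprintf("v_s%02d_%02d", s, seq_along(others)))
    variants[[s]] <- data.frame(
      variant_id = ids, signal_id = s, chrom = chrom, pos = pos,
      is_causal = ids == causal_id, lambda = config$causal_effect_lambda,
      stringsAsFactors = FALSE)
    if (s <= n_reg) {
      enh_segments[[s]] <- data.frame(
        chrom = chrom, start = cpos - 300L, end = cpos + 300L,
        state_label = c(sample(vocab$melanocyte$enhancer, 1L),
                        sample(vocab$melanoma$enhancer, 1L)),
        cell_context = c("melanocyte", "melanoma"), sample_id = "S1",
        stringsAsFactors = FALSE)
      atac_peaks[[s]] <- data.frame(chrom = chrom, start = cpos - 250L,
                                    end = cpos + 250L,
                                    stringsAsFactors = FALSE)
    }
    causal_bin <- bin_of_pos(chrom, cpos)
    loops[[s]] <- data.frame(bait_bin_id = causal_bin,
                             otherend_bin_id = prom_bin,
                             score = stats::runif(1L,
                                                  config$loop_true_score_range[1],
                                                  config$loop_true_score_range[2]),
                             decoy = FALSE, signal_id = s,
                             stringsAsFactors = FALSE)
    regions[[s]] <- data.frame(chrom = chrom, start = min(pos) - 1000L,
                               end = max(pos) + 1000L,
                               stringsAsFactors = FALSE)
    true_links[[s]] <- data.frame(variant_id = causal_id, gene_id = g,
                                  signal_id = s, stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, variants)
  true_links <- do.call(rbind, true_links)
  loops <- do.call(rbind, loops)

  # decoy loops: a causal's bin to the promoter bin of a non-target gene
  n_decoys <- round(config$loop_noise_rate * n_sig)
  decoy_pairs <- list()
  if (n_decoys > 0L) {
    prom_bins <- vapply(seq_len(nrow(tx)), function(i)
      bin_of_pos(tx$chrom[i], tx$tss[i]), integer(1))
    names(prom_bins) <- tx$gene_id
    guard <- 0L
    while (length(decoy_pairs) < n_decoys && guard < 1000L) {
      guard <- guard + 1L
      s <- sample.int(n_sig, 1L)
      g <- sample(setdiff(tx$gene_id, target_gene[s]), 1L)
      bait <- loops$bait_bin_id[loops$signal_id == s & !loops$decoy][1L]
      other <- prom_bins[[g]]
      if (identical(bait, other)) next
      # never duplicate a true loop or connect a causal to its true gene
      clash <- any(!loops$decoy & loops$bait_bin_id == bait &
                   loops$otherend_bin_id == other)
      if (clash) next
      decoy_pairs[[length(decoy_pairs) + 1L]] <- data.frame(
        bait_bin_id = bait, otherend_bin_id = other,
        score = stats::runif(1L, config$loop_true_score_range[1],
                             config$loop_true_score_range[2]),
        decoy = TRUE, signal_id = NA_integer_, stringsAsFactors = FALSE)
    }
    loops <- rbind(loops, do.call(rbind, decoy_pairs))
  }
  loops$loop_id <- paste0("L", seq_len(nrow(loops)))

  enh <- if (length(enh_segments) > 0L) do.call(rbind, enh_segments) else NULL
  chromhmm <- rbind(chromhmm, enh)
  atac <- if (length(atac_peaks) > 0L) do.call(rbind, atac_peaks) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))

  mpra <- data.frame(variant_id = variants$variant_id, tested = TRUE,
                     fdr_sig_mc = variants$is_causal,
                     fdr_sig_mel = variants$is_causal,
                     stringsAsFactors = FALSE)
  qtl <- data.frame(signal_id = true_links$signal_id,
                    gene_id = true_links$gene_id,
                    eqtl_or_twas = FALSE, meqtl_or_mwas = FALSE,
                    stringsAsFactors = FALSE)
  drivers <- data.frame(gene_id = character(0), melanoma_driver = logical(0),
                        pancancer_driver = logical(0))
  bayes <- data.frame(variant_id = causal_ids,
                      signal_id = seq_len(n_sig), pip = 0.95,
                      stringsAsFactors = FALSE)
  eqtl_p <- data.frame(variant_id = true_links$variant_id,
                       gene_id = true_links$gene_id, p = 1e-6,
                       stringsAsFactors = FALSE)
  sig_chrom <- vapply(seq_len(n_sig), function(s)
    variants$chrom[variants$signal_id == s][1L], character(1))
  sig_lo <- vapply(seq_len(n_sig), function(s)
    min(variants$pos[variants$signal_id == s]), integer(1))
  sig_hi <- vapply(seq_len(n_sig), function(s)
    max(variants$pos[variants$signal_id == s]), integer(1))
  signals <- data.frame(signal_id = seq_len(n_sig), locus_id = seq_len(n_sig),
                        lead_variant_id = causal_ids, is_secondary = FALSE,
                        chrom = sig_chrom,
                        region_start = pmax(sig_lo - 5000L, 1L),
                        region_end = sig_hi + 5000L,
                        stringsAsFactors = FALSE)
  if (length(replant_log) > 0L) message(paste(replant_log, collapse = "\n"))
  truth <- list(
    causal_variants = stats::setNames(as.list(causal_ids),
                                      paste0("signal_", seq_len(n_sig))),
    true_links = true_links,
    true_regulatory_elements = if (is.null(enh)) NULL else
      enh[enh$cell_context == "melanocyte", c("chrom", "start", "end")],
    true_loops = loops[!loops$decoy,
                       c("loop_id", "bait_bin_id", "otherend_bin_id")],
    decoy_loops = loops[loops$decoy,
                        c("loop_id", "bait_bin_id", "otherend_bin_id")],
    target_genes = stats::setNames(as.list(target_gene),
                                   paste0("signal_", seq_len(n_sig))))
  list(variants = variants, signals = signals, chromhmm = chromhmm,
       atac = list(melanocyte = atac, melanoma = atac), loops = loops,
       mpra = mpra, qtl = qtl, drivers = drivers, bayes = bayes,
       eqtl_p = eqtl_p,
       target_regions = do.call(rbind, regions), truth = truth)
}

#' Generate the complete synthetic universe in memory
#'
#' Genome, fragment map, bins, baitmap, planted architecture, LD table, and
#' simulated summary statistics, plus the planted-truth ledger.
#'
#' @param config A [synthetic_config()].
#' @param bin_k Fragments per bin (default 4).
#' @return list of all universe components.
#' @export
generate_universe <- function(config, bin_k = 4L) {
  bundle <- generate_genome(config)
  fragments <- digest_genome(bundle$sequences)
  bins <- make_bins(fragments, k = bin_k)
  arch <- plant_architecture(bundle, config, fragments, bins)
  # signed exponential-decay LD within each signal (a valid correlation)
  ld <- do.call(rbind, lapply(split(arch$variants, arch$variants$signal_id),
                              function(sv) {
    if (nrow(sv) < 2L) return(NULL)
    cmb <- utils::combn(nrow(sv), 2L)
    r <- exp(-config$ld_decay_rate * abs(sv$pos[cmb[1, ]] - sv$pos[cmb[2, ]]))
    data.frame(id_a = sv$variant_id[cmb[1, ]], id_b = sv$variant_id[cmb[2, ]],
               r = r, r2 = r^2, stringsAsFactors = FALSE)
  }))
  rownames(ld) <- NULL
  stats <- simulate_summary_stats(arch$variants, ld, seed = config$seed)
  bins <- build_baitmap(bins, fragments, arch$target_regions)
  c(list(config = config, bundle = bundle, fragments = fragments,
         bins = bins, ld = ld, summary_stats = stats), arch)
}

#' Write a synthetic universe as a pipeline input bundle
#'
#' Emits every external-interface file: FASTA (60-column wrap), GTF, rmap /
#' baitmap, summary-statistic / LD / Bayesian-membership TSVs, ChromHMM BED4
#' and ATAC BED3 per context, ibed interactions, MPRA / QTL-flag / driver /
#' marginal-eQTL TSVs, target regions, signals, and the planted-truth ledger
#' as JSON. Identical seed and config give byte-identical files.
#'
#' @param universe Output of [generate_universe()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_universe <- function(universe, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(universe$bundle$sequences, p("genome.fa"),
                              width = 60L)
  write_gtf(universe$bundle$transcripts, p("genes.gtf"))
  write_rmap(universe$fragments, p("fragments.rmap"))
  write_rmap(universe$bins, p("bins.rmap"))
  write_baitmap(universe$bins, p("bins.baitmap"))
  write_tsv(universe$summary_stats[, c("variant_id", "chrom", "pos", "beta",
                                       "se", "p")], p("summary_stats.tsv"))
  write_tsv(universe$ld[, c("id_a", "id_b", "r2")], p("ld.tsv"))
  write_tsv(universe$bayes, p("bayes.tsv"))
  write_tsv(universe$signals, p("signals.tsv"))
  write_tsv(universe$target_regions, p("target_regions.tsv"))
  for (ctx in c("melanocyte", "melanoma")) {
    seg <- universe$chromhmm[universe$chromhmm$cell_context == ctx, ,
                             drop = FALSE]
    write_bed(seg, p(sprintf("chromhmm_%s.bed", ctx)))
    write_bed(universe$atac[[ctx]], p(sprintf("atac_%s.bed", ctx)))
  }
  write_interactions_ibed(universe$loops, universe$bins, p("interactions.ibed"))
  write_tsv(universe$mpra, p("mpra.tsv"))
  write_tsv(universe$qtl, p("qtl_flags.tsv"))
  write_tsv(universe$drivers, p("drivers.tsv"))
  write_tsv(universe$eqtl_p, p("eqtl_p.tsv"))
  jsonlite::write_json(universe$truth, p("ledger.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c("genome.fa", "genes.gtf", "fragments.rmap", "bins.rmap",
             "bins.baitmap", "summary_stats.tsv", "ld.tsv", "bayes.tsv",
             "signals.tsv", "target_regions.tsv", "chromhmm_melanocyte.bed",
             "chromhmm_melanoma.bed", "atac_melanocyte.bed",
             "atac_melanoma.bed", "interactions.ibed", "mpra.tsv",
             "qtl_flags.tsv", "drivers.tsv", "eqtl_p.tsv", "ledger.json")
  invisible(stats::setNames(file.path(dir, files), files))
}
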