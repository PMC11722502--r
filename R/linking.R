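# Variant-to-gene nomination: connect CCV bins to gene promoters through
# score-filtered chromatin interaction loops or direct promoter overlap,
# classify distances, and flag alternative-promoter interactions.

#' Load CHiCAGO-style interaction calls
#'
#' Reads an ibed-style table (bait chrom/start/end/name, other-end
#' chrom/start/end/name, N_reads, score; tab-separated with header; 1-based
#' inclusive coordinates matching the rmap dialect) or a WashU long-range
#' text file. Records with score below the threshold are dropped (the
#' conventional high-confidence cutoff is a CHiCAGO score of 5, inclusive).
#' Trans-chromosomal records and records whose ends cannot be resolved to a
#' bin are skipped and counted.
#'
#' @param path Interaction file path.
#' @param bins Bin table used to resolve record ends to bin ids (a record
#'   end resolves to the bin whose hull contains its midpoint).
#' @param score_threshold Minimum retained score (inclusive; default 5).
#' @param format `"ibed"` or `"longrange"`.
#' @return data.frame with columns `loop_id`, `bait_bin_id`,
#'   `otherend_bin_id`, `score`; attributes `n_skipped` and `n_trans`.
#' @export
load_interactions <- function(path, bins, score_threshold = 5,
                              format = c("ibed", "longrange")) {
  format <- match.arg(format)
  if (format == "ibed") {
    x <- read_tsv(path)
    names(x)[1:10] <- c("bait_chr", "bait_start", "bait_end", "bait_name",
                        "otherEnd_chr", "otherEnd_start", "otherEnd_end",
                        "otherEnd_name", "N_reads", "score")
  } else {
    raw <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
    # chr1  start  end  chr2:start2-end2,score
    m <- regmatches(raw[[4]],
                    regexec("^([^:]+):([0-9]+)-([0-9]+),([0-9.]+)$", raw[[4]]))
    x <- data.frame(bait_chr = raw[[1]], bait_start = raw[[2]] + 1L,
                    bait_end = raw[[3]],
                    otherEnd_chr = vapply(m, `[`, "", 2L),
                    otherEnd_start = as.integer(vapply(m, `[`, "", 3L)) + 1L,
                    otherEnd_end = as.integer(vapply(m, `[`, "", 4L)),
                    N_reads = NA_integer_,
                    score = as.numeric(vapply(m, `[`, "", 5L)),
                    stringsAsFactors = FALSE)
  }
  n_trans <- sum(x$bait_chr != x$otherEnd_chr)
  x <- x[x$bait_chr == x$otherEnd_chr, , drop = FALSE]
  x <- x[x$score >= score_threshold, , drop = FALSE]
  resolve <- function(chr, lo, hi) {
    mid <- (lo + hi) / 2
    hit <- which(bins$chrom == chr & bins$start + 1L <= mid & bins$end >= mid)
    if (length(hit) == 0L) NA_integer_ else bins$bin_id[hit[1L]]
  }
  bait <- mapply(resolve, x$bait_chr, x$bait_start, x$bait_end)
  other <- mapply(resolve, x$otherEnd_chr, x$otherEnd_start, x$otherEnd_end)
  ok <- !is.na(bait) & !is.na(other)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    message(sprintf("load_interactions: skipped %d unresolvable record(s)",
                    n_skipped))
  out <- data.frame(loop_id = paste0("L", seq_len(sum(ok))),
                    bait_bin_id = as.integer(bait[ok]),
                    otherend_bin_id = as.integer(other[ok]),
                    score = x$score[ok], stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_trans") <- n_trans
  out
}

#' Write loops as an ibed file
#'
#' @param loops Loop table (`loop_id`, `bait_bin_id`, `otherend_bin_id`,
#'   `score`, optionally `n_reads`).
#' @param bins Bin table supplying coordinates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions_ibed <- function(loops, bins, path) {
  bi <- match(loops$bait_bin_id, bins$bin_id)
  oi <- match(loops$otherend_bin_id, bins$bin_id)
  n_reads <- if ("n_reads" %in% names(loops)) loops$n_reads
             else rep(10L, nrow(loops))
  write_tsv(data.frame(
    bait_chr = bins$chrom[bi], bait_start = bins$start[bi] + 1L,
    bait_end = bins$end[bi], bait_name = paste0("bin", loops$bait_bin_id),
    otherEnd_chr = bins$chrom[oi], otherEnd_start = bins$start[oi] + 1L,
    otherEnd_end = bins$end[oi],
    otherEnd_name = paste0("bin", loops$otherend_bin_id),
    N_reads = n_reads, score = loops$score), path)
}

#' Link credible variants to genes
#'
#' Two mechanisms: (a) *loop* — for each variant, every loop touching its
#' primary or adjacent bins (either end; loops are used symmetrically) links
#' it to every gene of every assigned promoter overlapping the loop's other
#' end; (b) *promoter_overlap* — a variant physically inside a promoter
#' links to that promoter's genes. Both mechanisms are kept as separate
#' records; exact duplicates are collapsed. Distance is variant position to
#' the nearest TSS of the linked gene among the target promoter's
#' transcripts (0 for promoter overlap).
#'
#' @param assignments Variant bin assignments from [assign_variant_bins()].
#' @param ccvs CCV table (`variant_id`, `signal_id`).
#' @param loops Loop table from [load_interactions()].
#' @param promoters Assigned promoter table from
#'   [assign_genes_to_promoters()] (unassigned promoters are ignored); the
#'   three definitions may be row-bound.
#' @param bins Bin table.
#' @param transcripts Transcript table.
#' @return VariantGeneLink data.frame: `variant_id`, `signal_id`, `gene_id`,
#'   `mechanism`, `via_bin_id`, `loop_id`, `promoter_id`, `promoter_source`,
#'   `distance`, `distance_class`, `alt_promoter`.
#' @export
link_variants_to_genes <- function(assignments, ccvs, loops, promoters, bins,
                                   transcripts) {
  promoters <- promoters[promoters$assigned, , drop = FALSE]
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  # promoters overlapping each bin hull, precomputed
  prom_by_bin <- NULL
  if (nrow(promoters) > 0L && nrow(bins) > 0L) {
    pr <- GenomicRanges::GRanges(promoters$chrom,
                                 IRanges::IRanges(promoters$start,
                                                  promoters$end))
    bg <- GenomicRanges::GRanges(bins$chrom,
                                 IRanges::IRanges(bins$start + 1L, bins$end))
    hits <- GenomicRanges::findOverlaps(bg, pr)
    prom_by_bin <- split(S4Vectors::subjectHits(hits),
                         bins$bin_id[S4Vectors::queryHits(hits)])
  }
  gene_tss_dist <- function(pos, gene, prom_row) {
    txs <- .uncollapse(promoters$transcript_ids[prom_row])
    tt <- transcripts[transcripts$transcript_id %in% txs &
                      transcripts$gene_id == gene, , drop = FALSE]
    if (nrow(tt) == 0L) return(NA_integer_)
    min(abs(pos - tt$tss))
  }
  for (vi in seq_len(nrow(assignments))) {
    v <- assignments$variant_id[vi]
    pos <- assignments$pos[vi]
    chrom <- assignments$chrom[vi]
    sig_ids <- unique(ccvs$signal_id[ccvs$variant_id == v])
    if (length(sig_ids) == 0L) next
    vbins <- unique(c(assignments$primary_bin_id[vi],
                      as.integer(.uncollapse(assignments$adjacent_bin_ids[vi]))))
    # loop mechanism (symmetric over ends)
    if (nrow(loops) > 0L) {
      for (li in seq_len(nrow(loops))) {
        ends <- c(loops$bait_bin_id[li], loops$otherend_bin_id[li])
        for (side in 1:2) {
          if (!(ends[side] %in% vbins)) next
          other <- ends[3L - side]
          pidx <- prom_by_bin[[as.character(other)]]
          for (pi in unique(pidx)) {
            for (g in .uncollapse(promoters$gene_ids[pi])) {
              add(variant_id = v, signal_id = rep(sig_ids, 1L),
                  gene_id = g, mechanism = "loop",
                  via_bin_id = ends[side], loop_id = loops$loop_id[li],
                  promoter_id = promoters$promoter_id[pi],
                  promoter_source = promoters$source[pi],
                  distance = gene_tss_dist(pos, g, pi))
            }
          }
        }
      }
    }
    # promoter-overlap mechanism
    if (nrow(promoters) > 0L) {
      inside <- which(promoters$chrom == chrom & promoters$start <= pos &
                      promoters$end >= pos)
      for (pi in inside) {
        for (g in .uncollapse(promoters$gene_ids[pi])) {
          add(variant_id = v, signal_id = rep(sig_ids, 1L), gene_id = g,
              mechanism = "promoter_overlap", via_bin_id = NA_integer_,
              loop_id = NA_character_,
              promoter_id = promoters$promoter_id[pi],
              promoter_source = promoters$source[pi], distance = 0L)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(variant_id = character(0), signal_id = integer(0),
                      gene_id = character(0), mechanism = character(0),
                      via_bin_id = integer(0), loop_id = character(0),
                      promoter_id = character(0),
                      promoter_source = character(0), distance = integer(0))
  } else {
    out <- unique(do.call(rbind, rows))
    rownames(out) <- NULL
  }
  out$distance_class <- classify_distance(out$distance, out$mechanism)
  out$alt_promoter <- rep(FALSE, nrow(out))
  out
}

#' Classify variant-to-promoter distances
#'
#' Classes: `overlap` (0), `lt_100kb` (0, 100 kb), `kb100_to_1Mb`
#' \[100 kb, 1 Mb\] (both boundaries inclusive), `gt_1Mb` (strictly beyond
#' 1 Mb). Promoter-overlap links are always `overlap`.
#'
#' @param distance Distances in bases.
#' @param mechanism Optional mechanism vector (`promoter_overlap` forces
#'   `overlap`).
#' @return Character vector of classes.
#' @export
classify_distance <- function(distance, mechanism = NULL) {
  cls <- ifelse(is.na(distance), NA_character_,
         ifelse(distance == 0, "overlap",
         ifelse(distance < 1e5, "lt_100kb",
         ifelse(distance <= 1e6, "kb100_to_1Mb", "gt_1Mb"))))
  if (!is.null(mechanism)) cls[mechanism == "promoter_overlap"] <- "overlap"
  cls
}

#' Flag loops to an alternative promoter of the same gene
#'
#' A loop link is flagged when the same (variant, gene) pair also carries a
#' promoter-overlap link and the loop's target promoter lies at least
#' `min_separation` bases (edge-to-edge) from the overlapped promoter.
#'
#' @param links Link table from [link_variants_to_genes()].
#' @param promoters Assigned promoter table (for interval lookup).
#' @param min_separation Minimum edge-to-edge separation in bases
#'   (default 10 kb).
#' @return `links` with `alt_promoter` updated.
#' @export
flag_alternative_promoter <- function(links, promoters,
                                      min_separation = 10000L) {
  if (nrow(links) == 0L) return(links)
  pidx <- match(links$promoter_id, promoters$promoter_id)
  ov <- links$mechanism == "promoter_overlap"
  for (i in which(links$mechanism == "loop")) {
    j <- which(ov & links$variant_id == links$variant_id[i] &
               links$gene_id == links$gene_id[i])
    if (length(j) == 0L) next
    a <- pidx[i]
    for (jj in j) {
      b <- pidx[jj]
      if (is.na(a) || is.na(b)) next
      if (promoters$chrom[a] != promoters$chrom[b]) next
      gap <- max(promoters$start[a], promoters$start[b]) -
             min(promoters$end[a], promoters$end[b])
      if (gap >= min_separation) { links$alt_promoter[i] <- TRUE; break }
    }
  }
  links
}

#' Per-signal summary of nominations
#'
#' @param links Link table.
#' @param signals Optional signal table so signals with zero nominations are
#'   listed.
#' @return data.frame with one row per signal (`signal_id`, `n_genes`,
#'   `n_variants`, one presence flag per distance class); attributes
#'   `median_genes_per_signal` and `n_signals_zero`.
#' @export
summarize_signals <- function(links, signals = NULL) {
  sids <- if (!is.null(signals)) unique(signals$signal_id)
          else sort(unique(links$signal_id))
  cls <- c("overlap", "lt_100kb", "kb100_to_1Mb", "gt_1Mb")
  out <- data.frame(signal_id = sids, n_genes = 0L, n_variants = 0L)
  for (cl in cls) out[[paste0("has_", cl)]] <- FALSE
  for (i in seq_along(sids)) {
    lk <- links[links$signal_id == sids[i], , drop = FALSE]
    out$n_genes[i] <- length(unique(lk$gene_id))
    out$n_variants[i] <- length(unique(lk$variant_id))
    for (cl in cls)
      out[[paste0("has_", cl)]][i] <- cl %in% lk$distance_class
  }
  attr(out, "median_genes_per_signal") <- stats::median(out$n_genes)
  attr(out, "n_signals_zero") <- sum(out$n_genes == 0L)
  out
}

#' Write nominated links as a WashU long-range text track
#'
#' @param links Link table (loop mechanism rows are emitted).
#' @param assignments Variant bin assignments (for variant-side coordinates).
#' @param promoters Assigned promoter table (for target coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_longrange <- function(links, assignments, promoters, path) {
  lk <- links[links$mechanism == "loop", , drop = FALSE]
  ai <- match(lk$variant_id, assignments$variant_id)
  pi <- match(lk$promoter_id, promoters$promoter_id)
  out <- data.frame(
    chrom = assignments$chrom[ai],
    start = assignments$pos[ai] - 1L,
    end = assignments$pos[ai],
    target = sprintf("%s:%d-%d,%s", promoters$chrom[pi],
                     promoters$start[pi] - 1L, promoters$end[pi], "5"))
  write_tsv(out, path, col.names = FALSE)
}
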