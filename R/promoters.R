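# Promoter construction under three definitions (melanocyte ChromHMM,
# melanoma ChromHMM, global TSS +/- 2.5 kb) and gene assignment.
#
# Promoter intervals are 1-based closed throughout this module; BED input is
# converted on read.

#' ChromHMM state vocabulary registry
#'
#' Promoter- and enhancer-state labels per cell context. Melanocyte labels
#' come from the Roadmap primary, auxiliary, and imputed state models;
#' melanoma labels from engineered melanoma cell-model segmentations. Any
#' region annotated as enhancer or promoter is considered regulatory.
#'
#' @return Nested list: `$melanocyte` / `$melanoma`, each with `$promoter`
#'   and `$enhancer` character vectors of state labels.
#' @export
chromhmm_vocab <- function() {
  list(
    melanocyte = list(
      promoter = c("PromU", "PromD1", "PromD2", "TssA", "PromP", "PromBiv",
                   "Tx_Reg"),
      enhancer = c(
        # primary model
        "Enh", "EnhG", "EnhBiv",
        # auxiliary model
        "EnhG1", "EnhG2", "EnhA1", "EnhA2", "EnhWk",
        # imputed model
        "TxEnh5", "TxEnh3", "TxEnhW", "EnhAF", "EnhW1", "EnhW2", "EnhAc")
    ),
    melanoma = list(
      promoter = c("1_TssA", "2_PromWkD", "3_TssWkP"),
      enhancer = c("4_EnhA", "5_EnhM", "6_EnhW", "7_TxEnhM", "7_TxEnhW",
                   "9_TxWkEnhW")
    )
  )
}

# Regulatory (promoter union enhancer) labels for one context.
.regulatory_labels <- function(context, vocab = chromhmm_vocab()) {
  v <- vocab[[context]]
  unique(c(v$promoter, v$enhancer))
}

#' Build merged ChromHMM promoter intervals for one cell context
#'
#' Keeps segments whose state label is in the context's promoter-state list,
#' takes the union across samples (a region is promoter if promoter-annotated
#' in *either* culture), and merges overlapping or book-ended intervals into
#' maximal regions. Segments with labels outside the registry are ignored
#' but counted.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end` (1-based
#'   closed), `state_label`, and optionally `cell_context` / `sample_id`.
#' @param context `"melanocyte"` or `"melanoma"`.
#' @param vocab Vocabulary registry (see [chromhmm_vocab()]).
#' @return data.frame of merged promoter intervals with columns `chrom`,
#'   `start`, `end`, `source`; attribute `n_unknown_labels` counts ignored
#'   segments.
#' @export
build_chromhmm_promoters <- function(segments, context,
                                     vocab = chromhmm_vocab()) {
  stopifnot(context %in% names(vocab))
  if ("cell_context" %in% names(segments))
    segments <- segments[segments$cell_context == context, , drop = FALSE]
  known <- unique(c(vocab[[context]]$promoter, vocab[[context]]$enhancer))
  n_unknown <- sum(!segments$state_label %in% known)
  keep <- segments[segments$state_label %in% vocab[[context]]$promoter, ,
                   drop = FALSE]
  if (nrow(keep) == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), source = character(0))
    attr(out, "n_unknown_labels") <- n_unknown
    return(out)
  }
  gr <- GenomicRanges::GRanges(keep$chrom, IRanges::IRanges(keep$start,
                                                            keep$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                    start = BiocGenerics::start(merged),
                    end = BiocGenerics::end(merged),
                    source = context, stringsAsFactors = FALSE)
  attr(out, "n_unknown_labels") <- n_unknown
  out
}

#' Build global promoters as TSS +/- flank windows
#'
#' One region per protein-coding transcript, `[tss - flank, tss + flank]`
#' (1-based closed), clamped at chromosome bounds when lengths are known.
#' The TSS is strand-aware (transcript start on `+`, transcript end on `-`).
#'
#' @param transcripts Transcript table (see [load_transcripts()]): columns
#'   `gene_id`, `transcript_id`, `chrom`, `strand`, `tss`, `biotype`.
#' @param flank Half-width in bases (default 2500).
#' @param chrom_lengths Optional named vector of chromosome lengths used for
#'   clamping.
#' @return PromoterRegion data.frame: `chrom`, `start`, `end`,
#'   `source = "global"`, `gene_ids`, `transcript_ids`.
#' @export
build_global_promoters <- function(transcripts, flank = 2500L,
                                   chrom_lengths = NULL) {
  tx <- transcripts[transcripts$biotype == "protein_coding", , drop = FALSE]
  if (nrow(tx) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), source = character(0),
                      gene_ids = character(0), transcript_ids = character(0)))
  start <- pmax(tx$tss - flank, 1L)
  end <- tx$tss + flank
  if (!is.null(chrom_lengths)) {
    lim <- unname(chrom_lengths[tx$chrom])
    end <- ifelse(is.na(lim), end, pmin(end, lim))
  }
  data.frame(chrom = tx$chrom, start = as.integer(start),
             end = as.integer(end), source = "global",
             gene_ids = tx$gene_id, transcript_ids = tx$transcript_id,
             stringsAsFactors = FALSE)
}

#' Assign genes to promoter intervals
#'
#' A gene is assigned to a promoter iff the promoter interval overlaps
#' `[tss - reach, tss + reach]` for any of the gene's transcripts.
#' ChromHMM-derived promoters may assign to both protein-coding and
#' non-coding transcripts. Promoters with an empty gene set are flagged
#' unassigned (and dropped from nomination downstream).
#'
#' @param promoters data.frame of intervals (`chrom`, `start`, `end`,
#'   `source`).
#' @param transcripts Transcript table.
#' @param reach Half-width of the TSS window in bases (default 2500).
#' @return `promoters` with columns `promoter_id`, `gene_ids`,
#'   `transcript_ids` (comma strings) and `assigned` added.
#' @export
assign_genes_to_promoters <- function(promoters, transcripts, reach = 2500L) {
  n <- nrow(promoters)
  gene_ids <- character(n); tx_ids <- character(n)
  if (n > 0L && nrow(transcripts) > 0L) {
    pr <- GenomicRanges::GRanges(promoters$chrom,
                                 IRanges::IRanges(promoters$start,
                                                  promoters$end))
    tw <- GenomicRanges::GRanges(
      transcripts$chrom,
      IRanges::IRanges(pmax(transcripts$tss - reach, 1L),
                       transcripts$tss + reach))
    hits <- GenomicRanges::findOverlaps(pr, tw)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (i in seq_len(n)) {
      j <- sh[qh == i]
      gene_ids[i] <- .collapse(transcripts$gene_id[j])
      tx_ids[i] <- .collapse(transcripts$transcript_id[j])
    }
  } else {
    gene_ids[] <- NA_character_; tx_ids[] <- NA_character_
  }
  out <- promoters
  out$promoter_id <- if (n > 0L) paste0("P", seq_len(n)) else character(0)
  out$gene_ids <- gene_ids
  out$transcript_ids <- tx_ids
  out$assigned <- !is.na(gene_ids)
  out
}

#' Load transcript models from a GTF file
#'
#' Imports GENCODE-style transcript records and computes the strand-aware
#' TSS (interval start on `+`, interval end on `-`).
#'
#' @param path GTF file path.
#' @return data.frame with columns `gene_id`, `gene_name`, `transcript_id`,
#'   `chrom`, `strand`, `start`, `end`, `tss`, `biotype`.
#' @export
load_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "transcript"]
  md <- S4Vectors::mcols(gr)
  biotype <- if ("transcript_biotype" %in% names(md)) md$transcript_biotype
             else if ("gene_biotype" %in% names(md)) md$gene_biotype
             else if ("transcript_type" %in% names(md)) md$transcript_type
             else rep(NA_character_, length(gr))
  gene_name <- if ("gene_name" %in% names(md)) md$gene_name else md$gene_id
  strand <- as.character(BiocGenerics::strand(gr))
  start <- BiocGenerics::start(gr); end <- BiocGenerics::end(gr)
  data.frame(gene_id = md$gene_id, gene_name = gene_name,
             transcript_id = md$transcript_id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = strand, start = start, end = end,
             tss = ifelse(strand == "-", end, start),
             biotype = biotype, stringsAsFactors = FALSE)
}

#' Read a BED file of ChromHMM segments or peaks
#'
#' BED is 0-based half-open on disk; intervals are returned 1-based closed.
#' For BED4 the name column is interpreted as the ChromHMM state label.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `state_label`.
#' @export
read_bed <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
  out <- data.frame(chrom = as.character(x[[1]]), start = x[[2]] + 1L,
                    end = x[[3]], stringsAsFactors = FALSE)
  if (ncol(x) >= 4L) out$state_label <- as.character(x[[4]])
  out
}

#' Write intervals to BED (3 or 4 columns)
#'
#' @param x data.frame with 1-based closed `chrom`, `start`, `end` and
#'   optionally `state_label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  out <- data.frame(chrom = x$chrom, start = x$start - 1L, end = x$end)
  if ("state_label" %in% names(x)) out$name <- x$state_label
  write_tsv(out, path, col.names = FALSE)
}
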