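# Restriction-fragment map, CHiCAGO-style rmap/baitmap, k-fragment binning,
# and variant-to-bin assignment.
#
# Coordinate conventions: fragments and bins are held internally as 0-based
# half-open intervals; rmap/baitmap files are emitted 1-based inclusive
# (CHiCAGO dialect); variant positions are ingested 1-based.

#' Dual-enzyme restriction motifs
#'
#' The default digestion model is the Arima-style dual-enzyme cocktail:
#' `^GATC` (cut before the G, offset 0) and `G^ANTC` (cut after the G,
#' offset 1), where `N` matches any base. Offsets are exposed so other
#' enzyme conventions can be configured.
#'
#' @return A data.frame with columns `motif` and `cut_offset`.
#' @export
restriction_motifs <- function() {
  data.frame(motif = c("GATC", "GANTC"),
             cut_offset = c(0L, 1L),
             stringsAsFactors = FALSE)
}

#' In-silico restriction digestion of one sequence
#'
#' Scans the sequence for every motif occurrence (IUPAC codes in the motif
#' are honoured; `N` in the *sequence* never matches), places a cut at
#' `match_start + cut_offset`, deduplicates and sorts the cuts, and returns
#' the fragments between consecutive cuts plus the sequence ends. Cuts at
#' position 0 or at the sequence end would create empty fragments and are
#' dropped. Fragment intervals are 0-based half-open and tile the sequence
#' exactly.
#'
#' @param sequence A `DNAString` or character scalar over A/C/G/T/N.
#' @param chrom Chromosome name recorded on each fragment.
#' @param motifs Motif table as from [restriction_motifs()].
#' @param first_frag_id Id assigned to the first fragment (ids ascend).
#' @return data.frame with columns `frag_id`, `chrom`, `start`, `end`.
#' @examples
#' digest("AAAGATCTTT") # cut at 3 -> fragments [0,3) and [3,10)
#' @export
digest <- function(sequence, chrom = "chr1", motifs = restriction_motifs(),
                   first_frag_id = 1L) {
  seq <- if (methods::is(sequence, "DNAString")) sequence
         else Biostrings::DNAString(toupper(as.character(sequence)))
  len <- length(seq)
  empty <- data.frame(frag_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (len == 0L) return(empty)
  cuts <- integer(0)
  for (i in seq_len(nrow(motifs))) {
    hits <- Biostrings::matchPattern(motifs$motif[i], seq, fixed = "subject")
    if (length(hits) > 0L) {
      # N (or any ambiguity) in the *sequence* never matches a motif
      clean <- !grepl("[^ACGT]", as.character(hits))
      if (any(clean))
        cuts <- c(cuts, BiocGenerics::start(hits)[clean] - 1L +
                    motifs$cut_offset[i])
    }
  }
  cuts <- sort(unique(cuts))
  cuts <- cuts[cuts > 0L & cuts < len]
  bounds <- c(0L, cuts, len)
  n <- length(bounds) - 1L
  data.frame(frag_id = seq.int(first_frag_id, length.out = n),
             chrom = rep(chrom, n),
             start = bounds[-length(bounds)],
             end = bounds[-1L],
             stringsAsFactors = FALSE)
}

#' Digest a whole genome
#'
#' Applies [digest()] per chromosome with globally ascending fragment ids.
#'
#' @param sequences A named `DNAStringSet` or named character vector.
#' @param motifs Motif table as from [restriction_motifs()].
#' @return data.frame of fragments across all chromosomes.
#' @export
digest_genome <- function(sequences, motifs = restriction_motifs()) {
  nms <- names(sequences)
  stopifnot(!is.null(nms), !anyDuplicated(nms))
  out <- vector("list", length(sequences))
  next_id <- 1L
  for (i in seq_along(sequences)) {
    f <- digest(sequences[[i]], chrom = nms[i], motifs = motifs,
                first_frag_id = next_id)
    next_id <- next_id + nrow(f)
    out[[i]] <- f
  }
  do.call(rbind, out)
}

#' Group consecutive restriction fragments into bins
#'
#' Greedy grouping of `k` consecutive fragments starting from each
#' chromosome's first fragment; a trailing partial bin is retained; bins
#' never span chromosomes. `k = 1` reproduces the fragment map. The bin
#' interval is the hull of its members.
#'
#' @param fragments Fragment table from [digest_genome()].
#' @param k Fragments per bin (the paper-style 4F analysis uses 4).
#' @return data.frame with columns `bin_id`, `chrom`, `start`, `end`,
#'   `first_frag_id`, `last_frag_id`, `n_frags`, `baited`.
#' @export
make_bins <- function(fragments, k = 4L) {
  stopifnot(k >= 1L)
  if (nrow(fragments) == 0L) {
    return(data.frame(bin_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      first_frag_id = integer(0), last_frag_id = integer(0),
                      n_frags = integer(0), baited = logical(0)))
  }
  per_chrom <- split(fragments, factor(fragments$chrom,
                                       levels = unique(fragments$chrom)))
  out <- vector("list", length(per_chrom))
  next_bin <- 1L
  for (ci in seq_along(per_chrom)) {
    fr <- per_chrom[[ci]]
    fr <- fr[order(fr$frag_id), , drop = FALSE]
    grp <- (seq_len(nrow(fr)) - 1L) %/% as.integer(k)
    idx <- split(seq_len(nrow(fr)), grp)
    b <- data.frame(
      bin_id = seq.int(next_bin, length.out = length(idx)),
      chrom = fr$chrom[1L],
      start = vapply(idx, function(i) min(fr$start[i]), integer(1)),
      end = vapply(idx, function(i) max(fr$end[i]), integer(1)),
      first_frag_id = vapply(idx, function(i) min(fr$frag_id[i]), integer(1)),
      last_frag_id = vapply(idx, function(i) max(fr$frag_id[i]), integer(1)),
      n_frags = lengths(idx),
      baited = FALSE,
      stringsAsFactors = FALSE)
    rownames(b) <- NULL
    next_bin <- next_bin + nrow(b)
    out[[ci]] <- b
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Bin id holding a given fragment id (NA if none).
.bin_of_fragment <- function(bins, frag_id) {
  hit <- bins$first_frag_id <= frag_id & bins$last_frag_id >= frag_id
  if (!any(hit)) return(NA_integer_)
  bins$bin_id[which(hit)[1L]]
}

#' Mark bins as baited by target regions
#'
#' A bin is baited iff any of its member fragments overlaps any target
#' (association) region. Target regions are 1-based inclusive intervals.
#'
#' @param bins Bin table from [make_bins()].
#' @param fragments Fragment table the bins were built from.
#' @param target_regions data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @return `bins` with the `baited` flag updated.
#' @export
build_baitmap <- function(bins, fragments, target_regions) {
  bins$baited <- FALSE
  if (nrow(target_regions) == 0L) return(bins)
  stopifnot(all(c("chrom", "start", "end") %in% names(target_regions)))
  baited_frags <- rep(FALSE, nrow(fragments))
  for (chr in unique(target_regions$chrom)) {
    tr <- target_regions[target_regions$chrom == chr, , drop = FALSE]
    fi <- which(fragments$chrom == chr)
    if (length(fi) == 0L) next
    fr_ir <- .ir_from_0based(fragments$start[fi], fragments$end[fi])
    tr_ir <- IRanges::IRanges(tr$start, tr$end)
    ov <- IRanges::overlapsAny(fr_ir, tr_ir)
    baited_frags[fi] <- ov
  }
  baited_ids <- fragments$frag_id[baited_frags]
  bins$baited <- vapply(seq_len(nrow(bins)), function(i) {
    any(baited_ids >= bins$first_frag_id[i] & baited_ids <= bins$last_frag_id[i])
  }, logical(1))
  bins
}

#' Assign each variant to its primary bin and window-adjacent bins
#'
#' The primary bin is the bin whose hull contains the variant position. A
#' window of `+/- window` bases (inclusive at both ends) is drawn around the
#' variant; any *immediately neighbouring* restriction fragment that overlaps
#' this window contributes its bin as an adjacent bin, unless that bin is the
#' primary bin itself. Downstream, interactions are read from the primary
#' and all adjacent bins.
#'
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based).
#' @param fragments Fragment table.
#' @param bins Bin table.
#' @param window Half-width of the adjacency window in bases (default 500).
#' @return data.frame with columns `variant_id`, `chrom`, `pos`, `frag_id`,
#'   `primary_bin_id`, `adjacent_bin_ids` (comma string, `NA` if none).
#' @export
assign_variant_bins <- function(variants, fragments, bins, window = 500L) {
  n <- nrow(variants)
  frag_id <- integer(n); primary <- integer(n); adj <- character(n)
  for (i in seq_len(n)) {
    chr <- variants$chrom[i]; pos <- variants$pos[i]
    p0 <- pos - 1L
    fi <- which(fragments$chrom == chr & fragments$start <= p0 &
                fragments$end > p0)
    if (length(fi) == 0L)
      stop(sprintf("variant %s at %s:%d lies outside all fragments",
                   variants$variant_id[i], chr, pos))
    fi <- fi[1L]
    frag_id[i] <- fragments$frag_id[fi]
    primary[i] <- .bin_of_fragment(bins, frag_id[i])
    # immediate fragment neighbours overlapping [pos - window, pos + window]
    win_lo <- pos - window; win_hi <- pos + window
    nb_bins <- integer(0)
    for (nb in c(frag_id[i] - 1L, frag_id[i] + 1L)) {
      j <- which(fragments$frag_id == nb)
      if (length(j) == 0L || fragments$chrom[j] != chr) next
      f1 <- fragments$start[j] + 1L; f2 <- fragments$end[j] # 1-based closed
      if (f1 <= win_hi && f2 >= win_lo) {
        b <- .bin_of_fragment(bins, nb)
        if (!is.na(b) && b != primary[i]) nb_bins <- c(nb_bins, b)
      }
    }
    adj[i] <- if (length(nb_bins) == 0L) NA_character_ else
      paste(sort(unique(nb_bins)), collapse = ",")
  }
  data.frame(variant_id = variants$variant_id, chrom = variants$chrom,
             pos = variants$pos, frag_id = frag_id,
             primary_bin_id = primary, adjacent_bin_ids = adj,
             stringsAsFactors = FALSE)
}

#' Baiting coverage report for a set of assigned variants
#'
#' @param assignments Output of [assign_variant_bins()].
#' @param bins Bin table with `baited` flags set.
#' @return list with `n`, `frac_baited` (variant's primary bin baited) and
#'   `frac_baited_or_adjacent` (primary or any adjacent bin baited).
#' @export
bait_coverage <- function(assignments, bins) {
  baited <- bins$bin_id[bins$baited]
  in_bait <- assignments$primary_bin_id %in% baited
  adj_bait <- vapply(assignments$adjacent_bin_ids, function(s) {
    any(as.integer(.uncollapse(s)) %in% baited)
  }, logical(1), USE.NAMES = FALSE)
  list(n = nrow(assignments),
       frac_baited = mean(in_bait),
       frac_baited_or_adjacent = mean(in_bait | adj_bait))
}

#' Read and write CHiCAGO-style rmap / baitmap files
#'
#' rmap: 4 tab-separated columns (chrom, start, end, id), 1-based inclusive,
#' no header. baitmap: rmap plus an annotation column, baited units only.
#' Both round-trip bit-exactly (read then write reproduces the file).
#'
#' @param units Fragment or bin table (internally 0-based half-open).
#' @param path File path.
#' @param annotation Annotation strings for the baitmap column.
#' @return Readers return the table converted back to internal 0-based
#'   half-open coordinates; writers return `path` invisibly.
#' @export
write_rmap <- function(units, path) {
  id <- if ("bin_id" %in% names(units)) units$bin_id else units$frag_id
  write_tsv(data.frame(chrom = units$chrom, start = units$start + 1L,
                       end = units$end, id = id), path, col.names = FALSE)
}

#' @rdname write_rmap
#' @export
read_rmap <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
  names(x) <- c("chrom", "start", "end", "frag_id")
  x$start <- x$start - 1L
  x[, c("frag_id", "chrom", "start", "end")]
}

#' @rdname write_rmap
#' @export
write_baitmap <- function(units, path, annotation = NULL) {
  stopifnot("baited" %in% names(units))
  b <- units[units$baited, , drop = FALSE]
  if (is.null(annotation)) annotation <- rep("bait", nrow(b))
  write_tsv(data.frame(chrom = b$chrom, start = b$start + 1L, end = b$end,
                       id = b$bin_id, annotation = annotation),
            path, col.names = FALSE)
}

#' @rdname write_rmap
#' @export
read_baitmap <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
  names(x) <- c("chrom", "start", "end", "bin_id", "annotation")
  x$start <- x$start - 1L
  x[, c("bin_id", "chrom", "start", "end", "annotation")]
}

#' CHiCAGO run parameters recorded as metadata
#'
#' Interaction calling itself is out of scope (CHiCAGO output is consumed),
#' but the caller settings used for one-fragment and four-fragment analyses
#' are carried as configuration metadata for the run manifest.
#'
#' @return Named list with `one_fragment` and `four_fragment` parameter sets
#'   (minFragLen, maxFragLen, binsize, maxLBrownEst, removeAdjacent).
#' @export
chicago_run_parameters <- function() {
  list(
    one_fragment = list(minFragLen = 75, maxFragLen = 1200,
                        binsize = 2000, maxLBrownEst = 150000,
                        removeAdjacent = TRUE),
    four_fragment = list(minFragLen = 150, maxFragLen = 5000,
                         binsize = 8000, maxLBrownEst = 600000,
                         removeAdjacent = FALSE)
  )
}
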