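# Shared fixture builders: tiny hand-laid genomic worlds, built in code.

# Fragment table from per-fragment lengths (one chromosome).
toy_fragments <- function(lengths, chrom = "chr1", first_id = 1L) {
  ends <- cumsum(lengths)
  data.frame(frag_id = seq.int(first_id, length.out = length(lengths)),
             chrom = chrom, start = c(0L, ends[-length(ends)]),
             end = as.integer(ends), stringsAsFactors = FALSE)
}

# Minimal transcript table.
toy_transcripts <- function(tss, strand = "+", chrom = "chr1",
                            biotype = "protein_coding",
                            gene_id = sprintf("G%d", seq_along(tss))) {
  n <- length(tss)
  strand <- rep_len(strand, n); biotype <- rep_len(biotype, n)
  start <- ifelse(strand == "-", tss - 1500L, tss)
  end <- ifelse(strand == "-", tss, tss + 1500L)
  data.frame(gene_id = gene_id, gene_name = gene_id,
             transcript_id = sprintf("T%d", seq_len(n)), chrom = chrom,
             strand = strand, start = as.integer(start),
             end = as.integer(end), tss = as.integer(tss),
             biotype = biotype, stringsAsFactors = FALSE)
}

# Assigned-promoter table from explicit intervals and gene sets.
toy_promoters <- function(start, end, gene_ids, chrom = "chr1",
                          source = "global",
                          transcript_ids = gene_ids) {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(end), source = rep_len(source, n),
             promoter_id = sprintf("P%d", seq_len(n)),
             gene_ids = gene_ids, transcript_ids = transcript_ids,
             assigned = !is.na(gene_ids), stringsAsFactors = FALSE)
}

# Independent brute-force digestion oracle: regex scan for the two motifs.
oracle_digest <- function(seq_str) {
  len <- nchar(seq_str)
  if (len == 0L) return(integer(0))
  cuts <- integer(0)
  g1 <- gregexpr("(?=GATC)", seq_str, perl = TRUE)[[1]]
  if (g1[1] != -1) cuts <- c(cuts, as.integer(g1) - 1L + 0L)
  g2 <- gregexpr("(?=GA[ACGT]TC)", seq_str, perl = TRUE)[[1]]
  if (g2[1] != -1) cuts <- c(cuts, as.integer(g2) - 1L + 1L)
  cuts <- sort(unique(cuts))
  cuts[cuts > 0L & cuts < len]
}

# Random A/C/G/T string.
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Brute-force linking oracle: exhaustive (variant, loop-end, promoter) and
# (variant, promoter) enumeration; returns "variant gene mechanism" keys.
oracle_links <- function(asg, loops, prom, b) {
  want <- character(0)
  for (i in seq_len(nrow(asg))) {
    vb <- c(asg$primary_bin_id[i],
            suppressWarnings(as.integer(strsplit(
              ifelse(is.na(asg$adjacent_bin_ids[i]), "",
                     asg$adjacent_bin_ids[i]), ",")[[1]])))
    vb <- vb[!is.na(vb)]
    for (li in seq_len(nrow(loops))) {
      for (dir in 1:2) {
        e1 <- if (dir == 1) loops$bait_bin_id[li] else loops$otherend_bin_id[li]
        e2 <- if (dir == 1) loops$otherend_bin_id[li] else loops$bait_bin_id[li]
        if (!(e1 %in% vb)) next
        bi <- match(e2, b$bin_id)
        for (pi in seq_len(nrow(prom))) {
          if (!prom$assigned[pi]) next
          if (prom$chrom[pi] == b$chrom[bi] &&
              prom$start[pi] <= b$end[bi] && prom$end[pi] >= b$start[bi] + 1L)
            want <- c(want, paste(asg$variant_id[i],
                                  strsplit(prom$gene_ids[pi], ",")[[1]],
                                  "loop"))
        }
      }
    }
    for (pi in seq_len(nrow(prom))) {
      if (prom$assigned[pi] && prom$chrom[pi] == asg$chrom[i] &&
          prom$start[pi] <= asg$pos[i] && prom$end[pi] >= asg$pos[i])
        want <- c(want, paste(asg$variant_id[i],
                              strsplit(prom$gene_ids[pi], ",")[[1]],
                              "promoter_overlap"))
    }
  }
  unique(want)
}

# A fully valid evidence record with all flags off, for scoring tests.
blank_record <- function(...) {
  rec <- data.frame(signal_id = 1L, gene_id = "G1", linked = FALSE,
                    var_regulatory = FALSE, var_mpra_sig = FALSE,
                    var_marginal_eqtl = FALSE, eqtl_or_twas = FALSE,
                    meqtl_or_mwas = FALSE, driver_melanoma = FALSE,
                    driver_pancancer = FALSE, stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

# Cached seed-42 universes + pipeline runs shared by pipeline and acceptance
# tests (generated once per test session).
.u_cache <- new.env(parent = emptyenv())
demo_run <- function(noise = 0) {
  key <- paste0("run_", noise)
  if (!is.null(.u_cache[[key]])) return(.u_cache[[key]])
  cfg <- synthetic_config(seed = 42L, loop_noise_rate = noise)
  dir <- file.path(tempdir(), paste0("universe_", noise))
  demo <- make_demo(seed = 42L, dir = dir, config = cfg)
  out <- file.path(tempdir(), paste0("out_", noise))
  res <- run_pipeline(pipeline_config(dir, out))
  .u_cache[[key]] <- list(demo = demo, res = res, dir = dir, out = out)
  .u_cache[[key]]
}
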