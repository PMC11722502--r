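# Loop loading, variant-gene linking, distance classes, alternative
# promoters, per-signal summaries.

# A hand-laid mini universe: 10 fragments of 2000 b, k = 2 -> 5 bins of
# 4000 b; gene G1's TSS at 17,000 (bin 5), variant in bin 1.
mini_universe <- function() {
  fr <- toy_fragments(rep(2000L, 10))
  b <- make_bins(fr, k = 2)
  tx <- toy_transcripts(tss = 17000L, gene_id = "G1")
  prom <- toy_promoters(start = 14500L, end = 19500L, gene_ids = "G1",
                        transcript_ids = "T1")
  ccvs <- data.frame(variant_id = "v1", signal_id = 1L)
  asg <- assign_variant_bins(data.frame(variant_id = "v1", chrom = "chr1",
                                        pos = 1000L), fr, b)
  list(fr = fr, b = b, tx = tx, prom = prom, ccvs = ccvs, asg = asg)
}

test_that("load_interactions applies the inclusive score >= 5 cutoff", {
  u <- mini_universe()
  f <- tempfile()
  write_tsv(data.frame(
    bait_chr = "chr1", bait_start = c(1L, 1L, 1L), bait_end = 4000L,
    bait_name = "bin1",
    otherEnd_chr = c("chr1", "chr1", "chr2"),
    otherEnd_start = 16001L, otherEnd_end = 20000L, otherEnd_name = "bin5",
    N_reads = 10L, score = c(5.0, 4.99, 8)), f)
  loops <- load_interactions(f, u$b)
  expect_equal(nrow(loops), 1L)   # 4.99 dropped, trans dropped
  expect_equal(loops$score, 5.0)
  expect_equal(attr(loops, "n_trans"), 1L)
  expect_equal(loops$bait_bin_id, 1L)
  expect_equal(loops$otherend_bin_id, 5L)
})

test_that("ibed writer and loader round-trip loop bins and scores", {
  u <- mini_universe()
  loops <- data.frame(loop_id = "L1", bait_bin_id = 1L, otherend_bin_id = 5L,
                      score = 6.5)
  f <- tempfile()
  write_interactions_ibed(loops, u$b, f)
  back <- load_interactions(f, u$b)
  expect_equal(back$bait_bin_id, 1L)
  expect_equal(back$otherend_bin_id, 5L)
  expect_equal(back$score, 6.5)
})

test_that("loop and promoter-overlap mechanisms nominate genes", {
  u <- mini_universe()
  loops <- data.frame(loop_id = "L1", bait_bin_id = 1L, otherend_bin_id = 5L,
                      score = 6)
  lk <- link_variants_to_genes(u$asg, u$ccvs, loops, u$prom, u$b, u$tx)
  expect_equal(nrow(lk), 1L)
  expect_equal(lk$gene_id, "G1")
  expect_equal(lk$mechanism, "loop")
  expect_equal(lk$distance, 16000L)
  expect_equal(lk$distance_class, "lt_100kb")

  # symmetric interaction use: swapping ends yields the same link
  swapped <- data.frame(loop_id = "L1", bait_bin_id = 5L,
                        otherend_bin_id = 1L, score = 6)
  lk2 <- link_variants_to_genes(u$asg, u$ccvs, swapped, u$prom, u$b, u$tx)
  expect_equal(lk2$gene_id, "G1")
  expect_equal(lk2$mechanism, "loop")

  # variant inside the promoter, no loops -> promoter_overlap only
  asg_in <- assign_variant_bins(data.frame(variant_id = "v1", chrom = "chr1",
                                           pos = 15000L), u$fr, u$b)
  lk3 <- link_variants_to_genes(asg_in, u$ccvs, loops[0, ], u$prom, u$b, u$tx)
  expect_equal(lk3$mechanism, "promoter_overlap")
  expect_equal(lk3$distance, 0L)
  expect_equal(lk3$distance_class, "overlap")

  # no loop and no promoter -> zero links
  lk4 <- link_variants_to_genes(u$asg, u$ccvs, loops[0, ], u$prom, u$b, u$tx)
  expect_equal(nrow(lk4), 0L)
})

test_that("linking equals a brute-force triple loop on random universes", {
  set.seed(47)
  for (rep in 1:15) {
    nf <- sample(8:40, 1)
    fr <- toy_fragments(sample(500:2000, nf, replace = TRUE))
    b <- make_bins(fr, k = sample(1:4, 1))
    L <- fr$end[nf]
    tss <- sort(sample(seq(3000L, L - 3000L), sample(1:3, 1)))
    tx <- toy_transcripts(tss = tss)
    prom <- assign_genes_to_promoters(
      build_global_promoters(tx)[, c("chrom", "start", "end", "source")], tx)
    npos <- sample(seq_len(L), sample(2:5, 1))
    ccvs <- data.frame(variant_id = paste0("v", seq_along(npos)),
                       signal_id = 1L)
    asg <- assign_variant_bins(data.frame(variant_id = ccvs$variant_id,
                                          chrom = "chr1", pos = npos), fr, b)
    nl <- sample(1:4, 1)
    loops <- data.frame(loop_id = paste0("L", 1:nl),
                        bait_bin_id = sample(b$bin_id, nl, TRUE),
                        otherend_bin_id = sample(b$bin_id, nl, TRUE),
                        score = runif(nl, 5, 12))
    got <- link_variants_to_genes(asg, ccvs, loops, prom, b, tx)
    # oracle: exhaustive (variant, loop-end, promoter) and (variant, promoter)
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
            if (prom$start[pi] <= b$end[bi] && prom$end[pi] >= b$start[bi] + 1L)
              want <- c(want, paste(asg$variant_id[i],
                                    strsplit(prom$gene_ids[pi], ",")[[1]],
                                    "loop"))
          }
        }
      }
      for (pi in seq_len(nrow(prom))) {
        if (prom$assigned[pi] && prom$start[pi] <= asg$pos[i] &&
            prom$end[pi] >= asg$pos[i])
          want <- c(want, paste(asg$variant_id[i],
                                strsplit(prom$gene_ids[pi], ",")[[1]],
                                "promoter_overlap"))
      }
    }
    got_keys <- paste(got$variant_id, got$gene_id, got$mechanism)
    expect_setequal(unique(got_keys), unique(want))
  }
})

test_that("distance classes use the stated boundaries", {
  expect_equal(classify_distance(c(0, 50, 99999, 100000, 550000, 1e6,
                                   1000001, 1100000)),
               c("overlap", "lt_100kb", "lt_100kb", "kb100_to_1Mb",
                 "kb100_to_1Mb", "kb100_to_1Mb", "gt_1Mb", "gt_1Mb"))
  expect_equal(classify_distance(5, "promoter_overlap"), "overlap")
})

test_that("alternative-promoter flag requires >= 10 kb separation", {
  base <- function(sep) {
    prom <- toy_promoters(start = c(1000L, 1000L + 2000L + sep),
                          end = c(3000L, 3000L + 2000L + sep),
                          gene_ids = c("G1", "G1"))
    links <- data.frame(
      variant_id = "v1", signal_id = 1L, gene_id = "G1",
      mechanism = c("promoter_overlap", "loop"),
      via_bin_id = c(NA, 1L), loop_id = c(NA, "L1"),
      promoter_id = c("P1", "P2"), promoter_source = "global",
      distance = c(0L, 50000L),
      distance_class = c("overlap", "lt_100kb"), alt_promoter = FALSE)
    flag_alternative_promoter(links, prom)
  }
  expect_true(base(15000L)$alt_promoter[2])   # 15 kb apart
  expect_false(base(8000L)$alt_promoter[2])   # 8 kb apart
  expect_true(base(10000L)$alt_promoter[2])   # boundary inclusive
  # loop to a different gene is never flagged
  prom <- toy_promoters(start = c(1000L, 30000L), end = c(3000L, 32000L),
                        gene_ids = c("G1", "G2"))
  links <- data.frame(variant_id = "v1", signal_id = 1L,
                      gene_id = c("G1", "G2"),
                      mechanism = c("promoter_overlap", "loop"),
                      via_bin_id = c(NA, 1L), loop_id = c(NA, "L1"),
                      promoter_id = c("P1", "P2"), promoter_source = "global",
                      distance = c(0L, 29000L),
                      distance_class = c("overlap", "lt_100kb"),
                      alt_promoter = FALSE)
  expect_false(any(flag_alternative_promoter(links, prom)$alt_promoter))
})

test_that("per-signal summary reports counts, zeros, and the median", {
  links <- data.frame(
    variant_id = c("v1", "v1", "v2", "v3", rep("v4", 9)),
    signal_id = c(1L, 1L, 1L, 2L, rep(3L, 9)),
    gene_id = c("A", "B", "A", "C", paste0("D", 1:9)),
    mechanism = "loop", distance_class = "lt_100kb")
  links$distance_class[4] <- "gt_1Mb"
  signals <- data.frame(signal_id = 1:4)
  s <- summarize_signals(links, signals)
  expect_equal(s$n_genes, c(2L, 1L, 9L, 0L))
  expect_equal(s$n_variants, c(2L, 1L, 1L, 0L))
  expect_true(s$has_gt_1Mb[2])
  expect_false(s$has_overlap[1])
  expect_equal(attr(s, "n_signals_zero"), 1L)
  # gene counts {2,1,9,0} -> median 1.5; spec example {1,5,9} -> median 5
  s2 <- summarize_signals(links[1:13, ], data.frame(signal_id = 1:3))
  expect_equal(attr(s2, "median_genes_per_signal"), 2)
  lk3 <- data.frame(variant_id = "v", signal_id = rep(1:3, c(1, 5, 9)),
                    gene_id = paste0("g", 1:15), mechanism = "loop",
                    distance_class = "lt_100kb")
  expect_equal(attr(summarize_signals(lk3), "median_genes_per_signal"), 5)
})
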