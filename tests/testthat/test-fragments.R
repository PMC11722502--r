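# Digestion, binning, baitmap, variant-bin assignment, rmap I/O.

test_that("digest places cuts by motif and offset", {
  f <- digest("AAAGATCTTT")
  expect_equal(f$start, c(0L, 3L))
  expect_equal(f$end, c(3L, 10L))

  f <- digest("AAGAATCTT") # GANTC at 0-based 2, cut offset 1 -> cut at 3
  expect_equal(f$start, c(0L, 3L))
  expect_equal(f$end, c(3L, 9L))

  expect_equal(nrow(digest("AAAATTTT")), 1L)
  expect_equal(digest("AAAATTTT")$end, 8L)
  expect_equal(nrow(digest("")), 0L)
})

test_that("N in the sequence never matches a motif", {
  expect_equal(nrow(digest("AAGANTCTT")), 1L) # subject N vs pattern N
  expect_equal(nrow(digest("AAGNTCTTT")), 1L)
})

test_that("cuts at sequence edges produce no empty fragments", {
  f <- digest("GATCAAAA") # motif at position 0 -> cut at 0, dropped
  expect_equal(f$start[1], 0L)
  expect_true(all(f$end > f$start))
  f <- digest("AAAAGATC")
  expect_true(all(f$end > f$start))
})

test_that("digestion equals the brute-force oracle and tiles the sequence", {
  set.seed(7)
  for (i in 1:25) {
    s <- random_seq(sample(50:400, 1))
    f <- digest(s)
    cuts <- oracle_digest(s)
    expect_equal(f$start, c(0L, cuts))
    expect_equal(f$end, c(cuts, nchar(s)))
    expect_equal(sum(f$end - f$start), nchar(s))
    # idempotence: each emitted fragment digests to a single fragment
    for (j in seq_len(nrow(f))) {
      sub <- substr(s, f$start[j] + 1L, f$end[j])
      expect_equal(nrow(digest(sub)), 1L)
    }
  }
})

test_that("make_bins groups k consecutive fragments, trailing bin retained", {
  fr <- toy_fragments(rep(100L, 4))
  b <- make_bins(fr, k = 4)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_frags, 4L)
  expect_equal(b$start, 0L); expect_equal(b$end, 400L)

  fr <- toy_fragments(rep(50L, 10))
  b <- make_bins(fr, k = 4)
  expect_equal(b$n_frags, c(4L, 4L, 2L))

  b1 <- make_bins(fr, k = 1)
  expect_equal(nrow(b1), 10L)
  expect_equal(b1$start, fr$start)
  expect_equal(b1$end, fr$end)
})

test_that("binning conserves fragments and never spans chromosomes", {
  set.seed(11)
  for (i in 1:20) {
    n1 <- sample(1:17, 1); n2 <- sample(1:17, 1); k <- sample(1:5, 1)
    fr <- rbind(toy_fragments(sample(30:200, n1, replace = TRUE), "chr1"),
                toy_fragments(sample(30:200, n2, replace = TRUE), "chr2",
                              first_id = n1 + 1L))
    b <- make_bins(fr, k = k)
    expect_equal(nrow(b), ceiling(n1 / k) + ceiling(n2 / k))
    expect_equal(sum(b$n_frags), n1 + n2)
    covered <- unlist(Map(seq, b$first_frag_id, b$last_frag_id))
    expect_equal(sort(covered), fr$frag_id)
    member_chroms_ok <- vapply(seq_len(nrow(b)), function(i) {
      members <- fr$chrom[fr$frag_id >= b$first_frag_id[i] &
                          fr$frag_id <= b$last_frag_id[i]]
      all(members == b$chrom[i])
    }, logical(1))
    expect_true(all(member_chroms_ok))
  }
})

test_that("build_baitmap baits bins whose member fragments hit target regions", {
  fr <- toy_fragments(rep(100L, 8))
  b <- make_bins(fr, k = 4) # bins: frags 1-4 [0,400), 5-8 [400,800)
  # region covering exactly fragment 2 (1-based 101..200)
  b1 <- build_baitmap(b, fr, data.frame(chrom = "chr1", start = 101L,
                                        end = 200L))
  expect_equal(b1$baited, c(TRUE, FALSE))
  # region straddling the two bins
  b2 <- build_baitmap(b, fr, data.frame(chrom = "chr1", start = 390L,
                                        end = 410L))
  expect_equal(b2$baited, c(TRUE, TRUE))
  # no overlap
  b3 <- build_baitmap(b, fr, data.frame(chrom = "chr2", start = 1L,
                                        end = 500L))
  expect_false(any(b3$baited))
  asg <- assign_variant_bins(
    data.frame(variant_id = "v", chrom = "chr1", pos = 150L), fr, b3)
  expect_equal(bait_coverage(asg, b3)$frac_baited, 0)
})

test_that("assign_variant_bins applies the +/-500 b fragment adjacency rule", {
  # fragments of 2000 b; k = 2 -> bins of 4000 b
  fr <- toy_fragments(rep(2000L, 6))
  b <- make_bins(fr, k = 2)
  # variant in the middle of fragment 3 (bin 2): >= 501 b from both edges
  a <- assign_variant_bins(data.frame(variant_id = "v1", chrom = "chr1",
                                      pos = 5000L), fr, b)
  expect_equal(a$primary_bin_id, 2L)
  expect_true(is.na(a$adjacent_bin_ids))
  # variant 300 b from the end of fragment 4; neighbour (frag 5) is in bin 3
  a <- assign_variant_bins(data.frame(variant_id = "v2", chrom = "chr1",
                                      pos = 7700L), fr, b)
  expect_equal(a$primary_bin_id, 2L)
  expect_equal(a$adjacent_bin_ids, "3")
  # variant 300 b from the end of fragment 3; neighbour (frag 4) shares bin 2
  a <- assign_variant_bins(data.frame(variant_id = "v3", chrom = "chr1",
                                      pos = 5700L), fr, b)
  expect_equal(a$primary_bin_id, 2L)
  expect_true(is.na(a$adjacent_bin_ids))
  # outside all fragments -> error
  expect_error(assign_variant_bins(
    data.frame(variant_id = "v4", chrom = "chr1", pos = 99999L), fr, b),
    "outside")
})

test_that("window boundary is inclusive at exactly 500 b", {
  fr <- toy_fragments(rep(2000L, 4))
  b <- make_bins(fr, k = 1)
  # fragment 2 spans 1-based 2001..4000; variant at 4500 sits in fragment 3;
  # window [4000, 5000] touches fragment 2's last base (4000) exactly
  a <- assign_variant_bins(data.frame(variant_id = "v", chrom = "chr1",
                                      pos = 4500L), fr, b, window = 500L)
  expect_equal(a$primary_bin_id, 3L)
  expect_equal(a$adjacent_bin_ids, "2")
  # one base narrower and fragment 2 no longer overlaps
  a <- assign_variant_bins(data.frame(variant_id = "v", chrom = "chr1",
                                      pos = 4501L), fr, b, window = 500L)
  expect_true(is.na(a$adjacent_bin_ids))
})

test_that("assignment equals brute-force interval arithmetic on random maps", {
  set.seed(23)
  for (rep in 1:20) {
    nf <- sample(5:30, 1)
    fr <- toy_fragments(sample(100:1500, nf, replace = TRUE))
    k <- sample(1:4, 1)
    b <- make_bins(fr, k = k)
    L <- fr$end[nf]
    pos <- sample(L, min(10L, L))
    a <- assign_variant_bins(data.frame(variant_id = paste0("v", pos),
                                        chrom = "chr1", pos = pos), fr, b)
    for (i in seq_along(pos)) {
      p0 <- pos[i] - 1L
      fid <- fr$frag_id[fr$start <= p0 & fr$end > p0]
      bid <- b$bin_id[b$first_frag_id <= fid & b$last_frag_id >= fid]
      expect_equal(a$primary_bin_id[i], bid)
      # brute-force adjacency
      adj <- integer(0)
      for (nb in c(fid - 1L, fid + 1L)) {
        j <- which(fr$frag_id == nb)
        if (length(j) == 0) next
        if (fr$start[j] + 1L <= pos[i] + 500L && fr$end[j] >= pos[i] - 500L) {
          nbid <- b$bin_id[b$first_frag_id <= nb & b$last_frag_id >= nb]
          if (nbid != bid) adj <- c(adj, nbid)
        }
      }
      got <- a$adjacent_bin_ids[i]
      if (length(adj) == 0) expect_true(is.na(got))
      else expect_equal(got, paste(sort(unique(adj)), collapse = ","))
    }
  }
})

test_that("rmap and baitmap round-trip bit-exactly", {
  fr <- toy_fragments(c(120L, 380L, 75L, 900L))
  b <- make_bins(fr, k = 2)
  b$baited <- c(TRUE, FALSE)
  f1 <- tempfile(); f2 <- tempfile()
  write_rmap(fr, f1)
  back <- read_rmap(f1)
  expect_equal(back$start, fr$start)
  expect_equal(back$end, fr$end)
  write_rmap(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  write_baitmap(b, f1)
  bb <- read_baitmap(f1)
  expect_equal(bb$bin_id, 1L)
  expect_equal(bb$start, b$start[1])
})
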