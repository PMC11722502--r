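# Regulatory annotation, marginal eQTL regression, expression filter,
# evidence records, high-confidence set.

test_that("regulatory flags come from ATAC overlap and state vocabulary", {
  v <- data.frame(variant_id = c("a", "b", "c"), chrom = "chr1",
                  pos = c(100L, 5000L, 9000L))
  atac <- list(melanocyte = data.frame(chrom = "chr1", start = 50L,
                                       end = 150L))
  hmm <- data.frame(chrom = "chr1", start = c(4900L, 8900L),
                    end = c(5100L, 9100L),
                    state_label = c("EnhWk", "Quies"),
                    cell_context = "melanocyte")
  ann <- annotate_regulatory(v, atac, hmm)
  expect_true(ann$atac_melanocyte[1])
  expect_true(ann$chromhmm_regulatory_melanocyte[2]) # auxiliary enhancer
  expect_false(any(unlist(ann[3, -1])))              # Quies is not regulatory
  expect_equal(ann$any_regulatory,
               ann$atac_melanocyte | ann$atac_melanoma |
                 ann$chromhmm_regulatory_melanocyte |
                 ann$chromhmm_regulatory_melanoma)
  # promoter states count as regulatory too ("enhancer or promoter")
  hmm2 <- data.frame(chrom = "chr1", start = 90L, end = 110L,
                     state_label = "1_TssA", cell_context = "melanoma")
  ann2 <- annotate_regulatory(v[1, , drop = FALSE], list(), hmm2)
  expect_true(ann2$chromhmm_regulatory_melanoma)
  expect_false(ann2$both_datasets)
})

test_that("marginal eQTL regression matches the normal-equations oracle", {
  # noiseless: expression = 2 * dosage
  d <- c(0, 1, 2, 0, 1, 2, 1, 0)
  r <- suppressWarnings(marginal_eqtl_test(d, 2 * d)) # perfect-fit warning
  expect_equal(r$beta, 2, tolerance = 1e-12)
  expect_lt(r$p, 1e-10)

  # n = 8 fixture with covariates: beta from (X'X)^{-1} X'y
  set.seed(5)
  X_cov <- matrix(rnorm(16), 8, 2)
  y <- 0.7 * d + X_cov %*% c(0.3, -0.2) + rnorm(8, 0, 0.1)
  r2 <- marginal_eqtl_test(d, as.vector(y), X_cov)
  Xd <- cbind(1, d, X_cov)
  beta_hat <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  expect_equal(r2$beta, beta_hat[2], tolerance = 1e-10)

  # constant dosage is untestable
  r3 <- marginal_eqtl_test(rep(1, 8), rnorm(8))
  expect_false(r3$tested)
  expect_true(is.na(r3$p))
  expect_error(marginal_eqtl_test(d[1:3], rnorm(3), matrix(rnorm(6), 3, 2)))
})

test_that("null p-values are roughly uniform (small calibration check)", {
  set.seed(13)
  p <- replicate(200, {
    marginal_eqtl_test(sample(0:2, 30, TRUE), rnorm(30))$p
  })
  expect_gt(mean(p < 0.05), 0.005)
  expect_lt(mean(p < 0.05), 0.12)
  expect_gt(mean(p < 0.5), 0.35)
})

test_that("expression filter applies the strict >20% low-sample rule", {
  m <- rbind(zero = rep(0, 10),
             edge2 = c(rep(0.01, 2), rep(5, 8)),   # exactly 20% low
             edge3 = c(rep(0.01, 3), rep(5, 7)),   # 30% low
             top = rep(100, 10),
             mid = rep(1, 10))
  r <- expression_filter(m)
  expect_false(r$retained[r$gene_id == "zero"])
  expect_true(r$retained[r$gene_id == "edge2"])
  expect_false(r$retained[r$gene_id == "edge3"])
  # always-highest among retained genes -> median percentile 100
  expect_equal(r$median_percentile[r$gene_id == "top"], 100)
  expect_true(is.na(r$median_percentile[r$gene_id == "zero"]))
})

# Shared scaffolding for record tests: one signal, one gene, two variants.
ev_world <- function(mpra = data.frame(variant_id = "v1", tested = TRUE,
                                       fdr_sig_mc = TRUE,
                                       fdr_sig_mel = FALSE)) {
  links <- data.frame(variant_id = c("v1", "v2"), signal_id = 1L,
                      gene_id = "G1", mechanism = "loop")
  reg <- data.frame(variant_id = c("v1", "v2"),
                    atac_melanocyte = TRUE, atac_melanoma = FALSE,
                    chromhmm_regulatory_melanocyte = FALSE,
                    chromhmm_regulatory_melanoma = FALSE,
                    any_regulatory = TRUE, both_datasets = FALSE)
  list(links = links, reg = reg, mpra = mpra)
}

test_that("evidence records nest flags over the same linking variant", {
  w <- ev_world()
  rec <- build_evidence_records(w$links, w$reg, mpra = w$mpra)
  expect_true(rec$linked && rec$var_regulatory && rec$var_mpra_sig)
  expect_false(rec$var_marginal_eqtl) # no eQTL table supplied
  expect_equal(rec$best_variant_id, "v1") # deeper ladder than v2

  # regulatory but MPRA-untested -> var_mpra_sig stays false
  rec2 <- build_evidence_records(w$links, w$reg, mpra = NULL)
  expect_true(rec2$var_regulatory)
  expect_false(rec2$var_mpra_sig)

  # MPRA-significant but NOT regulatory does not reach the MPRA level
  reg_off <- w$reg; reg_off$any_regulatory <- FALSE
  reg_off$atac_melanocyte <- FALSE
  rec3 <- build_evidence_records(w$links, reg_off, mpra = w$mpra)
  expect_false(rec3$var_mpra_sig)

  # marginal eQTL level needs MPRA significance and p < 0.05
  eq <- data.frame(variant_id = "v1", gene_id = "G1", p = 0.01)
  rec4 <- build_evidence_records(w$links, w$reg, mpra = w$mpra, eqtl_p = eq)
  expect_true(rec4$var_marginal_eqtl)
  eq$p <- 0.2
  rec5 <- build_evidence_records(w$links, w$reg, mpra = w$mpra, eqtl_p = eq)
  expect_false(rec5$var_marginal_eqtl)

  # nesting invariant holds on every record
  for (r in list(rec, rec2, rec3, rec4, rec5)) {
    expect_true((!r$var_marginal_eqtl | r$var_mpra_sig) &
                  (!r$var_mpra_sig | r$var_regulatory) &
                  (!r$var_regulatory | r$linked))
  }
})

test_that("QTL, driver and expression flags merge by key", {
  w <- ev_world()
  qtl <- data.frame(signal_id = 1L, gene_id = "G1", eqtl_or_twas = TRUE,
                    meqtl_or_mwas = FALSE)
  drv <- data.frame(gene_id = "G1", melanoma_driver = TRUE,
                    pancancer_driver = FALSE)
  m <- matrix(5, 1, 5, dimnames = list("G1", NULL))
  expr <- list(melanocyte = expression_filter(m))
  rec <- build_evidence_records(w$links, w$reg, mpra = w$mpra, qtl = qtl,
                                drivers = drv, expression = expr)
  expect_true(rec$eqtl_or_twas)
  expect_false(rec$meqtl_or_mwas)
  expect_true(rec$driver_melanoma)
  expect_false(rec$driver_pancancer)
  expect_true(rec$expressed_melanocyte)
})

test_that("high-confidence set collects depth >= 3 variants and their genes", {
  w <- ev_world()
  rec <- build_evidence_records(w$links, w$reg, mpra = w$mpra)
  hc <- high_confidence_set(rec)
  expect_equal(hc$genes, "G1")
  expect_equal(hc$variants, "v1") # v2 is regulatory but not MPRA-significant
  expect_equal(hc$signals, 1L)

  # no MPRA data at all -> empty set
  rec2 <- build_evidence_records(w$links, w$reg, mpra = NULL)
  hc2 <- high_confidence_set(rec2)
  expect_length(hc2$genes, 0)

  # one qualifying gene at each of 3 signals -> signal set of size 3
  links3 <- data.frame(variant_id = paste0("v", 1:3), signal_id = 1:3,
                       gene_id = paste0("G", 1:3), mechanism = "loop")
  reg3 <- data.frame(variant_id = paste0("v", 1:3),
                     atac_melanocyte = TRUE, atac_melanoma = FALSE,
                     chromhmm_regulatory_melanocyte = FALSE,
                     chromhmm_regulatory_melanoma = FALSE,
                     any_regulatory = TRUE, both_datasets = FALSE)
  mpra3 <- data.frame(variant_id = paste0("v", 1:3), tested = TRUE,
                      fdr_sig_mc = TRUE, fdr_sig_mel = TRUE)
  hc3 <- high_confidence_set(build_evidence_records(links3, reg3,
                                                    mpra = mpra3))
  expect_length(hc3$signals, 3)
})

test_that("adding evidence never removes a gene from the set (monotone)", {
  w <- ev_world(mpra = data.frame(variant_id = c("v1", "v2"), tested = TRUE,
                                  fdr_sig_mc = c(TRUE, FALSE),
                                  fdr_sig_mel = FALSE))
  base_hc <- high_confidence_set(build_evidence_records(w$links, w$reg,
                                                        mpra = w$mpra))
  # make v2 significant as well: the gene set can only grow
  w$mpra$fdr_sig_mel <- TRUE
  more_hc <- high_confidence_set(build_evidence_records(w$links, w$reg,
                                                        mpra = w$mpra))
  expect_true(all(base_hc$genes %in% more_hc$genes))
  expect_true(all(base_hc$variants %in% more_hc$variants))
})
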