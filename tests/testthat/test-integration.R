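toy_genes_tab <- function(n = 6, chrom = "chr1") {
  start <- seq(1000, by = 2000, length.out = n)
  data.frame(gene_id = sprintf("g%02d", 1:n), chrom = chrom, strand = "+",
             tss = start, tes = start + 1000, stringsAsFactors = FALSE)
}

test_that("gene dosage comes from the TSS-containing segment", {
  genes <- toy_genes_tab(4)
  segs <- data.frame(sample = "Ra", chrom = "chr1",
                     start = c(1, 2500, 5200), end = c(2499, 5199, 20000),
                     total_cn = c(4, 3, 1), b_allele_cn = c(1, 1, 0))
  d <- genes_in_cna(segs, genes, baseline_ploidy = 3)
  # TSS positions 1000, 3000, 5000, 7000: gene 3's TSS sits just inside the
  # neutral segment even though its body crosses into the loss segment
  expect_equal(d$dosage_class, c("gain", "neutral", "neutral", "loss"))
  expect_equal(d$copy_number, c(4, 3, 3, 1))
  expect_equal(d$straddles_boundary, c(FALSE, FALSE, TRUE, FALSE))
  # brute-force containment oracle on a random instance
  set.seed(16)
  genesr <- toy_genes_tab(20)
  bks <- sort(sample(seq(2000, 38000, by = 500), 4))
  segsr <- data.frame(sample = "Pa", chrom = "chr1",
                      start = c(1, bks + 1), end = c(bks, 50000),
                      total_cn = sample(c(1, 2, 3, 4, 6), 5, replace = TRUE),
                      b_allele_cn = 1)
  dr <- genes_in_cna(segsr, genesr)
  for (i in seq_len(20)) {
    j <- which(genesr$tss[i] >= segsr$start & genesr$tss[i] <= segsr$end)
    expect_equal(dr$copy_number[i], segsr$total_cn[j])
  }
})

test_that("one-sided KS matches the brute-force CDF oracle", {
  set.seed(31)
  x <- rnorm(5); y <- rnorm(5)
  ks <- ks_one_sided(x, y, "greater")
  expect_equal(ks$D, enum_ks_D(x, y, "x_above"), tolerance = 1e-12)
  ks2 <- ks_one_sided(x, y, "less")
  expect_equal(ks2$D, enum_ks_D(x, y, "x_below"), tolerance = 1e-12)
  # directional power: shifted-up sample is detected by "greater", not "less"
  up <- rnorm(60, 2)
  ref <- rnorm(60)
  expect_lt(ks_one_sided(up, ref, "greater")$p, 1e-6)
  expect_gt(ks_one_sided(up, ref, "less")$p, 0.5)
})

test_that("dosage KS test is null on identical classes and powered on gains", {
  genes <- toy_genes_tab(30)
  means <- cbind(Ra = rep(2^(1:30 / 10), 1), Pa = rep(2^(1:30 / 10), 1))
  rownames(means) <- genes$gene_id
  dosage <- data.frame(gene = genes$gene_id, sample = "Ra",
                       copy_number = c(rep(4, 10), rep(3, 20)),
                       dosage_class = c(rep("gain", 10), rep("neutral", 20)),
                       straddles_boundary = FALSE)
  # gain genes' changes identical to neutral genes' -> p = 1 direction-wise
  r <- ks_dosage_test(dosage, means, c("Ra", "Pa"))
  expect_equal(r$p_gain, 1)
  expect_true(is.na(r$D_loss))  # empty loss class is skipped
  # planted dosage effect: gains detected
  means2 <- means
  means2[1:10, "Ra"] <- means2[1:10, "Ra"] * 3
  r2 <- ks_dosage_test(dosage, means2, c("Ra", "Pa"))
  expect_lt(r2$p_gain, 0.01)
})

test_that("focal-specific CNA genes require others to agree", {
  mk <- function(cns) {
    do.call(rbind, lapply(names(cns), function(s)
      data.frame(gene = paste0("g", seq_along(cns[[s]])), sample = s,
                 copy_number = cns[[s]],
                 dosage_class = "x", straddles_boundary = FALSE)))
  }
  d <- mk(list(Ra = c(4, 4, 2), Pa = c(3, 4, 3), Pb = c(3, 4, 3),
               Rb = c(3, 3, 3)))
  out <- sample_specific_cna_genes(d, "Ra")
  expect_equal(out$gene, c("g1", "g3"))   # g2: Pa and Pb share the gain
  expect_equal(out$direction, c("up", "down"))
  expect_equal(out$delta_cn, c(1, -1))
  # relaxed mode: focal differs from the modal copy number
  d2 <- mk(list(Ra = c(5), Pa = c(3), Pb = c(3), Rb = c(4)))
  expect_equal(nrow(sample_specific_cna_genes(d2, "Ra")), 0)
  expect_equal(sample_specific_cna_genes(d2, "Ra", relaxed = TRUE)$gene, "g1")
  # scan oracle on random copy-number tables
  set.seed(41)
  for (rep in 1:5) {
    cns <- lapply(setNames(nm = c("Ra", "Pa", "Pb", "Rb")), function(s)
      sample(2:4, 12, replace = TRUE))
    out <- sample_specific_cna_genes(mk(cns), "Ra")
    oracle <- vapply(1:12, function(i) {
      o <- c(cns$Pa[i], cns$Pb[i], cns$Rb[i])
      length(unique(o)) == 1 && cns$Ra[i] != o[1]
    }, logical(1))
    expect_equal(sort(out$gene), sort(sprintf("g%d", which(oracle))))
  }
})

test_that("driven-gene accounting reproduces the printed worked example", {
  s <- driven_summary(330, 249, 580, 540, 25)
  expect_equal(s$pct_cna_label, "75.45%")
  expect_equal(s$pct_dmgb_label, "93.10%")
  expect_equal(s$n_union, 764)
  # identity holds for arbitrary counts
  set.seed(50)
  for (i in 1:10) {
    ov <- sample(50:500, 2); cons <- vapply(ov, function(o) sample(o, 1), 0)
    b <- sample(0:min(cons), 1)
    s2 <- driven_summary(ov[1], cons[1], ov[2], cons[2], b)
    expect_equal(s2$n_union, cons[1] + cons[2] - b)
    expect_equal(s2$pct_cna, 100 * cons[1] / ov[1])
  }
})

test_that("driven classification enforces directional consistency", {
  cna <- data.frame(gene = c("g1", "g2", "g3"), delta_cn = c(1, -1, 2))
  dmgb <- data.frame(gene = c("g3", "g4", "g5"), delta_ml = c(0.4, -0.3, 0.3))
  degs <- data.frame(gene = c("g1", "g2", "g3", "g4", "g6"),
                     log2_fc = c(1.2, 0.8, 1.1, -0.9, 2))
  out <- classify_driven(cna, dmgb, degs)
  calls <- out$calls
  # g1: gain & up -> cna; g2: loss & up -> inconsistent, excluded
  # g3: gain+hyper & up -> both; g4: hypo & down -> methylation
  # g5: not a DEG; g6: DEG only
  expect_setequal(calls$gene, c("g1", "g3", "g4"))
  expect_equal(calls$mechanism[calls$gene == "g1"], "cna")
  expect_equal(calls$mechanism[calls$gene == "g3"], "both")
  expect_equal(calls$mechanism[calls$gene == "g4"], "methylation")
  s <- out$summary
  expect_equal(s$n_cna_overlap, 3)
  expect_equal(s$n_cna_consistent, 2)
  expect_equal(s$n_union, s$n_cna_consistent + s$n_dmgb_consistent - s$n_both)
})

test_that("binomial overlap test matches closed forms and enumeration", {
  r <- binomial_overlap_test(0, 10, 0.2)
  expect_equal(r$p_depletion, 0.8^10, tolerance = 1e-12)
  expect_equal(r$p_depletion, enum_binom_tail(0, 10, 0.2, "le"),
               tolerance = 1e-9)
  r2 <- binomial_overlap_test(4, 20, 0.2)  # k = n * p0 exactly
  expect_gt(r2$p_two_sided, 0.9)
  expect_equal(r2$p_enrichment, enum_binom_tail(4, 20, 0.2, "ge"),
               tolerance = 1e-9)
  # full wrapper with set bookkeeping
  uni <- paste0("g", 1:100)
  mut <- paste0("g", 1:10); deg <- paste0("g", 91:100)
  ov <- mutation_deg_overlap(mut, deg, uni)
  expect_equal(ov$k_observed, 0)
  expect_equal(ov$p0, 0.1)
  expect_equal(ov$p_depletion, 0.9^10, tolerance = 1e-12)
  expect_error(mutation_deg_overlap(mut, deg, character(0)), "universe")
})

test_that("gene-set enrichment matches the hypergeometric closed form", {
  uni <- paste0("g", 1:100)
  sets <- list(hit = paste0("g", 1:10), other = paste0("g", 40:60),
               off = paste0("x", 1:5))
  res <- gene_set_enrichment(paste0("g", 1:10), sets, uni)
  expect_equal(nrow(res), 2)  # 'off' has no universe members
  p_hit <- res$p[res$set == "hit"]
  expect_equal(p_hit, choose(10, 10) * choose(90, 0) / choose(100, 10),
               tolerance = 1e-12)
  expect_equal(p_hit, enum_hyper_p(10, 10, 100, 10), tolerance = 1e-9)
  expect_gt(res$p[res$set == "other"], 0.5)
  expect_true(all(res$q >= res$p - 1e-12))
})

test_that("methylation-expression correlation handles exact and degenerate input", {
  dmf <- data.frame(owner_id = paste0("g", 1:10), category = "gene_body",
                    delta_ml = seq(-0.5, 0.4, 0.1), is_dmf = TRUE)
  fc <- setNames(2 * seq(-0.5, 0.4, 0.1), paste0("g", 1:10))
  r <- dml_expression_correlation(dmf, fc)
  expect_equal(r$r, 1)
  dmf0 <- dmf; dmf0$delta_ml <- 0.3
  r0 <- dml_expression_correlation(dmf0, fc)
  expect_true(r0$degenerate)
  expect_true(is.na(r0$r))
  expect_error(dml_expression_correlation(dmf[1:2, ], fc[1:2]), "fewer than 3")
})
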