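# Small configuration for fast structural checks; statistical checks use
# the full defaults where the contract depends on scale.
small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 400, n_cpg_sites = 6000, n_cgi = 60,
             n_repeats = 50, n_planted_dmgb = 30, n_planted_dmp = 30,
             n_planted_both = 4,
             cna_events_per_branch = c(trunk = 2, "Pa+Pb" = 1, "Ra+Rb" = 1,
                                       Pa = 1, Pb = 1, Ra = 3, Rb = 1),
             cna_genes_per_event_range = c(4, 8), ...)
}

test_that("identical config and seed give a byte-identical truth and bundle", {
  t1 <- generate_truth(small_cfg(seed = 5))
  t2 <- generate_truth(small_cfg(seed = 5))
  expect_identical(t1, t2)
  d1 <- file.path(tempdir(), "bundle_a"); d2 <- file.path(tempdir(), "bundle_b")
  m1 <- render_dataset(t1, d1); m2 <- render_dataset(t2, d2)
  expect_identical(m1$md5, m2$md5)
  expect_identical(basename(m1$file), basename(m2$file))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("zero branch counts give an empty variant set", {
  cfg <- small_cfg(seed = 2,
                   branch_snv_counts = c(trunk = 0, "Pa+Pb" = 0, "Ra+Rb" = 0,
                                         Pa = 0, Pb = 0, Ra = 0, Rb = 0))
  tr <- generate_truth(cfg)
  expect_equal(nrow(tr$snv), 0)
  snv <- simulate_snv_table(tr)
  expect_equal(nrow(snv), 0)
})

test_that("branch SNV counts are respected exactly and carrier sets are clades", {
  counts <- c(trunk = 20, "Pa+Pb" = 5, "Ra+Rb" = 3, Pa = 2, Pb = 2,
              Ra = 2, Rb = 2)
  tr <- generate_truth(small_cfg(seed = 3, branch_snv_counts = counts))
  # conservation
  expect_equal(nrow(tr$snv), sum(counts))
  # independent tally of carrier-set equivalence classes
  tally <- table(tr$snv$carriers)
  branches <- tree_branches("((Pa,Pb),(Ra,Rb))")
  for (b in names(counts)) {
    key <- paste(branches[[b]], collapse = ",")
    expect_equal(unname(tally[[key]]), unname(counts[[b]]), info = b)
  }
  # every carrier set is a branch clade (perfect phylogeny, no homoplasy)
  clades <- vapply(branches, paste, character(1), collapse = ",")
  expect_true(all(tr$snv$carriers %in% clades))
})

test_that("a mismatched topology names the offending leaf", {
  expect_error(small_cfg(tree_topology = "((Pa,Pb),(Ra,Xx))"),
               "Xx|Rb")
  expect_error(small_cfg(samples = c("Pa", "Pb", "Ra", "TIL")),
               "outgroup")
})

test_that("rendered SNV counts pass the somatic filter at the expected rate", {
  tr <- generate_truth(small_cfg(seed = 4))
  snv <- simulate_snv_table(tr)
  f <- filter_snvs(snv)
  # closed-form lower bound at depth 60, VAF 1/3 for a triploid carrier:
  # P(reads > 5) alone leaves < 1e-4 failures; strand split adds ~2^-19
  p_pass <- 1 - pbinom(5, 60, 1 / 3)
  expect_gt(p_pass, 0.999)
  carriers <- strsplit(tr$snv$carriers, ",")
  n_flag <- 0; n_carry <- 0
  for (s in c("Pa", "Pb", "Ra", "Rb")) {
    is_c <- vapply(carriers, function(x) s %in% x, logical(1))
    key <- paste0(snv$chrom, ":", snv$pos)
    tkey <- paste0(tr$snv$chrom, ":", tr$snv$pos)
    pres <- f$presence[match(tkey, rownames(f$presence)), s]
    n_flag <- n_flag + sum(pres & is_c, na.rm = TRUE)
    n_carry <- n_carry + sum(is_c)
    # non-carriers are never flagged
    expect_false(any(pres & !is_c, na.rm = TRUE))
  }
  expect_gte(n_flag / n_carry, 0.99)
})

test_that("per-sample genome methylation means match configured targets", {
  tr <- generate_truth(sim_config(seed = 6))   # full 50k-site defaults
  tab <- load_and_filter_sites(simulate_methylation(tr))
  expect_gte(nrow(tab), 45000)
  for (s in names(tr$config$global_methylation_level)) {
    expect_lt(abs(genome_mean(tab, s) -
                    tr$config$global_methylation_level[[s]]), 0.02,
              label = paste("genome mean of", s))
  }
})

test_that("null couplings leave expression flat across samples", {
  cfg <- sim_config(seed = 7, methylation_expression_coupling = 0,
                    dosage_coupling = 0,
                    cna_events_per_branch = c(trunk = 0))
  tr <- generate_truth(cfg)
  expect_equal(length(unique(as.vector(tr$expression_mu))) > 1, TRUE)
  expect_equal(tr$expression_mu[, "Pa"], tr$expression_mu[, "Ra"])
  counts <- simulate_counts(tr)
  means <- sample_means(upper_quartile_normalize(counts)$counts)
  keep <- rowSums(means) > 0 & apply(means, 1, min) > 0
  expect_gte(sum(keep), 2000)
  lfc <- log2(means[keep, "Ra"] / means[keep, "Pa"])
  expect_lt(abs(mean(lfc)), 0.1)
})

test_that("segment tables tile chromosomes and honor allele bounds", {
  tr <- generate_truth(small_cfg(seed = 8))
  segs <- truth_segments(tr)
  expect_true(all(segs$b_allele_cn <= pmax(segs$total_cn, 1)))
  for (s in tr$config$samples) {
    for (chr in names(tr$chrom_lengths)) {
      sc <- segs[segs$sample == s & segs$chrom == chr, ]
      sc <- sc[order(sc$start), ]
      expect_equal(sc$start[1], 1)
      expect_equal(sc$end[nrow(sc)], unname(tr$chrom_lengths[chr]))
      if (nrow(sc) > 1)
        expect_true(all(sc$start[-1] == sc$end[-nrow(sc)] + 1))
    }
  }
  # LOH truth consistent: b_allele 0 segments only
  expect_true(all(tr$loh$b_allele_cn == 0))
})

test_that("driven truth genes sit in focal-only events of the right kind", {
  tr <- generate_truth(small_cfg(seed = 9))
  cfg <- tr$config
  dt <- tr$driven_truth
  cna_rows <- dt[dt$mechanism %in% c("cna", "both"), ]
  for (i in seq_len(nrow(cna_rows))) {
    g <- cna_rows$gene[i]
    cn <- tr$gene_cn[g, ]
    expect_true(cn[cfg$focal_sample] != cfg$baseline_ploidy)
    expect_true(all(cn[setdiff(cfg$samples, cfg$focal_sample)] ==
                      cfg$baseline_ploidy))
    expect_equal(unname(cn[cfg$focal_sample] - cfg$baseline_ploidy),
                 cna_rows$delta_cn[i])
  }
  meth_rows <- dt[dt$mechanism %in% c("methylation", "both"), ]
  expect_true(all(abs(meth_rows$delta_ml) > 0))
  # planted gene bodies are disjoint from planted promoter-only genes
  expect_length(intersect(dt$gene[dt$mechanism == "methylation"],
                          tr$dmp_genes), 0)
})

test_that("the rendered bundle round-trips through the readers", {
  tr <- generate_truth(small_cfg(seed = 10))
  out <- file.path(tempdir(), "roundtrip")
  man <- render_dataset(tr, out)
  expect_true(all(file.exists(man$file)))
  snv_mem <- simulate_snv_table(tr)
  snv_disk <- read_snv_table(file.path(out, "snv_table.tsv"))
  expect_equal(snv_disk[order(snv_disk$chrom, snv_disk$pos), ],
               snv_mem[order(snv_mem$chrom, snv_mem$pos), ],
               ignore_attr = TRUE)
  seg_disk <- read_seg(file.path(out, "Ra.seg"))
  seg_mem <- truth_segments(tr)
  seg_mem <- seg_mem[seg_mem$sample == "Ra", ]
  expect_equal(seg_disk$start, seg_mem$start)
  expect_equal(seg_disk$total_cn, seg_mem$total_cn)
  counts_disk <- read_counts(file.path(out, "counts.tsv"))
  expect_equal(counts_disk, simulate_counts(tr))
  genes_disk <- read_genes(file.path(out, "genes.tsv"))
  expect_equal(genes_disk$tss, tr$genes$tss)
  cgi_disk <- read_bed(file.path(out, "cgi.bed"))
  expect_equal(cgi_disk$start, tr$cgis$start)  # BED round-trip restores 1-based
  expect_equal(cgi_disk$end, tr$cgis$end)
  cov_disk <- load_and_filter_sites(
    setNames(file.path(out, paste0(tr$meth_samples, ".cov")),
             tr$meth_samples), min_depth = 0)
  cov_mem <- load_and_filter_sites(simulate_methylation(tr), min_depth = 0)
  expect_equal(cov_disk, cov_mem)
  unlink(out, recursive = TRUE)
})
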