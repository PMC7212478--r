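toy_cov <- function(pos, meth, unmeth, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, meth = meth, unmeth = unmeth,
             stringsAsFactors = FALSE)
}

test_that("site filter keeps sites covered > min_depth in every sample", {
  files <- list(
    S1 = toy_cov(c(10, 20, 30), c(6, 6, 6), c(6, 9, 4)),   # depths 12 15 10
    S2 = toy_cov(c(10, 20, 30), c(7, 8, 20), c(8, 7, 5)),
    S3 = toy_cov(c(10, 20), c(5, 9), c(6, 6)))             # site 30 missing
  tab <- load_and_filter_sites(files, min_depth = 10, merge_strands = FALSE)
  expect_equal(tab$pos, c(10, 20))  # site 30: depth 10 in S1 and absent in S3
  expect_equal(tab$level_S1, c(6 / 12, 6 / 15))
  # brute-force filter oracle on random tables
  set.seed(8)
  pos <- seq(2, 100, by = 2)
  fl <- lapply(1:3, function(i) {
    cov <- rpois(length(pos), 14)
    toy_cov(pos, rbinom(length(pos), cov, 0.4), NA) ->
      d; d$unmeth <- cov - d$meth; d
  })
  names(fl) <- paste0("S", 1:3)
  tab2 <- load_and_filter_sites(fl, min_depth = 10, merge_strands = FALSE)
  depth_ok <- Reduce(`&`, lapply(fl, function(d) d$meth + d$unmeth > 10))
  expect_equal(tab2$pos, pos[depth_ok])
})

test_that("strand merging pools adjacent cytosine records", {
  f <- list(S1 = toy_cov(c(100, 101, 200), c(3, 4, 10), c(5, 2, 10)),
            S2 = toy_cov(c(100, 101, 200), c(6, 6, 12), c(4, 4, 8)))
  tab <- load_and_filter_sites(f, min_depth = 10)
  expect_equal(tab$pos, c(100, 200))
  expect_equal(tab$meth_S1[1], 7)   # 3 + 4
  expect_equal(tab$total_S1[1], 14)
  expect_error(
    load_and_filter_sites(list(S1 = toy_cov(1, -1, 5)), min_depth = 0),
    "negative counts")
})

test_that("vectorized Fisher agrees exactly with fisher.test and enumeration", {
  set.seed(77)
  a <- rpois(300, 8); b <- rpois(300, 8); c <- rpois(300, 8); d <- rpois(300, 8)
  p <- fisher_exact_2x2(a, b, c, d)
  for (i in sample(300, 40)) {
    expect_equal(p[i], fisher.test(rbind(c(a[i], b[i]),
                                         c(c[i], d[i])))$p.value,
                 tolerance = 1e-12)
    expect_equal(p[i], enum_fisher_p(a[i], b[i], c[i], d[i]),
                 tolerance = 1e-9)
  }
  # symmetry: swapping samples, and swapping labels, leave p unchanged
  expect_equal(fisher_exact_2x2(a, b, c, d), fisher_exact_2x2(c, d, a, b))
  expect_equal(fisher_exact_2x2(a, b, c, d), fisher_exact_2x2(b, a, d, c))
})

test_that("DMS calling reproduces the exact-test worked example", {
  # 5/10 methylated vs 0/10: two-sided Fisher p ~= 0.0325
  tab <- data.frame(chrom = "chr1", pos = 2,
                    meth_A = 5, total_A = 10, level_A = 0.5,
                    meth_B = 0, total_B = 10, level_B = 0)
  d <- call_dms(tab, c("A", "B"))
  expect_equal(d$p, 0.03250774, tolerance = 1e-6)
  expect_equal(d$p, enum_fisher_p(5, 5, 0, 10), tolerance = 1e-9)
  expect_equal(d$delta_ml, -0.5)
  # identical counts: p = 1, never a DMS
  tab2 <- tab; tab2$meth_B <- 5; tab2$level_B <- 0.5
  d2 <- call_dms(tab2, c("A", "B"))
  expect_equal(d2$p, 1)
  expect_false(d2$is_dms)
})

test_that("BH adjustment is monotone and DMS calls ignore site order", {
  set.seed(9)
  n <- 200
  tab <- data.frame(chrom = "chr1", pos = seq(2, 2 * n, by = 2),
                    meth_A = rbinom(n, 20, 0.5), total_A = 20,
                    meth_B = rbinom(n, 20, runif(n, 0.2, 0.8)), total_B = 20)
  tab$level_A <- tab$meth_A / 20; tab$level_B <- tab$meth_B / 20
  d <- call_dms(tab, c("A", "B"))
  ord <- order(d$p)
  expect_true(all(diff(d$p_adj[ord]) >= -1e-12))
  expect_true(all(d$p_adj >= d$p - 1e-12))
  expect_true(all(d$p_adj <= 1))
  shuf <- sample(n)
  d2 <- call_dms(tab[shuf, ], c("A", "B"))
  expect_equal(d2$is_dms, d$is_dms[shuf])
})

test_that("region levels are unweighted means of site levels", {
  tab <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 500),
                    meth_A = c(2, 4, 6, 5), total_A = c(10, 10, 10, 10),
                    level_A = c(0.2, 0.4, 0.6, 0.5))
  regions <- data.frame(region_id = c("r1", "r2", "r3"),
                        category = "gene_body", owner_id = c("g1", "g2", "g3"),
                        chrom = "chr1", start = c(5, 495, 600),
                        end = c(35, 505, 700))
  out <- region_levels(tab, regions, min_sites = 1)
  expect_equal(out$level_A, c(0.4, 0.5, NA))
  expect_equal(out$n_sites, c(3, 1, 0))
  expect_equal(out$ok, c(TRUE, TRUE, FALSE))
  # single-site region equals the site's level; pooled counts sum
  expect_equal(out$meth_A, c(12, 5, 0))
  # brute-force per-region means on a random instance
  set.seed(3)
  tab2 <- data.frame(chrom = "chr1", pos = sample(1:1000, 60),
                     meth_B = rbinom(60, 15, 0.5), total_B = 15)
  tab2$level_B <- tab2$meth_B / 15
  regs2 <- data.frame(region_id = paste0("r", 1:8),
                      chrom = "chr1", start = st <- sample(1:800, 8),
                      end = st + 150)
  out2 <- region_levels(tab2, regs2, min_sites = 1)
  for (j in 1:8) {
    inside <- tab2$pos >= regs2$start[j] & tab2$pos <= regs2$end[j]
    expect_equal(out2$n_sites[j], sum(inside))
    if (any(inside))
      expect_equal(out2$level_B[j], mean(tab2$level_B[inside]))
  }
})

test_that("region differential calls gate on both delta and the exact test", {
  mk_reg <- function(mA, tA, mB, tB, n_sites = 5) {
    data.frame(region_id = "r1", category = "gene_body", owner_id = "g1",
               chrom = "chr1", start = 1, end = 100, n_sites = n_sites,
               level_A = mA / tA, meth_A = mA, total_A = tA,
               level_B = mB / tB, meth_B = mB, total_B = tB, ok = TRUE)
  }
  # 80/100 vs 40/100: delta 0.4 and tiny p -> DMF
  d <- call_dmf(mk_reg(80, 100, 40, 100), c("A", "B"))
  expect_true(d$is_dmf)
  expect_equal(d$delta_ml, -0.4)
  expect_equal(d$p, enum_fisher_p(80, 20, 40, 60), tolerance = 1e-9)
  # delta gate: 0.15 difference is never enough, whatever the p
  d2 <- call_dmf(mk_reg(5000, 10000, 6500, 10000), c("A", "B"))
  expect_false(d2$is_dmf)
  # tiny counts: delta 0.33 but p > 0.05
  d3 <- call_dmf(mk_reg(2, 3, 1, 3), c("A", "B"))
  expect_gt(d3$p, 0.05)
  expect_false(d3$is_dmf)
})

test_that("global comparison flags degenerate input and detects forced shifts", {
  n <- 50
  tab <- data.frame(chrom = "chr1", pos = seq(2, 2 * n, 2),
                    level_A = runif(n, 0.2, 0.6))
  tab$level_B <- tab$level_A
  tab$meth_A <- tab$meth_B <- 10; tab$total_A <- tab$total_B <- 20
  g <- global_compare(tab, c("A", "B"))
  expect_true(g$all_equal)
  expect_equal(g$p, 1)
  tab$level_B <- tab$level_A + 0.1
  g2 <- global_compare(tab, c("A", "B"))
  expect_lt(g2$p, 1e-9)
  expect_equal(genome_mean(tab, "A"), mean(tab$level_A))
})

test_that("methylome clustering merges a duplicated sample first", {
  set.seed(14)
  n <- 100
  tab <- data.frame(chrom = "chr1", pos = seq(2, 2 * n, 2))
  for (s in c("A", "B")) {
    tab[[paste0("meth_", s)]] <- rbinom(n, 20, 0.5)
    tab[[paste0("total_", s)]] <- 20
    tab[[paste0("level_", s)]] <- tab[[paste0("meth_", s)]] / 20
  }
  tab$meth_C <- tab$meth_A; tab$total_C <- 20; tab$level_C <- tab$level_A
  cl <- cluster_methylomes(tab)
  expect_equal(first_merge_pair(cl), c("A", "C"))
})
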