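#' Integration of copy number, methylation, and expression
#'
#' @name integration
NULL

#' Per-gene copy number and dosage class from segment calls
#'
#' Each gene takes the copy number of the segment containing its TSS; genes
#' whose body straddles a segment boundary are flagged and excluded from
#' dosage testing by default.
#'
#' @param segments segment table: `sample`, `chrom`, `start`, `end`,
#'   `total_cn`, `b_allele_cn`.
#' @param genes gene table (`gene_id`, `chrom`, `strand`, `tss`, `tes`).
#' @param baseline_ploidy neutral copy number (default 3).
#' @return data frame `gene`, `sample`, `copy_number`, `dosage_class`
#'   (`gain`/`loss`/`neutral`), `straddles_boundary`.
#' @export
genes_in_cna <- function(segments, genes, baseline_ploidy = 3) {
  out <- list()
  body <- gene_body_of(genes)
  for (s in unique(segments$sample)) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    tg <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$tss, genes$tss))
    gg <- GenomicRanges::GRanges(body$chrom, IRanges::IRanges(body$start, body$end))
    sg <- GenomicRanges::GRanges(seg$chrom, IRanges::IRanges(seg$start, seg$end))
    hit <- GenomicRanges::findOverlaps(tg, sg, select = "first")
    cn <- ifelse(is.na(hit), baseline_ploidy, seg$total_cn[hit])
    if (anyNA(hit))
      cd_log("sample %s: %d genes outside all segments set to baseline",
             s, sum(is.na(hit)))
    nseg <- GenomicRanges::countOverlaps(gg, sg)
    straddle <- nseg > 1
    out[[s]] <- data.frame(gene = genes$gene_id, sample = s,
                           copy_number = cn,
                           dosage_class = ifelse(cn > baseline_ploidy, "gain",
                                          ifelse(cn < baseline_ploidy, "loss",
                                                 "neutral")),
                           straddles_boundary = straddle,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Dosage effect on expression: one-sided KS against neutral genes
#'
#' Compares the distribution of expression change (focal minus other, log2
#' of mean normalized counts) of genes in gain regions against neutral
#' genes with the alternative "shifted up", and loss genes with "shifted
#' down". Genes with mean count < 1 in either compared sample, and genes
#' straddling a segment boundary, are excluded.
#'
#' @param dosage [genes_in_cna()] table for the focal sample.
#' @param means matrix genes x samples of mean normalized counts.
#' @param pair character(2): `(focal, other)`.
#' @return list with `D_gain`, `p_gain`, `D_loss`, `p_loss`, and class sizes;
#'   an empty class yields `NA` entries.
#' @export
ks_dosage_test <- function(dosage, means, pair) {
  stopifnot(all(pair %in% colnames(means)))
  d <- dosage[!dosage$straddles_boundary, , drop = FALSE]
  d <- d[d$gene %in% rownames(means), , drop = FALSE]
  ex <- means[d$gene, pair, drop = FALSE]
  keep <- ex[, 1] >= 1 & ex[, 2] >= 1
  d <- d[keep, , drop = FALSE]
  chg <- log2(ex[keep, 1]) - log2(ex[keep, 2])
  res <- list(D_gain = NA_real_, p_gain = NA_real_,
              D_loss = NA_real_, p_loss = NA_real_,
              n_gain = sum(d$dosage_class == "gain"),
              n_loss = sum(d$dosage_class == "loss"),
              n_neutral = sum(d$dosage_class == "neutral"))
  neutral <- chg[d$dosage_class == "neutral"]
  if (res$n_gain > 0 && res$n_neutral > 0) {
    ks <- ks_one_sided(chg[d$dosage_class == "gain"], neutral, "greater")
    res$D_gain <- ks$D; res$p_gain <- ks$p
  } else cd_log("gain class empty; KS test skipped")
  if (res$n_loss > 0 && res$n_neutral > 0) {
    ks <- ks_one_sided(chg[d$dosage_class == "loss"], neutral, "less")
    res$D_loss <- ks$D; res$p_loss <- ks$p
  } else cd_log("loss class empty; KS test skipped")
  res
}

#' Correlation between region methylation differences and expression change
#'
#' @param dmf [call_dmf()] table restricted to one category (promoters or
#'   gene bodies) with an `owner_id` gene column; only `is_dmf` rows are
#'   used.
#' @param log2_fc named numeric vector of expression log2 fold changes
#'   (same pair orientation as the DMF `delta_ml`).
#' @return list with `r`, `p`, `n`, and the paired `table` for plotting;
#'   `r = NA` with `degenerate = TRUE` when either vector has zero variance.
#' @export
dml_expression_correlation <- function(dmf, log2_fc) {
  d <- dmf[dmf$is_dmf & dmf$owner_id %in% names(log2_fc), , drop = FALSE]
  tab <- data.frame(gene = d$owner_id, delta_ml = d$delta_ml,
                    log2_fc = unname(log2_fc[d$owner_id]),
                    stringsAsFactors = FALSE)
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  if (nrow(tab) < 3) stop("fewer than 3 genes with both methylation and expression")
  if (stats::sd(tab$delta_ml) == 0 || stats::sd(tab$log2_fc) == 0) {
    cd_log("zero-variance vector in methylation-expression correlation")
    return(list(r = NA_real_, p = NA_real_, n = nrow(tab), table = tab,
                degenerate = TRUE))
  }
  ct <- stats::cor.test(tab$delta_ml, tab$log2_fc, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(tab), table = tab,
       degenerate = FALSE)
}

#' Sample-specific CNA genes
#'
#' A gene is focal-specific when the focal sample's copy number differs from
#' every other sample's and the other samples agree with each other
#' (relaxed mode: focal differs from the modal copy number of the others).
#'
#' @param dosage [genes_in_cna()] table over all samples.
#' @param focal focal sample name.
#' @param relaxed use the modal-copy-number rule.
#' @return data frame `gene`, `copy_number` (focal), `others_cn`,
#'   `delta_cn`, `direction`.
#' @export
sample_specific_cna_genes <- function(dosage, focal, relaxed = FALSE) {
  wide <- split(dosage, dosage$sample)
  samples <- names(wide)
  stopifnot(focal %in% samples)
  genes <- wide[[focal]]$gene
  cn <- vapply(wide, function(d) d$copy_number[match(genes, d$gene)],
               numeric(length(genes)))
  cn <- matrix(cn, nrow = length(genes), dimnames = list(genes, names(wide)))
  straddle <- Reduce(`|`, lapply(wide, function(d)
    d$straddles_boundary[match(genes, d$gene)]))
  others <- setdiff(samples, focal)
  cno <- cn[, others, drop = FALSE]
  if (relaxed) {
    ref <- apply(cno, 1, function(x) as.numeric(names(sort(table(x),
                                                           decreasing = TRUE))[1]))
    spec <- cn[, focal] != ref
  } else {
    agree <- apply(cno, 1, function(x) length(unique(x)) == 1)
    ref <- cno[, 1]
    spec <- agree & cn[, focal] != ref
  }
  spec <- spec & !straddle
  data.frame(gene = genes[spec],
             copy_number = cn[spec, focal],
             others_cn = ref[spec],
             delta_cn = cn[spec, focal] - ref[spec],
             direction = ifelse(cn[spec, focal] > ref[spec], "up", "down"),
             stringsAsFactors = FALSE)
}

#' Driven-gene accounting identity
#'
#' Percentages of direction-consistent genes among overlaps and the union
#' count `n_cna_consistent + n_dmgb_consistent - n_both`.
#'
#' @param n_cna_overlap,n_cna_consistent CNA genes overlapping DEGs, and the
#'   direction-consistent subset.
#' @param n_dmgb_overlap,n_dmgb_consistent same for gene-body methylation.
#' @param n_both genes consistent under both mechanisms.
#' @return list with `pct_cna`, `pct_dmgb` (percent, full precision),
#'   formatted 2-dp labels, and `n_union`.
#' @export
driven_summary <- function(n_cna_overlap, n_cna_consistent,
                           n_dmgb_overlap, n_dmgb_consistent, n_both) {
  stopifnot(n_cna_consistent <= n_cna_overlap,
            n_dmgb_consistent <= n_dmgb_overlap,
            n_both <= min(n_cna_consistent, n_dmgb_consistent))
  pct_cna <- if (n_cna_overlap > 0) 100 * n_cna_consistent / n_cna_overlap else NA
  pct_dmgb <- if (n_dmgb_overlap > 0) 100 * n_dmgb_consistent / n_dmgb_overlap else NA
  list(n_cna_overlap = n_cna_overlap, n_cna_consistent = n_cna_consistent,
       pct_cna = pct_cna, pct_cna_label = sprintf("%.2f%%", pct_cna),
       n_dmgb_overlap = n_dmgb_overlap, n_dmgb_consistent = n_dmgb_consistent,
       pct_dmgb = pct_dmgb, pct_dmgb_label = sprintf("%.2f%%", pct_dmgb),
       n_both = n_both,
       n_union = n_cna_consistent + n_dmgb_consistent - n_both)
}

#' Classify sample-specific DEGs as CNA-driven, methylation-driven, or both
#'
#' CNA-driven: the gene is a focal-specific CNA gene and a focal-specific
#' DEG whose expression change has the same sign as the copy-number change.
#' Methylation-driven: focal-specific differentially methylated gene body
#' with expression change of the same sign as the methylation change
#' (gene-body methylation couples positively to expression).
#'
#' @param cna_genes [sample_specific_cna_genes()] table (`gene`, `delta_cn`).
#' @param dmgb_genes data frame `gene`, `delta_ml` of focal-specific
#'   differentially methylated gene bodies (focal minus others orientation).
#' @param degs [sample_specific_degs()] table (`gene`, `log2_fc`).
#' @return list with `calls` (gene, mechanism, direction, evidence) and
#'   `summary` ([driven_summary()]).
#' @export
classify_driven <- function(cna_genes, dmgb_genes, degs) {
  deg_fc <- setNames(degs$log2_fc, degs$gene)
  cna_ov <- cna_genes[cna_genes$gene %in% degs$gene, , drop = FALSE]
  cna_cons <- cna_ov[sign(cna_ov$delta_cn) ==
                       sign(deg_fc[cna_ov$gene]), , drop = FALSE]
  dmgb_ov <- dmgb_genes[dmgb_genes$gene %in% degs$gene, , drop = FALSE]
  dmgb_cons <- dmgb_ov[sign(dmgb_ov$delta_ml) ==
                         sign(deg_fc[dmgb_ov$gene]), , drop = FALSE]
  both <- intersect(cna_cons$gene, dmgb_cons$gene)
  all_genes <- union(cna_cons$gene, dmgb_cons$gene)
  calls <- data.frame(
    gene = all_genes,
    mechanism = ifelse(all_genes %in% both, "both",
                ifelse(all_genes %in% cna_cons$gene, "cna", "methylation")),
    direction = ifelse(deg_fc[all_genes] > 0, "up", "down"),
    delta_cn = cna_cons$delta_cn[match(all_genes, cna_cons$gene)],
    delta_ml = dmgb_cons$delta_ml[match(all_genes, dmgb_cons$gene)],
    log2_fc = unname(deg_fc[all_genes]),
    stringsAsFactors = FALSE, row.names = NULL)
  list(calls = calls,
       summary = driven_summary(nrow(cna_ov), nrow(cna_cons),
                                nrow(dmgb_ov), nrow(dmgb_cons),
                                length(both)))
}

#' Overlap of sample-specific mutated genes with sample-specific DEGs
#'
#' Exact binomial test of the observed overlap against independent draws
#' from the gene universe; both enrichment and depletion tails reported.
#'
#' @param mutated_genes,deg_genes,universe character vectors of gene ids;
#'   the universe must contain both sets.
#' @return list with `k_observed`, `n`, `p0`, `expected`, and the three
#'   p-values of [binomial_overlap_test()].
#' @export
mutation_deg_overlap <- function(mutated_genes, deg_genes, universe) {
  if (!length(universe)) stop("empty gene universe")
  mutated_genes <- intersect(mutated_genes, universe)
  deg_genes <- intersect(deg_genes, universe)
  k <- length(intersect(mutated_genes, deg_genes))
  n <- length(mutated_genes)
  p0 <- length(deg_genes) / length(universe)
  c(list(k_observed = k, n = n, p0 = p0, expected = n * p0),
    binomial_overlap_test(k, n, p0))
}

#' Hypergeometric over-representation of gene sets
#'
#' @param gene_list character vector of genes of interest.
#' @param gene_sets named list of character vectors (e.g. read with
#'   [read_gmt()]).
#' @param universe background gene ids.
#' @return data frame `set`, `k` (hits), `K` (set size in universe), `n`
#'   (list size in universe), `N` (universe), `p` (one-sided
#'   hypergeometric), `q` (BH across sets). Sets with no universe members
#'   are skipped.
#' @export
gene_set_enrichment <- function(gene_list, gene_sets, universe) {
  gene_list <- intersect(gene_list, universe)
  n <- length(gene_list); N <- length(universe)
  rows <- lapply(names(gene_sets), function(nm) {
    K <- length(intersect(gene_sets[[nm]], universe))
    if (K == 0) { cd_log("set %s has no universe members; skipped", nm); return(NULL) }
    k <- length(intersect(gene_list, gene_sets[[nm]]))
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(set = character(), k = integer(),
                                      K = integer(), n = integer(),
                                      N = integer(), p = numeric(),
                                      q = numeric()))
  out$q <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}
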