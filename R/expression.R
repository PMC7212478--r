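#' Expression count normalization, DEG calling, and divergence
#'
#' Columns of a count matrix are sample replicates named `<sample>.rep<k>`;
#' a replicate map (column -> sample) can also be given explicitly.
#'
#' @name expression
NULL

#' Replicate map from column names
#' @param cols column names following the `sample.repN` convention.
#' @return named character vector column -> sample.
#' @export
replicate_map_from_names <- function(cols) {
  smp <- sub("\\.rep[0-9]+$", "", cols)
  if (any(smp == cols)) stop("columns not in 'sample.repN' form: ",
                             paste(cols[smp == cols], collapse = ", "))
  setNames(smp, cols)
}

#' Upper-quartile normalization
#'
#' Each column is scaled so that its 75th percentile over genes with nonzero
#' count in that column equals the across-column mean of the raw upper
#' quartiles.
#'
#' @param counts numeric matrix, genes x replicate columns.
#' @return list with `counts` (normalized matrix), `scale_factors`, and
#'   `target` (common upper quartile).
#' @export
upper_quartile_normalize <- function(counts) {
  counts <- as.matrix(counts)
  uq <- apply(counts, 2, function(x) {
    xs <- x[x > 0]
    if (!length(xs)) NA_real_ else stats::quantile(xs, 0.75, names = FALSE)
  })
  if (anyNA(uq) || any(uq <= 0))
    stop("all-zero column(s): ", paste(colnames(counts)[is.na(uq) | uq <= 0],
                                       collapse = ", "))
  target <- mean(uq)
  sf <- target / uq
  cd_log("upper-quartile scale factors: %s",
         paste(sprintf("%s=%.3f", colnames(counts), sf), collapse = ", "))
  list(counts = sweep(counts, 2, sf, `*`), scale_factors = sf, target = target)
}

#' Per-sample mean matrix from normalized replicate counts
#' @param norm normalized matrix, genes x replicate columns.
#' @param replicate_map named vector column -> sample.
#' @return matrix genes x samples of mean normalized counts.
#' @export
sample_means <- function(norm, replicate_map = NULL) {
  replicate_map <- replicate_map %||% replicate_map_from_names(colnames(norm))
  samples <- unique(unname(replicate_map[colnames(norm)]))
  out <- sapply(samples, function(s)
    rowMeans(norm[, names(replicate_map)[replicate_map == s], drop = FALSE]))
  matrix(out, nrow = nrow(norm), dimnames = list(rownames(norm), samples))
}

#' Genes expressed (mean normalized count > 1) in at least one sample
#' @param means matrix genes x samples of mean normalized counts.
#' @return character vector of gene ids.
#' @export
expressed_genes <- function(means) {
  rownames(means)[apply(means > 1, 1, any)]
}

## pooled method-of-moments NB dispersion across genes and conditions
.pooled_dispersion <- function(norm, groups) {
  num <- 0; den <- 0
  for (g in unique(groups)) {
    sub <- norm[, groups == g, drop = FALSE]
    if (ncol(sub) < 2) next
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    ok <- m > 0
    num <- num + sum(v[ok] - m[ok])
    den <- den + sum(m[ok]^2)
  }
  max(num / den, 0)
}

#' Pairwise differential expression on normalized counts
#'
#' Evidence score per gene: a two-sided test of equal means under an
#' overdispersed count model. A common dispersion is pooled across genes by
#' method of moments; per-condition log2 means are compared with a normal
#' approximation (delta method), p-values are Benjamini-Hochberg adjusted
#' across genes, and `score = 1 - adjusted p` so that `score > 0.99`
#' corresponds to adjusted p < 0.01. A gene is a DEG when the score gate and
#' the fold-change gate (`max(FC, 1/FC) > fc_threshold` on the ratio of
#' normalized means) both pass. This decision surface mirrors
#' posterior-probability + fold-change DEG calling with few replicates, but
#' the score is frequentist, not an empirical-Bayes posterior.
#'
#' @param norm normalized matrix, genes x replicate columns.
#' @param pair character(2): `(sample_a, sample_b)`; fold change is b over a.
#' @param replicate_map named vector column -> sample.
#' @param score_threshold DEG evidence gate (default 0.99).
#' @param fc_threshold DEG fold-change gate (default 1.5).
#' @return data frame: `gene`, `mean_a`, `mean_b`, `fold_change`, `log2_fc`,
#'   `p`, `score`, `is_deg`, with attributes `pair` and `dispersion`. Genes
#'   with zero mean in both samples are excluded.
#' @export
call_degs <- function(norm, pair, replicate_map = NULL,
                      score_threshold = 0.99, fc_threshold = 1.5) {
  replicate_map <- replicate_map %||% replicate_map_from_names(colnames(norm))
  stopifnot(length(pair) == 2, all(pair %in% replicate_map))
  ca <- names(replicate_map)[replicate_map == pair[1]]
  cb <- names(replicate_map)[replicate_map == pair[2]]
  if (length(ca) < 2 || length(cb) < 2) stop("need >= 2 replicates per sample")
  ma <- rowMeans(norm[, ca, drop = FALSE])
  mb <- rowMeans(norm[, cb, drop = FALSE])
  keep <- ma > 0 | mb > 0
  if (any(!keep)) cd_log("excluded %d genes with zero mean in both samples", sum(!keep))
  ma <- ma[keep]; mb <- mb[keep]
  phi <- .pooled_dispersion(norm[keep, c(ca, cb), drop = FALSE],
                            replicate_map[c(ca, cb)])
  eps <- 0.25  # pseudo-mean stabilizing logs and variances near zero
  la <- log2(ma + eps); lb <- log2(mb + eps)
  va <- (1 / (ma + eps) + phi) / (length(ca) * log(2)^2)
  vb <- (1 / (mb + eps) + phi) / (length(cb) * log(2)^2)
  z <- (lb - la) / sqrt(va + vb)
  p <- 2 * stats::pnorm(-abs(z))
  score <- 1 - bh_adjust(p)
  fc <- mb / ma  # Inf when ma == 0; gate below handles it
  fc_gate <- pmax(fc, 1 / fc) > fc_threshold
  out <- data.frame(gene = rownames(norm)[keep],
                    mean_a = ma, mean_b = mb,
                    fold_change = fc, log2_fc = lb - la,
                    p = p, score = score,
                    is_deg = score > score_threshold & fc_gate,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "pair") <- pair
  attr(out, "dispersion") <- phi
  out
}

#' Sample-specific DEGs: intersection over all comparisons against one focal
#' sample
#'
#' @param deg_tables list of [call_degs()] tables, each with
#'   `pair = c(other, focal)` for the same focal sample (fold change =
#'   focal / other).
#' @return data frame `gene`, `direction` (`up`/`down` in the focal sample;
#'   `NA` when discordant across comparisons), `discordant`, `log2_fc` (mean
#'   over the comparisons).
#' @export
sample_specific_degs <- function(deg_tables) {
  focal <- unique(vapply(deg_tables, function(d) attr(d, "pair")[2], character(1)))
  if (length(focal) != 1)
    stop("all DEG tables must share the same focal (second) sample")
  ids <- Reduce(intersect, lapply(deg_tables, function(d) d$gene[d$is_deg]))
  if (!length(ids))
    return(data.frame(gene = character(), direction = character(),
                      discordant = logical(), log2_fc = numeric()))
  lfc <- sapply(deg_tables, function(d) d$log2_fc[match(ids, d$gene)])
  lfc <- matrix(lfc, nrow = length(ids))
  up <- rowSums(lfc > 0) == ncol(lfc)
  down <- rowSums(lfc < 0) == ncol(lfc)
  data.frame(gene = ids,
             direction = ifelse(up, "up", ifelse(down, "down", NA_character_)),
             discordant = !(up | down),
             log2_fc = rowMeans(lfc),
             stringsAsFactors = FALSE)
}

#' Sample-by-sample transcriptome correlation
#'
#' Correlations of `log2(mean normalized count + 1)` across genes expressed
#' in at least one sample.
#'
#' @param means matrix genes x samples of mean normalized counts.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return symmetric correlation matrix.
#' @export
transcriptome_divergence <- function(means, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  keep <- expressed_genes(means)
  if (length(keep) < 3) stop("fewer than 3 expressed genes")
  stats::cor(log2(means[keep, , drop = FALSE] + 1), method = method)
}

#' Agglomerative clustering of sample profiles
#'
#' Complete-linkage clustering on Euclidean distances between sample columns
#' (the defaults of the heatmap-clustering tool commonly used for such
#' panels); the dendrogram is also serialized as Newick.
#'
#' @param values numeric matrix, features x samples.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list with `hclust`, `newick`, `merges` (data frame of merge
#'   steps), and helpers-ready labels.
#' @export
hierarchical_cluster <- function(values, linkage = "complete") {
  if (ncol(values) < 2 || nrow(values) < 3)
    stop("need >= 2 samples and >= 3 features")
  hc <- stats::hclust(stats::dist(t(values)), method = linkage)
  ph <- ape::as.phylo(hc)
  list(hclust = hc,
       newick = ape::write.tree(ph),
       merges = data.frame(step = seq_len(nrow(hc$merge)),
                           a = hc$merge[, 1], b = hc$merge[, 2],
                           height = hc$height))
}

#' Labels merged at the first agglomeration step
#' @param cl result of [hierarchical_cluster()] (or an `hclust`).
#' @return character(2) of the two labels merging first.
#' @export
first_merge_pair <- function(cl) {
  hc <- if (inherits(cl, "hclust")) cl else cl$hclust
  sort(hc$labels[-hc$merge[1, ]])
}

#' Label of the sample joining the tree last (if the final merge attaches a
#' singleton), else `NA`.
#' @inheritParams first_merge_pair
#' @export
last_joined <- function(cl) {
  hc <- if (inherits(cl, "hclust")) cl else cl$hclust
  last <- hc$merge[nrow(hc$merge), ]
  singles <- last[last < 0]
  if (length(singles) == 1) hc$labels[-singles] else NA_character_
}
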