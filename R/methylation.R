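#' CpG methylation: site table, differential calls, region summaries
#'
#' The site table is a wide data frame with `chrom`, `pos` and per sample
#' `meth_<s>`, `total_<s>`, `level_<s>` columns, restricted to CpG sites
#' covered by more than `min_depth` reads in every sample.
#'
#' @name methylation
NULL

.meth_samples <- function(tab) sub("^level_", "", grep("^level_", names(tab), value = TRUE))

#' Load per-sample coverage files and filter to well-covered common sites
#'
#' Input follows the Bismark coverage layout: chrom, start (1-based), end,
#' methylation percentage, methylated count, unmethylated count.
#'
#' @param files named character vector (name = sample) of coverage file
#'   paths, or a named list of data frames with columns `chrom`, `pos`,
#'   `meth`, `unmeth`.
#' @param min_depth retain sites with total reads strictly greater than this
#'   in *every* sample (default 10).
#' @param merge_strands merge records at adjacent positions (the two
#'   cytosines of one CpG reported per strand) into one site at the lower
#'   position before filtering.
#' @return site table (see [methylation]).
#' @export
load_and_filter_sites <- function(files, min_depth = 10, merge_strands = TRUE) {
  if (is.null(names(files)) || any(!nzchar(names(files))))
    stop("'files' must be named by sample")
  tabs <- lapply(seq_along(files), function(i) {
    f <- files[[i]]
    if (is.data.frame(f)) {
      df <- data.table::as.data.table(f)
    } else {
      df <- data.table::fread(f, header = FALSE,
                              col.names = c("chrom", "pos", "end", "pct",
                                            "meth", "unmeth"))
      df <- df[, c("chrom", "pos", "meth", "unmeth")]
    }
    bad <- which(df$meth < 0 | df$unmeth < 0)
    if (length(bad))
      stop(sprintf("negative counts in sample %s at line %d",
                   names(files)[i], bad[1]))
    if (merge_strands) {
      data.table::setorderv(df, c("chrom", "pos"))
      d <- c(Inf, diff(df$pos))
      same <- c(FALSE, df$chrom[-1] == df$chrom[-nrow(df)])
      pair2 <- d == 1 & same
      pair2 <- pair2 & !c(FALSE, pair2[-length(pair2)])  # greedy, no chains
      idx <- seq_len(nrow(df))
      grp <- idx
      grp[pair2] <- idx[pair2] - 1L
      df <- df[, .(pos = pos[1], meth = sum(meth), unmeth = sum(unmeth)),
               by = .(chrom, grp)][, c("chrom", "pos", "meth", "unmeth")]
    }
    df
  })
  names(tabs) <- names(files)
  merged <- NULL
  for (s in names(tabs)) {
    t <- tabs[[s]]
    data.table::setnames(t, c("meth", "unmeth"),
                         c(paste0("meth_", s), paste0("u_", s)))
    merged <- if (is.null(merged)) t else
      merge(merged, t, by = c("chrom", "pos"))
  }
  merged <- as.data.frame(merged)
  keep <- rep(TRUE, nrow(merged))
  for (s in names(tabs)) {
    tot <- merged[[paste0("meth_", s)]] + merged[[paste0("u_", s)]]
    keep <- keep & tot > min_depth
  }
  cd_log("retained %d / %d common sites at depth > %d in all samples",
         sum(keep), nrow(merged), min_depth)
  out <- merged[keep, , drop = FALSE]
  for (s in names(tabs)) {
    tot <- out[[paste0("meth_", s)]] + out[[paste0("u_", s)]]
    out[[paste0("total_", s)]] <- tot
    out[[paste0("level_", s)]] <- out[[paste0("meth_", s)]] / tot
    out[[paste0("u_", s)]] <- NULL
  }
  rownames(out) <- NULL
  out
}

#' Differentially methylated sites (Fisher exact + Benjamini-Hochberg)
#'
#' Per site, a two-sided Fisher exact test on the 2x2 table of
#' methylated/unmethylated counts in the two samples; adjustment is across
#' all retained sites of the comparison.
#'
#' @param tab site table.
#' @param pair character(2) of sample names; `delta_ml` is level(b) -
#'   level(a).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return data frame `chrom`, `pos`, `level_a`, `level_b`, `delta_ml`, `p`,
#'   `p_adj`, `is_dms`.
#' @export
call_dms <- function(tab, pair, alpha = 0.05) {
  stopifnot(length(pair) == 2, all(paste0("level_", pair) %in% names(tab)))
  m1 <- tab[[paste0("meth_", pair[1])]]
  t1 <- tab[[paste0("total_", pair[1])]]
  m2 <- tab[[paste0("meth_", pair[2])]]
  t2 <- tab[[paste0("total_", pair[2])]]
  p <- fisher_exact_2x2(m1, t1 - m1, m2, t2 - m2)
  padj <- bh_adjust(p)
  data.frame(chrom = tab$chrom, pos = tab$pos,
             level_a = m1 / t1, level_b = m2 / t2,
             delta_ml = m2 / t2 - m1 / t1,
             p = p, p_adj = padj, is_dms = padj < alpha,
             stringsAsFactors = FALSE)
}

#' Region-level methylation from site levels
#'
#' Per sample, the unweighted mean of site levels over sites inside each
#' region, plus pooled read counts (used by the region-level Fisher test).
#'
#' @param tab site table.
#' @param regions data frame `region_id`, `chrom`, `start`, `end`, and
#'   optionally `category`, `owner_id`.
#' @param min_sites regions with fewer retained sites are reported with
#'   `ok = FALSE`.
#' @return data frame with one row per region: `n_sites`, per-sample
#'   `level_<s>`, `meth_<s>`, `total_<s>`, and `ok`.
#' @export
region_levels <- function(tab, regions, min_sites = 3) {
  samples <- .meth_samples(tab)
  sg <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$pos, tab$pos))
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  ov <- GenomicRanges::findOverlaps(sg, rg)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  out <- regions[, intersect(c("region_id", "category", "owner_id", "chrom",
                               "start", "end"), names(regions)), drop = FALSE]
  out$n_sites <- tabulate(sh, nbins = nrow(regions))
  for (s in samples) {
    lv <- tab[[paste0("level_", s)]]
    mc <- tab[[paste0("meth_", s)]]
    tc <- tab[[paste0("total_", s)]]
    sums <- function(x) {
      v <- numeric(nrow(regions))
      agg <- rowsum(x[qh], sh)
      v[as.integer(rownames(agg))] <- agg[, 1]
      v
    }
    out[[paste0("level_", s)]] <- ifelse(out$n_sites > 0,
                                         sums(lv) / out$n_sites, NA_real_)
    out[[paste0("meth_", s)]] <- sums(mc)
    out[[paste0("total_", s)]] <- sums(tc)
  }
  out$ok <- out$n_sites >= min_sites
  if (any(!out$ok))
    cd_log("%d regions below min_sites=%d reported as missing",
           sum(!out$ok), min_sites)
  out
}

#' Differentially methylated functional categories (regions)
#'
#' A region is differentially methylated between two samples when the
#' difference in mean site-level methylation exceeds `delta` and a two-sided
#' Fisher exact test on the pooled methylated/unmethylated counts of its
#' sites gives p < `alpha` (unadjusted). Promoter- and gene-body-restricted
#' subsets of this call are the DMP and DMGB sets.
#'
#' @param reg output of [region_levels()].
#' @param pair character(2); `delta_ml` is level(b) - level(a).
#' @param delta methylation-difference gate (default 0.20).
#' @param alpha Fisher p cutoff (default 0.05).
#' @return `reg` restricted to usable regions, with `delta_ml`, `p`,
#'   `is_dmf` columns added.
#' @export
call_dmf <- function(reg, pair, delta = 0.20, alpha = 0.05) {
  stopifnot(all(paste0("level_", pair) %in% names(reg)))
  reg <- reg[reg$ok, , drop = FALSE]
  m1 <- reg[[paste0("meth_", pair[1])]]
  t1 <- reg[[paste0("total_", pair[1])]]
  m2 <- reg[[paste0("meth_", pair[2])]]
  t2 <- reg[[paste0("total_", pair[2])]]
  dml <- reg[[paste0("level_", pair[2])]] - reg[[paste0("level_", pair[1])]]
  p <- fisher_exact_2x2(round(m1), round(t1 - m1), round(m2), round(t2 - m2))
  reg$delta_ml <- dml
  reg$p <- p
  reg$is_dmf <- abs(dml) > delta & p < alpha
  reg
}

#' Genome-wide paired comparison and mean methylation level
#'
#' @param tab site table.
#' @param pair character(2) of samples; Wilcoxon signed-rank on per-site
#'   level differences (zero differences dropped).
#' @return list with `statistic`, `p`, `all_equal` flag.
#' @export
global_compare <- function(tab, pair) {
  a <- tab[[paste0("level_", pair[1])]]
  b <- tab[[paste0("level_", pair[2])]]
  if (length(a) < 10) stop("need >= 10 common sites")
  if (all(a == b))
    return(list(statistic = NA_real_, p = 1, all_equal = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, all_equal = FALSE)
}

#' @rdname global_compare
#' @param sample sample name.
#' @return `genome_mean`: unweighted mean of site levels.
#' @export
genome_mean <- function(tab, sample) {
  mean(tab[[paste0("level_", sample)]])
}

#' Hierarchical clustering of methylomes
#'
#' Clusters samples on per-site methylation levels, either over all common
#' sites or over a differentially-methylated-site subset; both give the same
#' sample grouping when divergence is genuine.
#'
#' @param tab site table.
#' @param sites optional logical/integer index restricting to a site subset
#'   (e.g. the union of DMS calls across pairs).
#' @param linkage linkage method.
#' @return as [hierarchical_cluster()].
#' @export
cluster_methylomes <- function(tab, sites = NULL, linkage = "complete") {
  samples <- .meth_samples(tab)
  if (length(samples) < 2) stop("need >= 2 samples")
  if (!is.null(sites)) tab <- tab[sites, , drop = FALSE]
  if (nrow(tab) < 3) stop("need >= 3 sites")
  m <- as.matrix(tab[, paste0("level_", samples), drop = FALSE])
  colnames(m) <- samples
  hierarchical_cluster(m, linkage = linkage)
}
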