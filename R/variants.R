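#' Somatic SNV filtering and presence/absence coding
#'
#' An SNV table holds one row per candidate variant with per-sample
#' strand-split variant read counts and total depth, plus variant reads in
#' the matched normal. Column convention: `<sample>_var_fwd`,
#' `<sample>_var_rev`, `<sample>_depth`, and `normal_var`, `normal_depth`.
#'
#' @name variants
NULL

snv_sample_names <- function(snv) {
  cols <- grep("_var_fwd$", names(snv), value = TRUE)
  sub("_var_fwd$", "", cols)
}

#' Filter somatic SNVs and flag per-sample presence
#'
#' A variant is *present* in a tumor sample when its variant allele fraction
#' exceeds `min_vaf`, its variant reads exceed `min_reads`, and it has
#' double-strand support (at least one forward and one reverse variant read;
#' `per_strand_min` raises that floor). A variant is *retained* when present
#' in at least one sample and supported by zero variant reads in the matched
#' normal.
#'
#' @param snv SNV table (see [variants]).
#' @param samples sample names to evaluate; defaults to all found in the
#'   table.
#' @param min_vaf presence requires variant reads / depth strictly greater
#'   than this (default 0.10).
#' @param min_reads presence requires variant reads strictly greater than
#'   this (default 5).
#' @param per_strand_min minimum variant reads required on *each* strand
#'   (default 1; set higher to read the double-strand rule as per-strand).
#' @return list with `snv` (retained rows), `presence` (logical matrix
#'   variants x samples with rownames `chrom:pos`), and `n_rejected`
#'   (malformed rows dropped).
#' @export
filter_snvs <- function(snv, samples = NULL, min_vaf = 0.10, min_reads = 5,
                        per_strand_min = 1) {
  samples <- samples %||% snv_sample_names(snv)
  if (!length(samples)) stop("no per-sample count columns found")
  if (nrow(snv) == 0)
    return(list(snv = snv,
                presence = matrix(FALSE, 0, length(samples),
                                  dimnames = list(NULL, samples)),
                n_rejected = 0L))
  ## reject malformed rows: negative counts or depth < variant reads
  bad <- rep(FALSE, nrow(snv))
  for (s in samples) {
    vf <- snv[[paste0(s, "_var_fwd")]]
    vr <- snv[[paste0(s, "_var_rev")]]
    dp <- snv[[paste0(s, "_depth")]]
    bad <- bad | vf < 0 | vr < 0 | dp < vf + vr
  }
  if (any(bad)) cd_log("rejected %d malformed SNV rows", sum(bad))
  snv <- snv[!bad, , drop = FALSE]
  if (nrow(snv) == 0)
    return(list(snv = snv,
                presence = matrix(FALSE, 0, length(samples),
                                  dimnames = list(NULL, samples)),
                n_rejected = sum(bad)))
  pres <- sapply(samples, function(s) {
    vf <- snv[[paste0(s, "_var_fwd")]]
    vr <- snv[[paste0(s, "_var_rev")]]
    dp <- snv[[paste0(s, "_depth")]]
    v <- vf + vr
    vaf <- ifelse(dp > 0, v / dp, 0)
    vaf > min_vaf & v > min_reads & vf >= per_strand_min & vr >= per_strand_min
  })
  pres <- matrix(pres, nrow = nrow(snv),
                 dimnames = list(paste0(snv$chrom, ":", snv$pos), samples))
  keep <- rowSums(pres) >= 1 & snv$normal_var == 0
  cd_log("retained %d / %d SNVs after somatic filter", sum(keep), nrow(snv))
  list(snv = snv[keep, , drop = FALSE],
       presence = pres[keep, , drop = FALSE],
       n_rejected = sum(bad))
}

#' Partition variants into commonly shared vs polymorphic
#'
#' @param presence logical matrix variants x samples.
#' @return list with `shared` and `polymorphic` variant id vectors and their
#'   counts.
#' @export
classify_shared_polymorphic <- function(presence) {
  if (!nrow(presence)) stop("empty presence matrix")
  ns <- rowSums(presence)
  shared <- rownames(presence)[ns == ncol(presence)]
  poly <- rownames(presence)[ns >= 1 & ns < ncol(presence)]
  list(shared = shared, polymorphic = poly,
       n_shared = length(shared), n_polymorphic = length(poly))
}

#' Exclude variants falling in LOH regions
#'
#' Loss of heterozygosity (B-allele copy number 0) in any sample can delete
#' the mutant allele and corrupt presence/absence coding for the whole panel,
#' so by default a variant inside an LOH segment of *any* sample is removed.
#'
#' @param snv SNV table with `chrom`, `pos`.
#' @param segments copy-number segment table: `sample`, `chrom`, `start`,
#'   `end`, `total_cn`, `b_allele_cn`.
#' @param samples samples whose LOH segments are honored (default: all in
#'   `segments`).
#' @param per_sample if `TRUE`, return instead a logical matrix marking, per
#'   sample, which variants sit in that sample's LOH regions (the relaxed
#'   masking mode).
#' @return logical vector (`TRUE` = keep) aligned with `snv` rows, or the
#'   per-sample matrix when `per_sample = TRUE`.
#' @export
mask_loh <- function(snv, segments, samples = NULL, per_sample = FALSE) {
  samples <- samples %||% unique(segments$sample)
  loh <- segments[segments$b_allele_cn == 0 & segments$sample %in% samples, ,
                  drop = FALSE]
  if (!nrow(snv)) return(logical(0))
  in_loh_for <- function(seg) {
    if (!nrow(seg)) return(rep(FALSE, nrow(snv)))
    sg <- GenomicRanges::GRanges(snv$chrom, IRanges::IRanges(snv$pos, snv$pos))
    lg <- GenomicRanges::GRanges(seg$chrom, IRanges::IRanges(seg$start, seg$end))
    GenomicRanges::countOverlaps(sg, lg) > 0
  }
  if (per_sample) {
    m <- sapply(samples, function(s) in_loh_for(loh[loh$sample == s, , drop = FALSE]))
    return(matrix(m, nrow = nrow(snv),
                  dimnames = list(paste0(snv$chrom, ":", snv$pos), samples)))
  }
  hit <- in_loh_for(loh)
  cd_log("excluded %d / %d variants in LOH regions", sum(hit), nrow(snv))
  !hit
}

#' Percentage of shared events, formatted as in summary reporting
#'
#' @param k number of shared events.
#' @param n total number of events.
#' @param digits decimal places for the label.
#' @return list with `fraction`, `percent`, and a formatted `label`.
#' @export
percent_shared <- function(k, n, digits = 2) {
  stopifnot(n > 0, k >= 0, k <= n)
  pct <- 100 * k / n
  list(fraction = k / n, percent = pct,
       label = sprintf(paste0("%.", digits, "f%%"), pct))
}
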