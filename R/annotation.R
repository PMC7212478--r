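#' Functional genomic category geometry
#'
#' Categories are defined on 1-based inclusive coordinates. A promoter spans
#' 1500 bp upstream to 500 bp downstream of the transcription start site
#' (strand-aware, 2001 bp before clipping to chromosome bounds); a gene body
#' spans TSS to TES; CpG-island (CGI) shores are the 2-kb flanks of an island
#' and shelves the 2-kb flanks of the shores, with overlap precedence
#' island > shore > shelf.
#'
#' @name annotation-geometry
NULL

.new_category <- function(category, chrom, start, end, owner_id = "") {
  data.frame(category = category, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             owner_id = owner_id, stringsAsFactors = FALSE)
}

.check_genes <- function(genes) {
  req <- c("gene_id", "chrom", "strand", "tss", "tes")
  miss <- setdiff(req, names(genes))
  if (length(miss)) stop("gene table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  invisible(genes)
}

#' Promoter interval of one or more genes
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `tes`. `tss`/`tes` are genomic coordinates in transcription orientation
#'   (`tss > tes` on the minus strand).
#' @param chrom_lengths optional named integer vector of chromosome lengths
#'   used to clip intervals; unnamed chromosomes are left unclipped.
#' @param upstream,downstream extent of the promoter relative to the TSS in
#'   the gene's reading direction (bp).
#' @return data frame of category intervals (`category`, `chrom`, `start`,
#'   `end`, `owner_id`), one row per gene.
#' @export
promoter_of <- function(genes, chrom_lengths = NULL,
                        upstream = 1500, downstream = 500) {
  .check_genes(genes)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end   <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  if (!is.null(chrom_lengths)) {
    len <- unname(chrom_lengths[genes$chrom])
    if (any(!is.na(len) & (genes$tss < 1 | genes$tss > len)))
      stop("TSS outside chromosome bounds for gene(s): ",
           paste(genes$gene_id[!is.na(len) & (genes$tss < 1 | genes$tss > len)],
                 collapse = ", "))
    end <- ifelse(is.na(len), end, pmin(end, len))
  }
  start <- pmax(start, 1L)
  .new_category("promoter", genes$chrom, start, end, genes$gene_id)
}

#' Gene-body interval (TSS to TES, orientation-normalized)
#'
#' @inheritParams promoter_of
#' @return data frame of category intervals, one row per gene. A zero-length
#'   body (`tss == tes`) is kept as a single-position interval and logged.
#' @export
gene_body_of <- function(genes) {
  .check_genes(genes)
  start <- pmin(genes$tss, genes$tes)
  end <- pmax(genes$tss, genes$tes)
  if (any(start == end))
    cd_log("%d zero-length gene bodies kept as single positions", sum(start == end))
  .new_category("gene_body", genes$chrom, start, end, genes$gene_id)
}

#' CGI shores and shelves from island intervals
#'
#' Shores are the two 2-kb flanks of each island minus island bases; shelves
#' are the 2-kb flanks of the shores minus island and shore bases, so every
#' base belongs to at most one of island/shore/shelf.
#'
#' @param cgis data frame with columns `chrom`, `start`, `end` and optionally
#'   `cgi_id`; islands must not overlap within a chromosome.
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   clipping.
#' @param flank flank width in bp (default 2000).
#' @return data frame of `cgi_shore` and `cgi_shelf` category intervals;
#'   `owner_id` is the id of the nearest island.
#' @export
cgi_context <- function(cgis, chrom_lengths = NULL, flank = 2000) {
  if (nrow(cgis) == 0)
    return(.new_category(character(), character(), integer(), integer(), character()))
  if (is.null(cgis$cgi_id)) cgis$cgi_id <- sprintf("cgi_%05d", seq_len(nrow(cgis)))
  out <- list()
  for (chr in unique(cgis$chrom)) {
    ci <- cgis[cgis$chrom == chr, , drop = FALSE]
    ci <- ci[order(ci$start), , drop = FALSE]
    isl <- IRanges::IRanges(ci$start, ci$end)
    ov <- IRanges::findOverlaps(isl, isl)
    bad <- S4Vectors::queryHits(ov) != S4Vectors::subjectHits(ov)
    if (any(bad))
      stop("overlapping CGIs on ", chr, ": ",
           paste(unique(ci$cgi_id[S4Vectors::queryHits(ov)[bad]]), collapse = ", "))
    lim <- if (!is.null(chrom_lengths) && chr %in% names(chrom_lengths))
      chrom_lengths[[chr]] else max(ci$end) + 2L * flank
    shore_cand <- c(IRanges::IRanges(ci$start - flank, ci$start - 1L),
                    IRanges::IRanges(ci$end + 1L, ci$end + flank))
    shore_cand <- IRanges::restrict(shore_cand, start = 1L, end = as.integer(lim))
    shores <- IRanges::setdiff(IRanges::reduce(shore_cand), isl)
    shelf_cand <- c(IRanges::IRanges(ci$start - 2L * flank, ci$start - flank - 1L),
                    IRanges::IRanges(ci$end + flank + 1L, ci$end + 2L * flank))
    shelf_cand <- IRanges::restrict(shelf_cand, start = 1L, end = as.integer(lim))
    shelves <- IRanges::setdiff(IRanges::reduce(shelf_cand),
                                IRanges::union(isl, shores))
    owner <- function(ir) {
      if (length(ir) == 0) return(character())
      near <- IRanges::nearest(ir, isl)
      ci$cgi_id[near]
    }
    if (length(shores))
      out[[length(out) + 1L]] <- .new_category(
        "cgi_shore", chr, IRanges::start(shores), IRanges::end(shores), owner(shores))
    if (length(shelves))
      out[[length(out) + 1L]] <- .new_category(
        "cgi_shelf", chr, IRanges::start(shelves), IRanges::end(shelves), owner(shelves))
  }
  if (!length(out))
    return(.new_category(character(), character(), integer(), integer(), character()))
  do.call(rbind, out)
}

#' Assign positions to category intervals
#'
#' Multi-membership is allowed: a site belongs to every interval containing
#' it. Sites contained in no interval are labeled `intergenic`.
#'
#' @param sites data frame with columns `chrom`, `pos` (1-based).
#' @param categories data frame of category intervals as produced by
#'   [promoter_of()], [gene_body_of()], [cgi_context()], or assembled by hand.
#' @return long-format data frame (`chrom`, `pos`, `category`, `owner_id`),
#'   one row per (site, matching category), with `intergenic` rows for
#'   unmatched sites.
#' @export
assign_sites <- function(sites, categories) {
  if (nrow(sites) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      category = character(), owner_id = character()))
  unknown <- setdiff(unique(sites$chrom), unique(categories$chrom))
  if (length(unknown))
    cd_log("sites on chromosome(s) %s have no annotation; labeled intergenic",
           paste(unknown, collapse = ","))
  sg <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  cg <- GenomicRanges::GRanges(categories$chrom,
                               IRanges::IRanges(categories$start, categories$end))
  ov <- GenomicRanges::findOverlaps(sg, cg)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  hit <- data.frame(chrom = sites$chrom[qh], pos = sites$pos[qh],
                    category = categories$category[sh],
                    owner_id = categories$owner_id[sh],
                    stringsAsFactors = FALSE)
  orphan <- setdiff(seq_len(nrow(sites)), unique(qh))
  if (length(orphan))
    hit <- rbind(hit, data.frame(chrom = sites$chrom[orphan],
                                 pos = sites$pos[orphan],
                                 category = "intergenic", owner_id = "",
                                 stringsAsFactors = FALSE))
  hit[order(match(hit$chrom, unique(sites$chrom)), hit$pos), , drop = FALSE]
}
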