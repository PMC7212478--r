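#' Readers and writers for the standard formats
#'
#' Internal coordinates are 1-based inclusive; BED input/output is 0-based
#' half-open and converted exactly at this boundary. All tables are plain
#' tab-separated text.
#'
#' @name io
NULL

#' @rdname io
#' @param x data frame to write.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' @rdname io
#' @export
read_snv_table <- function(path) {
  df <- read_tsv(path)
  req <- c("chrom", "pos", "ref", "alt", "normal_var")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(path, ": missing SNV columns ",
                         paste(miss, collapse = ", "))
  if (is.unsorted(order(df$chrom, df$pos))) df <- df[order(df$chrom, df$pos), ]
  df
}

#' @rdname io
#' @export
read_seg <- function(path, sample = NULL) {
  df <- read_tsv(path)
  req <- c("chrom", "start", "end", "total_cn", "b_allele_cn")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(path, ": missing SEG columns ",
                         paste(miss, collapse = ", "))
  bad <- which(df$b_allele_cn > df$total_cn | df$start > df$end)
  if (length(bad))
    stop(sprintf("%s: invalid segment at line %d", path, bad[1] + 1L))
  df$sample <- sample %||% sub("\\.seg$", "", basename(path))
  df[, c("sample", req)]
}

#' @rdname io
#' @param cov data frame `chrom`, `pos`, `meth`, `unmeth`; rows with zero
#'   coverage are omitted on write (the coverage format lists covered sites
#'   only).
#' @export
write_coverage <- function(cov, path) {
  cov <- cov[cov$meth + cov$unmeth > 0, , drop = FALSE]
  out <- data.frame(chrom = cov$chrom, start = cov$pos, end = cov$pos,
                    pct = round(100 * cov$meth / (cov$meth + cov$unmeth), 6),
                    meth = cov$meth, unmeth = cov$unmeth)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param counts integer matrix genes x replicate columns.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname io
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname io
#' @param genes gene table; the exon list is serialized as
#'   `start-end;start-end`.
#' @export
write_genes <- function(genes, path) {
  out <- genes[, c("gene_id", "chrom", "strand", "tss", "tes")]
  lo <- pmin(genes$tss, genes$tes); hi <- pmax(genes$tss, genes$tes)
  n_ex <- genes$n_exons %||% rep(1L, nrow(genes))
  out$exons <- vapply(seq_len(nrow(genes)), function(i) {
    k <- n_ex[i]
    cuts <- round(seq(lo[i], hi[i], length.out = 2 * k))
    paste(sprintf("%d-%d", cuts[seq(1, 2 * k, by = 2)],
                  cuts[seq(2, 2 * k, by = 2)]), collapse = ";")
  }, character(1))
  write_tsv(out, path)
}

#' @rdname io
#' @export
read_genes <- function(path) {
  df <- read_tsv(path)
  req <- c("gene_id", "chrom", "strand", "tss", "tes")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(path, ": missing gene columns ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname io
#' @param intervals data frame `chrom`, `start`, `end` in 1-based inclusive
#'   coordinates.
#' @param names optional BED name column.
#' @export
write_bed <- function(intervals, path, names = NULL) {
  out <- data.frame(chrom = intervals$chrom,
                    start = intervals$start - 1L,  # 1-based -> 0-based half-open
                    end = intervals$end)
  if (!is.null(names)) out$name <- names
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_bed <- function(path) {
  df <- data.table::fread(path, header = FALSE, sep = "\t")
  df <- as.data.frame(df)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  bad <- which(df$start < 0 | df$end <= df$start)
  if (length(bad)) stop(sprintf("%s: malformed BED interval at line %d",
                                path, bad[1]))
  df$start <- df$start + 1L  # 0-based half-open -> 1-based inclusive
  df
}

#' @rdname io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop(path, ": GMT line with fewer than 3 fields")
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' @rdname io
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1)), path)
  invisible(path)
}
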