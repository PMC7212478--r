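#' End-to-end pipeline orchestration
#'
#' Runs the stages in dependency order on one output directory:
#' `simulate` writes the synthetic bundle; `variants` filters SNVs, masks
#' LOH, and builds the presence matrix; `phylogeny` runs the exhaustive
#' Wagner parsimony search; `expression` normalizes counts and calls
#' (sample-specific) DEGs; `methylation` builds the site table, region
#' levels, and differential calls; `integrate` joins the three layers into
#' driven-gene calls and dosage/correlation tests; `report` writes a summary
#' text block. Every artifact is recorded in a manifest with content hashes.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param simulate a [sim_config()] used by the `simulate` stage (and the
#'   source of sample names, outgroup, and ploidy).
#' @param outdir output directory.
#' @param min_vaf,min_reads SNV presence thresholds.
#' @param min_depth CpG site depth threshold.
#' @param delta,alpha region methylation-difference and test thresholds.
#' @param score_threshold,fc_threshold DEG thresholds.
#' @param min_sites minimum CpG sites per reported region.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(), outdir = tempfile("clonediverge_"),
                            min_vaf = 0.10, min_reads = 5, min_depth = 10,
                            delta = 0.20, alpha = 0.05,
                            score_threshold = 0.99, fc_threshold = 1.5,
                            min_sites = 3) {
  structure(as.list(environment()), class = "pipeline_config")
}

.need <- function(path, stage) {
  if (!file.exists(path))
    stop("missing artifact '", basename(path), "': run stage '", stage,
         "' first", call. = FALSE)
  path
}

#' Run pipeline stages
#'
#' @param config a [pipeline_config()].
#' @param stages subset of `c("simulate", "variants", "phylogeny",
#'   "expression", "methylation", "integrate", "report")`, executed in
#'   canonical order.
#' @return invisibly, a list of per-stage results, with the artifact
#'   manifest in `$manifest`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "variants", "phylogeny",
                                    "expression", "methylation", "integrate",
                                    "report")) {
  all_stages <- c("simulate", "variants", "phylogeny", "expression",
                  "methylation", "integrate", "report")
  stages <- all_stages[all_stages %in% match.arg(stages, all_stages,
                                                 several.ok = TRUE)]
  cfg <- config$simulate
  focal <- cfg$focal_sample
  dd <- file.path(config$outdir, "data")
  rd <- file.path(config$outdir, "results")
  dir.create(rd, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  artifacts <- character(0)
  art <- function(p) { artifacts <<- c(artifacts, p); p }

  if ("simulate" %in% stages) {
    truth <- generate_truth(cfg)
    man <- render_dataset(truth, dd)
    artifacts <- c(artifacts, man$file)
    res$truth <- truth
  }

  if ("variants" %in% stages) {
    snv <- read_snv_table(.need(file.path(dd, "snv_table.tsv"), "simulate"))
    segs <- do.call(rbind, lapply(cfg$samples, function(s)
      read_seg(.need(file.path(dd, paste0(s, ".seg")), "simulate"), sample = s)))
    filt <- filter_snvs(snv, samples = cfg$samples,
                        min_vaf = config$min_vaf, min_reads = config$min_reads)
    keep <- mask_loh(filt$snv, segs, samples = cfg$samples)
    shared <- classify_shared_polymorphic(filt$presence)
    pres <- filt$presence[keep, , drop = FALSE]
    write_tsv(data.frame(variant = rownames(pres), pres * 1L),
              art(file.path(rd, "presence_masked.tsv")))
    res$variants <- list(presence = filt$presence, presence_masked = pres,
                         shared = shared, segments = segs,
                         n_masked = sum(!keep))
  }

  if ("phylogeny" %in% stages) {
    pres <- res$variants$presence_masked
    if (is.null(pres)) {
      pm <- read_tsv(.need(file.path(rd, "presence_masked.tsv"), "variants"))
      pres <- as.matrix(pm[, -1, drop = FALSE]) > 0
      rownames(pres) <- pm$variant
    }
    tree <- wagner_tree(pres, outgroup = cfg$outgroup)
    writeLines(tree$newick, art(file.path(rd, "tree.nwk")))
    res$phylogeny <- tree
  }

  if ("expression" %in% stages) {
    counts <- read_counts(.need(file.path(dd, "counts.tsv"), "simulate"))
    uq <- upper_quartile_normalize(counts)
    means <- sample_means(uq$counts)
    others <- setdiff(cfg$samples, focal)
    degs <- lapply(others, function(o)
      call_degs(uq$counts, pair = c(o, focal),
                score_threshold = config$score_threshold,
                fc_threshold = config$fc_threshold))
    spec <- sample_specific_degs(degs)
    corr <- transcriptome_divergence(means)
    cl <- hierarchical_cluster(
      log2(means[expressed_genes(means), , drop = FALSE] + 1))
    write_tsv(spec, art(file.path(rd, "focal_specific_degs.tsv")))
    write_tsv(data.frame(sample = rownames(corr), corr),
              art(file.path(rd, "transcriptome_correlation.tsv")))
    writeLines(cl$newick, art(file.path(rd, "expression_dendrogram.nwk")))
    res$expression <- list(normalized = uq, means = means, degs = degs,
                           specific_degs = spec, correlation = corr,
                           clustering = cl)
  }

  if ("methylation" %in% stages) {
    meth_samples <- names(cfg$global_methylation_level)
    files <- setNames(file.path(dd, paste0(meth_samples, ".cov")), meth_samples)
    for (f in files) .need(f, "simulate")
    tab <- load_and_filter_sites(files, min_depth = config$min_depth)
    genes <- read_genes(.need(file.path(dd, "genes.tsv"), "simulate"))
    bodies <- gene_body_of(genes)
    proms <- promoter_of(genes)
    regions <- rbind(
      data.frame(region_id = paste0("body_", bodies$owner_id), bodies),
      data.frame(region_id = paste0("prom_", proms$owner_id), proms))
    reg <- region_levels(tab, regions, min_sites = config$min_sites)
    others <- setdiff(meth_samples, focal)
    dmf <- lapply(others, function(o)
      call_dmf(reg, pair = c(o, focal), delta = config$delta,
               alpha = config$alpha))
    names(dmf) <- others
    gm <- vapply(meth_samples, function(s) genome_mean(tab, s), numeric(1))
    cl <- cluster_methylomes(tab)
    writeLines(cl$newick, art(file.path(rd, "methylome_dendrogram.nwk")))
    write_tsv(data.frame(sample = names(gm), genome_mean = unname(gm)),
              art(file.path(rd, "genome_mean_methylation.tsv")))
    res$methylation <- list(sites = tab, regions = reg, dmf = dmf,
                            genome_means = gm, clustering = cl)
  }

  if ("integrate" %in% stages) {
    if (is.null(res$variants) || is.null(res$expression) ||
        is.null(res$methylation))
      stop("stage 'integrate' needs 'variants', 'expression', and ",
           "'methylation' results in the same run", call. = FALSE)
    genes <- read_genes(file.path(dd, "genes.tsv"))
    dosage <- genes_in_cna(res$variants$segments, genes,
                           baseline_ploidy = cfg$baseline_ploidy)
    cna_spec <- sample_specific_cna_genes(dosage, focal)
    spec <- res$expression$specific_degs
    dmgb_spec <- focal_specific_dmf(res$methylation$dmf, category = "gene_body")
    driven <- classify_driven(cna_spec, dmgb_spec, spec)
    other <- setdiff(cfg$samples, focal)[1]
    ks <- ks_dosage_test(dosage[dosage$sample == focal, ],
                         res$expression$means, pair = c(focal, other))
    write_tsv(driven$calls, art(file.path(rd, "driven_genes.tsv")))
    res$integrate <- list(dosage = dosage, cna_specific = cna_spec,
                          dmgb_specific = dmgb_spec, driven = driven, ks = ks)
  }

  if ("report" %in% stages) {
    if (is.null(res$integrate))
      stop("stage 'report' needs the 'integrate' stage in the same run",
           call. = FALSE)
    s <- res$integrate$driven$summary
    v <- res$variants$shared
    lines <- c(
      "cloneDiverge pipeline report",
      sprintf("samples: %s (outgroup %s, focal %s)",
              paste(cfg$samples, collapse = ", "), cfg$outgroup, focal),
      sprintf("SNVs retained: %d (shared %d, polymorphic %d, LOH-masked %d)",
              nrow(res$variants$presence), v$n_shared, v$n_polymorphic,
              res$variants$n_masked),
      sprintf("parsimony tree: %s (score %d)",
              res$phylogeny$topology_newick, res$phylogeny$total_score),
      sprintf("genome mean methylation: %s",
              paste(sprintf("%s=%.3f", names(res$methylation$genome_means),
                            res$methylation$genome_means), collapse = ", ")),
      sprintf("focal-specific DEGs: %d", nrow(res$expression$specific_degs)),
      sprintf("CNA genes overlapping DEGs: %d, consistent %d (%s)",
              s$n_cna_overlap, s$n_cna_consistent, s$pct_cna_label),
      sprintf("DMGB genes overlapping DEGs: %d, consistent %d (%s)",
              s$n_dmgb_overlap, s$n_dmgb_consistent, s$pct_dmgb_label),
      sprintf("both mechanisms: %d; driven-gene union: %d", s$n_both,
              s$n_union))
    writeLines(lines, art(file.path(rd, "report.txt")))
    res$report <- lines
  }

  res$manifest <- data.frame(file = artifacts,
                             md5 = unname(tools::md5sum(artifacts)),
                             stringsAsFactors = FALSE)
  write_tsv(res$manifest, file.path(rd, "manifest.tsv"))
  invisible(res)
}

#' Focal-specific differentially methylated regions across comparisons
#'
#' Intersection of the per-comparison DMF calls (optionally restricted to a
#' category) with direction agreement; `delta_ml` is averaged over the
#' comparisons (focal minus other orientation).
#'
#' @param dmf_list named list of [call_dmf()] tables, each for
#'   `pair = c(other, focal)`.
#' @param category optional category restriction (e.g. `"gene_body"`).
#' @return data frame `gene`, `delta_ml`.
#' @export
focal_specific_dmf <- function(dmf_list, category = NULL) {
  pick <- function(d) {
    if (!is.null(category)) d <- d[d$category == category, , drop = FALSE]
    d[d$is_dmf, , drop = FALSE]
  }
  tabs <- lapply(dmf_list, pick)
  ids <- Reduce(intersect, lapply(tabs, function(d) d$owner_id))
  if (!length(ids)) return(data.frame(gene = character(), delta_ml = numeric()))
  dml <- sapply(tabs, function(d) d$delta_ml[match(ids, d$owner_id)])
  dml <- matrix(dml, nrow = length(ids))
  concord <- apply(sign(dml), 1, function(x) length(unique(x)) == 1)
  data.frame(gene = ids[concord], delta_ml = rowMeans(dml)[concord],
             stringsAsFactors = FALSE)
}
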