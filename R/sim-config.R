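#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a triploid genome,
#' four tumor subclones (`Pa`, `Pb`, `Ra`, `Rb`) and a lymphocyte outgroup
#' (`TIL`) related by the clonal tree `((Pa,Pb),(Ra,Rb))`, branch-specific
#' somatic SNVs, copy-number gain/loss segments with optional LOH,
#' CpG methylation with sample-specific global levels (0.460 / 0.409 / 0.407
#' for `Pa` / `Ra` / `Rb`) plus planted region-level differences, and
#' negative-binomial expression (2 replicates per sample) coupled positively
#' to gene copy number and gene-body methylation and decoupled from promoter
#' methylation. One designated divergent sample (default `Ra`) carries the
#' sample-specific plantings.
#'
#' @param seed integer RNG seed; the entire bundle is a deterministic
#'   function of the configuration including the seed.
#' @param n_chromosomes,chrom_length_bp genome shape.
#' @param n_genes,n_cgi,n_cpg_sites,n_repeats annotation sizes.
#' @param samples,outgroup sample panel and matched-normal name.
#' @param tree_topology nested grouping over `samples` (newick without the
#'   outgroup).
#' @param branch_snv_counts named integer vector: `trunk`, one entry per
#'   internal clade (leaves joined with `+`, sorted), one per leaf.
#' @param baseline_ploidy neutral total copy number.
#' @param cna_events_per_branch named integer vector over the same branch
#'   names.
#' @param cna_gain_states,cna_loss_states integer copy numbers drawn for
#'   gain/loss events.
#' @param cna_genes_per_event_range number of consecutive genes covered by
#'   one event (range).
#' @param loh_fraction fraction of loss events with B-allele copy number 0.
#' @param focal_sample sample receiving the sample-specific plantings.
#' @param global_methylation_level named vector sample -> genome-wide mean
#'   CpG methylation; only these samples receive methylation data.
#' @param cpg_coverage_mean expected reads per CpG site (Poisson).
#' @param n_planted_dmgb,n_planted_dmp,n_planted_both planted counts of
#'   focal-specific differentially methylated gene bodies, promoters
#'   (expression-decoupled), and genes carrying both a CNA and a gene-body
#'   planting.
#' @param dmgb_delta_ml center of the planted methylation difference
#'   magnitude (jittered by +/- 0.1).
#' @param methylation_expression_coupling log2 expression change per unit of
#'   planted gene-body methylation change.
#' @param dosage_coupling exponent on (copy number / baseline ploidy) in the
#'   expression mean.
#' @param nb_dispersion negative-binomial dispersion of replicate counts.
#' @param n_replicates RNA replicates per sample (>= 2).
#' @param library_size_mean expected total baseline counts per replicate.
#' @param snv_coverage_mean expected sequencing depth at SNV sites.
#' @param mutant_copies mutant allele copies carried by a clonal SNV.
#' @return validated object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 4,
                       chrom_length_bp = 5e6,
                       n_genes = 2400,
                       n_cgi = 300,
                       n_cpg_sites = 50000,
                       n_repeats = 400,
                       samples = c("Pa", "Pb", "Ra", "Rb"),
                       outgroup = "TIL",
                       tree_topology = "((Pa,Pb),(Ra,Rb))",
                       branch_snv_counts = c(trunk = 40, "Pa+Pb" = 15,
                                             "Ra+Rb" = 15, Pa = 8, Pb = 8,
                                             Ra = 8, Rb = 8),
                       baseline_ploidy = 3,
                       cna_events_per_branch = c(trunk = 4, "Pa+Pb" = 2,
                                                 "Ra+Rb" = 2, Pa = 2, Pb = 2,
                                                 Ra = 6, Rb = 2),
                       cna_gain_states = c(4, 5, 6),
                       cna_loss_states = c(1, 2),
                       cna_genes_per_event_range = c(8, 24),
                       loh_fraction = 0.5,
                       focal_sample = "Ra",
                       global_methylation_level = c(Pa = 0.460, Ra = 0.409,
                                                    Rb = 0.407),
                       cpg_coverage_mean = 30,
                       n_planted_dmgb = 150,
                       n_planted_dmp = 200,
                       n_planted_both = 10,
                       dmgb_delta_ml = 0.35,
                       methylation_expression_coupling = 3.5,
                       dosage_coupling = 1,
                       nb_dispersion = 0.01,
                       n_replicates = 2,
                       library_size_mean = 4e5,
                       snv_coverage_mean = 60,
                       mutant_copies = 1) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg a `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(seed == as.integer(seed),
              n_chromosomes >= 1, chrom_length_bp >= 1e5,
              n_genes >= 10, n_cpg_sites >= 100,
              n_replicates >= 2,
              baseline_ploidy >= 1,
              loh_fraction >= 0, loh_fraction <= 1,
              all(global_methylation_level >= 0 &
                    global_methylation_level <= 1),
              all(branch_snv_counts >= 0),
              all(cna_events_per_branch >= 0),
              cpg_coverage_mean > 0, snv_coverage_mean > 0,
              dmgb_delta_ml >= 0, dmgb_delta_ml <= 0.9)
  })
  if (cfg$outgroup %in% cfg$samples)
    stop("configuration error: outgroup '", cfg$outgroup,
         "' appears inside the ingroup sample list")
  leaves <- sort(ape::read.tree(text = paste0(cfg$tree_topology, ";"))$tip.label)
  if (!identical(leaves, sort(cfg$samples))) {
    off <- c(setdiff(leaves, cfg$samples), setdiff(cfg$samples, leaves))
    stop("configuration error: topology leaves do not match sample list; ",
         "offending leaf/leaves: ", paste(off, collapse = ", "))
  }
  br <- names(tree_branches(cfg$tree_topology))
  missing_br <- setdiff(names(cfg$branch_snv_counts), br)
  if (length(missing_br))
    stop("configuration error: unknown branch name(s) in branch_snv_counts: ",
         paste(missing_br, collapse = ", "))
  if (!cfg$focal_sample %in% cfg$samples)
    stop("configuration error: focal_sample not in samples")
  invisible(cfg)
}

#' Branches of an ingroup topology
#'
#' @param tree_topology newick-style grouping over the ingroup samples.
#' @return named list branch label -> character vector of carrier samples;
#'   `trunk` carries all samples, internal clades are labeled by their
#'   sorted leaves joined with `+`, leaves by their own name.
#' @export
tree_branches <- function(tree_topology) {
  ph <- ape::read.tree(text = paste0(tree_topology, ";"))
  n <- length(ph$tip.label)
  br <- list(trunk = sort(ph$tip.label))
  for (node in unique(ph$edge[, 1])) {
    tips <- sort(ph$tip.label[phylo_clade_tips(ph, node)])
    if (length(tips) < n)
      br[[paste(tips, collapse = "+")]] <- tips
  }
  for (tip in ph$tip.label) br[[tip]] <- tip
  br
}

phylo_clade_tips <- function(ph, node) {
  n <- length(ph$tip.label)
  if (node <= n) return(node)
  kids <- ph$edge[ph$edge[, 1] == node, 2]
  unlist(lapply(kids, phylo_clade_tips, ph = ph))
}

#' Read / write a simulation configuration as YAML
#' @param path file path.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  num_named <- c("branch_snv_counts", "cna_events_per_branch",
                 "global_methylation_level")
  for (nm in num_named)
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param cfg a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x), path)
  invisible(path)
}
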