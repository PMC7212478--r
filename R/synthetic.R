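#' Synthetic multi-omics dataset with planted truth
#'
#' [generate_truth()] derives, deterministically from a [sim_config()], the
#' complete ground truth of a simulated subclone panel: genome layout and
#' annotation, the clonal tree with branch-specific SNVs, copy-number events
#' with LOH, per-site methylation targets with planted focal-sample
#' differences, and the expression mean structure coupling copy number and
#' gene-body methylation to transcript abundance. The `simulate_*` builders
#' then draw read-count noise around those targets, and [render_dataset()]
#' writes the standard-format file bundle plus a machine-readable truth
#' record.
#'
#' @name synthetic-data
NULL

#' Generate the planted ground truth
#'
#' @param cfg a [sim_config()].
#' @return object of class `clone_truth`; see Details. Key elements:
#'   `genes`, `cgis`, `repeats`, `sites` (CpG positions with region ids and
#'   per-sample methylation targets), `snv` (variant -> branch and carrier
#'   set), `cna_events`, `gene_cn` (genes x samples copy-number matrix),
#'   `loh`, `expression_mu` (genes x samples mean matrix), `driven_truth`,
#'   `methylation_truth`, and `tree` (branches and newick).
#' @export
generate_truth <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  chrom_names <- paste0("chr", seq_len(cfg$n_chromosomes))
  chrom_len <- setNames(rep(cfg$chrom_length_bp, cfg$n_chromosomes), chrom_names)
  meth_samples <- names(cfg$global_methylation_level)

  ## ---- genes: non-overlapping, evenly slotted with jitter ----
  per_chr <- rep(cfg$n_genes %/% cfg$n_chromosomes, cfg$n_chromosomes)
  extra <- cfg$n_genes %% cfg$n_chromosomes
  if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
  genes <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(ci) {
    nc <- per_chr[ci]
    spacing <- cfg$chrom_length_bp / nc
    len <- runif(nc, 2000, min(6000, 0.6 * spacing))
    start <- floor((seq_len(nc) - 1) * spacing) +
      floor(runif(nc, 2000, pmax(2001, spacing - len - 2000)))
    data.frame(chrom = chrom_names[ci],
               start = as.integer(start),
               end = as.integer(start + len),
               stringsAsFactors = FALSE)
  }))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tes <- ifelse(genes$strand == "+", genes$end, genes$start)
  ## 1-3 exons per gene tiling part of the span (annotation output only)
  genes$n_exons <- sample(1:3, nrow(genes), replace = TRUE)

  ## ---- repeats ----
  rep_chrom <- sample(chrom_names, cfg$n_repeats, replace = TRUE)
  rep_start <- floor(runif(cfg$n_repeats, 1, cfg$chrom_length_bp - 2000))
  repeats <- data.frame(chrom = rep_chrom, start = as.integer(rep_start),
                        end = as.integer(rep_start +
                                           floor(runif(cfg$n_repeats, 200, 2000))),
                        class = sample(c("LINE", "SINE", "LTR", "Satellite"),
                                       cfg$n_repeats, replace = TRUE,
                                       prob = c(0.4, 0.35, 0.2, 0.05)),
                        stringsAsFactors = FALSE)

  ## ---- CGIs: ~60% promoter-anchored, rest random; non-overlapping ----
  n_prom_cgi <- min(round(0.6 * cfg$n_cgi), nrow(genes))
  anchors <- sample(nrow(genes), n_prom_cgi)
  cand <- rbind(
    data.frame(chrom = genes$chrom[anchors],
               start = pmax(1L, as.integer(genes$tss[anchors] - 400L)),
               end = as.integer(genes$tss[anchors] + 400L),
               stringsAsFactors = FALSE),
    local({
      st <- floor(runif(cfg$n_cgi - n_prom_cgi, 1, cfg$chrom_length_bp - 1500))
      data.frame(chrom = sample(chrom_names, cfg$n_cgi - n_prom_cgi,
                                replace = TRUE),
                 start = as.integer(st),
                 end = as.integer(st + floor(runif(cfg$n_cgi - n_prom_cgi,
                                                   500, 1500))),
                 stringsAsFactors = FALSE)
    }))
  cand <- cand[order(cand$chrom, cand$start), ]
  keep <- rep(TRUE, nrow(cand))
  last_end <- -Inf; last_chr <- ""
  for (i in seq_len(nrow(cand))) {
    if (cand$chrom[i] == last_chr && cand$start[i] <= last_end + 1) {
      keep[i] <- FALSE
    } else {
      last_chr <- cand$chrom[i]; last_end <- cand$end[i]
    }
  }
  cgis <- cand[keep, , drop = FALSE]
  cgis$cgi_id <- sprintf("cgi_%04d", seq_len(nrow(cgis)))
  rownames(cgis) <- NULL

  ## ---- CpG sites: gene bodies, promoters, intergenic blocks ----
  ## promoters are CpG-dense relative to gene bodies, so they get a larger
  ## per-bp share; region-level tests then see 6-7 promoter sites per gene
  n_body <- round(0.62 * cfg$n_cpg_sites)
  n_prom <- round(0.30 * cfg$n_cpg_sites)
  n_ig <- cfg$n_cpg_sites - n_body - n_prom
  body_alloc <- tabulate(sample(nrow(genes), n_body, replace = TRUE),
                         nbins = nrow(genes))
  proms <- promoter_of(genes, chrom_lengths = chrom_len)
  prom_alloc <- tabulate(sample(nrow(genes), n_prom, replace = TRUE),
                         nbins = nrow(genes))
  ## body CpGs are placed beyond the promoter's downstream window (600 bp
  ## past the TSS) so gene-body and promoter methylation signals stay
  ## spatially distinct, as they are in real gene architecture; even
  ## positions only, so sites never collide with (odd-position) SNVs
  body_lo <- ifelse(genes$strand == "+",
                    pmin(genes$tss + 600L, genes$tes - 100L),
                    pmin(genes$tes, genes$tss))
  body_hi <- ifelse(genes$strand == "+",
                    pmax(genes$tss, genes$tes),
                    pmax(genes$tss - 600L, genes$tes + 100L))
  bg <- rep(seq_len(nrow(genes)), body_alloc)
  bpos <- 2L * floor(runif(length(bg), body_lo[bg] / 2, body_hi[bg] / 2))
  pg <- rep(seq_len(nrow(genes)), prom_alloc)
  ppos <- 2L * floor(runif(length(pg), proms$start[pg] / 2, proms$end[pg] / 2))
  ig_chrom <- sample(chrom_names, n_ig, replace = TRUE)
  ig_pos <- 2L * floor(runif(n_ig, 1, (cfg$chrom_length_bp - 2) / 2))
  sites <- data.frame(
    chrom = c(genes$chrom[bg], proms$chrom[pg], ig_chrom),
    pos = c(bpos, ppos, ig_pos),
    region_id = c(paste0("body_", genes$gene_id[bg]),
                  paste0("prom_", genes$gene_id[pg]),
                  paste0("ig_", ig_chrom, "_", floor(ig_pos / 1e5))),
    stringsAsFactors = FALSE)
  sites <- sites[!duplicated(paste(sites$chrom, sites$pos)), ]
  sites <- sites[order(match(sites$chrom, chrom_names), sites$pos), ]
  rownames(sites) <- NULL

  ## ---- methylation baseline: region base level + site jitter ----
  regions <- unique(sites$region_id)
  rtype <- substr(regions, 1, 2)
  rbase <- setNames(numeric(length(regions)), regions)
  rbase[rtype == "bo"] <- rbeta(sum(rtype == "bo"), 5, 3)
  rbase[rtype == "pr"] <- rbeta(sum(rtype == "pr"), 2, 6)
  rbase[rtype == "ig"] <- rbeta(sum(rtype == "ig"), 4, 3)
  site_base <- clamp(rbase[sites$region_id] + rnorm(nrow(sites), 0, 0.04),
                     0.01, 0.99)
  ## per-sample global offsets, one recalibration pass to undo clamping bias
  targets <- sapply(meth_samples, function(s) {
    tgt <- cfg$global_methylation_level[[s]]
    off <- tgt - mean(site_base)
    t1 <- clamp(site_base + off, 0.005, 0.995)
    clamp(site_base + off + (tgt - mean(t1)), 0.005, 0.995)
  })
  targets <- matrix(targets, nrow = nrow(sites),
                    dimnames = list(NULL, meth_samples))

  ## ---- clonal tree, branch SNVs ----
  branches <- tree_branches(cfg$tree_topology)
  snv_counts <- setNames(rep(0L, length(branches)), names(branches))
  snv_counts[names(cfg$branch_snv_counts)] <- cfg$branch_snv_counts
  n_snv <- sum(snv_counts)
  bases <- c("A", "C", "G", "T")
  snv <- NULL
  if (n_snv > 0) {
    sc <- sample(chrom_names, n_snv, replace = TRUE)
    sp <- 1L + 2L * floor(runif(n_snv, 1, (cfg$chrom_length_bp - 2) / 2))  # odd: never collides with even CpG positions
    dup <- duplicated(paste(sc, sp))
    while (any(dup)) {
      sp[dup] <- 1L + 2L * floor(runif(sum(dup), 1, (cfg$chrom_length_bp - 2) / 2))
      dup <- duplicated(paste(sc, sp))
    }
    ref <- sample(bases, n_snv, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    branch <- rep(names(snv_counts), snv_counts)
    snv <- data.frame(snv_id = sprintf("snv_%05d", seq_len(n_snv)),
                      chrom = sc, pos = sp, ref = ref, alt = alt,
                      branch = branch,
                      carriers = vapply(branch, function(b)
                        paste(branches[[b]], collapse = ","), character(1)),
                      stringsAsFactors = FALSE)
  } else {
    snv <- data.frame(snv_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      branch = character(), carriers = character(),
                      stringsAsFactors = FALSE)
  }

  ## ---- CNA events: runs of whole genes, globally disjoint ----
  ev_counts <- setNames(rep(0L, length(branches)), names(branches))
  ev_counts[names(cfg$cna_events_per_branch)] <- cfg$cna_events_per_branch
  gene_cn <- matrix(cfg$baseline_ploidy, nrow(genes), length(cfg$samples),
                    dimnames = list(genes$gene_id, cfg$samples))
  used <- rep(FALSE, nrow(genes))
  gidx_by_chr <- split(seq_len(nrow(genes)), genes$chrom)
  events <- list()
  eid <- 0L
  for (b in names(ev_counts)) {
    k <- ev_counts[[b]]
    if (k == 0) next
    is_focal_leaf <- identical(branches[[b]], cfg$focal_sample)
    for (j in seq_len(k)) {
      m <- sample(seq(cfg$cna_genes_per_event_range[1],
                      cfg$cna_genes_per_event_range[2]), 1)
      placed <- FALSE
      for (try in 1:50) {
        chr <- sample(chrom_names, 1)
        gl <- gidx_by_chr[[chr]]
        if (length(gl) < m) next
        i0 <- sample(length(gl) - m + 1L, 1)
        run <- gl[i0:(i0 + m - 1L)]
        if (any(used[run])) next
        used[run] <- TRUE; placed <- TRUE; break
      }
      if (!placed) { cd_log("could not place CNA event on branch %s", b); next }
      gain <- runif(1) < 0.5
      if (is_focal_leaf && j <= ceiling(k / 2)) {
        ## guarantee strong focal events (doubling gains / near-total losses)
        state <- if (j %% 2 == 1) max(cfg$cna_gain_states) else min(cfg$cna_loss_states)
      } else {
        state <- if (gain) sample(cfg$cna_gain_states, 1) else
          sample(cfg$cna_loss_states, 1)
      }
      loss <- state < cfg$baseline_ploidy
      b_allele <- if (loss && runif(1) < cfg$loh_fraction) 0L else
        sample(seq_len(max(1L, floor(state / 2))), 1)
      first <- min(run); last <- max(run)
      seg_start <- if (first == min(gidx_by_chr[[chr]])) 1L else
        as.integer(floor((genes$end[first - 1L] + genes$start[first]) / 2))
      seg_end <- if (last == max(gidx_by_chr[[chr]])) as.integer(chrom_len[[chr]]) else
        as.integer(floor((genes$end[last] + genes$start[last + 1L]) / 2))
      eid <- eid + 1L
      events[[eid]] <- data.frame(
        event_id = sprintf("cna_%03d", eid), branch = b,
        carriers = paste(branches[[b]], collapse = ","),
        chrom = chr, start = seg_start, end = seg_end,
        total_cn = as.integer(state), b_allele_cn = as.integer(b_allele),
        n_genes = m, genes = paste(genes$gene_id[run], collapse = ","),
        stringsAsFactors = FALSE)
      gene_cn[run, branches[[b]]] <- as.integer(state)
    }
  }
  cna_events <- if (length(events)) do.call(rbind, events) else
    data.frame(event_id = character(), branch = character(),
               carriers = character(), chrom = character(), start = integer(),
               end = integer(), total_cn = integer(), b_allele_cn = integer(),
               n_genes = integer(), genes = character(),
               stringsAsFactors = FALSE)

  ## ---- expression baselines ----
  base <- rlnorm(nrow(genes), log(150), 1.2)
  base <- base * cfg$library_size_mean / sum(base)

  ## ---- planted focal methylation differences ----
  body_sites <- tabulate(match(sites$region_id,
                               paste0("body_", genes$gene_id)),
                         nbins = nrow(genes))
  prom_sites <- tabulate(match(sites$region_id,
                               paste0("prom_", genes$gene_id)),
                         nbins = nrow(genes))
  in_cna <- used
  focal <- cfg$focal_sample
  focal_has_meth <- focal %in% meth_samples
  ## methylation plantings go to genes with solid baseline expression: gene
  ## bodies of active genes are where methylation tracks transcription, and
  ## near-silent genes carry no recoverable expression signal at 2 replicates
  expressed_enough <- base >= 100
  pick <- function(x, k) x[sample.int(length(x), min(k, length(x)))]
  elig <- which(expressed_enough & body_sites >= 4 & !in_cna)
  dmgb_idx <- sort(pick(elig, cfg$n_planted_dmgb))
  focal_event_genes <- which(in_cna & gene_cn[, focal] != cfg$baseline_ploidy &
                               apply(gene_cn[, setdiff(cfg$samples, focal),
                                             drop = FALSE], 1, function(x)
                                               all(x == cfg$baseline_ploidy)))
  both_pool <- intersect(focal_event_genes,
                         which(expressed_enough & body_sites >= 4))
  both_idx <- sort(pick(both_pool, cfg$n_planted_both))
  elig_p <- setdiff(which(expressed_enough & prom_sites >= 4 & !in_cna), dmgb_idx)
  dmp_idx <- sort(pick(elig_p, cfg$n_planted_dmp))

  dev_gene <- numeric(nrow(genes))       # realized focal gene-body shift
  dmp_dev <- numeric(nrow(genes))        # realized focal promoter shift
  meth_truth <- NULL
  if (focal_has_meth) {
    site_rows_by_region <- split(seq_len(nrow(sites)), sites$region_id)
    plant <- function(idx, region_prefix) {
      mag <- runif(length(idx), cfg$dmgb_delta_ml - 0.1, cfg$dmgb_delta_ml + 0.1)
      dev <- numeric(length(idx))
      for (i in seq_along(idx)) {
        gi <- idx[i]
        rid <- paste0(region_prefix, genes$gene_id[gi])
        rows <- site_rows_by_region[[rid]]
        lev0 <- mean(targets[rows, focal])
        sgn <- if (region_prefix == "body_" && gi %in% both_idx)
          sign(gene_cn[gi, focal] - cfg$baseline_ploidy) else
            if (lev0 >= 0.5) -1 else 1
        t_new <- clamp(targets[rows, focal] + sgn * mag[i], 0.005, 0.995)
        dev[i] <- mean(t_new) - lev0
        targets[rows, focal] <<- t_new
      }
      dev
    }
    dev_gene[c(dmgb_idx, both_idx)] <- plant(c(dmgb_idx, both_idx), "body_")
    dmp_dev[dmp_idx] <- plant(dmp_idx, "prom_")
    others <- setdiff(meth_samples, focal)
    region_mean <- function(rows, s) mean(targets[rows, s])
    rows_of <- function(prefix, gi)
      site_rows_by_region[[paste0(prefix, genes$gene_id[gi])]]
    mk_truth <- function(idx, prefix, dev) {
      if (!length(idx)) return(NULL)
      lv <- t(vapply(idx, function(gi)
        colMeans(targets[rows_of(prefix, gi), , drop = FALSE]),
        numeric(length(meth_samples))))
      colnames(lv) <- meth_samples
      data.frame(gene = genes$gene_id[idx],
                 region = ifelse(prefix == "body_", "gene_body", "promoter"),
                 lv,
                 delta_ml = lv[, focal] -
                   rowMeans(lv[, others, drop = FALSE]),
                 planted_dev = dev, stringsAsFactors = FALSE,
                 row.names = NULL)
    }
    meth_truth <- rbind(
      mk_truth(c(dmgb_idx, both_idx), "body_", dev_gene[c(dmgb_idx, both_idx)]),
      mk_truth(dmp_idx, "prom_", dmp_dev[dmp_idx]))
  }

  ## ---- expression mean structure ----
  dosage <- (gene_cn / cfg$baseline_ploidy)^cfg$dosage_coupling
  mu <- base * dosage
  mu[, focal] <- mu[, focal] *
    2^(cfg$methylation_expression_coupling * dev_gene)

  ## ---- driven-gene truth ----
  planted_lfc <- cfg$dosage_coupling *
    log2(gene_cn[, focal] / cfg$baseline_ploidy) +
    cfg$methylation_expression_coupling * dev_gene
  mk_row <- function(gi, mech) {
    data.frame(gene = genes$gene_id[gi], mechanism = mech,
               direction = ifelse(planted_lfc[gi] > 0, "up", "down"),
               delta_cn = gene_cn[gi, focal] - cfg$baseline_ploidy,
               delta_ml = dev_gene[gi],
               planted_log2fc = planted_lfc[gi],
               base_mean = base[gi],
               stringsAsFactors = FALSE)
  }
  cna_only <- setdiff(focal_event_genes, both_idx)
  driven_truth <- rbind(
    if (length(cna_only)) mk_row(cna_only, "cna"),
    if (length(dmgb_idx)) mk_row(dmgb_idx, "methylation"),
    if (length(both_idx)) mk_row(both_idx, "both"))
  if (is.null(driven_truth))
    driven_truth <- data.frame(gene = character(), mechanism = character(),
                               direction = character(), delta_cn = numeric(),
                               delta_ml = numeric(), planted_log2fc = numeric(),
                               base_mean = numeric())

  structure(list(
    config = cfg,
    chrom_lengths = chrom_len,
    genes = genes, cgis = cgis, repeats = repeats,
    sites = cbind(sites, as.data.frame(targets)),
    tree = list(newick = paste0(cfg$tree_topology, ";"),
                branches = branches,
                branch_snv_counts = snv_counts),
    snv = snv,
    cna_events = cna_events,
    gene_cn = gene_cn,
    loh = cna_events[cna_events$b_allele_cn == 0, , drop = FALSE],
    expression_base = setNames(base, genes$gene_id),
    expression_mu = mu,
    driven_truth = driven_truth,
    methylation_truth = meth_truth,
    dmp_genes = genes$gene_id[dmp_idx],
    meth_samples = meth_samples
  ), class = "clone_truth")
}

#' Per-sample copy-number segment tables from the truth
#'
#' Tiles each chromosome with baseline-ploidy segments interrupted by the
#' sample's CNA events.
#' @param truth a `clone_truth`.
#' @return segment data frame (`sample`, `chrom`, `start`, `end`,
#'   `total_cn`, `b_allele_cn`) covering every chromosome for every sample.
#' @export
truth_segments <- function(truth) {
  cfg <- truth$config
  acc <- list(sample = character(), chrom = character(), start = integer(),
              end = integer(), total_cn = integer(), b_allele_cn = integer())
  push <- function(s, chr, st, en, cn, b) {
    acc$sample <<- c(acc$sample, s); acc$chrom <<- c(acc$chrom, chr)
    acc$start <<- c(acc$start, st); acc$end <<- c(acc$end, en)
    acc$total_cn <<- c(acc$total_cn, cn); acc$b_allele_cn <<- c(acc$b_allele_cn, b)
  }
  for (s in cfg$samples) {
    ev <- truth$cna_events[vapply(strsplit(truth$cna_events$carriers, ","),
                                  function(x) s %in% x, logical(1)), ,
                           drop = FALSE]
    for (chr in names(truth$chrom_lengths)) {
      L <- truth$chrom_lengths[[chr]]
      e <- ev[ev$chrom == chr, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      cur <- 1L
      for (i in seq_len(nrow(e))) {
        if (e$start[i] > cur)
          push(s, chr, cur, e$start[i] - 1L, cfg$baseline_ploidy, 1L)
        push(s, chr, e$start[i], e$end[i], e$total_cn[i], e$b_allele_cn[i])
        cur <- e$end[i] + 1L
      }
      if (cur <= L) push(s, chr, cur, as.integer(L), cfg$baseline_ploidy, 1L)
    }
  }
  as.data.frame(acc, stringsAsFactors = FALSE)
}

#' Simulate the SNV read-count table
#'
#' Carriers draw variant reads as Binomial(depth, mutant copies / local
#' total copy number); non-carriers and the matched normal draw zero.
#' @param truth a `clone_truth`.
#' @return SNV table in the [variants] column convention.
#' @export
simulate_snv_table <- function(truth) {
  cfg <- truth$config
  set.seed(cfg$seed + 101L)
  snv <- truth$snv
  n <- nrow(snv)
  out <- snv[, c("chrom", "pos", "ref", "alt")]
  if (n == 0) {
    for (s in cfg$samples)
      for (suf in c("_var_fwd", "_var_rev", "_depth"))
        out[[paste0(s, suf)]] <- integer(0)
    out$normal_var <- integer(0); out$normal_depth <- integer(0)
    return(out)
  }
  segs <- truth_segments(truth)
  carrier <- sapply(cfg$samples, function(s)
    vapply(strsplit(snv$carriers, ","), function(x) s %in% x, logical(1)))
  carrier <- matrix(carrier, nrow = n, dimnames = list(NULL, cfg$samples))
  sg <- GenomicRanges::GRanges(snv$chrom, IRanges::IRanges(snv$pos, snv$pos))
  for (s in cfg$samples) {
    seg <- segs[segs$sample == s, , drop = FALSE]
    gg <- GenomicRanges::GRanges(seg$chrom, IRanges::IRanges(seg$start, seg$end))
    hit <- GenomicRanges::findOverlaps(sg, gg, select = "first")
    cn <- ifelse(is.na(hit), cfg$baseline_ploidy, seg$total_cn[hit])
    depth <- pmax(1L, rpois(n, cfg$snv_coverage_mean))
    p <- pmin(1, cfg$mutant_copies / pmax(cn, 1))
    vr <- ifelse(carrier[, s], rbinom(n, depth, p), 0L)
    fwd <- rbinom(n, vr, 0.5)
    out[[paste0(s, "_var_fwd")]] <- as.integer(fwd)
    out[[paste0(s, "_var_rev")]] <- as.integer(vr - fwd)
    out[[paste0(s, "_depth")]] <- as.integer(depth)
  }
  out$normal_var <- 0L
  out$normal_depth <- as.integer(pmax(1L, rpois(n, cfg$snv_coverage_mean)))
  out
}

#' Simulate per-sample CpG coverage counts
#'
#' Coverage is Poisson around the configured mean; methylated counts are
#' Binomial around the per-site, per-sample target level.
#' @param truth a `clone_truth`.
#' @return named list (one element per methylation sample) of data frames
#'   `chrom`, `pos`, `meth`, `unmeth`.
#' @export
simulate_methylation <- function(truth) {
  cfg <- truth$config
  set.seed(cfg$seed + 102L)
  n <- nrow(truth$sites)
  out <- lapply(truth$meth_samples, function(s) {
    cov <- rpois(n, cfg$cpg_coverage_mean)
    m <- rbinom(n, cov, truth$sites[[s]])
    data.frame(chrom = truth$sites$chrom, pos = truth$sites$pos,
               meth = m, unmeth = cov - m, stringsAsFactors = FALSE)
  })
  names(out) <- truth$meth_samples
  out
}

#' Simulate the raw expression count matrix
#'
#' Negative-binomial replicate counts around the truth's mean structure,
#' with a modest uniform library-size factor per replicate so that
#' upper-quartile normalization has real work to do.
#' @param truth a `clone_truth`.
#' @return integer matrix genes x `sample.repN` columns.
#' @export
simulate_counts <- function(truth) {
  cfg <- truth$config
  set.seed(cfg$seed + 103L)
  cols <- as.vector(outer(cfg$samples, seq_len(cfg$n_replicates),
                          function(s, r) paste0(s, ".rep", r)))
  cols <- sort(cols)
  rf <- setNames(runif(length(cols), 0.85, 1.2), cols)
  m <- sapply(cols, function(cl) {
    s <- sub("\\.rep[0-9]+$", "", cl)
    mu <- truth$expression_mu[, s] * rf[[cl]]
    rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
  })
  matrix(as.integer(m), nrow = nrow(truth$genes),
         dimnames = list(truth$genes$gene_id, cols))
}

#' Write the full synthetic bundle to disk
#'
#' @param truth a `clone_truth`.
#' @param outdir output directory (created if needed).
#' @param what subset of `c("snv", "seg", "methylation", "expression",
#'   "annotation", "truth")`.
#' @return invisibly, a manifest data frame (`file`, `md5`).
#' @export
render_dataset <- function(truth, outdir,
                           what = c("snv", "seg", "methylation",
                                    "expression", "annotation", "truth")) {
  what <- match.arg(what, several.ok = TRUE)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  cfg <- truth$config
  files <- character(0)
  add <- function(path) files <<- c(files, path)

  if ("snv" %in% what) {
    p <- file.path(outdir, "snv_table.tsv")
    write_tsv(simulate_snv_table(truth), p); add(p)
  }
  if ("seg" %in% what) {
    segs <- truth_segments(truth)
    for (s in cfg$samples) {
      p <- file.path(outdir, paste0(s, ".seg"))
      write_tsv(segs[segs$sample == s,
                     c("chrom", "start", "end", "total_cn", "b_allele_cn")], p)
      add(p)
    }
  }
  if ("methylation" %in% what) {
    cov <- simulate_methylation(truth)
    for (s in names(cov)) {
      p <- file.path(outdir, paste0(s, ".cov"))
      write_coverage(cov[[s]], p); add(p)
    }
  }
  if ("expression" %in% what) {
    p <- file.path(outdir, "counts.tsv")
    write_counts(simulate_counts(truth), p); add(p)
  }
  if ("annotation" %in% what) {
    p <- file.path(outdir, "genes.tsv"); write_genes(truth$genes, p); add(p)
    p <- file.path(outdir, "cgi.bed")
    write_bed(truth$cgis[, c("chrom", "start", "end")],
              names = truth$cgis$cgi_id, path = p); add(p)
    p <- file.path(outdir, "repeats.bed")
    write_bed(truth$repeats[, c("chrom", "start", "end")],
              names = truth$repeats$class, path = p); add(p)
  }
  if ("truth" %in% what) {
    td <- file.path(outdir, "truth")
    dir.create(td, showWarnings = FALSE)
    writeLines(truth$tree$newick, file.path(td, "tree.nwk")); add(file.path(td, "tree.nwk"))
    write_tsv(truth$snv, file.path(td, "snv_truth.tsv")); add(file.path(td, "snv_truth.tsv"))
    write_tsv(truth$cna_events, file.path(td, "cna_truth.tsv")); add(file.path(td, "cna_truth.tsv"))
    write_tsv(truth$driven_truth, file.path(td, "driven_truth.tsv")); add(file.path(td, "driven_truth.tsv"))
    if (!is.null(truth$methylation_truth)) {
      write_tsv(truth$methylation_truth, file.path(td, "methylation_truth.tsv"))
      add(file.path(td, "methylation_truth.tsv"))
    }
    write_sim_config(cfg, file.path(td, "config.yaml")); add(file.path(td, "config.yaml"))
  }
  manifest <- data.frame(file = files, md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(manifest)
}
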