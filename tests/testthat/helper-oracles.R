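# Independent brute-force oracles used across tests. These deliberately do
# not reuse any package internals.

# Two-sided Fisher p by explicit enumeration over all 2x2 tables with the
# observed margins, using factorials directly.
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  prob <- function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }
  supp <- max(0, c1 - r2):min(c1, r1)
  dens <- vapply(supp, prob, numeric(1))
  sum(dens[dens <= prob(a) * (1 + 1e-7)])
}

# One-sided KS statistic by brute-force max difference of empirical CDFs.
enum_ks_D <- function(x, y, direction = c("x_above", "x_below")) {
  direction <- match.arg(direction)
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  if (direction == "x_above") max(Fy - Fx) else max(Fx - Fy)
}

# Exact binomial tails by direct summation of the mass function.
enum_binom_tail <- function(k, n, p, side = c("le", "ge")) {
  side <- match.arg(side)
  xs <- if (side == "le") 0:k else k:n
  sum(vapply(xs, function(x) choose(n, x) * p^x * (1 - p)^(n - x), numeric(1)))
}

# Hypergeometric over-representation p by enumeration.
enum_hyper_p <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(vapply(xs, function(x)
    choose(K, x) * choose(N - K, n - x) / choose(N, n), numeric(1)))
}

# Quadratic all-pairs site-in-interval containment.
enum_containment <- function(sites, intervals) {
  hits <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(intervals))) {
      if (sites$chrom[i] == intervals$chrom[j] &&
          sites$pos[i] >= intervals$start[j] &&
          sites$pos[i] <= intervals$end[j])
        hits[[length(hits) + 1]] <- c(i, j)
    }
  }
  if (!length(hits)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, hits)
}

# Minimum parsimony score of a binary character matrix (taxa x characters)
# on a *given* unrooted topology, by exhaustive enumeration of internal
# node states. `edge` is a 2-column matrix (e.g. from an ape "phylo").
enum_tree_score <- function(edge, tip_states) {
  n_tip <- nrow(tip_states)
  internal <- setdiff(unique(as.vector(edge)), seq_len(n_tip))
  total <- 0
  for (ch in seq_len(ncol(tip_states))) {
    best <- Inf
    for (mask in 0:(2^length(internal) - 1)) {
      st <- integer(max(edge))
      st[seq_len(n_tip)] <- tip_states[, ch]
      st[internal] <- bitwAnd(bitwShiftR(mask, seq_along(internal) - 1L), 1L)
      chg <- sum(st[edge[, 1]] != st[edge[, 2]])
      best <- min(best, chg)
    }
    total <- total + best
  }
  total
}

# Minimum score over all topologies on the given taxa (phangorn supplies the
# independent topology enumeration; scoring is the brute force above).
enum_best_score <- function(tip_states) {
  taxa <- rownames(tip_states)
  trees <- phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
  min(vapply(trees, function(tr) {
    ord <- match(taxa, tr$tip.label)
    # relabel edges so tips 1..n follow tip_states row order
    edge <- tr$edge
    map <- integer(max(edge))
    map[ord] <- seq_along(taxa)
    others <- setdiff(seq_len(max(edge)), ord)
    map[others] <- length(taxa) + seq_along(others)
    edge[] <- map[edge]
    enum_tree_score(edge, tip_states)
  }, numeric(1)))
}

# Small random presence matrix with named taxa.
random_presence <- function(n_taxa, n_char, p = 0.5) {
  m <- matrix(runif(n_taxa * n_char) < p, n_char, n_taxa) * 1L
  colnames(m) <- paste0("t", seq_len(n_taxa))
  rownames(m) <- paste0("v", seq_len(n_char))
  m
}
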