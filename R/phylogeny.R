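#' Wagner parsimony tree from a binary presence/absence matrix
#'
#' On binary characters the Wagner criterion coincides with Fitch small
#' parsimony, so each candidate topology is scored exactly by the Fitch
#' union count and the global optimum is found by exhaustive enumeration of
#' all unrooted binary topologies. The tree is rooted at the matched-normal
#' outgroup (an all-absent taxon). Exhaustive search is exact up to 12
#' ingroup taxa; larger panels need heuristic search, which is out of scope.
#'
#' @name wagner-parsimony
NULL

## All unrooted binary topologies on n >= 3 labeled leaves, built by
## stepwise edge insertion. Leaves are nodes 1..n, internal nodes
## n+1 .. 2n-2; each topology is an edge matrix (2 columns).
all_topologies <- function(n) {
  stopifnot(n >= 2)
  if (n == 2) return(list(matrix(c(1L, 2L), ncol = 2)))
  trees <- list(matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L),
                       ncol = 2, byrow = TRUE))
  if (n == 3) return(trees)
  for (k in 4L:n) {
    new_int <- n + k - 2L
    nxt <- vector("list", length(trees) * (2L * (k - 1L) - 3L))
    j <- 0L
    for (tr in trees) {
      for (e in seq_len(nrow(tr))) {
        j <- j + 1L
        nxt[[j]] <- rbind(tr[-e, , drop = FALSE],
                          c(tr[e, 1L], new_int),
                          c(new_int, tr[e, 2L]),
                          c(new_int, k))
      }
    }
    trees <- nxt
  }
  trees
}

## Root an edge matrix at a leaf; returns children list and a postorder of
## nodes (children before parents), plus each node's parent.
.root_at <- function(edges, root) {
  nn <- max(edges)
  adj <- vector("list", nn)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- integer(nn); parent[root] <- 0L
  order <- integer(0)
  stack <- root
  seen <- logical(nn); seen[root] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, v)
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE; parent[w] <- v; stack <- c(stack, w)
    }
  }
  children <- vector("list", nn)
  for (v in order) if (parent[v] > 0L)
    children[[parent[v]]] <- c(children[[parent[v]]], v)
  list(postorder = rev(order), preorder = order,
       parent = parent, children = children, n_nodes = nn)
}

## Fitch first pass, vectorized over characters.
## X: leaves x characters binary matrix. Returns total score, per-character
## scores, and the candidate-state sets (two logical matrices node x char).
.fitch_pass <- function(edges, X, root_leaf = 1L) {
  rt <- .root_at(edges, root_leaf)
  nchar_ <- ncol(X)
  nn <- rt$n_nodes
  can0 <- matrix(FALSE, nn, nchar_)
  can1 <- matrix(FALSE, nn, nchar_)
  nleaf <- nrow(X)
  can0[seq_len(nleaf), ] <- X == 0L
  can1[seq_len(nleaf), ] <- X == 1L
  score <- integer(nchar_)
  for (v in rt$postorder) {
    kids <- rt$children[[v]]
    if (!length(kids)) next
    s0 <- can0[v, ] | v > nleaf  # internal nodes start as full set for AND
    s1 <- can1[v, ] | v > nleaf
    if (v <= nleaf) { s0 <- can0[v, ]; s1 <- can1[v, ] }  # rooted leaf
    first <- TRUE
    for (w in kids) {
      if (first && v > nleaf) { s0 <- can0[w, ]; s1 <- can1[w, ]; first <- FALSE; next }
      i0 <- s0 & can0[w, ]; i1 <- s1 & can1[w, ]
      empty <- !(i0 | i1)
      score <- score + empty
      u0 <- s0 | can0[w, ]; u1 <- s1 | can1[w, ]
      s0 <- ifelse(empty, u0, i0)
      s1 <- ifelse(empty, u1, i1)
    }
    can0[v, ] <- s0; can1[v, ] <- s1
  }
  list(score = score, total = sum(score), can0 = can0, can1 = can1, rooting = rt)
}

## Fitch refinement rooted at outgroup leaf: assign states top-down, ties
## resolved toward state 0, and count state changes per edge.
.fitch_changes <- function(fp, X, root_leaf) {
  rt <- fp$rooting
  nn <- rt$n_nodes
  nchar_ <- ncol(X)
  state <- matrix(NA_integer_, nn, nchar_)
  state[root_leaf, ] <- X[root_leaf, ]
  changes <- matrix(0L, nn, nchar_)  # row v = changes on edge (parent(v), v)
  for (v in rt$preorder) {
    if (v == root_leaf) next
    ps <- state[rt$parent[v], ]
    keep0 <- fp$can0[v, ]; keep1 <- fp$can1[v, ]
    take_parent <- (ps == 0L & keep0) | (ps == 1L & keep1)
    st <- ifelse(take_parent, ps, ifelse(keep0, 0L, 1L))
    state[v, ] <- st
    changes[v, ] <- as.integer(st != ps)
  }
  list(state = state, changes_per_edge = rowSums(changes))
}

.clade_leaves <- function(rt, v, nleaf, labels) {
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (u <= nleaf) out <- c(out, u) else stack <- c(stack, rt$children[[u]])
  }
  sort(labels[out])
}

.newick_of <- function(rt, v, nleaf, labels, lens = NULL) {
  build <- function(u) {
    if (u <= nleaf) {
      s <- labels[u]
    } else {
      parts <- sort(vapply(rt$children[[u]], build, character(1)))
      s <- paste0("(", paste(parts, collapse = ","), ")")
    }
    if (!is.null(lens) && u != rt$preorder[1L])
      s <- paste0(s, ":", lens[u])
    s
  }
  ## root is a leaf: present as (subtree, root_leaf);
  kids <- rt$children[[rt$preorder[1L]]]
  parts <- sort(c(vapply(kids, build, character(1)),
                  paste0(labels[rt$preorder[1L]],
                         if (!is.null(lens)) ":0" else "")))
  paste0("(", paste(parts, collapse = ","), ");")
}

#' Exhaustive Wagner/Fitch parsimony tree search
#'
#' @param presence logical or 0/1 matrix, variants x samples (columns are
#'   taxa). The outgroup is appended as an all-absent taxon if not already a
#'   column.
#' @param outgroup outgroup taxon name used to root the tree.
#' @return object of class `wagner_tree`: list with `newick` (primary tree,
#'   canonical form, branch lengths = change counts), `total_score`,
#'   `branch_changes` (named by the child clade of each branch),
#'   `all_best_newick` (topology-only strings of every tied optimum),
#'   `n_topologies_searched`, and `taxa`.
#' @export
wagner_tree <- function(presence, outgroup = "TIL") {
  X <- t(as.matrix(presence) * 1L)  # taxa x characters
  if (!outgroup %in% rownames(X))
    X <- rbind(X, matrix(0L, 1, ncol(X), dimnames = list(outgroup, NULL)))
  taxa <- rownames(X)
  n <- length(taxa)
  if (n - 1L > 12L) stop("more than 12 ingroup taxa: exhaustive search not supported")
  if (n < 3L) stop("need at least 2 ingroup taxa plus the outgroup")
  drop_empty <- colSums(X) == 0 & ncol(X) > 0
  Xs <- X[, !drop_empty, drop = FALSE]
  topos <- all_topologies(n)
  og <- match(outgroup, taxa)
  scores <- vapply(topos, function(e) .fitch_pass(e, Xs, root_leaf = og)$total,
                   numeric(1))
  best <- which(scores == min(scores))
  ## canonical topology-only newick for each optimum, pick lexicographic min
  infos <- lapply(best, function(i) {
    fp <- .fitch_pass(topos[[i]], Xs, root_leaf = og)
    rt <- fp$rooting
    nw_topo <- .newick_of(rt, NULL, n, taxa)
    list(i = i, fp = fp, rt = rt, nw_topo = nw_topo)
  })
  ord <- order(vapply(infos, `[[`, character(1), "nw_topo"))
  infos <- infos[ord]
  prim <- infos[[1L]]
  ref <- .fitch_changes(prim$fp, Xs, og)
  stopifnot(sum(ref$changes_per_edge) == prim$fp$total)
  ## branch labels: the leaf set below each node (edge to its parent)
  lens <- ref$changes_per_edge
  labs <- vapply(seq_len(prim$rt$n_nodes), function(v)
    paste(.clade_leaves(prim$rt, v, n, taxa), collapse = "+"), character(1))
  bc <- setNames(lens, labs)[prim$rt$preorder[-1L]]
  structure(list(
    newick = .newick_of(prim$rt, NULL, n, taxa, lens = lens),
    topology_newick = prim$nw_topo,
    total_score = prim$fp$total,
    branch_changes = bc,
    all_best_newick = vapply(infos, `[[`, character(1), "nw_topo"),
    n_topologies_searched = length(topos),
    n_constant_dropped = sum(drop_empty),
    taxa = taxa
  ), class = "wagner_tree")
}

#' @export
print.wagner_tree <- function(x, ...) {
  cat("Wagner parsimony tree (exhaustive Fitch search)\n")
  cat("  taxa:", paste(x$taxa, collapse = ", "), "\n")
  cat("  topologies searched:", x$n_topologies_searched, "\n")
  cat("  total score:", x$total_score, "\n")
  cat("  primary tree:", x$newick, "\n")
  if (length(x$all_best_newick) > 1)
    cat("  (", length(x$all_best_newick), "equally parsimonious topologies )\n")
  invisible(x)
}

#' Topology-only canonical newick for a sample grouping
#'
#' Helper to compare a recovered tree against an expected grouping such as
#' `((Pa,Pb),(Ra,Rb))` rooted by the outgroup.
#' @param ingroup_newick unrooted/nested grouping over the ingroup, e.g.
#'   `"((Pa,Pb),(Ra,Rb))"`.
#' @param outgroup outgroup name.
#' @return canonical topology string comparable with
#'   `wagner_tree()$topology_newick`.
#' @export
canonical_topology <- function(ingroup_newick, outgroup = "TIL") {
  txt <- gsub(";$", "", ingroup_newick)
  ph <- ape::read.tree(text = paste0(txt, ";"))
  canon <- function(node) {
    kids <- ph$edge[ph$edge[, 1] == node, 2]
    if (!length(kids)) return(ph$tip.label[node])
    paste0("(", paste(sort(vapply(kids, canon, character(1))), collapse = ","), ")")
  }
  root <- setdiff(ph$edge[, 1], ph$edge[, 2])[1]
  inner <- canon(root)
  paste0("(", paste(sort(c(inner, outgroup)), collapse = ","), ");")
}
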