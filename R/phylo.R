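# Tree search lives on a light adjacency representation: nodes 1..ntip are
# leaves (in tip.label order), higher numbers internal; `adj` is a list of
# integer neighbor vectors, `elen` a named vector of branch lengths keyed by
# edge_key(u, v).  ape "phylo" objects are the public interface.

edge_key <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "|")

adj_add_edge <- function(adj, u, v) {
  adj[[u]] <- c(adj[[u]], v)
  adj[[v]] <- c(adj[[v]], u)
  adj
}

adj_drop_edge <- function(adj, u, v) {
  adj[[u]] <- adj[[u]][adj[[u]] != v]
  adj[[v]] <- adj[[v]][adj[[v]] != u]
  adj
}

adj_from_phylo <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  adj <- vector("list", nn)
  elen <- numeric(0)
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
    adj <- adj_add_edge(adj, u, v)
    if (!is.null(tree$edge.length))
      elen[edge_key(u, v)] <- tree$edge.length[k]
  }
  list(adj = adj, ntip = ntip, tip.label = tree$tip.label,
       elen = if (length(elen)) elen else NULL)
}

# Orient an adjacency tree from `root` (preorder internal renumbering) and
# return an ape phylo object.  With a degree-3+ root this yields ape's
# unrooted representation; with a degree-2 root a rooted binary tree.
adj_to_phylo <- function(st, root = NULL) {
  adj <- st$adj; ntip <- st$ntip
  nodes_present <- which(lengths(adj) > 0L | seq_along(adj) <= ntip)
  internal <- setdiff(nodes_present, seq_len(ntip))
  if (is.null(root)) root <- min(internal)
  newid <- integer(length(adj))
  newid[seq_len(ntip)] <- seq_len(ntip)
  counter <- ntip
  parent <- integer(0); child <- integer(0); elen_out <- numeric(0)
  # iterative DFS
  stack <- list(c(root, 0L))
  order_nodes <- integer(0)
  prev <- integer(length(adj))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    v <- top[1]; p <- top[2]
    prev[v] <- p
    order_nodes <- c(order_nodes, v)
    if (v > ntip) { counter <- counter + 1L; newid[v] <- counter }
    for (w in rev(sort(adj[[v]]))) if (w != p) stack[[length(stack) + 1L]] <- c(w, v)
  }
  for (v in order_nodes) {
    p <- prev[v]
    if (p == 0L) next
    parent <- c(parent, newid[p]); child <- c(child, newid[v])
    elen_out <- c(elen_out, if (!is.null(st$elen)) unname(st$elen[edge_key(p, v)]) else NA_real_)
  }
  tr <- list(edge = cbind(parent, child),
             tip.label = st$tip.label,
             Nnode = counter - ntip)
  if (!is.null(st$elen)) tr$edge.length <- elen_out
  dimnames(tr$edge) <- NULL
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

# Topological (edge-count) or weighted path lengths from every leaf to every
# leaf, by BFS over the adjacency structure.
leaf_path_counts <- function(adj, ntip) {
  nn <- length(adj)
  out <- matrix(0L, ntip, ntip)
  for (s in seq_len(ntip)) {
    dist <- rep(-1L, nn); dist[s] <- 0L
    queue <- s; head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      for (w in adj[[v]]) if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    out[s, ] <- dist[seq_len(ntip)]
  }
  out
}

# Leaf->leaf path as a sequence of nodes (BFS parent tracking).
adj_path <- function(adj, from, to) {
  nn <- length(adj)
  prev <- rep(0L, nn); prev[from] <- from
  queue <- from; head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    if (v == to) break
    for (w in adj[[v]]) if (prev[w] == 0L) { prev[w] <- v; queue <- c(queue, w) }
  }
  path <- to
  while (path[1] != from) path <- c(prev[path[1]], path)
  path
}

#' Neighbor-joining tree
#'
#' Classical neighbor joining (Studier-Keppler Q criterion) from a distance
#' matrix.  Ties in Q are broken deterministically by the lowest index pair.
#' Negative branch-length estimates are clamped to zero.
#'
#' @param dm a `dist_matrix` with at least 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  st <- nj_adj(dm)
  adj_to_phylo(st)
}

nj_adj <- function(dm) {
  n <- length(dm$taxa)
  if (n < 3L) stop("need at least 3 taxa")
  nn <- 2L * n - 2L
  adj <- vector("list", nn)
  elen <- numeric(0)
  active <- seq_len(n)                     # node ids of current clusters
  D <- dm$d
  rownames(D) <- colnames(D) <- NULL
  ids <- seq_len(n)                        # node id per row of D
  nextnode <- n
  while (length(ids) > 3L) {
    na <- length(ids)
    R <- rowSums(D)
    best <- NULL; bestQ <- Inf
    for (i in seq_len(na - 1L)) {
      for (j in (i + 1L):na) {
        q <- (na - 2) * D[i, j] - R[i] - R[j]
        if (q < bestQ - 1e-12) { bestQ <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (na - 2))
    lj <- D[i, j] - li
    nextnode <- nextnode + 1L
    adj <- adj_add_edge(adj, ids[i], nextnode)
    adj <- adj_add_edge(adj, ids[j], nextnode)
    elen[edge_key(ids[i], nextnode)] <- max(0, li)
    elen[edge_key(ids[j], nextnode)] <- max(0, lj)
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(na), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    ids <- c(ids[keep], nextnode)
  }
  # join the final three clusters at a central node
  x <- ids[1]; y <- ids[2]; z <- ids[3]
  nextnode <- nextnode + 1L
  lx <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  ly <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lz <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  adj <- adj_add_edge(adj, x, nextnode)
  adj <- adj_add_edge(adj, y, nextnode)
  adj <- adj_add_edge(adj, z, nextnode)
  elen[edge_key(x, nextnode)] <- max(0, lx)
  elen[edge_key(y, nextnode)] <- max(0, ly)
  elen[edge_key(z, nextnode)] <- max(0, lz)
  list(adj = adj, ntip = length(dm$taxa), tip.label = dm$taxa, elen = elen)
}

#' Balanced minimum-evolution length of a topology
#'
#' Pauplin's formula: `L = sum_{i<j} d_ij * 2^(-p_ij)` where `p_ij` is the
#' number of edges on the path between leaves i and j.  Branch lengths play
#' no role; this is the objective minimised by [me_tree()].
#'
#' @param tree an unrooted binary `phylo` topology over `dm$taxa`.
#' @param dm a `dist_matrix`.
#' @return the balanced minimum-evolution tree length.
#' @export
bme_tree_length <- function(tree, dm) {
  if (!setequal(tree$tip.label, dm$taxa))
    stop("tree taxa do not match distance matrix taxa")
  st <- adj_from_phylo(tree)
  bme_length_adj(st$adj, st$ntip,
                 match(st$tip.label, dm$taxa), dm$d)
}

bme_length_adj <- function(adj, ntip, tipmap, d) {
  p <- leaf_path_counts(adj, ntip)
  dd <- d[tipmap, tipmap]
  sum(dd[upper.tri(dd)] * 2^(-p[upper.tri(p)]))
}

# Internal edges (both endpoints internal), canonical order.
internal_edges <- function(adj, ntip) {
  out <- NULL
  for (u in (ntip + 1L):length(adj)) {
    if (!length(adj[[u]])) next
    for (v in adj[[u]]) if (v > u) out <- rbind(out, c(u, v))
  }
  if (is.null(out)) return(matrix(integer(0), 0, 2))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# Swap subtree x (neighbor of u) with subtree y (neighbor of v).
adj_nni_swap <- function(adj, u, x, v, y) {
  adj <- adj_drop_edge(adj, u, x)
  adj <- adj_drop_edge(adj, v, y)
  adj <- adj_add_edge(adj, u, y)
  adj_add_edge(adj, v, x)
}

#' Minimum-evolution tree by NJ start and NNI search
#'
#' Builds a neighbor-joining starting topology, then hill-climbs over
#' nearest-neighbor interchanges, minimising the balanced
#' minimum-evolution length ([bme_tree_length()]).  Branch lengths on the
#' final topology are estimated by ordinary least squares against the
#' distance matrix, with negative estimates clamped to zero.  The search is
#' fully deterministic.
#'
#' @param dm a `dist_matrix` (>= 3 taxa; for 3 taxa the NJ tree is
#'   returned).
#' @param strategy `"best"` accepts the best strictly-improving NNI per
#'   sweep, `"first"` the first one found.
#' @param max_sweeps sweep limit; if reached a warning is issued and the
#'   best tree so far returned.
#' @return an unrooted `phylo` tree with OLS branch lengths.
#' @export
me_tree <- function(dm, strategy = c("best", "first"), max_sweeps = 200L) {
  strategy <- match.arg(strategy)
  st <- nj_adj(dm)
  if (length(dm$taxa) == 3L) return(adj_to_phylo(st))
  adj <- st$adj; ntip <- st$ntip
  tipmap <- match(st$tip.label, dm$taxa)
  L <- bme_length_adj(adj, ntip, tipmap, dm$d)
  for (sweep in seq_len(max_sweeps)) {
    ie <- internal_edges(adj, ntip)
    best <- NULL; bestL <- L
    done <- FALSE
    for (k in seq_len(nrow(ie))) {
      u <- ie[k, 1]; v <- ie[k, 2]
      a <- sort(adj[[u]][adj[[u]] != v])
      c2 <- sort(adj[[v]][adj[[v]] != u])
      for (y in c2) {
        cand <- adj_nni_swap(adj, u, a[2], v, y)
        Lc <- bme_length_adj(cand, ntip, tipmap, dm$d)
        if (Lc < bestL - 1e-12) {
          bestL <- Lc; best <- cand
          if (strategy == "first") { done <- TRUE; break }
        }
      }
      if (done) break
    }
    if (is.null(best)) break
    adj <- best; L <- bestL
    if (sweep == max_sweeps)
      warning("NNI search did not converge within ", max_sweeps,
              " sweeps; returning best tree so far")
  }
  st$adj <- adj
  st$elen <- NULL
  tree <- adj_to_phylo(st)
  ols_branch_lengths(tree, dm)
}

#' Ordinary least-squares branch lengths for a fixed topology
#'
#' Solves the least-squares fit of the leaf-to-leaf path lengths to the
#' distance matrix; negative estimates are clamped to zero.
#'
#' @param tree a `phylo` topology over `dm$taxa`.
#' @param dm a `dist_matrix`.
#' @return `tree` with `edge.length` replaced by the OLS estimates.
#' @export
ols_branch_lengths <- function(tree, dm) {
  st <- adj_from_phylo(tree)
  adj <- st$adj; ntip <- st$ntip
  nedges <- nrow(tree$edge)
  keys <- edge_key(tree$edge[, 1], tree$edge[, 2])
  npairs <- ntip * (ntip - 1L) / 2L
  A <- matrix(0, npairs, nedges)
  b <- numeric(npairs)
  tipmap <- match(st$tip.label, dm$taxa)
  r <- 0L
  for (i in seq_len(ntip - 1L)) {
    for (j in (i + 1L):ntip) {
      r <- r + 1L
      path <- adj_path(adj, i, j)
      pk <- edge_key(path[-length(path)], path[-1])
      A[r, match(pk, keys)] <- 1
      b[r] <- dm$d[tipmap[i], tipmap[j]]
    }
  }
  est <- qr.coef(qr(A), b)
  est[is.na(est)] <- 0
  tree$edge.length <- pmax(est, 0)
  tree
}

#' Enumerate all unrooted binary topologies over a set of taxa
#'
#' Sequential leaf insertion; `(2n-5)!!` trees for `n` taxa.  Intended for
#' exhaustive minimum-evolution searches at small n (oracle-scale).
#'
#' @param taxa character vector of leaf labels (3 <= n <= 8 sensible).
#' @return list of unrooted `phylo` topologies (no branch lengths).
#' @export
all_topologies <- function(taxa) {
  n <- length(taxa)
  if (n < 3L) stop("need at least 3 taxa")
  nn <- 2L * n - 2L
  base <- vector("list", nn)
  base <- adj_add_edge(base, 1L, n + 1L)
  base <- adj_add_edge(base, 2L, n + 1L)
  base <- adj_add_edge(base, 3L, n + 1L)
  trees <- list(list(adj = base, nextnode = n + 1L))
  if (n > 3L) {
    for (k in 4L:n) {
      nxt <- list()
      for (tr in trees) {
        adj <- tr$adj
        # enumerate current edges once
        ed <- NULL
        for (u in seq_along(adj)) for (v in adj[[u]]) if (v > u)
          ed <- rbind(ed, c(u, v))
        for (e in seq_len(nrow(ed))) {
          u <- ed[e, 1]; v <- ed[e, 2]
          w <- tr$nextnode + 1L
          a2 <- adj_drop_edge(adj, u, v)
          a2 <- adj_add_edge(a2, u, w)
          a2 <- adj_add_edge(a2, v, w)
          a2 <- adj_add_edge(a2, k, w)
          nxt[[length(nxt) + 1L]] <- list(adj = a2, nextnode = w)
        }
      }
      trees <- nxt
    }
  }
  lapply(trees, function(tr)
    adj_to_phylo(list(adj = tr$adj, ntip = n, tip.label = taxa, elen = NULL)))
}

#' Exhaustive balanced minimum-evolution search
#'
#' Evaluates [bme_tree_length()] on every unrooted topology (small n only)
#' and returns the optimum — the oracle counterpart of [me_tree()].
#'
#' @param dm a `dist_matrix` with few taxa (n <= 8 sensible).
#' @return list with `tree` (the optimal topology, OLS branch lengths) and
#'   `length` (its balanced ME length).
#' @export
exhaustive_me_tree <- function(dm) {
  trees <- all_topologies(dm$taxa)
  lens <- vapply(trees, bme_tree_length, numeric(1), dm = dm)
  best <- which.min(lens)
  list(tree = ols_branch_lengths(trees[[best]], dm), length = lens[best])
}

# Leaf label sets on the far side of each edge (relative to `from` node).
edge_leafsets <- function(adj, ntip, tip.label) {
  ed <- NULL
  for (u in seq_along(adj)) for (v in adj[[u]]) if (v > u)
    ed <- rbind(ed, c(u, v))
  sets <- vector("list", nrow(ed))
  for (k in seq_len(nrow(ed))) {
    u <- ed[k, 1]; v <- ed[k, 2]
    # BFS from v with edge (u,v) removed
    seen <- rep(FALSE, length(adj)); seen[v] <- TRUE
    queue <- v; head <- 1L
    while (head <= length(queue)) {
      x <- queue[head]; head <- head + 1L
      for (w in adj[[x]]) if (!seen[w] && !(x == v && w == u)) {
        seen[w] <- TRUE; queue <- c(queue, w)
      }
    }
    sets[[k]] <- sort(tip.label[which(seen[seq_len(ntip)])])
  }
  list(edges = ed, leafsets = sets)
}

#' Root an unrooted tree on the edge above an outgroup
#'
#' The root is placed on the edge separating the outgroup from the rest of
#' the leaves, splitting that edge's length equally.  Errors if the
#' outgroup is not monophyletic in the unrooted tree.
#'
#' @param tree an unrooted `phylo`.
#' @param outgroup character vector of leaf labels.
#' @return a rooted `phylo` (root of degree 2).
#' @export
root_tree <- function(tree, outgroup) {
  if (!all(outgroup %in% tree$tip.label))
    stop("outgroup labels not in tree: ",
         paste(setdiff(outgroup, tree$tip.label), collapse = ", "))
  if (setequal(outgroup, tree$tip.label))
    stop("outgroup cannot contain all leaves")
  tree <- ape::unroot(tree)
  st <- adj_from_phylo(tree)
  og <- sort(outgroup)
  els <- edge_leafsets(st$adj, st$ntip, st$tip.label)
  hit <- 0L
  for (k in seq_along(els$leafsets)) {
    s <- els$leafsets[[k]]
    if (identical(s, og) ||
        identical(sort(setdiff(st$tip.label, s)), og)) { hit <- k; break }
  }
  if (hit == 0L) {
    # report the smallest clade containing the outgroup for diagnostics
    sizes <- vapply(els$leafsets, function(s)
      if (all(og %in% s)) length(s) else
        if (all(og %in% setdiff(st$tip.label, s)))
          length(st$tip.label) - length(s) else NA_integer_, integer(1))
    best <- which.min(sizes)
    clash <- els$leafsets[[best]]
    if (!all(og %in% clash)) clash <- setdiff(st$tip.label, clash)
    stop("outgroup {", paste(og, collapse = ","),
         "} is not monophyletic; smallest containing split is {",
         paste(clash, collapse = ","), "}")
  }
  u <- els$edges[hit, 1]; v <- els$edges[hit, 2]
  e <- if (!is.null(st$elen)) unname(st$elen[edge_key(u, v)]) else NA_real_
  rootnode <- length(st$adj) + 1L
  st$adj[[rootnode]] <- integer(0)
  st$adj <- adj_drop_edge(st$adj, u, v)
  st$adj <- adj_add_edge(st$adj, u, rootnode)
  st$adj <- adj_add_edge(st$adj, v, rootnode)
  if (!is.null(st$elen)) {
    st$elen <- st$elen[names(st$elen) != edge_key(u, v)]
    st$elen[edge_key(u, rootnode)] <- e / 2
    st$elen[edge_key(v, rootnode)] <- e / 2
  }
  adj_to_phylo(st, root = rootnode)
}

# Non-trivial bipartitions of an unrooted tree as canonical strings.
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  st <- adj_from_phylo(tree)
  els <- edge_leafsets(st$adj, st$ntip, st$tip.label)
  ref <- min(st$tip.label)
  n <- st$ntip
  out <- character(0)
  for (s in els$leafsets) {
    if (length(s) < 2L || length(s) > n - 2L) next
    if (ref %in% s) s <- sort(setdiff(st$tip.label, s))
    out <- c(out, paste(s, collapse = "|"))
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of non-trivial bipartitions; 0 means the
#' unrooted topologies are identical.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return integer RF distance.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Root-to-tip path lengths of a rooted tree
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return named numeric vector of root-to-leaf path lengths.
#' @export
root_to_tip <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  stats::setNames(d[seq_along(tree$tip.label)], tree$tip.label)
}

#' Estimate the paralog rate-multiplier from a tree
#'
#' For each pair of species present in both paralog sets, the patristic
#' distance between their isoform-1 copies is divided by the distance
#' between their isoform-2 copies; under a clock-like species tree with a
#' uniform isoform-1 rate multiplier r, each ratio estimates r (duplicated
#' subtree depths scale by r).  The mean over pairs is returned.
#'
#' @param tree a `phylo` containing both paralog copies as leaves.
#' @param iso1_ids,iso2_ids leaf labels of the two paralog sets, matched by
#'   species (same order, same length).
#' @return estimated rate multiplier (mean of pairwise ratios).
#' @export
paralog_rate_ratio <- function(tree, iso1_ids, iso2_ids) {
  stopifnot(length(iso1_ids) == length(iso2_ids), length(iso1_ids) >= 2L)
  pd <- ape::cophenetic.phylo(tree)
  n <- length(iso1_ids)
  ratios <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d2 <- pd[iso2_ids[i], iso2_ids[j]]
      if (d2 > 0)
        ratios <- c(ratios, pd[iso1_ids[i], iso1_ids[j]] / d2)
    }
  }
  if (!length(ratios)) stop("no usable species pairs (zero distances)")
  mean(ratios)
}

#' Write a tree to a Newick file
#'
#' Branch lengths are written in substitutions per site with 6 decimal
#' places (a length of 0.01 is one substitution per 100 sites).
#'
#' @param tree a `phylo`.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file.
#' @return a `phylo`.
#' @export
read_newick <- function(path) ape::read.tree(path)
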