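# Independent brute-force oracles used across the suite.  These are kept
# deliberately naive: enumeration and direct summation, sharing no code
# with the implementation paths they check.

# --- global alignment: exhaustive enumeration over all alignments --------
# Affine convention: a gap run of length L costs open + L * ext.
bf_align_score <- function(a, b, mat, open, ext) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  la <- length(va); lb <- length(vb)
  best <- -Inf
  rec <- function(i, j, state, acc) {
    if (i == la && j == lb) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (i < la && j < lb)
      rec(i + 1L, j + 1L, 0L, acc + mat[va[i + 1L], vb[j + 1L]])
    if (i < la)   # va[i+1] against a gap
      rec(i + 1L, j, 1L, acc - ext - if (state == 1L) 0 else open)
    if (j < lb)
      rec(i, j + 1L, 2L, acc - ext - if (state == 2L) 0 else open)
  }
  rec(0L, 0L, -1L, 0)
  best
}

# --- likelihood: direct summation over all internal-state assignments ----
# tree: rooted phylo; column: named residues; model: equal_input_model.
bf_site_likelihood <- function(tree, column, model) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  internal <- (ntip + 1L):nn
  P <- lapply(seq_len(nrow(tree$edge)), function(k)
    transition_matrix(model, tree$edge.length[k]))
  leafstate <- match(column[tree$tip.label], AA20)  # NA = missing
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  root <- ntip + 1L
  pr <- model$pi[grid[, root - ntip]]
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
    su <- grid[, u - ntip]
    if (v <= ntip) {
      if (!is.na(leafstate[v])) pr <- pr * P[[k]][cbind(su, leafstate[v])]
    } else {
      pr <- pr * P[[k]][cbind(su, grid[, v - ntip])]
    }
  }
  sum(pr)
}

# Marginal posterior at one internal node by conditioning the brute force.
bf_node_posterior <- function(tree, column, model, node) {
  ntip <- length(tree$tip.label)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  P <- lapply(seq_len(nrow(tree$edge)), function(k)
    transition_matrix(model, tree$edge.length[k]))
  leafstate <- match(column[tree$tip.label], AA20)
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  root <- ntip + 1L
  pr <- model$pi[grid[, root - ntip]]
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
    su <- grid[, u - ntip]
    if (v <= ntip) {
      if (!is.na(leafstate[v])) pr <- pr * P[[k]][cbind(su, leafstate[v])]
    } else {
      pr <- pr * P[[k]][cbind(su, grid[, v - ntip])]
    }
  }
  post <- vapply(1:20, function(s)
    sum(pr[grid[, node - ntip] == s]), numeric(1))
  post / sum(post)
}

# --- random additive distance matrix from a random tree ------------------
random_additive_dm <- function(n, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n, tip.label = paste0("t", seq_len(n))))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  d <- ape::cophenetic.phylo(tr)
  list(tree = tr, dm = as_dist_matrix(d))
}

# --- small fixtures ------------------------------------------------------
toy_joint_alignment <- function() {
  alignment(c(h1 = "AC-EFGHIK", s1 = "AC-EFGHIK", t1 = "AC-EFGHIR",
              h2 = "ADWEFGHLK", s2 = "ADWEFGHLK", t2 = "GDWEFGHLK"))
}

toy_isoform_map <- function() {
  c(h1 = "ISO1", s1 = "ISO1", t1 = "ISO1",
    h2 = "ISO2", s2 = "ISO2", t2 = "ISO2")
}

mutate_seq <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  at <- sample(length(v), k)
  for (i in at) v[i] <- sample(setdiff(AA20, v[i]), 1)
  paste(v, collapse = "")
}

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# Shallow duplication-free simulation used for topology-recovery checks.
# Random topologies with every branch bounded away from zero: an internal
# edge much shorter than 1/n_sites expected substitutions is unresolvable
# by construction and would measure the noise floor, not the search.
shallow_sim_config <- function(seed, n_species = 12L, n_sites = 2000L) {
  set.seed(100000L + seed)
  sp <- ape::rtree(n_species, tip.label = sprintf("sp%02d", seq_len(n_species)))
  sp$edge.length <- stats::runif(nrow(sp$edge), 0.02, 0.15)
  sim_config(species_tree = sp, duplication_clade = NULL,
             site_classes = NULL,
             motif_blocks = data.frame(start = integer(), end = integer()),
             iso1_deletion = NULL, seq_length = n_sites, seed = seed)
}

# uniform-rate duplication config for rate-multiplier recovery
rate_recovery_config <- function(seed, r = 2) {
  sim_config(seed = seed, rate_multiplier = r, site_classes = NULL,
             motif_blocks = data.frame(start = integer(), end = integer()),
             iso1_deletion = NULL)
}
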