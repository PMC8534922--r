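#' Equal-input (F81-type) amino-acid substitution model
#'
#' Time-reversible model with stationary frequencies `pi` and closed-form
#' transition probabilities
#' `P_ij(t) = exp(-beta t) * delta_ij + (1 - exp(-beta t)) * pi_j`,
#' where `beta = 1 / (1 - sum(pi^2))` normalises branch lengths to expected
#' substitutions per site.
#'
#' @param pi stationary frequencies over the 20 amino acids (named or in
#'   [AA20] order); default uniform.
#' @param aln optional `aln` object; when given and `pi` is `NULL`, `pi` is
#'   set to the empirical residue frequencies of the alignment (with a
#'   small floor so no frequency is zero).
#' @return object of class `equal_input_model` with `pi` and `beta`.
#' @export
equal_input_model <- function(pi = NULL, aln = NULL) {
  if (is.null(pi)) {
    if (is.null(aln)) {
      pi <- rep(1 / 20, 20)
    } else {
      cnt <- table(factor(aln$mat[aln$mat %in% AA20], levels = AA20))
      pi <- (as.numeric(cnt) + 0.5) / sum(as.numeric(cnt) + 0.5)
    }
    names(pi) <- AA20
  } else {
    if (!is.null(names(pi))) pi <- pi[AA20]
    if (length(pi) != 20 || any(is.na(pi)) || any(pi <= 0))
      stop("pi must give a positive frequency for all 20 amino acids")
    pi <- pi / sum(pi)
    names(pi) <- AA20
  }
  structure(list(pi = pi, beta = 1 / (1 - sum(pi^2))),
            class = "equal_input_model")
}

#' Transition probability matrix of the equal-input model
#'
#' @param model an `equal_input_model`.
#' @param t branch length in substitutions per site (>= 0).
#' @return 20 x 20 row-stochastic matrix `P(t)`.
#' @export
transition_matrix <- function(model, t) {
  if (t < 0) stop("branch length must be >= 0")
  e <- exp(-model$beta * t)
  P <- (1 - e) * matrix(model$pi, 20, 20, byrow = TRUE)
  diag(P) <- diag(P) + e
  dimnames(P) <- list(AA20, AA20)
  P
}

# residues (character) -> 20 x S partial-likelihood matrix; gaps, X and NA
# are missing data (all-ones column).
leaf_partials <- function(residues) {
  S <- length(residues)
  L <- matrix(1, 20, S)
  known <- which(residues %in% AA20)
  if (length(known)) {
    L[, known] <- 0
    L[cbind(match(residues[known], AA20), known)] <- 1
  }
  L
}

# Shared pruning machinery.  Returns per-node partials (scaled), per-node
# up-messages, per-site log-scale accumulators and bookkeeping.
prune_tree <- function(tree, aln, model) {
  ntip <- length(tree$tip.label)
  if (!all(tree$tip.label %in% aln$ids))
    stop("alignment is missing tree leaves: ",
         paste(setdiff(tree$tip.label, aln$ids), collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  S <- ncol(aln$mat)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  partial <- vector("list", nn)
  upmsg <- vector("list", nn)       # message from node to its parent
  logscale <- numeric(S)
  for (v in seq_len(ntip)) partial[[v]] <- leaf_partials(aln$mat[tree$tip.label[v], ])
  # accumulate products at parents in postorder
  prodat <- vector("list", nn)
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; v <- po$edge[k, 2]
    if (v > ntip) {
      partial[[v]] <- prodat[[v]]
      # per-site scaling
      mx <- apply(partial[[v]], 2, max)
      mx[mx == 0] <- 1
      partial[[v]] <- sweep(partial[[v]], 2, mx, "/")
      logscale <- logscale + log(mx)
    }
    P <- transition_matrix(model, po$edge.length[k])
    upmsg[[v]] <- P %*% partial[[v]]
    prodat[[p]] <- if (is.null(prodat[[p]])) upmsg[[v]] else
      prodat[[p]] * upmsg[[v]]
  }
  root <- po$edge[nrow(po$edge), 1]
  partial[[root]] <- prodat[[root]]
  mx <- apply(partial[[root]], 2, max)
  mx[mx == 0] <- 1
  partial[[root]] <- sweep(partial[[root]], 2, mx, "/")
  logscale <- logscale + log(mx)
  site_ll <- log(colSums(model$pi * partial[[root]])) + logscale
  list(partial = partial, upmsg = upmsg, root = root, ntip = ntip,
       S = S, site_ll = site_ll, tree = tree)
}

#' Per-site log-likelihood of an alignment on a rooted tree
#'
#' Felsenstein pruning under the equal-input model; gaps and `X` are
#' treated as missing data.  Partial likelihoods are rescaled per node and
#' site to avoid underflow.
#'
#' @param tree a rooted `phylo` with branch lengths (substitutions/site).
#' @param aln an `aln` whose sequences cover all tree leaves.
#' @param model an `equal_input_model`.
#' @return numeric vector of per-site log-likelihoods.
#' @export
tree_log_likelihood <- function(tree, aln, model) {
  prune_tree(tree, aln, model)$site_ll
}

#' Log-likelihood of a single alignment column
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param column named character vector of leaf residues (names = leaf
#'   labels); gaps/`X`/`NA` are missing data.
#' @param model an `equal_input_model`.
#' @return the log-likelihood of the column.
#' @export
site_log_likelihood <- function(tree, column, model) {
  missing <- setdiff(tree$tip.label, names(column))
  if (length(missing))
    stop("column lacks residues for leaves: ",
         paste(missing, collapse = ", "))
  v <- column[tree$tip.label]
  v[is.na(v) | v == GAP_CHAR] <- UNKNOWN_CHAR  # both mean "missing" here
  aln <- alignment(stats::setNames(v, tree$tip.label))
  tree_log_likelihood(tree, aln, model)[1]
}

#' Marginal maximum-likelihood ancestral reconstruction
#'
#' Computes, for every internal node and site, the posterior distribution
#' over the 20 amino acids given all leaf data (up-down message passing on
#' the rooted tree), and the maximum-a-posteriori residue (ties broken
#' alphabetically).
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param aln an `aln` covering all tree leaves.
#' @param model an `equal_input_model`.
#' @return object of class `ancestral_recon`: list with `posterior` (named
#'   list of 20 x S matrices, one per internal node), `map` (named
#'   character vector of MAP sequences), `site_loglik`, `node_labels`,
#'   `tree`.
#' @export
marginal_posteriors <- function(tree, aln, model) {
  pr <- prune_tree(tree, aln, model)
  ntip <- pr$ntip; S <- pr$S
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  children <- split(po$edge[, 2], po$edge[, 1])
  edge_len <- stats::setNames(po$edge.length,
                              paste(po$edge[, 1], po$edge[, 2]))
  outside <- vector("list", nn)
  outside[[pr$root]] <- matrix(model$pi, 20, S)
  # preorder: parents before children
  for (k in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[k, 1]; v <- po$edge[k, 2]
    if (v <= ntip) next
    sibs <- setdiff(children[[as.character(p)]], v)
    m <- outside[[p]]
    for (w in sibs) m <- m * pr$upmsg[[w]]
    P <- transition_matrix(model, edge_len[paste(p, v)])
    ov <- crossprod(P, m)         # t(P) %*% m
    mx <- apply(ov, 2, max); mx[mx == 0] <- 1
    outside[[v]] <- sweep(ov, 2, mx, "/")
  }
  labels <- node_label_vector(tree)
  internal <- (ntip + 1L):nn
  posterior <- vector("list", length(internal))
  map <- character(length(internal))
  for (i in seq_along(internal)) {
    v <- internal[i]
    post <- outside[[v]] * pr$partial[[v]]
    post <- sweep(post, 2, colSums(post), "/")
    rownames(post) <- AA20
    posterior[[i]] <- post
    map[i] <- paste(AA20[apply(post, 2, which.max)], collapse = "")
  }
  names(posterior) <- names(map) <- labels
  structure(list(posterior = posterior, map = map,
                 site_loglik = pr$site_ll, node_labels = labels,
                 tree = tree),
            class = "ancestral_recon")
}

node_label_vector <- function(tree) {
  ntip <- length(tree$tip.label)
  if (!is.null(tree$node.label) && all(nzchar(tree$node.label)))
    tree$node.label
  else paste0("node", (ntip + 1L):(ntip + tree$Nnode))
}

#' Write ancestral reconstruction outputs
#'
#' FASTA of MAP sequences (one entry per internal node) and a TSV of
#' `(node, site, map, posterior_map)`.
#'
#' @param recon an `ancestral_recon`.
#' @param fasta_path output FASTA for MAP sequences.
#' @param tsv_path optional output TSV of per-site MAP posteriors.
#' @export
write_ancestral_fasta <- function(recon, fasta_path, tsv_path = NULL) {
  write_fasta(recon$map, fasta_path)
  if (!is.null(tsv_path)) {
    rows <- lapply(names(recon$posterior), function(nm) {
      post <- recon$posterior[[nm]]
      mapres <- strsplit(recon$map[nm], "")[[1]]
      data.frame(node = nm, site = seq_len(ncol(post)), map = mapres,
                 posterior_map = post[cbind(match(mapres, AA20),
                                            seq_len(ncol(post)))],
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    con <- file(tsv_path, "w")
    writeLines("# paraloglens ancestral MAP posteriors", con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  invisible(fasta_path)
}

#' Read back the ancestral posterior TSV
#'
#' @param path TSV written by [write_ancestral_fasta()].
#' @export
read_ancestral_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
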