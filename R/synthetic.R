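#' Default 12-species ultrametric species tree
#'
#' Twelve species `sp01..sp12`; the clade `sp01..sp06` is the one carrying
#' the younger paralog in the default simulation. Root-to-tip depth 0.25
#' substitutions per site at unit rate.
#'
#' @return a rooted `phylo` with branch lengths.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "((((sp01:0.05,sp02:0.05):0.05,(sp03:0.05,sp04:0.05):0.05):0.05,",
    "(sp05:0.10,sp06:0.10):0.05):0.10,",
    "(((sp07:0.05,sp08:0.05):0.05,(sp09:0.05,sp10:0.05):0.05):0.05,",
    "(sp11:0.10,sp12:0.10):0.05):0.10);"))
}

#' Simulation configuration for a paralog family
#'
#' Defines the conditions emulated by [simulate_paralogs()]: a species
#' tree; a gene duplication restricted to one clade (the isoform-1 paralog
#' exists only there, isoform 2 on all leaves); a rate multiplier `r >= 1`
#' on all isoform-1 branches (the younger paralog evolves faster); per-site
#' rate classes (conserved domain blocks vs drifting termini); planted
#' isoform-specific motif blocks (frozen within each isoform, forced
#' different between isoforms); and an N-terminal span deleted in
#' isoform 1 (the lost domain).
#'
#' @param species_tree rooted `phylo` with branch lengths (default
#'   [default_species_tree()]).
#' @param duplication_clade leaf labels of the clade carrying isoform 1
#'   (must be monophyletic), or `NULL` for no duplication (a single
#'   orthologous family labelled ISO2).
#' @param rate_multiplier branch-rate multiplier `r >= 1` for isoform-1
#'   branches.
#' @param site_classes data frame (`start`, `end`, `rate`) of relative-rate
#'   blocks; unspanned sites have rate 1.
#' @param motif_blocks data frame (`start`, `end`) of planted
#'   isoform-specific blocks (relative rate 0 within isoforms).
#' @param iso1_deletion `c(start, end)` span deleted in isoform-1
#'   sequences, or `NULL`.
#' @param seq_length number of sites.
#' @param pi stationary amino-acid frequencies (default uniform).
#' @param seed integer seed; the simulation is byte-reproducible given the
#'   config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(species_tree = default_species_tree(),
                       duplication_clade = paste0("sp0", 1:6),
                       rate_multiplier = 2,
                       site_classes = default_site_classes(),
                       motif_blocks = data.frame(start = 540L, end = 556L),
                       iso1_deletion = c(1L, 100L),
                       seq_length = 900L,
                       pi = NULL,
                       seed = 1L) {
  cfg <- list(species_tree = species_tree,
              duplication_clade = duplication_clade,
              rate_multiplier = rate_multiplier,
              site_classes = site_classes,
              motif_blocks = motif_blocks,
              iso1_deletion = iso1_deletion,
              seq_length = as.integer(seq_length),
              model = equal_input_model(pi),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Default per-site rate classes
#'
#' Emulates a two-domain protein layout: drifting N/C-terminal
#' extremities, two strongly conserved domain blocks (a cyclic-nucleotide
#' binding domain analogue and a catalytic domain analogue) and a
#' moderately conserved interaction region hosting the motif block.
#'
#' @return data frame with columns `start`, `end`, `rate`.
#' @export
default_site_classes <- function() {
  data.frame(start = c(1L, 101L, 261L, 451L, 621L, 851L),
             end = c(100L, 260L, 450L, 620L, 850L, 900L),
             rate = c(2.0, 0.25, 1.0, 0.7, 0.25, 2.0))
}

validate_sim_config <- function(cfg) {
  L <- cfg$seq_length
  if (L < 1L) stop("seq_length must be positive")
  if (cfg$rate_multiplier < 1) stop("rate_multiplier must be >= 1")
  if (!inherits(cfg$species_tree, "phylo") ||
      is.null(cfg$species_tree$edge.length))
    stop("species_tree must be a phylo with branch lengths")
  sc <- cfg$site_classes
  if (!is.null(sc) && nrow(sc)) {
    if (any(sc$start < 1L | sc$end > L | sc$start > sc$end))
      stop("site_classes spans must lie within 1..seq_length")
    if (any(sc$rate < 0)) stop("site rates must be >= 0")
    cov <- unlist(mapply(seq, sc$start, sc$end, SIMPLIFY = FALSE))
    if (anyDuplicated(cov)) stop("site_classes spans must be disjoint")
  }
  mb <- cfg$motif_blocks
  if (!is.null(mb) && nrow(mb)) {
    if (any(mb$start < 1L | mb$end > L | mb$start > mb$end))
      stop("motif_blocks spans must lie within 1..seq_length")
    cov <- unlist(mapply(seq, mb$start, mb$end, SIMPLIFY = FALSE))
    if (anyDuplicated(cov)) stop("motif_blocks must be disjoint")
    if (!is.null(cfg$iso1_deletion) &&
        any(mb$start <= cfg$iso1_deletion[2] &
            mb$end >= cfg$iso1_deletion[1]))
      stop("motif_blocks must not overlap iso1_deletion")
  }
  if (!is.null(cfg$iso1_deletion)) {
    d <- cfg$iso1_deletion
    if (length(d) != 2L || d[1] < 1L || d[2] > L || d[1] > d[2])
      stop("iso1_deletion must be c(start, end) within 1..seq_length")
  }
  if (!is.null(cfg$duplication_clade)) {
    if (!all(cfg$duplication_clade %in% cfg$species_tree$tip.label))
      stop("duplication_clade species missing from species tree")
    if (length(cfg$duplication_clade) < 2L)
      stop("duplication_clade needs at least 2 species")
  }
  invisible(cfg)
}

# Newick for the gene tree: the species tree with, at the duplication
# node, two parallel copies of the duplicated subtree (stem length 0);
# isoform-1 branch lengths are scaled by the rate multiplier.  Internal
# labels A1_*/A2_* identify ancestors; DUP marks the duplication node.
gene_tree_newick <- function(tree, dup_node, r) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- stats::setNames(tree$edge.length,
                          paste(tree$edge[, 1], tree$edge[, 2]))
  sub <- function(v, iso, mult) {
    lab <- if (v <= ntip) paste0(tree$tip.label[v], "_", iso)
           else paste0("A", substr(iso, 4, 4), "_", v)
    if (!is.null(dup_node) && v == dup_node && iso == "ISO2") {
      inner2 <- sub_children(v, "ISO2", 1)
      inner1 <- sub_children(v, "ISO1", r)
      return(paste0("(", inner1, ":0,", inner2, ":0)DUP"))
    }
    if (v <= ntip) return(lab)
    ch <- kids[[as.character(v)]]
    paste0("(", paste(vapply(ch, function(w)
      paste0(sub(w, iso, mult), ":",
             format(elen[paste(v, w)] * mult, digits = 10)),
      character(1)), collapse = ","), ")", lab)
  }
  sub_children <- function(v, iso, mult) {
    ch <- kids[[as.character(v)]]
    lab <- paste0("A", substr(iso, 4, 4), "_", v)
    paste0("(", paste(vapply(ch, function(w)
      paste0(sub(w, iso, mult), ":",
             format(elen[paste(v, w)] * mult, digits = 10)),
      character(1)), collapse = ","), ")", lab)
  }
  root <- ntip + 1L
  paste0(sub(root, "ISO2", 1), ";")
}

#' Simulate a paralog family with known ground truth
#'
#' Draws a root sequence from the model's stationary frequencies and
#' evolves it down the gene tree (species tree plus duplication) under the
#' equal-input model with per-site relative rates.  Motif-block sites have
#' rate 0; on the isoform-1 side of the duplication the block residues are
#' replaced by a frozen alternative string differing at every position.
#' Isoform-1 sequences finally lose the deletion span.  The emitted
#' alignment is the by-construction true alignment (gap block for the
#' deletion).
#'
#' @param config a `sim_config`.
#' @return list with `records` (a `seq_records` data frame), `aln` (the
#'   true `aln`), and `truth` (list: `gene_tree`, `ancestors`,
#'   `motif_truth`, `motif_strings`, `site_rates`, `branch_expected`,
#'   `config`).
#' @export
simulate_paralogs <- function(config) {
  validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  L <- config$seq_length
  model <- config$model
  pi <- model$pi; beta <- model$beta
  rates <- rep(1, L)
  sc <- config$site_classes
  if (!is.null(sc) && nrow(sc))
    for (k in seq_len(nrow(sc))) rates[sc$start[k]:sc$end[k]] <- sc$rate[k]
  mb <- config$motif_blocks
  motif_sites <- integer(0)
  if (!is.null(mb) && nrow(mb)) {
    motif_sites <- unlist(mapply(seq, mb$start, mb$end, SIMPLIFY = FALSE))
    rates[motif_sites] <- 0
  }

  dup_node <- NULL
  if (!is.null(config$duplication_clade)) {
    dup_node <- ape::getMRCA(config$species_tree, config$duplication_clade)
    clade_tips <- ape::extract.clade(config$species_tree, dup_node)$tip.label
    if (!setequal(clade_tips, config$duplication_clade))
      stop("duplication_clade is not monophyletic in the species tree ",
           "(clade at its MRCA is {", paste(sort(clade_tips), collapse = ","),
           "})")
  }
  gt <- ape::read.tree(text = gene_tree_newick(config$species_tree, dup_node,
                                               config$rate_multiplier))

  # evolve along the gene tree (preorder); integer state vectors 1..20
  ntip <- length(gt$tip.label)
  nn <- ntip + gt$Nnode
  seqs <- vector("list", nn)
  root <- ntip + 1L
  seqs[[root]] <- sample.int(20, L, replace = TRUE, prob = pi)
  # frozen alternative motif string for isoform 1, differing everywhere
  iso1_motif <- seqs[[root]]
  for (s in motif_sites) {
    alt <- sample.int(20, 1, prob = pi)
    while (alt == seqs[[root]][s]) alt <- sample.int(20, 1, prob = pi)
    iso1_motif[s] <- alt
  }
  labels <- c(gt$tip.label, node_label_vector(gt))
  pre <- ape::reorder.phylo(gt, "cladewise")
  for (k in seq_len(nrow(pre$edge))) {
    p <- pre$edge[k, 1]; v <- pre$edge[k, 2]
    t <- pre$edge.length[k]
    s <- seqs[[p]]
    if (t > 0) {
      stayp <- exp(-beta * rates * t)
      mut <- stats::runif(L) >= stayp
      if (any(mut))
        s[mut] <- sample.int(20, sum(mut), replace = TRUE, prob = pi)
    }
    # entering the isoform-1 copy: plant the alternative motif string
    if (grepl("_ISO1$", labels[v]) || grepl("^A1_", labels[v])) {
      plab <- labels[p]
      if (identical(plab, "DUP")) s[motif_sites] <- iso1_motif[motif_sites]
    }
    seqs[[v]] <- s
  }

  all_chr <- vapply(seqs, function(s) paste(AA20[s], collapse = ""),
                    character(1))
  names(all_chr) <- labels
  leaf_seqs <- all_chr[gt$tip.label]

  # alignment rows: isoform-1 leaves carry a gap block over the deletion
  rows <- leaf_seqs
  del <- config$iso1_deletion
  iso1_leaves <- grep("_ISO1$", names(rows), value = TRUE)
  if (!is.null(del) && length(iso1_leaves)) {
    gapblk <- paste(rep(GAP_CHAR, del[2] - del[1] + 1L), collapse = "")
    for (id in iso1_leaves) {
      substr(rows[id], del[1], del[2]) <- gapblk
    }
  }
  aln <- alignment(rows)
  records <- seq_records(
    id = names(rows),
    residues = gsub("-", "", rows, fixed = TRUE),
    species = sub("_(ISO1|ISO2)$", "", names(rows)),
    isoform = sub("^.*_(ISO1|ISO2)$", "\\1", names(rows)))

  # planted motif coordinates in ungapped reference coordinates
  motif_truth <- NULL
  if (!is.null(mb) && nrow(mb)) {
    dlen <- if (is.null(del)) 0L else del[2] - del[1] + 1L
    off1 <- ifelse(mb$start > (if (is.null(del)) 0L else del[2]), dlen, 0L)
    motif_truth <- rbind(
      data.frame(isoform = "ISO1", start = mb$start - off1,
                 end = mb$end - off1, col_start = mb$start,
                 col_end = mb$end, stringsAsFactors = FALSE),
      data.frame(isoform = "ISO2", start = mb$start, end = mb$end,
                 col_start = mb$start, col_end = mb$end,
                 stringsAsFactors = FALSE))
  }
  branch_expected <- data.frame(
    parent = labels[gt$edge[, 1]], child = labels[gt$edge[, 2]],
    length = gt$edge.length,
    expected_subst = gt$edge.length * mean(rates),
    stringsAsFactors = FALSE)
  truth <- list(gene_tree = gt,
                ancestors = all_chr[setdiff(labels, gt$tip.label)],
                motif_truth = motif_truth,
                motif_strings = list(
                  ISO1 = paste(AA20[iso1_motif[motif_sites]], collapse = ""),
                  ISO2 = paste(AA20[seqs[[root]][motif_sites]], collapse = "")),
                site_rates = rates,
                branch_expected = branch_expected,
                config = config)
  list(records = records, aln = aln, truth = truth)
}

#' Write simulation ground truth to TSV/Newick/FASTA files
#'
#' @param truth the `truth` element of [simulate_paralogs()] output.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
truth_tables <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(truth$gene_tree, file.path(dir, "true_tree.nwk"))
  write_fasta(truth$ancestors, file.path(dir, "true_ancestors.fasta"))
  if (!is.null(truth$motif_truth)) {
    con <- file(file.path(dir, "motifs_truth.tsv"), "w")
    writeLines("# paraloglens planted motif coordinates (ungapped reference)",
               con)
    utils::write.table(truth$motif_truth, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  invisible(dir)
}
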