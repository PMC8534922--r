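test_that("equal-input transition matrices satisfy the model identities", {
  set.seed(2)
  pi <- stats::setNames(as.numeric(stats::runif(20, 0.5, 2)), AA20)
  model <- equal_input_model(pi)
  expect_equal(sum(model$pi), 1)
  for (t in c(0, 0.01, 0.3, 2)) {
    P <- transition_matrix(model, t)
    expect_equal(unname(rowSums(P)), rep(1, 20))
    # detailed balance pi_i P_ij = pi_j P_ji
    F <- model$pi * P
    expect_equal(F, t(F), tolerance = 1e-12)
  }
  expect_equal(transition_matrix(model, 0), diag(20),
               ignore_attr = TRUE)
  Pinf <- transition_matrix(model, 1e6)
  expect_equal(unname(Pinf[3, ]), unname(model$pi), tolerance = 1e-9)
  expect_error(transition_matrix(model, -1), ">= 0")
})

test_that("single-column likelihoods match direct closed forms", {
  model <- equal_input_model()
  # single pendant branch of length 0 below the root
  tr <- ape::read.tree(text = "(A:0,B:1e9);")
  ll <- site_log_likelihood(tr, c(A = "A", B = "X"), model)
  expect_equal(ll, log(model$pi[["A"]]))
  # two leaves joined at the root: direct summation over root states
  tr2 <- ape::read.tree(text = "(A:0.3,B:0.7);")
  P1 <- transition_matrix(model, 0.3)
  P2 <- transition_matrix(model, 0.7)
  want <- log(sum(model$pi * P1[, "A"] * P2[, "A"]))
  expect_equal(site_log_likelihood(tr2, c(A = "A", B = "A"), model), want)
  expect_error(site_log_likelihood(tr2, c(A = "A"), model), "lacks")
})

test_that("pruning equals brute-force enumeration on 4- and 5-leaf trees", {
  set.seed(6)
  pi <- stats::setNames(as.numeric(stats::runif(20, 0.5, 2)), AA20)
  model <- equal_input_model(pi)
  trees <- c("((A:0.2,B:0.4):0.1,(C:0.3,D:0.1):0.2);",
             "(((A:0.1,B:0.2):0.15,C:0.3):0.1,(D:0.2,E:0.25):0.3);")
  cols <- list(c(A = "A", B = "A", C = "C", D = "W", E = "K"),
               c(A = "K", B = "-", C = "K", D = "K", E = "X"),
               c(A = "F", B = "Y", C = "W", D = "F", E = "F"))
  for (nwk in trees) {
    tr <- ape::read.tree(text = nwk)
    for (col in cols) {
      col <- col[tr$tip.label]
      got <- site_log_likelihood(tr, col, model)
      want <- log(bf_site_likelihood(tr, col, model))
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("marginal posteriors equal brute-force conditioning at every node", {
  model <- equal_input_model()
  tr <- ape::read.tree(text = "(((A:0.1,B:0.2):0.15,C:0.3):0.1,(D:0.2,E:0.25):0.3);")
  col <- c(A = "K", B = "K", C = "R", D = "K", E = "H")
  aln <- alignment(vapply(col, function(x) x, character(1)))
  rec <- marginal_posteriors(tr, aln, model)
  ntip <- 5L
  for (v in (ntip + 1L):(ntip + tr$Nnode)) {
    want <- bf_node_posterior(tr, col, model, v)
    got <- rec$posterior[[v - ntip]][, 1]
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("likelihood is invariant to re-rooting (pulley principle)", {
  model <- equal_input_model()
  base <- ape::read.tree(text = "(((A:0.1,B:0.2):0.15,C:0.3):0.1,(D:0.2,E:0.25):0.3);")
  un <- ape::unroot(base)
  aln <- alignment(c(A = "KAF", B = "KCF", C = "RC-", D = "KAY", E = "HAY"))
  ref <- sum(tree_log_likelihood(base, aln, model))
  for (tip in un$tip.label) {
    rr <- root_tree(un, tip)
    expect_equal(sum(tree_log_likelihood(rr, aln, model)), ref,
                 tolerance = 1e-9)
  }
  # and on every internal edge via midpoint-style rooting of each split
  for (og in list(c("A", "B"), c("D", "E"), c("A", "B", "C"))) {
    rr <- root_tree(un, og)
    expect_equal(sum(tree_log_likelihood(rr, aln, model)), ref,
                 tolerance = 1e-9)
  }
})

test_that("posteriors approach the stationary distribution on long branches", {
  model <- equal_input_model()
  tr <- ape::read.tree(text = "((A:50,B:50):50,(C:50,D:50):50);")
  aln <- alignment(c(A = "K", B = "K", C = "K", D = "K"))
  rec <- marginal_posteriors(tr, aln, model)
  for (p in rec$posterior)
    expect_equal(unname(p[, 1]), rep(1 / 20, 20), tolerance = 1e-6)
  # and a conserved column on short branches pins the root
  tr2 <- ape::read.tree(text = "((A:0.01,B:0.01):0.01,(C:0.01,D:0.01):0.01);")
  rec2 <- marginal_posteriors(tr2, aln, model)
  expect_equal(substr(rec2$map[[1]], 1, 1), "K")
  expect_gt(rec2$posterior[[1]]["K", 1], 0.99)
})

test_that("ancestral outputs round-trip and carry Newick node labels", {
  model <- equal_input_model()
  tr <- ape::read.tree(text = "((A:0.1,B:0.1)AB:0.1,(C:0.1,D:0.1)CD:0.1)R;")
  aln <- alignment(c(A = "KAY", B = "KAY", C = "KCY", D = "KCY"))
  rec <- marginal_posteriors(tr, aln, model)
  expect_setequal(names(rec$map), c("R", "AB", "CD"))
  expect_equal(nchar(rec$map[["R"]]), 3L)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_ancestral_fasta(rec, fa, tsv)
  back <- read_fasta(fa)
  expect_setequal(back$id, names(rec$map))
  expect_equal(stats::setNames(back$residues, back$id)[names(rec$map)],
               rec$map)
  tab <- read_ancestral_tsv(tsv)
  expect_equal(nrow(tab), 9L)
  expect_true(all(tab$posterior_map > 0 & tab$posterior_map <= 1))
})

test_that("MAP reconstruction recovers simulated ancestors on shallow trees", {
  # clock-like tree of depth 0.25 substitutions/site, uniform site rates
  cfg <- sim_config(species_tree = default_species_tree(),
                    duplication_clade = NULL, site_classes = NULL,
                    motif_blocks = data.frame(start = integer(),
                                              end = integer()),
                    iso1_deletion = NULL, seq_length = 500L, seed = 1L)
  sim <- simulate_paralogs(cfg)
  model <- equal_input_model()
  rec <- marginal_posteriors(sim$truth$gene_tree, sim$aln, model)
  root_lab <- names(sim$truth$ancestors)[1]
  acc <- mean(strsplit(rec$map[[root_lab]], "")[[1]] ==
              strsplit(sim$truth$ancestors[[root_lab]], "")[[1]])
  expect_gte(acc, 0.9)
})
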