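noisy_dm <- function(n, seed, sd = 0.05) {
  x <- random_additive_dm(n, seed)
  set.seed(seed + 5000)
  e <- matrix(stats::rnorm(n * n, 0, sd), n, n)
  e <- (e + t(e)) / 2
  diag(e) <- 0
  d <- pmax(x$dm$d + e, 0.01)
  diag(d) <- 0
  as_dist_matrix((d + t(d)) / 2)
}

test_that("3-taxon NJ solves the closed-form star", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(as_dist_matrix(d))
  rt <- root_to_tip(root_tree(tr, "A"))
  # pendant lengths: (d12+d13-d23)/2 = 1, then 2, 3
  pend <- stats::setNames(tr$edge.length[tr$edge[, 2] <= 3],
                          tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(pend[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("NJ recovers the split of a 4-taxon additive matrix", {
  tr0 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  dm <- as_dist_matrix(ape::cophenetic.phylo(tr0))
  expect_equal(robinson_foulds(nj_tree(dm), tr0), 0)
})

test_that("Q-criterion ties resolve to the lowest index pair", {
  d <- matrix(1, 4, 4, dimnames = list(paste0("t", 1:4), paste0("t", 1:4)))
  diag(d) <- 0
  tr <- nj_tree(as_dist_matrix(d))
  # all Q equal: the (1,2) join must be chosen
  expect_equal(robinson_foulds(
    tr, ape::read.tree(text = "((t1,t2),(t3,t4));")), 0)
})

test_that("hand-written NJ agrees with ape::nj topologies", {
  skip_if_not_installed("phangorn")
  for (seed in 1:10) {
    dm <- noisy_dm(8, seed)
    expect_equal(robinson_foulds(nj_tree(dm), ape::nj(dm$d)), 0,
                 info = paste("seed", seed))
  }
})

test_that("Pauplin length matches hand evaluation and is linear in d", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  d <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(d) <- 0
  dm <- as_dist_matrix(d)
  expect_equal(bme_tree_length(star, dm), 0.75)   # 3 * 1 * 2^-2
  x <- random_additive_dm(6, seed = 9)
  L1 <- bme_tree_length(x$tree, x$dm)
  dm3 <- as_dist_matrix(3 * x$dm$d)
  expect_equal(bme_tree_length(x$tree, dm3), 3 * L1)
})

test_that("the generating topology minimises Pauplin length among 4-leaf trees", {
  tr0 <- ape::read.tree(text = "((A:1,B:2):1.5,(C:1,D:2.5):1);")
  dm <- as_dist_matrix(ape::cophenetic.phylo(tr0))
  lens <- vapply(all_topologies(c("A", "B", "C", "D")),
                 bme_tree_length, numeric(1), dm = dm)
  expect_equal(length(lens), 3L)
  best <- all_topologies(c("A", "B", "C", "D"))[[which.min(lens)]]
  expect_equal(robinson_foulds(best, tr0), 0)
})

test_that("NNI search finds the exhaustive balanced-ME optimum (small battery)", {
  for (seed in 1:6) {
    n <- if (seed %% 2) 5 else 6
    x <- random_additive_dm(n, seed)
    got <- me_tree(x$dm)
    ex <- exhaustive_me_tree(x$dm)
    expect_equal(robinson_foulds(got, ex$tree), 0, info = paste("seed", seed))
    expect_equal(bme_tree_length(got, x$dm), ex$length, tolerance = 1e-9)
  }
})

test_that("search result never exceeds the NJ start in balanced-ME length", {
  for (seed in 1:8) {
    dm <- noisy_dm(9, seed)
    expect_lte(bme_tree_length(me_tree(dm), dm),
               bme_tree_length(nj_tree(dm), dm) + 1e-12)
  }
})

test_that("me_tree is invariant to taxa input order", {
  dm <- noisy_dm(7, 31)
  t1 <- me_tree(dm)
  set.seed(1)
  perm <- sample(length(dm$taxa))
  dm2 <- as_dist_matrix(dm$d[perm, perm])
  expect_equal(robinson_foulds(t1, me_tree(dm2)), 0)
})

test_that("me_tree agrees with an independent balanced-ME implementation", {
  # ape::fastme.bal as cross-check only
  for (seed in 20:24) {
    x <- random_additive_dm(6, seed)
    expect_equal(robinson_foulds(me_tree(x$dm),
                                 ape::fastme.bal(x$dm$d)), 0,
                 info = paste("seed", seed))
  }
})

test_that("OLS branch lengths reproduce additive distances exactly", {
  x <- random_additive_dm(7, seed = 77)
  fit <- me_tree(x$dm)
  got <- ape::cophenetic.phylo(fit)[x$dm$taxa, x$dm$taxa]
  expect_equal(got, x$dm$d, tolerance = 1e-9)
})

test_that("outgroup rooting splits the stem edge and round-trips", {
  tr <- ape::read.tree(text = "((A:1,B:1):0.5,(C:1,D:1):0.7);")
  rt <- root_tree(tr, "A")
  expect_equal(length(rt$tip.label), 4L)
  # A is a child of the root
  root <- length(rt$tip.label) + 1L
  rootkids <- rt$edge[rt$edge[, 1] == root, 2]
  expect_true(which(rt$tip.label == "A") %in% rootkids)
  # the pendant edge of A (length 1) is split into two halves
  rootlens <- rt$edge.length[rt$edge[, 1] == root]
  expect_equal(sort(rootlens)[1], 0.5)
  expect_equal(robinson_foulds(rt, tr), 0)    # unrooted topology unchanged

  rt2 <- root_tree(tr, c("C", "D"))
  cd_edge <- rt2$edge.length[rt2$edge[, 1] == length(rt2$tip.label) + 1L]
  expect_equal(sort(cd_edge), c(0.6, 0.6))    # 0.5 + 0.7 split equally
  expect_error(root_tree(tr, c("A", "C")), "not monophyletic")
})

test_that("on ultrametric noise-free data root-to-tip depths are equal", {
  # symmetric root stems, so equal-split rooting restores the clock root
  sp <- default_species_tree()
  dm <- as_dist_matrix(ape::cophenetic.phylo(sp))
  fit <- me_tree(dm)
  depths <- root_to_tip(root_tree(fit, paste0("sp0", 1:6)))
  expect_lt(max(depths) - min(depths), 1e-9)
  expect_equal(unname(depths[1]), 0.25, tolerance = 1e-9)
})

test_that("Robinson-Foulds matches forced values and phangorn", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  expect_equal(robinson_foulds(t1, t1), 0)
  # one NNI on a 4-leaf tree exchanges its single non-trivial split
  q1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  q2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(robinson_foulds(q1, q2), 2)
  expect_error(robinson_foulds(t1, ape::read.tree(text = "((A,B),(C,F),E);")),
               "leaf sets")
  skip_if_not_installed("phangorn")
  for (seed in 1:10) {
    ta <- ape::rtree(8, tip.label = paste0("t", 1:8))
    tb <- ape::rtree(8, tip.label = paste0("t", 1:8))
    expect_equal(robinson_foulds(ta, tb),
                 as.integer(phangorn::RF.dist(ape::unroot(ta),
                                              ape::unroot(tb))),
                 info = paste("seed", seed))
  }
})

test_that("rate ratio on the true gene tree recovers the multiplier exactly", {
  sim <- simulate_paralogs(rate_recovery_config(seed = 2, r = 2))
  r <- paralog_rate_ratio(sim$truth$gene_tree,
                          paste0("sp0", 1:6, "_ISO1"),
                          paste0("sp0", 1:6, "_ISO2"))
  expect_equal(r, 2, tolerance = 1e-9)
})
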