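# Hand-built profile: `spec` is a character vector over
# {"m" (match, conserved), "d" (divergent, conserved both), "x" (divergent
# but under-conserved), "g" (reference gap)}.
profile_from_pattern <- function(spec) {
  n <- length(spec)
  data.frame(
    col = seq_len(n),
    pos1 = cumsum(spec != "g"),
    pos2 = seq_len(n),
    res1 = ifelse(spec == "g", "-", ifelse(spec == "m", "A", "K")),
    res2 = "A",
    match = ifelse(spec == "g", NA, spec == "m"),
    cons1 = ifelse(spec == "g", NA, ifelse(spec == "x", 0.3, 1)),
    cons2 = ifelse(spec == "g", NA, 1),
    stringsAsFactors = FALSE)
}

test_that("profiles without divergent columns yield no motif calls", {
  p <- profile_from_pattern(rep("m", 30))
  calls <- call_motifs(p)
  expect_s3_class(calls, "motif_calls")
  expect_equal(nrow(calls), 0L)
  expect_error(call_motifs(p, min_cons = 0), "min_cons")
})

test_that("a planted 17-column divergent block is called exactly once per isoform", {
  p <- profile_from_pattern(c(rep("m", 20), rep("d", 17), rep("m", 20)))
  calls <- call_motifs(p, min_cons = 0.5, min_len = 10, max_violations = 2)
  expect_equal(nrow(calls), 2L)
  expect_equal(unique(calls$col_start), 21L)
  expect_equal(unique(calls$col_end), 37L)
  expect_equal(calls$ref_start[calls$isoform == "ISO2"], 21L)
  expect_equal(calls$n_cols, c(17L, 17L))
  expect_equal(calls$n_mismatch_cols, c(0L, 0L))
})

test_that("interior violations merge or split runs according to the budget", {
  spec <- c(rep("m", 15), rep("d", 7), "m", "m", rep("d", 8), rep("m", 15))
  p <- profile_from_pattern(spec)
  merged <- call_motifs(p, max_violations = 2)
  expect_equal(nrow(merged), 2L)
  expect_equal(unique(merged$col_start), 16L)
  expect_equal(unique(merged$col_end), 32L)
  expect_equal(unique(merged$n_mismatch_cols), 2L)
  strict <- call_motifs(p, max_violations = 0)
  expect_equal(nrow(strict), 0L)   # 7- and 8-column sub-runs < min_len
  relaxed <- call_motifs(p, max_violations = 0, min_len = 8)
  expect_equal(nrow(relaxed), 2L)  # only the 8-column sub-run survives
  expect_equal(unique(relaxed$col_start), 25L)
})

test_that("under-conserved or reference-gap columns cannot join a motif", {
  spec <- c(rep("m", 12), rep("d", 6), "x", rep("d", 6), rep("g", 3),
            rep("d", 12), rep("m", 12))
  p <- profile_from_pattern(spec)
  calls <- call_motifs(p, max_violations = 1)
  # x bridged (1 violation) but the 3-gap block cannot be bridged
  expect_equal(nrow(calls), 4L)
  expect_equal(sort(unique(calls$col_start)), c(13L, 29L))
  spans <- unique(calls[, c("col_start", "col_end")])
  expect_true(all(spans$col_end[1] < spans$col_start[2]))  # disjoint, sorted
})

test_that("motif calls appear in order and are invariant to duplicated members", {
  sim <- simulate_paralogs(sim_config(seed = 3))
  map <- stats::setNames(sim$records$isoform, sim$records$id)
  p <- conservation_profile(sim$aln, map, "sp01_ISO1", "sp01_ISO2")
  calls <- call_motifs(p)
  expect_true(all(diff(unique(calls$col_start)) > 0))
  dup <- alignment(rbind(sim$aln$mat, dup1 = sim$aln$mat["sp02_ISO1", ]))
  map2 <- c(map, dup1 = "ISO1")
  p2 <- conservation_profile(dup, map2, "sp01_ISO1", "sp01_ISO2")
  calls2 <- call_motifs(p2)
  expect_equal(calls2[, c("isoform", "ref_start", "ref_end")],
               calls[, c("isoform", "ref_start", "ref_end")])
})

test_that("Henikoff weights match hand-evaluated values", {
  w1 <- henikoff_weights(alignment(c(a = "ACDE")))
  expect_equal(unname(w1), 1)
  wn <- henikoff_weights(alignment(c(a = "ACDE", b = "ACDE", c = "ACDE")))
  expect_equal(unname(wn), rep(1 / 3, 3))
  w <- henikoff_weights(alignment(c(s1 = "AA", s2 = "AA", s3 = "AC")))
  expect_equal(unname(w), c(7, 7, 10) / 24, tolerance = 1e-6)
  expect_equal(unname(round(w, 6)), c(0.291667, 0.291667, 0.416667))
})

test_that("logo heights obey the closed forms and the sign rule", {
  a <- alignment(c(s1 = "KA", s2 = "KC", s3 = "KD", s4 = "KE"))
  lg <- logo_matrix(a, columns = 1:2,
                    weights = stats::setNames(rep(0.25, 4), a$ids))
  # fully conserved column, uniform background: single letter log2(20)
  expect_equal(lg$heights[1, "K"], log2(20))
  expect_equal(sum(lg$heights[1, ] != 0), 1L)
  expect_equal(unname(rowSums(lg$p)), c(1, 1))
  # column where p == q exactly gives all-zero heights
  aa20 <- alignment(stats::setNames(AA20, paste0("s", 1:20)))
  lg20 <- logo_matrix(aa20, columns = 1,
                      weights = stats::setNames(rep(1 / 20, 20), aa20$ids))
  expect_true(all(abs(lg20$heights) < 1e-12))
  # sign rule: sign(height) == sign(p - q) wherever p > 0
  q <- lg$q
  nz <- lg$p[2, ] > 0
  expect_equal(sign(lg$heights[2, nz]), sign(lg$p[2, nz] - q[nz]))
  # absent letters contribute 0, not -Inf
  expect_true(all(lg$heights[2, !nz] == 0))
})

test_that("equal weights reproduce the unweighted logo; gap-heavy columns flag", {
  set.seed(4)
  seqs <- stats::setNames(replicate(6, random_protein(10)), paste0("s", 1:6))
  a <- alignment(seqs)
  lg_w <- logo_matrix(a, 1:10,
                      weights = stats::setNames(rep(1 / 6, 6), a$ids))
  # unweighted counts computed directly
  for (cc in 1:10) {
    counts <- table(factor(a$mat[, cc], levels = AA20)) / 6
    expect_equal(unname(lg_w$p[cc, ]), as.numeric(counts))
  }
  gappy <- alignment(c(s1 = "A-", s2 = "A-", s3 = "A-", s4 = "AC"))
  lg <- logo_matrix(gappy, 1:2,
                    weights = stats::setNames(rep(0.25, 4), gappy$ids))
  expect_false(lg$flagged[1])
  expect_true(lg$flagged[2])
  expect_true(all(is.na(lg$heights[2, ])))
})

test_that("motif reports round-trip through their readers", {
  sim <- simulate_paralogs(sim_config(seed = 5))
  map <- stats::setNames(sim$records$isoform, sim$records$id)
  p <- conservation_profile(sim$aln, map, "sp01_ISO1", "sp01_ISO2")
  calls <- call_motifs(p)
  expect_gt(nrow(calls), 0L)
  iso2 <- aln_subset(sim$aln, sim$records$id[sim$records$isoform == "ISO2"],
                     drop_allgap = FALSE)
  lg <- logo_matrix(iso2, calls$col_start[1]:calls$col_end[1])
  dir <- withr::local_tempdir()
  motif_report(calls, list(ISO2_1 = lg), dir, profile = p)
  back <- read_motif_tsv(file.path(dir, "motifs.tsv"))
  expect_equal(back$ref_start, calls$ref_start)
  expect_equal(back$mean_cons1, calls$mean_cons1, tolerance = 1e-9)
  m <- read_logo_tsv(file.path(dir, "logo_ISO2_1.tsv"))
  expect_equal(dim(m), dim(lg$heights))
  expect_equal(unname(m), unname(lg$heights), tolerance = 1e-9)
  # empty calls still produce a header-only table
  dir2 <- withr::local_tempdir()
  motif_report(call_motifs(profile_from_pattern(rep("m", 12))), list(), dir2)
  expect_equal(nrow(read_motif_tsv(file.path(dir2, "motifs.tsv"))), 0L)
})
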