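#' Call isoform-specific motifs from a conservation profile
#'
#' An isoform-specific motif is a run of alignment columns that are
#' divergent between the two isoform references (`match == FALSE`) while
#' being conserved within each isoform (`cons1 >= min_cons` and
#' `cons2 >= min_cons`).  Maximal runs are reported, allowing up to
#' `max_violations` interior columns that fail any single test; runs
#' shorter than `min_len` columns are discarded.  Each surviving run is
#' emitted once per isoform, with start/end mapped to ungapped reference
#' coordinates.
#'
#' @param profile a `cons_profile` (see [conservation_profile()]).
#' @param min_cons minimum within-isoform conservation, in `(0, 1]`.
#' @param min_len minimum motif length in columns.
#' @param max_violations maximum number of interior failing columns
#'   tolerated inside a run.
#' @return a `motif_calls` data frame: `motif`, `isoform`, `ref_start`,
#'   `ref_end`, `col_start`, `col_end`, `n_cols`, `mean_cons1`,
#'   `mean_cons2`, `n_mismatch_cols`; zero rows when nothing is called.
#' @export
call_motifs <- function(profile, min_cons = 0.5, min_len = 10L,
                        max_violations = 2L) {
  if (!(min_cons > 0 && min_cons <= 1))
    stop("min_cons must lie in (0, 1]")
  pass <- !is.na(profile$match) & !profile$match &
    !is.na(profile$cons1) & profile$cons1 >= min_cons &
    !is.na(profile$cons2) & profile$cons2 >= min_cons
  spans <- merge_runs(pass, max_violations)
  calls <- list()
  m <- 0L
  for (sp in spans) {
    if (sp[2] - sp[1] + 1L < min_len) next
    m <- m + 1L
    idx <- sp[1]:sp[2]
    viol <- sum(!pass[idx])
    for (iso in c("ISO1", "ISO2")) {
      pos <- if (iso == "ISO1") profile$pos1[idx] else profile$pos2[idx]
      pos <- pos[!is.na(pos)]
      calls[[length(calls) + 1L]] <- data.frame(
        motif = m, isoform = iso,
        ref_start = if (length(pos)) min(pos) else NA_integer_,
        ref_end = if (length(pos)) max(pos) else NA_integer_,
        col_start = sp[1], col_end = sp[2],
        n_cols = length(idx),
        mean_cons1 = mean(profile$cons1[idx], na.rm = TRUE),
        mean_cons2 = mean(profile$cons2[idx], na.rm = TRUE),
        n_mismatch_cols = viol,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(motif = integer(), isoform = character(),
               ref_start = integer(), ref_end = integer(),
               col_start = integer(), col_end = integer(),
               n_cols = integer(), mean_cons1 = numeric(),
               mean_cons2 = numeric(), n_mismatch_cols = integer(),
               stringsAsFactors = FALSE)
  attr(out, "params") <- list(min_cons = min_cons, min_len = min_len,
                              max_violations = max_violations)
  class(out) <- c("motif_calls", "data.frame")
  out
}

# Maximal disjoint windows that start and end on passing columns and
# contain at most max_violations failing columns, scanning left to right.
merge_runs <- function(pass, max_violations) {
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pruns <- which(r$values)
  if (!length(pruns)) return(list())
  out <- list()
  i <- 1L
  while (i <= length(pruns)) {
    j <- i
    viol <- 0L
    while (j < length(pruns)) {
      gap <- sum(r$lengths[(pruns[j] + 1L):(pruns[j + 1L] - 1L)])
      if (viol + gap > max_violations) break
      viol <- viol + gap
      j <- j + 1L
    }
    out[[length(out) + 1L]] <- c(starts[pruns[i]], ends[pruns[j]])
    i <- j + 1L
  }
  out
}

#' Position-based sequence weights (Henikoff & Henikoff)
#'
#' At each column with `r` distinct residues, a sequence carrying a residue
#' observed `s` times contributes `1/(r*s)`; gaps and `X` contribute
#' nothing.  Raw weights are summed over columns and normalised to sum
#' to 1.
#'
#' @param aln an `aln` object.
#' @return named numeric weights, one per sequence, summing to 1.
#' @export
henikoff_weights <- function(aln) {
  mat <- aln$mat
  n <- nrow(mat)
  w <- numeric(n)
  for (c in seq_len(ncol(mat))) {
    colv <- mat[, c]
    use <- colv != GAP_CHAR & colv != UNKNOWN_CHAR
    if (!any(use)) next
    tab <- table(colv[use])
    r <- length(tab)
    w[use] <- w[use] + 1 / (r * as.numeric(tab[colv[use]]))
  }
  if (sum(w) == 0) w <- rep(1, n)
  stats::setNames(w / sum(w), aln$ids)
}

#' Two-sided Kullback-Leibler logo matrix
#'
#' For each requested column, computes sequence-weighted residue
#' frequencies `p_a` (gap mass excluded from the normalisation; optional
#' pseudocount toward the background) and signed letter heights
#' `h_a = p_a * log2(p_a / q_a)` in bits: positive for enriched residues
#' (`p_a > q_a`), negative for depleted ones.  Residues absent at a
#' position (`p_a = 0`) get height 0.  Columns with more than half of the
#' total weight on gaps are flagged and their heights set to `NA`.
#'
#' @param aln an `aln` object.
#' @param columns alignment column indices (the motif span).
#' @param weights per-sequence weights (default [henikoff_weights()]).
#' @param background named vector of background frequencies over the 20
#'   amino acids (default uniform 1/20), or `"empirical"` for frequencies
#'   of the whole alignment.
#' @param pseudocount pseudocount `alpha` toward the background.
#' @return a `logo_matrix` list: `heights` and `p` (positions x 20
#'   matrices), `q`, `weights`, `columns`, `flagged`.
#' @export
logo_matrix <- function(aln, columns, weights = NULL, background = NULL,
                        pseudocount = 0) {
  mat <- aln$mat
  if (any(columns < 1L | columns > ncol(mat)))
    stop("columns out of alignment range")
  if (is.null(weights)) weights <- henikoff_weights(aln)
  weights <- weights[aln$ids]
  if (any(is.na(weights))) stop("weights must cover every sequence")
  q <- logo_background(background, aln)
  np <- length(columns)
  p <- matrix(0, np, 20, dimnames = list(columns, AA20))
  flagged <- logical(np)
  for (k in seq_len(np)) {
    colv <- mat[, columns[k]]
    gapw <- sum(weights[colv == GAP_CHAR])
    use <- colv != GAP_CHAR & colv != UNKNOWN_CHAR
    tot <- sum(weights[use])
    if (gapw > 0.5 * sum(weights) || tot == 0) {
      flagged[k] <- TRUE
      p[k, ] <- NA_real_
      next
    }
    wc <- vapply(AA20, function(a) sum(weights[use & colv == a]), numeric(1))
    p[k, ] <- (wc + pseudocount * q) / (tot + pseudocount)
  }
  heights <- p * log2(sweep(p, 2, q, "/"))
  heights[p == 0] <- 0
  heights[is.na(p)] <- NA_real_
  structure(list(heights = heights, p = p, q = q, weights = weights,
                 columns = columns, flagged = flagged),
            class = "logo_matrix")
}

logo_background <- function(background, aln) {
  if (is.null(background)) {
    q <- stats::setNames(rep(1 / 20, 20), AA20)
  } else if (identical(background, "empirical")) {
    cnt <- table(factor(aln$mat[aln$mat %in% AA20], levels = AA20))
    q <- as.numeric(cnt) / sum(cnt)
    names(q) <- AA20
    if (any(q == 0)) {      # keep log2 well-defined
      q <- (q + 1e-4) / sum(q + 1e-4)
    }
  } else {
    q <- background[AA20]
    if (any(is.na(q))) stop("background must name all 20 amino acids")
  }
  if (abs(sum(q) - 1) > 1e-8) stop("background frequencies must sum to 1")
  q
}

#' Write motif calls and logo matrices to a report directory
#'
#' Writes `motifs.tsv` (one row per call and isoform, `#` header echoing
#' the calling parameters and, when a profile is given, the reference
#' subsequence over each span) plus one `logo_<isoform>_<motif>.tsv`
#' per logo (position x 20 signed heights).
#'
#' @param calls a `motif_calls` data frame.
#' @param logos named list of `logo_matrix` objects, names like
#'   `"ISO1_1"` (`<isoform>_<motif>`); may be empty.
#' @param dir output directory (created if needed).
#' @param profile optional `cons_profile` used to embed reference
#'   subsequences in the header.
#' @return the directory, invisibly.
#' @export
motif_report <- function(calls, logos = list(), dir, profile = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  par <- attr(calls, "params") %||%
    list(min_cons = NA, min_len = NA, max_violations = NA)
  path <- file.path(dir, "motifs.tsv")
  con <- file(path, "w")
  writeLines(sprintf(
    "# paraloglens motif calls; min_cons=%s min_len=%s max_violations=%s",
    par$min_cons, par$min_len, par$max_violations), con)
  if (!is.null(profile) && nrow(calls)) {
    for (k in seq_len(nrow(calls))) {
      idx <- calls$col_start[k]:calls$col_end[k]
      res <- if (calls$isoform[k] == "ISO1") profile$res1[idx] else
        profile$res2[idx]
      writeLines(sprintf("# motif %d %s sequence: %s", calls$motif[k],
                         calls$isoform[k],
                         paste(res[res != GAP_CHAR], collapse = "")), con)
    }
  }
  utils::write.table(as.data.frame(calls), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  for (nm in names(logos)) {
    lg <- logos[[nm]]
    lp <- file.path(dir, paste0("logo_", nm, ".tsv"))
    lcon <- file(lp, "w")
    writeLines(paste0("# paraloglens logo matrix (bits); columns: ",
                      paste(lg$columns, collapse = ",")), lcon)
    df <- data.frame(column = lg$columns, lg$heights, check.names = FALSE)
    utils::write.table(df, lcon, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(lcon)
  }
  invisible(dir)
}

#' Read back a motif report table
#'
#' @param path `motifs.tsv` written by [motif_report()].
#' @return data frame of motif calls.
#' @export
read_motif_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read back a logo matrix table
#'
#' @param path `logo_*.tsv` written by [motif_report()].
#' @return matrix of signed heights (positions x 20).
#' @export
read_logo_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$column
  m
}
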