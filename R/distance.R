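#' Pairwise distance matrix from a protein alignment
#'
#' Computes p-distances (fraction of differing residues) under pairwise
#' deletion: for each sequence pair only columns where both sequences carry
#' a non-gap, non-`X` residue are compared.  The Poisson correction
#' `d = -ln(1 - p)` converts a p-distance into an estimate of amino-acid
#' substitutions per site.
#'
#' @param aln an `aln` object with at least 3 sequences.
#' @param correction `"p"` (raw p-distance) or `"poisson"`.
#' @return object of class `dist_matrix`: list with `taxa`, `d` (symmetric
#'   numeric matrix), `units` (`"P_DISTANCE"` or `"SUBST_PER_SITE"`).
#' @export
distance_matrix <- function(aln, correction = c("p", "poisson")) {
  correction <- match.arg(correction)
  mat <- aln$mat
  n <- nrow(mat)
  if (n < 3L) stop("need at least 3 sequences for a distance matrix")
  ok <- mat != GAP_CHAR & mat != UNKNOWN_CHAR
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L)
        stop("no comparable columns between ", aln$ids[i], " and ",
             aln$ids[j])
      p <- sum(mat[i, comp] != mat[j, comp]) / nc
      if (correction == "poisson") {
        if (p >= 1)
          stop("saturated pair under Poisson correction (p >= 1): ",
               aln$ids[i], " vs ", aln$ids[j])
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  dist_matrix_obj(aln$ids, d,
                  if (correction == "p") "P_DISTANCE" else "SUBST_PER_SITE")
}

#' Wrap a symmetric matrix as a `dist_matrix`
#'
#' @param d symmetric non-negative matrix with identical row/column names
#'   (the taxa).
#' @param units `"P_DISTANCE"` or `"SUBST_PER_SITE"`.
#' @return a `dist_matrix` object.
#' @export
as_dist_matrix <- function(d, units = "SUBST_PER_SITE") {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("matrix must have taxa names")
  dist_matrix_obj(rownames(d), d, units)
}

dist_matrix_obj <- function(taxa, d, units = "SUBST_PER_SITE") {
  d <- as.matrix(d)
  dimnames(d) <- list(taxa, taxa)
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and >= 0")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  structure(list(taxa = taxa, d = d, units = units), class = "dist_matrix")
}

#' Poisson distance correction
#'
#' @param p p-distance(s) in `[0, 1)`.
#' @return `-log(1 - p)`, substitutions per site.
#' @export
poisson_correct <- function(p) {
  if (any(p < 0 | p >= 1)) stop("p must lie in [0, 1) for Poisson correction")
  -log(1 - p)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dm a `dist_matrix`.
#' @param path output file.
#' @export
write_phylip <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(dm$taxa)), con)
  for (i in seq_along(dm$taxa)) {
    writeLines(paste0(sprintf("%-10s", dm$taxa[i]),
                      paste(sprintf("%.6f", dm$d[i, ]), collapse = "  ")),
               con)
  }
  invisible(path)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("Distance matrix:", length(x$taxa), "taxa, units", x$units, "\n")
  print(round(x$d, 4))
  invisible(x)
}
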