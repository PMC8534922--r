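#' Per-column conservation/divergence profile of a joint paralog alignment
#'
#' For every column of a joint alignment of both isoform families, records
#' the residues of the designated reference sequence of each isoform, a
#' cross-isoform match flag (are the two reference residues identical, both
#' non-gap?), and the within-isoform conservation `cons1`/`cons2`: the
#' fraction of isoform-k sequences (excluding the reference itself, and
#' excluding sequences with a gap or `X` at that column) whose residue
#' equals the reference residue.
#'
#' @param aln an `aln` object holding both families.
#' @param isoform_map named character vector or data frame
#'   (`seq_id`, `isoform`) assigning `ISO1`/`ISO2` to sequence ids;
#'   sequences labelled `OTHER` or absent are ignored.
#' @param ref1,ref2 sequence ids of the isoform-1 and isoform-2 reference
#'   (e.g. the human sequences).
#' @param exclude_ref exclude the reference from the conservation
#'   denominator (default TRUE).
#' @return a `cons_profile` data frame with columns `col`, `pos1`, `pos2`,
#'   `res1`, `res2`, `match`, `cons1`, `cons2` (fractions in `[0,1]`,
#'   `NA` where the reference is gapped) and attributes `ref1`, `ref2`.
#' @export
conservation_profile <- function(aln, isoform_map, ref1, ref2,
                                 exclude_ref = TRUE) {
  map <- normalize_isoform_map(isoform_map)
  iso_of <- function(id) unname(map[id])
  if (is.na(iso_of(ref1)) || iso_of(ref1) != "ISO1")
    stop("ref1 (", ref1, ") must be labelled ISO1 in the isoform map")
  if (is.na(iso_of(ref2)) || iso_of(ref2) != "ISO2")
    stop("ref2 (", ref2, ") must be labelled ISO2 in the isoform map")
  if (!ref1 %in% aln$ids || !ref2 %in% aln$ids)
    stop("reference sequence(s) missing from the alignment")
  ids1 <- intersect(aln$ids, names(map)[map == "ISO1"])
  ids2 <- intersect(aln$ids, names(map)[map == "ISO2"])
  if (length(ids1) < 2L || length(ids2) < 2L)
    stop("each isoform needs at least 2 sequences in the alignment")
  mat <- aln$mat
  r1 <- mat[ref1, ]; r2 <- mat[ref2, ]
  cons_for <- function(ids, ref_id, refrow) {
    sub <- mat[setdiff(ids, if (exclude_ref) ref_id else character(0)), ,
               drop = FALSE]
    usable <- sub != GAP_CHAR & sub != UNKNOWN_CHAR
    agree <- sweep(sub, 2, refrow, "==") & usable
    denom <- colSums(usable)
    out <- ifelse(denom > 0, colSums(agree) / denom, NA_real_)
    out[refrow == GAP_CHAR] <- NA_real_
    out
  }
  nc <- ncol(mat)
  match_flag <- ifelse(r1 == GAP_CHAR | r2 == GAP_CHAR, NA, r1 == r2)
  prof <- data.frame(
    col = seq_len(nc),
    pos1 = col_to_residue(aln, ref1, seq_len(nc)),
    pos2 = col_to_residue(aln, ref2, seq_len(nc)),
    res1 = unname(r1), res2 = unname(r2),
    match = as.logical(match_flag),
    cons1 = unname(cons_for(ids1, ref1, r1)),
    cons2 = unname(cons_for(ids2, ref2, r2)),
    stringsAsFactors = FALSE)
  attr(prof, "ref1") <- ref1
  attr(prof, "ref2") <- ref2
  class(prof) <- c("cons_profile", "data.frame")
  prof
}

normalize_isoform_map <- function(isoform_map) {
  if (is.data.frame(isoform_map)) {
    map <- stats::setNames(isoform_map$isoform, isoform_map$seq_id)
  } else map <- isoform_map
  bad <- !map %in% ISOFORM_LEVELS
  if (any(bad)) stop("invalid isoform labels: ",
                     paste(unique(map[bad]), collapse = ", "))
  map
}

#' Per-domain summary of within-isoform conservation
#'
#' Summarises `cons1` and `cons2` (min, max, mean) over the profile columns
#' whose reference residue falls inside each annotated domain.  Annotations
#' must refer to the profile's reference sequences (coordinates on the
#' ungapped references).
#'
#' @param profile a `cons_profile`.
#' @param annotations data frame with columns `seq_id`, `domain`, `start`,
#'   `end`.
#' @return data frame with one row per annotation: `seq_id`, `domain`,
#'   `n_cols`, `min1`, `max1`, `mean1`, `min2`, `max2`, `mean2`.
#' @export
domain_identity_summary <- function(profile, annotations) {
  ref1 <- attr(profile, "ref1"); ref2 <- attr(profile, "ref2")
  rows <- list()
  for (k in seq_len(nrow(annotations))) {
    a <- annotations[k, ]
    pos <- if (a$seq_id == ref1) profile$pos1 else
           if (a$seq_id == ref2) profile$pos2 else
           stop("annotation on ", a$seq_id,
                " does not refer to a profile reference")
    reflen <- max(pos, na.rm = TRUE)
    if (a$start < 1 || a$end > reflen)
      stop("domain [", a$start, ",", a$end, "] outside reference ",
           a$seq_id, " (length ", reflen, ")")
    sel <- !is.na(pos) & pos >= a$start & pos <= a$end
    s1 <- profile$cons1[sel]; s2 <- profile$cons2[sel]
    rows[[k]] <- data.frame(
      seq_id = a$seq_id, domain = a$domain, n_cols = sum(sel),
      min1 = suppressWarnings(min(s1, na.rm = TRUE)),
      max1 = suppressWarnings(max(s1, na.rm = TRUE)),
      mean1 = mean(s1, na.rm = TRUE),
      min2 = suppressWarnings(min(s2, na.rm = TRUE)),
      max2 = suppressWarnings(max(s2, na.rm = TRUE)),
      mean2 = mean(s2, na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write a conservation profile as TSV
#'
#' Conservation values are written as percentages in `[0, 100]`; internal
#' storage is fractional.  `#`-prefixed header comments echo the reference
#' ids.
#'
#' @param profile a `cons_profile`.
#' @param path output file.
#' @export
profile_to_tsv <- function(profile, path) {
  if (!nrow(profile)) stop("empty profile")
  out <- profile
  out$cons1 <- round(100 * out$cons1, 4)
  out$cons2 <- round(100 * out$cons2, 4)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# paraloglens conservation profile; ref1=",
                    attr(profile, "ref1"), " ref2=", attr(profile, "ref2"),
                    "; cons columns in percent"), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a conservation profile written by [profile_to_tsv()]
#'
#' @param path TSV file.
#' @return a `cons_profile` data frame.
#' @export
read_profile_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  refs <- regmatches(header,
                     regexec("ref1=(\\S+) ref2=(\\S+);", header))[[1]]
  prof <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
  prof$cons1 <- prof$cons1 / 100
  prof$cons2 <- prof$cons2 / 100
  prof$match <- as.logical(prof$match)
  if (length(refs) == 3L) {
    attr(prof, "ref1") <- refs[2]
    attr(prof, "ref2") <- refs[3]
  }
  class(prof) <- c("cons_profile", "data.frame")
  prof
}
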