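#' Construct a set of sequence records
#'
#' A `seq_records` object is a data frame with one row per protein sequence
#' and columns `id`, `species`, `isoform`, `residues`, `description`.
#' Residues are ungapped strings over the 20 amino-acid letters plus `X`
#' (unknown).
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param residues character vector of ungapped residue strings.
#' @param species,isoform,description optional per-sequence metadata;
#'   `isoform` must be one of `"ISO1"`, `"ISO2"`, `"OTHER"`.
#' @return a `seq_records` data frame.
#' @export
seq_records <- function(id, residues, species = "", isoform = "OTHER",
                        description = "") {
  stopifnot(length(id) == length(residues))
  x <- data.frame(id = as.character(id),
                  species = rep_len(as.character(species), length(id)),
                  isoform = rep_len(as.character(isoform), length(id)),
                  residues = toupper(as.character(residues)),
                  description = rep_len(as.character(description), length(id)),
                  stringsAsFactors = FALSE)
  validate_seq_records(x)
  class(x) <- c("seq_records", "data.frame")
  x
}

validate_seq_records <- function(x) {
  if (any(!nzchar(x$id))) stop("sequence ids must be non-empty")
  if (anyDuplicated(x$id))
    stop("duplicate sequence ids: ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  if (any(!nzchar(x$residues))) stop("residues must be non-empty")
  if (any(grepl("-", x$residues, fixed = TRUE)))
    stop("residues must not contain gap characters")
  bad <- grepl(paste0("[^", paste(c(AA20, "X"), collapse = ""), "]"),
               x$residues)
  if (any(bad))
    stop("non amino-acid letters in sequences: ",
         paste(x$id[bad], collapse = ", "))
  if (any(!x$isoform %in% ISOFORM_LEVELS))
    stop("isoform must be one of ", paste(ISOFORM_LEVELS, collapse = ", "))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Headers are split at the first whitespace into `id` and `description`.
#' When a side-car isoform/species map is supplied (see
#' [read_isoform_map()]), the `species` and `isoform` columns are filled
#' from it; unmapped sequences get `OTHER` / `""`.
#'
#' @param path FASTA file.
#' @param map optional data frame with columns `seq_id`, `species`,
#'   `isoform`, or a path to such a tab-separated file.
#' @return a `seq_records` data frame.
#' @export
read_fasta <- function(path, map = NULL) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    x <- data.frame(id = character(), species = character(),
                    isoform = character(), residues = character(),
                    description = character(), stringsAsFactors = FALSE)
    class(x) <- c("seq_records", "data.frame")
    return(x)
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA in ", path, ": line ", nonblank[1],
         " is not a header line")
  ss <- Biostrings::readAAStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  recs <- seq_records(id = ids, residues = as.character(ss),
                      description = desc)
  if (!is.null(map)) recs <- apply_isoform_map(recs, map)
  recs
}

#' Read a side-car isoform/species map
#'
#' Tab-separated file with columns `seq_id`, `species`, `isoform`.
#'
#' @param path TSV file.
#' @return data frame with those three columns.
#' @export
read_isoform_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("seq_id", "species", "isoform")
  if (!all(need %in% names(m)))
    stop("isoform map must have columns ", paste(need, collapse = ", "))
  if (any(!m$isoform %in% ISOFORM_LEVELS))
    stop("isoform map values must be in ",
         paste(ISOFORM_LEVELS, collapse = ", "))
  m[need]
}

apply_isoform_map <- function(recs, map) {
  if (is.character(map) && length(map) == 1L) map <- read_isoform_map(map)
  i <- match(recs$id, map$seq_id)
  hit <- !is.na(i)
  recs$species[hit] <- map$species[i[hit]]
  recs$isoform[hit] <- map$isoform[i[hit]]
  recs
}

#' Write sequences to FASTA
#'
#' @param x a `seq_records` data frame or a named character vector of
#'   (possibly gapped) sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.data.frame(x)) {
    seqs <- x$residues
    hdr <- ifelse(nzchar(x$description), paste(x$id, x$description), x$id)
  } else {
    seqs <- as.character(x)
    hdr <- names(x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(seqs)) {
    writeLines(paste0(">", hdr[k]), con)
    s <- seqs[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct an alignment object
#'
#' An `aln` object stores a multiple sequence alignment as a character
#' matrix (rows = sequences, columns = alignment columns; gap = `-`).
#'
#' @param seqs named character vector of equal-length gapped sequences, or
#'   a character matrix with row names.
#' @return an object of class `aln` with elements `mat` (character matrix)
#'   and `ids`.
#' @export
alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    ids <- names(seqs)
    if (is.null(ids)) stop("sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequences of differing length: ",
           paste(ids[lens != stats::median(lens)], collapse = ", "))
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- ids
  }
  if (is.null(rownames(mat))) stop("alignment matrix must have row names")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate sequence ids in alignment")
  if (ncol(mat) == 0L) stop("alignment has zero columns")
  allgap <- colSums(mat != GAP_CHAR) == 0L
  if (any(allgap))
    stop("all-gap alignment columns: ",
         paste(which(allgap), collapse = ", "))
  structure(list(mat = mat, ids = rownames(mat)), class = "aln")
}

#' @export
print.aln <- function(x, ...) {
  cat("Alignment:", nrow(x$mat), "sequences x", ncol(x$mat), "columns\n")
  invisible(x)
}

#' Number of columns of an alignment
#' @param aln an `aln` object.
#' @export
n_cols <- function(aln) ncol(aln$mat)

#' Gapped sequences of an alignment as a named character vector
#' @param aln an `aln` object.
#' @export
aln_strings <- function(aln) {
  stats::setNames(apply(aln$mat, 1L, paste, collapse = ""), aln$ids)
}

#' Degap one aligned sequence
#' @param aln an `aln` object.
#' @param seq_id sequence identifier.
#' @export
degap <- function(aln, seq_id) {
  row <- aln_row(aln, seq_id)
  paste(row[row != GAP_CHAR], collapse = "")
}

aln_row <- function(aln, seq_id) {
  if (!seq_id %in% aln$ids) stop("sequence not in alignment: ", seq_id)
  aln$mat[seq_id, ]
}

#' Subset an alignment by sequence id
#'
#' @param aln an `aln` object.
#' @param ids sequences to keep.
#' @param drop_allgap drop columns that become all-gap after subsetting.
#' @export
aln_subset <- function(aln, ids, drop_allgap = TRUE) {
  missing <- setdiff(ids, aln$ids)
  if (length(missing)) stop("not in alignment: ", paste(missing, collapse = ", "))
  mat <- aln$mat[ids, , drop = FALSE]
  if (drop_allgap) {
    mat <- mat[, colSums(mat != GAP_CHAR) > 0L, drop = FALSE]
    return(alignment(mat))
  }
  # keeping original column numbering may leave all-gap columns (e.g. a
  # family-specific deletion); bypass that single constructor check
  structure(list(mat = mat, ids = rownames(mat)), class = "aln")
}

#' Read a multiple sequence alignment
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return an `aln` object.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    lines <- readLines(path, warn = FALSE)
    nonblank <- which(nzchar(trimws(lines)))
    if (!length(nonblank)) stop("empty alignment file: ", path)
    if (!startsWith(trimws(lines[nonblank[1]]), ">"))
      stop("malformed FASTA in ", path, ": line ", nonblank[1],
           " is not a header line")
    ss <- Biostrings::readAAStringSet(path)
    seqs <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else {
    seqs <- read_clustal(path)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    med <- stats::median(lens)
    stop("ragged alignment in ", path, ": ",
         paste(names(seqs)[lens != med], collapse = ", "))
  }
  alignment(seqs)
}

# Minimal Clustal block parser: skips the header line, conservation lines
# and optional trailing residue counts.
read_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^CLUSTAL", lines[1]))
    stop("not a Clustal file (missing CLUSTAL header): ", path)
  seqs <- list()
  for (ln in lines[-1]) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s", ln)) next            # conservation line
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 2L) next
    id <- f[1]; chunk <- f[2]
    seqs[[id]] <- paste0(seqs[[id]] %||% "", chunk)
  }
  if (!length(seqs)) stop("no sequences found in Clustal file: ", path)
  unlist(seqs)
}

#' Write an alignment to FASTA or Clustal
#'
#' @param aln an `aln` object.
#' @param path output file.
#' @param format `"fasta"` or `"clustal"`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  seqs <- aln_strings(aln)
  if (format == "fasta") return(write_fasta(seqs, path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("CLUSTAL multiple sequence alignment (paraloglens)", con)
  writeLines("", con)
  idw <- max(nchar(names(seqs))) + 3L
  for (start in seq(1L, n_cols(aln), by = 60L)) {
    for (k in seq_along(seqs)) {
      chunk <- substr(seqs[k], start, min(start + 59L, n_cols(aln)))
      writeLines(sprintf("%-*s%s", idw, names(seqs)[k], chunk), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Map an alignment column to an ungapped residue index
#'
#' Returns the 1-based residue index of `seq_id` at alignment column `col`,
#' or `NA` when the sequence has a gap there.
#'
#' @param aln an `aln` object.
#' @param seq_id sequence identifier.
#' @param col 1-based column index (vectorised).
#' @return integer vector (NA = gap).
#' @export
col_to_residue <- function(aln, seq_id, col) {
  row <- aln_row(aln, seq_id)
  if (any(col < 1L | col > length(row)))
    stop("column out of range 1..", length(row))
  idx <- cumsum(row != GAP_CHAR)
  out <- idx[col]
  out[row[col] == GAP_CHAR] <- NA_integer_
  as.integer(out)
}

#' Map an ungapped residue index to its alignment column
#'
#' Inverse of [col_to_residue()] over non-gap columns.
#'
#' @param aln an `aln` object.
#' @param seq_id sequence identifier.
#' @param res 1-based residue index (vectorised).
#' @return integer vector of column indices.
#' @export
residue_to_col <- function(aln, seq_id, res) {
  row <- aln_row(aln, seq_id)
  cols <- which(row != GAP_CHAR)
  if (any(res < 1L | res > length(cols)))
    stop("residue index out of range 1..", length(cols))
  as.integer(cols[res])
}

#' Read domain annotations from a TSV file
#'
#' Columns: `seq_id`, `domain`, `start`, `end` (1-based inclusive ungapped
#' residue coordinates).
#'
#' @param path TSV file.
#' @export
read_domain_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("seq_id", "domain", "start", "end")
  if (!all(need %in% names(d)))
    stop("domain table must have columns ", paste(need, collapse = ", "))
  if (any(d$start < 1L | d$start > d$end))
    stop("invalid domain coordinates (need 1 <= start <= end)")
  d[need]
}

#' Extract a domain subsequence from a sequence record
#'
#' @param records a `seq_records` data frame.
#' @param seq_id which sequence.
#' @param domain domain name (suffixed onto the new id).
#' @param start,end 1-based inclusive ungapped coordinates.
#' @return a one-row `seq_records` data frame with id `"<id>_<domain>"`.
#' @export
extract_domain <- function(records, seq_id, domain, start, end) {
  i <- match(seq_id, records$id)
  if (is.na(i)) stop("unknown sequence id: ", seq_id)
  len <- nchar(records$residues[i])
  if (start < 1L || end > len || start > end)
    stop("domain [", start, ",", end, "] out of bounds for ", seq_id,
         " (length ", len, ")")
  seq_records(id = paste0(seq_id, "_", domain),
              residues = substr(records$residues[i], start, end),
              species = records$species[i],
              isoform = records$isoform[i],
              description = records$description[i])
}
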