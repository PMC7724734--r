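#' Sequence alignments
#'
#' An alignment is stored as a character matrix (rows = sequences,
#' columns = sites) over the alphabet `A C G T - ?`, with sequence
#' identifiers as row names and an optional per-sequence metadata
#' data frame in the `"meta"` attribute (columns `id`, `role`,
#' `supergroup`; `role` distinguishes `"study"` from `"reference"`
#' sequences for strain typing).
#'
#' On construction sequences are normalized: lower case is raised,
#' `U` becomes `T`, and every IUPAC ambiguity code (or other stray
#' character) becomes `?`, which all distance computations treat as
#' missing.
#'
#' @param seqs character matrix, or a list/vector of equal-length
#'   strings, with sequence identifiers as (row) names.
#' @param meta optional data frame of per-sequence metadata with an
#'   `id` column matching the identifiers.
#' @return An object of class `symbio_aln` (a character matrix).
#' @examples
#' aln <- alignment(c(s1 = "ACGT", s2 = "ACGA"))
#' ungapped_lengths(aln)
#' @export
alignment <- function(seqs, meta = NULL) {
  if (is.list(seqs) || (is.character(seqs) && is.null(dim(seqs)))) {
    seqs <- unlist(seqs)
    ids <- names(seqs)
    if (is.null(ids) || anyNA(ids) || any(ids == "")) {
      sym_stop("symbio_bad_ids", "every sequence needs an identifier")
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      sym_stop("symbio_ragged_alignment", sprintf(
        "sequences are not aligned: lengths %s",
        paste(unique(lens), collapse = ", ")
      ))
    }
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(seqs) <- ids
  } else {
    seqs <- toupper(as.matrix(seqs))
  }
  if (anyDuplicated(rownames(seqs))) {
    sym_stop("symbio_bad_ids", "duplicate sequence identifiers")
  }
  seqs[seqs == "U"] <- "T"
  seqs[!seqs %in% c("A", "C", "G", "T", "-")] <- "?"
  if (!is.null(meta)) {
    if (!"id" %in% names(meta) || !all(rownames(seqs) %in% meta$id)) {
      sym_stop("symbio_bad_meta", "meta must have an 'id' column covering all sequences")
    }
    meta <- meta[match(rownames(seqs), meta$id), , drop = FALSE]
    rownames(meta) <- NULL
  } else {
    meta <- data.frame(id = rownames(seqs), role = "study",
                       stringsAsFactors = FALSE)
  }
  structure(seqs, meta = meta, class = c("symbio_aln", "matrix", "array"))
}

#' @export
print.symbio_aln <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d sites\n", nrow(x), ncol(x)))
  roles <- table(attr(x, "meta")$role)
  cat(" ", paste(sprintf("%s: %d", names(roles), roles), collapse = ", "), "\n")
  invisible(x)
}

#' Number of non-gap sites per sequence
#'
#' @param aln a [alignment()] object.
#' @return Named integer vector of ungapped lengths.
#' @export
ungapped_lengths <- function(aln) {
  apply(unclass(aln), 1L, function(s) sum(s != "-" & s != "?"))
}

#' Read an aligned FASTA file
#'
#' Reads pre-aligned sequences, normalizes the alphabet (see
#' [alignment()]) and drops sequences whose ungapped length is below
#' `min_length`, reporting each exclusion. Short amplicons carry too
#' little signal for distance estimation and are removed up front.
#'
#' @param path FASTA file.
#' @param min_length minimum number of ungapped sites a sequence must
#'   have to be retained (default 500; use 0 to disable).
#' @param meta optional metadata data frame passed to [alignment()].
#' @return A `symbio_aln`; excluded ids are available in
#'   `attr(, "excluded")`.
#' @export
read_alignment <- function(path, min_length = 500, meta = NULL) {
  recs <- ape::read.FASTA(path)
  if (length(recs) == 0L) {
    sym_stop("symbio_empty_alignment", sprintf("no sequences in '%s'", path))
  }
  lens <- lengths(recs)
  if (length(unique(lens)) > 1L) {
    sym_stop("symbio_ragged_alignment", sprintf(
      "'%s' is not an alignment: sequence lengths %s",
      path, paste(sort(unique(lens)), collapse = ", ")
    ))
  }
  mat <- toupper(as.character(as.matrix(recs)))
  aln <- alignment(mat, meta = meta)
  keep <- ungapped_lengths(aln) >= min_length
  excluded <- rownames(aln)[!keep]
  if (length(excluded)) {
    message(sprintf("excluded %d sequence(s) shorter than %d ungapped sites: %s",
                    length(excluded), min_length,
                    paste(excluded, collapse = ", ")))
  }
  if (!any(keep)) {
    sym_stop("symbio_empty_alignment",
             sprintf("no sequences left after the %d-site length filter", min_length))
  }
  m <- attr(aln, "meta")[keep, , drop = FALSE]
  out <- alignment(unclass(aln)[keep, , drop = FALSE], meta = m)
  attr(out, "excluded") <- excluded
  out
}

#' Write an alignment to FASTA
#'
#' @param aln a [alignment()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  lines <- character(2L * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
  lines[c(FALSE, TRUE)] <- apply(unclass(aln), 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Extract a subset of sequences
#'
#' @param aln a [alignment()] object.
#' @param ids sequence identifiers to keep.
#' @return A `symbio_aln`.
#' @export
subset_alignment <- function(aln, ids) {
  missing <- setdiff(ids, rownames(aln))
  if (length(missing)) {
    sym_stop("symbio_unknown_id",
             paste("unknown sequence id(s):", paste(missing, collapse = ", ")))
  }
  meta <- attr(aln, "meta")
  alignment(unclass(aln)[ids, , drop = FALSE],
            meta = meta[meta$id %in% ids, , drop = FALSE])
}
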