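TISSUES <- c("leg", "gut", "reproductive")
TISSUE_CALLS <- c("positive", "negative", "not-assessed")

#' Validate a specimen screening table
#'
#' A specimen table records one screened individual per row:
#' `specimen_id`, `species`, `locality`, `sex` (`F`/`M`), one infection
#' call per tissue (`leg`, `gut`, `reproductive`; each `positive`,
#' `negative` or `not-assessed`), and `control_pass` (did the internal
#' control amplify for any tissue). The derived `overall` column is
#' `positive` iff any tissue is positive.
#'
#' @param df data frame with the columns above (`overall` optional;
#'   it is recomputed).
#' @return The validated data frame, class `specimen_table`.
#' @export
as_specimen_table <- function(df) {
  req <- c("specimen_id", "species", "locality", "sex", TISSUES, "control_pass")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    sym_stop("symbio_bad_columns",
             paste("missing column(s):", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$specimen_id)) {
    sym_stop("symbio_bad_ids", "specimen IDs are not unique")
  }
  bad <- which(!df$sex %in% c("F", "M"))
  if (length(bad)) {
    sym_stop("symbio_bad_value", sprintf(
      "invalid sex value '%s' in row %d (specimen %s)",
      df$sex[bad[1L]], bad[1L], df$specimen_id[bad[1L]]))
  }
  for (tis in TISSUES) {
    bad <- which(!df[[tis]] %in% TISSUE_CALLS)
    if (length(bad)) {
      sym_stop("symbio_bad_value", sprintf(
        "invalid %s call '%s' in row %d (specimen %s)",
        tis, df[[tis]][bad[1L]], bad[1L], df$specimen_id[bad[1L]]))
    }
  }
  df$control_pass <- as.logical(df$control_pass)
  if (anyNA(df$control_pass)) {
    sym_stop("symbio_bad_value", "control_pass must be logical (TRUE/FALSE)")
  }
  df$overall <- ifelse(
    df$leg == "positive" | df$gut == "positive" | df$reproductive == "positive",
    "positive", "negative")
  class(df) <- c("specimen_table", "data.frame")
  df
}

#' Read a specimen screening table from CSV
#'
#' @param path CSV file with a header (see [as_specimen_table()] for
#'   the required columns).
#' @return A `specimen_table` data frame.
#' @export
read_specimen_table <- function(path) {
  as_specimen_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Read a binary host x strain association matrix from TSV
#'
#' First column = host labels, remaining columns = strain labels, cells
#' 0/1. Every strain must occur in at least one host.
#'
#' @param path TSV file.
#' @return Binary integer matrix, hosts as rows.
#' @export
read_association <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  as_association(m)
}

#' Validate a host x strain association matrix
#'
#' @param m matrix of 0/1 incidences, hosts as rows, strains as
#'   columns, both with dimnames.
#' @return The validated integer matrix.
#' @export
as_association <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    sym_stop("symbio_bad_association", "association matrix needs host and strain labels")
  }
  if (!all(m %in% c(0, 1))) {
    sym_stop("symbio_bad_association", "association cells must be 0 or 1")
  }
  storage.mode(m) <- "integer"
  empty <- colnames(m)[colSums(m) == 0L]
  if (length(empty)) {
    sym_stop("symbio_bad_association", sprintf(
      "strain(s) with no host: %s", paste(empty, collapse = ", ")))
  }
  m
}

#' Write an association matrix to TSV
#'
#' @param m association matrix (see [as_association()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_association <- function(m, path) {
  df <- data.frame(host = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export host-symbiont association links
#'
#' Plain-text tanglegram export: one row per host-strain link, the
#' format consumed by cophylogeny viewers.
#'
#' @param m association matrix.
#' @return Data frame with columns `host`, `strain`.
#' @export
association_links <- function(m) {
  idx <- which(m == 1L, arr.ind = TRUE)
  out <- data.frame(host = rownames(m)[idx[, 1L]],
                    strain = colnames(m)[idx[, 2L]],
                    stringsAsFactors = FALSE)
  out[order(out$host, out$strain), , drop = FALSE]
}
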