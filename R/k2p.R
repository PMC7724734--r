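#' Kimura two-parameter distances
#'
#' Pairwise K2P distances
#' \deqn{d = -\tfrac12 \log(1 - 2P - Q) - \tfrac14 \log(1 - 2Q)}
#' with \eqn{P} the transition and \eqn{Q} the transversion proportion
#' over the columns retained for the pair.
#'
#' Gap handling follows the usual barcoding convention: terminal gaps
#' and `?` are missing data and their columns are simply dropped for
#' the pair; internal gaps are indels -- also excluded from the
#' \eqn{P}/\eqn{Q} counts, but tallied per pair in `attr(, "indels")`
#' (set `internal_gaps = "missing"` to skip the tally). Pairs whose
#' K2P logarithms are undefined (saturation) receive a sentinel of
#' twice the largest finite distance in the matrix, with a warning;
#' they are flagged in `attr(, "saturated")`.
#'
#' @param aln a [alignment()] object with at least two sequences.
#' @param internal_gaps `"indel"` (default) or `"missing"`.
#' @return Symmetric distance matrix with zero diagonal and attributes
#'   `sites` (per-pair retained columns), `indels`, `saturated`.
#' @examples
#' a <- alignment(c(x = "ACGT", y = "GCGT"))
#' k2p_distance(a)[1, 2]  # -0.5 * log(0.5)
#' @export
k2p_distance <- function(aln, internal_gaps = c("indel", "missing")) {
  internal_gaps <- match.arg(internal_gaps)
  m <- unclass(aln)
  n <- nrow(m)
  if (n < 2L) sym_stop("symbio_too_few", "need at least 2 sequences")
  # terminal gaps -> missing
  for (i in seq_len(n)) {
    s <- m[i, ]
    real <- which(s != "-" & s != "?")
    if (length(real) == 0L) { m[i, ] <- "?"; next }
    if (real[1L] > 1L) m[i, seq_len(real[1L] - 1L)] <- "?"
    if (real[length(real)] < ncol(m)) m[i, (real[length(real)] + 1L):ncol(m)] <- "?"
  }
  ids <- rownames(m)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  sites <- matrix(0L, n, n, dimnames = list(ids, ids))
  indels <- matrix(0L, n, n, dimnames = list(ids, ids))
  sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      x <- m[i, ]; y <- m[j, ]
      miss <- x == "?" | y == "?"
      gap <- (x == "-" | y == "-") & !miss
      use <- !miss & !gap
      L <- sum(use)
      if (L == 0L) {
        sym_stop("symbio_no_overlap", sprintf(
          "sequences '%s' and '%s' share no comparable columns", ids[i], ids[j]))
      }
      xi <- x[use]; yi <- y[use]
      diff <- xi != yi
      ts <- sum(diff & (purine[xi] == purine[yi]))
      tv <- sum(diff) - ts
      P <- ts / L; Q <- tv / L
      w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
      d <- if (w1 <= 0 || w2 <= 0) NA_real_ else -0.5 * log(w1) - 0.25 * log(w2)
      D[i, j] <- D[j, i] <- d
      sites[i, j] <- sites[j, i] <- L
      indels[i, j] <- indels[j, i] <- if (internal_gaps == "indel") sum(gap) else NA_integer_
      sat[i, j] <- sat[j, i] <- is.na(d)
    }
  }
  if (any(sat)) {
    finite <- D[!sat]
    sentinel <- if (length(finite) && max(finite) > 0) 2 * max(finite) else 1
    D[sat] <- sentinel
    warning(sprintf("%d saturated pair(s) set to sentinel distance %.4g",
                    sum(sat) / 2, sentinel))
  }
  structure(D, sites = sites, indels = indels, saturated = sat)
}
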