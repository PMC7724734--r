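#' Neighbour-joining tree
#'
#' Classic Saitou--Nei agglomeration on a distance matrix. When two
#' pairs share the minimal Q criterion the lexicographically smallest
#' label pair is joined (cluster label = smallest tip label inside),
#' so the result is deterministic. Negative estimated branch lengths
#' are clamped to zero with the deficit transferred to the sibling
#' edge, preserving the joined pair's path length.
#'
#' @param D symmetric distance matrix with labelled dimnames (at least
#'   two taxa; two taxa give a single edge, split evenly across the
#'   root for representation as a `phylo`).
#' @return An unrooted `phylo` (basal trifurcation for `n >= 3`).
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  labels <- rownames(D)
  if (is.null(labels) || is.null(colnames(D))) {
    sym_stop("symbio_bad_distance", "distance matrix needs dimnames")
  }
  if (anyNA(D) || any(!is.finite(D))) {
    sym_stop("symbio_bad_distance", "distance matrix contains NA/NaN/Inf")
  }
  if (max(abs(D - t(D))) > 1e-8) {
    sym_stop("symbio_bad_distance", "distance matrix is not symmetric")
  }
  n <- nrow(D)
  if (n < 2L) sym_stop("symbio_too_few", "need at least 2 taxa")
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  if (n == 2L) {
    txt <- sprintf("(%s:%s,%s:%s);", labels[1L], fmt(D[1, 2] / 2),
                   labels[2L], fmt(D[1, 2] / 2))
    return(ape::read.tree(text = txt))
  }
  # working state: newick fragment and min-tip "name" per cluster
  frag <- labels
  name <- labels
  repeat {
    m <- nrow(D)
    if (m == 3L) break
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      p <- sort(c(name[cand[k, 1]], name[cand[k, 2]]))
      paste(p, collapse = "\r")
    }, character(1L))
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vi <- max(vi, 0); vj <- max(vj, 0)
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(vi), frag[j], fmt(vj))
    newname <- min(name[i], name[j])
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    name <- c(name[keep], newname)
    rownames(D2) <- colnames(D2) <- name
    D <- D2
  }
  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1L], fmt(a), frag[2L], fmt(b), frag[3L], fmt(c3))
  ape::read.tree(text = txt)
}
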