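#' Principal coordinates with Cailliez correction
#'
#' Classical scaling of a distance matrix. If the configuration is not
#' Euclidean (negative eigenvalues beyond tolerance), the smallest
#' Cailliez constant `c` is added to every off-diagonal distance to
#' make it so, and the scaling is recomputed. Axes with eigenvalues
#' above `tol` times the leading eigenvalue are returned.
#'
#' The constant is the largest real eigenvalue of the 2n x 2n block
#' matrix `[[0, 2*D1], [-I, -4*D2]]`, where `D1` and `D2` are the
#' double-centred matrices of `-d^2/2` and `-d/2`.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param tol relative eigenvalue tolerance (default 1e-8).
#' @return List with `vectors` (coordinates, rows = objects),
#'   `values` (positive eigenvalues), `cailliez` (the constant, 0 when
#'   no correction was needed).
#' @export
pcoa_cailliez <- function(D, tol = 1e-8) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || max(abs(D - t(D))) > 1e-8 || any(diag(D) != 0)) {
    sym_stop("symbio_bad_distance", "need a symmetric zero-diagonal distance matrix")
  }
  if (all(D == 0)) {
    return(list(vectors = matrix(0, n, 1, dimnames = list(rownames(D), "Axis1")),
                values = 0, cailliez = 0))
  }
  centre <- function(M) {
    rm <- rowMeans(M); gm <- mean(M)
    M - outer(rm, rm, "+") + gm  # outer(rm, cm) with cm = rm for symmetric M
  }
  gower <- function(d) centre(-0.5 * d * d)
  decompose <- function(d) eigen(gower(d), symmetric = TRUE)
  e <- decompose(D)
  cc <- 0
  lead <- max(abs(e$values))
  if (min(e$values) < -tol * lead) {
    D1 <- gower(D)
    D2 <- centre(-0.5 * D)
    M <- rbind(cbind(matrix(0, n, n), 2 * D1),
               cbind(-diag(n), -4 * D2))
    ev <- eigen(M, only.values = TRUE)$values
    cc <- max(Re(ev[abs(Im(ev)) < 1e-8]))
    Dc <- D + cc
    diag(Dc) <- 0
    e <- decompose(Dc)
    lead <- max(abs(e$values))
  }
  keep <- which(e$values > tol * lead)
  vec <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                                  length(keep))
  dimnames(vec) <- list(rownames(D), paste0("Axis", seq_along(keep)))
  list(vectors = vec, values = e$values[keep], cailliez = cc)
}

# shared machinery: principal coordinates + fourth-corner statistic
parafit_setup <- function(host_D, symb_D, assoc, tol = 1e-8) {
  assoc <- as_association(assoc)
  host_D <- as.matrix(host_D); symb_D <- as.matrix(symb_D)
  if (!all(rownames(assoc) %in% rownames(host_D)) ||
      !all(colnames(assoc) %in% rownames(symb_D))) {
    sym_stop("symbio_label_mismatch",
             "association labels must match the distance matrices")
  }
  host_D <- host_D[rownames(assoc), rownames(assoc)]
  symb_D <- symb_D[colnames(assoc), colnames(assoc)]
  hp <- pcoa_cailliez(host_D, tol)
  sp <- pcoa_cailliez(symb_D, tol)
  list(B = hp$vectors, C = sp$vectors, A = t(assoc),  # A: symbionts x hosts
       cailliez = c(host = hp$cailliez, symbiont = sp$cailliez))
}

parafit_stat <- function(A, B, C) {
  M <- crossprod(C, A %*% B)   # t(C) %*% A %*% B
  sum(M * M)
}

# one permutation: shuffle host incidences independently within each
# symbiont row of A, using pre-drawn column orders (rows of `ord`)
permute_rows <- function(A, ord) {
  out <- A
  for (i in seq_len(nrow(A))) out[i, ] <- A[i, ord[i, ]]
  out
}

#' ParaFit global test of host-symbiont congruence
#'
#' The global statistic is the sum of squared entries of the
#' fourth-corner cross product `t(C) A B`, with `B` and `C` the
#' Cailliez-corrected principal coordinates of the host and symbiont
#' distance matrices and `A` the symbiont x host incidence matrix.
#' Significance is assessed by independently permuting, within each
#' symbiont row of `A`, its host incidences;
#' `P = (#(stat_perm >= stat) + 1) / (n_perm + 1)`.
#'
#' @param host_D host distances (patristic or sequence), labelled.
#' @param symb_D symbiont distances, labelled.
#' @param assoc host x strain association matrix.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param tol eigenvalue tolerance for [pcoa_cailliez()].
#' @return A `parafit_result` list: `global`, `p`, `n_perm`,
#'   `cailliez`, `seed`.
#' @export
parafit_global <- function(host_D, symb_D, assoc, n_perm = 999, seed = NULL,
                           tol = 1e-8) {
  su <- parafit_setup(host_D, symb_D, assoc, tol)
  stat <- parafit_stat(su$A, su$B, su$C)
  if (!is.null(seed)) set.seed(seed)
  nh <- ncol(su$A)
  ns <- nrow(su$A)
  k <- rowSums(su$A)
  hits <- 0L
  X <- matrix(0, ns, ncol(su$B))
  for (r in seq_len(n_perm)) {
    # shuffling a binary row = redrawing its hosts uniformly: build the
    # permuted A %*% B directly from k[i] sampled rows of B
    for (i in seq_len(ns)) {
      idx <- sample.int(nh, k[i])
      X[i, ] <- if (k[i] == 1L) su$B[idx, ] else colSums(su$B[idx, , drop = FALSE])
    }
    M <- crossprod(su$C, X)
    if (sum(M * M) >= stat) hits <- hits + 1L
  }
  structure(list(global = stat, p = (hits + 1) / (n_perm + 1),
                 n_perm = n_perm, cailliez = su$cailliez, seed = seed),
            class = "parafit_result")
}

#' @export
print.parafit_result <- function(x, ...) {
  cat(sprintf("ParaFit global = %.6g, P = %.4g (%d permutations)\n",
              x$global, x$p, x$n_perm))
  if (!is.null(x$links)) {
    cat("Per-link tests:\n")
    print(x$links, row.names = FALSE)
  }
  invisible(x)
}

#' ParaFit per-link tests
#'
#' The statistic of a link is its contribution to the global
#' statistic: global minus the global statistic recomputed with the
#' link removed. Each permutation applies one row-wise shuffle (the
#' global scheme) to both the full and the link-deleted matrix, and
#' the permuted contribution is compared to the observed one. A link
#' whose removal leaves its strain hostless is still computed (for a
#' single-host strain the contribution is the strain's whole share)
#' but flagged in the `undefined` column.
#'
#' @inheritParams parafit_global
#' @return A `parafit_result` with `global`, `p`, and a `links` data
#'   frame (`host`, `strain`, `stat`, `p`, `undefined`), links in
#'   input (association) order.
#' @export
parafit_links <- function(host_D, symb_D, assoc, n_perm = 999, seed = NULL,
                          tol = 1e-8) {
  su <- parafit_setup(host_D, symb_D, assoc, tol)
  A <- su$A
  stat <- parafit_stat(A, su$B, su$C)
  links <- which(t(A) == 1L, arr.ind = TRUE)  # host-major input order
  links <- data.frame(host = rownames(t(A))[links[, 1L]],
                      strain = colnames(t(A))[links[, 2L]],
                      stringsAsFactors = FALSE)
  nl <- nrow(links)
  lstat <- rep(NA_real_, nl); lp <- rep(NA_real_, nl)
  undef <- logical(nl)
  if (!is.null(seed)) set.seed(seed)
  nh <- ncol(A)
  ords <- lapply(seq_len(n_perm), function(r) {
    t(vapply(seq_len(nrow(A)), function(i) sample.int(nh), integer(nh)))
  })
  stat_perm_full <- vapply(ords, function(ord) {
    parafit_stat(permute_rows(A, ord), su$B, su$C)
  }, numeric(1L))
  for (k in seq_len(nl)) {
    i <- match(links$strain[k], rownames(A))
    j <- match(links$host[k], colnames(A))
    undef[k] <- sum(A[i, ]) == 1L  # removal empties the strain's row
    Ak <- A; Ak[i, j] <- 0L
    lstat[k] <- stat - parafit_stat(Ak, su$B, su$C)
    hits <- 0L
    for (r in seq_len(n_perm)) {
      sk <- stat_perm_full[r] - parafit_stat(permute_rows(Ak, ords[[r]]), su$B, su$C)
      if (sk >= lstat[k]) hits <- hits + 1L
    }
    lp[k] <- (hits + 1) / (n_perm + 1)
  }
  links$stat <- lstat; links$p <- lp; links$undefined <- undef
  structure(list(global = stat, p = NA_real_, n_perm = n_perm,
                 cailliez = su$cailliez, seed = seed, links = links),
            class = "parafit_result")
}
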