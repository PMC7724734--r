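#' Phylogenetic host-specificity score
#'
#' Mean patristic distance over all unordered pairs of the host
#' species infected by one strain. Small values mean the strain's
#' hosts are phylogenetically clustered.
#'
#' @param host_tree host `phylo` with branch lengths, or a
#'   precomputed patristic distance matrix.
#' @param hosts character vector of at least two host tips.
#' @return The PS value (numeric scalar).
#' @export
ps_score <- function(host_tree, hosts) {
  D <- if (is.matrix(host_tree)) host_tree else patristic_distances(host_tree)
  hosts <- unique(hosts)
  if (length(hosts) < 2L) {
    sym_stop("symbio_too_few", "PS needs at least two host species")
  }
  missing <- setdiff(hosts, rownames(D))
  if (length(missing)) {
    sym_stop("symbio_unknown_tip",
             paste("host(s) not on the tree:", paste(missing, collapse = ", ")))
  }
  sub <- D[hosts, hosts]
  mean(sub[upper.tri(sub)])
}

#' Standardized phylogenetic host-specificity (SPS)
#'
#' Standardizes the observed PS of a strain against a permutation
#' null: each replicate draws the same number of host species
#' uniformly without replacement from the host tree's tips
#' (`null = "uniform"`; `null = "tipshuffle"` shuffles tip labels
#' instead, which is marginally equivalent) and recomputes PS.
#' \deqn{SPS = (PS - mean(PS_{null})) / sd(PS_{null})}
#' The P value is the lower-tail add-one rank,
#' \eqn{P = (\#\{PS_r \le PS\} + 1)/(n_{null} + 1)}: clustered hosts
#' give small PS and small P (low host flexibility, P < 0.05);
#' phylogenetically even hosts give large PS and large P (high
#' flexibility, P > 0.95).
#'
#' @param host_tree host `phylo` (or patristic distance matrix).
#' @param hosts host species of the strain (>= 2), or give `assoc` and
#'   `strain` instead.
#' @param assoc optional host x strain association matrix.
#' @param strain optional strain (column) name looked up in `assoc`.
#' @param n_null number of null replicates (default 999).
#' @param null `"uniform"` or `"tipshuffle"`.
#' @param seed integer seed for reproducibility.
#' @return An `sps_result` list: `strain`, `n_hosts`, `ps`,
#'   `null_mean`, `null_sd`, `sps`, `p`, `n_null`, `seed`,
#'   `degenerate` (TRUE when the null has zero spread, e.g. on a star
#'   tree, and SPS is undefined).
#' @export
sps_score <- function(host_tree, hosts = NULL, assoc = NULL, strain = NULL,
                      n_null = 999, null = c("uniform", "tipshuffle"),
                      seed = NULL) {
  null <- match.arg(null)
  if (is.null(hosts)) {
    if (is.null(assoc) || is.null(strain)) {
      sym_stop("symbio_bad_call", "give either hosts or assoc+strain")
    }
    if (!strain %in% colnames(assoc)) {
      sym_stop("symbio_unknown_strain", paste("strain not in association matrix:", strain))
    }
    hosts <- rownames(assoc)[assoc[, strain] == 1L]
  }
  D <- if (is.matrix(host_tree)) host_tree else patristic_distances(host_tree)
  ps <- ps_score(D, hosts)
  k <- length(unique(hosts))
  tips <- rownames(D)
  if (!is.null(seed)) set.seed(seed)
  ps_null <- vapply(seq_len(n_null), function(r) {
    draw <- if (null == "uniform") sample(tips, k) else {
      relab <- setNames(sample(tips), tips)
      unname(relab[unique(hosts)])
    }
    sub <- D[draw, draw]
    mean(sub[upper.tri(sub)])
  }, numeric(1L))
  mu <- mean(ps_null)
  sdv <- sd(ps_null)
  degenerate <- !is.finite(sdv) || sdv < 1e-12
  structure(list(
    strain = strain %||% NA_character_,
    n_hosts = k,
    ps = ps,
    null_mean = mu,
    null_sd = sdv,
    sps = if (degenerate) NA_real_ else (ps - mu) / sdv,
    p = (sum(ps_null <= ps) + 1) / (n_null + 1),
    n_null = n_null,
    seed = seed,
    degenerate = degenerate
  ), class = "sps_result")
}

#' @export
print.sps_result <- function(x, ...) {
  cat(sprintf("SPS%s: n hosts = %d, PS = %.4g, SPS = %.3f, P = %.4g (%d nulls)%s\n",
              if (is.na(x$strain)) "" else paste0(" [", x$strain, "]"),
              x$n_hosts, x$ps, x$sps, x$p, x$n_null,
              if (x$degenerate) " [degenerate null]" else ""))
  invisible(x)
}

#' SPS table for all generalist strains
#'
#' @param host_tree host `phylo`.
#' @param assoc host x strain association matrix.
#' @param n_null,null,seed passed to [sps_score()].
#' @return Data frame with one row per generalist strain: `strain`,
#'   `n_hosts`, `ps`, `sps`, `p`, `degenerate`.
#' @export
sps_table <- function(host_tree, assoc, n_null = 999, null = "uniform",
                      seed = NULL) {
  assoc <- as_association(assoc)
  gen <- colnames(assoc)[colSums(assoc) >= 2L]
  rows <- lapply(seq_along(gen), function(i) {
    r <- sps_score(host_tree, assoc = assoc, strain = gen[i], n_null = n_null,
                   null = null,
                   seed = if (is.null(seed)) NULL else seed + i - 1L)
    data.frame(strain = gen[i], n_hosts = r$n_hosts, ps = r$ps, sps = r$sps,
               p = r$p, degenerate = r$degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
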