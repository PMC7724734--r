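# Canonical keys for the non-trivial bipartitions of an unrooted tree.
# Each internal edge splits the tips; the side NOT containing the
# alphabetically first tip is the key, so rooted representations of the
# same unrooted tree agree.
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  first <- tips[1L]
  n <- length(tree$tip.label)
  clades <- clade_tips(tree)
  keys <- character(0)
  nodes <- integer(0)
  for (nd in as.integer(names(clades))) {
    cl <- clades[[as.character(nd)]]
    if (length(cl) <= 1L || length(cl) >= n - 1L) next
    side <- if (first %in% cl) setdiff(tree$tip.label, cl) else cl
    keys <- c(keys, paste(sort(side), collapse = "\r"))
    nodes <- c(nodes, nd)
  }
  names(keys) <- nodes
  keys
}

# tip labels below each internal node (names = node numbers)
clade_tips <- function(tree) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  kids <- vector("list", n + nn)
  for (i in seq_len(n)) kids[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    kids[[p]] <- c(kids[[p]], kids[[ch]])
  }
  out <- kids[(n + 1L):(n + nn)]
  names(out) <- (n + 1L):(n + nn)
  out
}

#' Neighbour-joining tree with bootstrap support
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `n_reps` times, rebuilds the tree per
#' replicate and records, for every internal edge of the original tree,
#' the fraction of replicates whose tree contains the same (unrooted)
#' bipartition. One pseudo-random stream is consumed replicate by
#' replicate, so for a fixed seed the first `k` replicates of a longer
#' run are identical to a run with `n_reps = k`.
#'
#' @param aln a [alignment()] object.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param internal_gaps passed to [k2p_distance()].
#' @return The NJ `phylo` with support fractions in `node.label`
#'   (`NA`/empty on the basal trifurcation and tips). With fewer than
#'   four sequences support is undefined: the tree is returned without
#'   support, with a warning.
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = NULL,
                              internal_gaps = "indel") {
  stopifnot(n_reps >= 1)
  D <- suppressWarnings(k2p_distance(aln, internal_gaps))
  tree <- nj_tree(D)
  if (nrow(aln) < 4L) {
    warning("fewer than 4 sequences: bipartition support is undefined")
    return(tree)
  }
  obs <- tree_bipartitions(tree)
  counts <- setNames(numeric(length(obs)), obs)
  L <- ncol(aln)
  if (!is.null(seed)) set.seed(seed)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    sub <- alignment(unclass(aln)[, cols, drop = FALSE], meta = attr(aln, "meta"))
    Dr <- suppressWarnings(k2p_distance(sub, internal_gaps))
    tr <- nj_tree(Dr)
    hit <- unique(tree_bipartitions(tr))
    inobs <- hit[hit %in% obs]
    counts[inobs] <- counts[inobs] + 1
  }
  sup <- rep(NA_real_, tree$Nnode)
  idx <- as.integer(names(obs)) - length(tree$tip.label)
  sup[idx] <- counts[obs] / n_reps
  node_support(tree) <- sup
  tree
}
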