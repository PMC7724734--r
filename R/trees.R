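#' Prune a tree to one representative tip per species
#'
#' Keeps exactly one tip for every species. The representative is the
#' tip with the longest ungapped sequence when `ungapped_lengths` is
#' supplied (ties broken by the lexicographically smallest identifier),
#' otherwise the lexicographically smallest identifier. Degree-2 nodes
#' created by pruning are suppressed with their branch lengths summed,
#' so patristic distances among retained tips are unchanged.
#'
#' @param tree a `phylo`.
#' @param species_of named character vector mapping every tip label to
#'   a species name.
#' @param ungapped_lengths optional named numeric vector (e.g. from
#'   [ungapped_lengths()]) used to pick representatives.
#' @return A pruned `phylo`; the representative map is in
#'   `attr(, "representatives")`.
#' @export
prune_one_per_species <- function(tree, species_of, ungapped_lengths = NULL) {
  unmapped <- setdiff(tree$tip.label, names(species_of))
  if (length(unmapped)) {
    sym_stop("symbio_unmapped_tip",
             paste("tip(s) not mapped to a species:", paste(unmapped, collapse = ", ")))
  }
  sp <- species_of[tree$tip.label]
  reps <- vapply(split(tree$tip.label, sp), function(tips) {
    if (!is.null(ungapped_lengths)) {
      len <- ungapped_lengths[tips]
      len[is.na(len)] <- -Inf
      tips <- tips[len == max(len)]
    }
    sort(tips)[1L]
  }, character(1L))
  out <- if (length(reps) == length(tree$tip.label)) tree else
    ape::keep.tip(tree, unname(reps))
  attr(out, "representatives") <- reps
  out
}

#' Root a tree at the midpoint of its longest tip-to-tip path
#'
#' @param tree a `phylo` with branch lengths.
#' @return A rooted `phylo`; node support labels are carried with the
#'   edges they describe. Patristic distances are unchanged.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length)) {
    sym_stop("symbio_no_lengths", "midpoint rooting needs branch lengths")
  }
  phangorn::midpoint(tree, node.labels = "support")
}

#' Root a tree on the edge separating an outgroup
#'
#' @param tree a `phylo`.
#' @param outgroup_tips tip labels of the outgroup; they must form one
#'   side of some edge of the unrooted tree.
#' @return A rooted `phylo` with support labels kept on their edges.
#' @export
outgroup_root <- function(tree, outgroup_tips) {
  missing <- setdiff(outgroup_tips, tree$tip.label)
  if (length(missing)) {
    sym_stop("symbio_unknown_tip",
             paste("outgroup tip(s) absent:", paste(missing, collapse = ", ")))
  }
  if (length(outgroup_tips) > 1L &&
      !ape::is.monophyletic(tree, outgroup_tips)) {
    sym_stop("symbio_outgroup_not_monophyletic", sprintf(
      "outgroup {%s} is not monophyletic: no edge separates it from the ingroup {%s}",
      paste(outgroup_tips, collapse = ", "),
      paste(setdiff(tree$tip.label, outgroup_tips), collapse = ", ")
    ))
  }
  ape::root(tree, outgroup = outgroup_tips, resolve.root = TRUE,
            edgelabel = TRUE)
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree a `phylo` with branch lengths.
#' @return Symmetric matrix with zero diagonal, tips as dimnames.
#' @export
patristic_distances <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    sym_stop("symbio_no_lengths", "patristic distances need branch lengths")
  }
  as.matrix(stats::cophenetic(tree))
}
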