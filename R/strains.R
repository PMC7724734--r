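#' Delimit putative strains from a supported tree
#'
#' Strains are maximal clades consisting only of study sequences whose
#' subtending edge has bootstrap support at or above
#' `primary_threshold`. Study sequences not captured that way are
#' evaluated against a fallback rule: if the smallest study-only clade
#' containing such a sequence has support at or above
#' `secondary_threshold`, the unassigned sequences of that clade are
#' merged into one strain; otherwise the sequence becomes a singleton
#' strain. Strains are numbered `Wol 1`, `Wol 2`, ... by the traversal
#' order of the (rooted) input tree.
#'
#' @param tree rooted `phylo` whose `node.label` carries support
#'   fractions (see [read_newick()], [bootstrap_support()]).
#' @param study_ids tip labels of the study's own sequences; all other
#'   tips are treated as references and never enter a strain.
#' @param primary_threshold clade support delimiting a strain
#'   (default 0.97).
#' @param secondary_threshold fallback support for the merge rule
#'   (default 0.90; must not exceed `primary_threshold`).
#' @return A `strain_assignment`: list with `strain_of` (named map
#'   sequence -> strain), `strains` (list strain -> members),
#'   `supergroup`, `hosts`, `class` (filled by later steps).
#' @export
cluster_strains <- function(tree, study_ids, primary_threshold = 0.97,
                            secondary_threshold = 0.90) {
  sup <- node_support(tree)
  if (all(is.na(sup))) {
    sym_stop("symbio_unsupported_tree", "tree carries no support values")
  }
  if (secondary_threshold > primary_threshold) {
    sym_stop("symbio_bad_threshold",
             "secondary_threshold must not exceed primary_threshold")
  }
  study_ids <- intersect(tree$tip.label, study_ids)
  if (!length(study_ids)) {
    sym_stop("symbio_too_few", "no study sequences on the tree")
  }
  sup[is.na(sup)] <- 0
  n <- length(tree$tip.label)
  clades <- clade_tips(tree)
  study_only <- vapply(clades, function(cl) all(cl %in% study_ids), logical(1L))
  csize <- lengths(clades)

  primary <- which(study_only & sup >= primary_threshold)
  # maximality: drop candidates nested inside another candidate
  if (length(primary) > 1L) {
    nested <- vapply(primary, function(i) any(vapply(primary, function(j) {
      i != j && csize[j] > csize[i] && all(clades[[i]] %in% clades[[j]])
    }, logical(1L))), logical(1L))
    primary <- primary[!nested]
  }

  blocks <- lapply(primary, function(i) clades[[i]])
  assigned <- unlist(blocks)
  leftovers <- setdiff(study_ids, assigned)

  fallback_of <- character(0)
  for (tip in leftovers) {
    holds <- which(study_only & sup >= secondary_threshold &
                     vapply(clades, function(cl) tip %in% cl, logical(1L)))
    fallback_of[tip] <- if (length(holds)) {
      as.character(holds[which.min(csize[holds])])
    } else NA_character_
  }
  for (cl in unique(fallback_of[!is.na(fallback_of)])) {
    members <- names(fallback_of)[!is.na(fallback_of) & fallback_of == cl]
    blocks <- c(blocks, list(members))
  }
  for (tip in names(fallback_of)[is.na(fallback_of)]) {
    blocks <- c(blocks, list(tip))
  }

  # deterministic numbering: order blocks by first member in tip order
  tip_rank <- setNames(seq_len(n), tree$tip.label)
  blocks <- blocks[order(vapply(blocks, function(b) min(tip_rank[b]), numeric(1L)))]
  labels <- paste("Wol", seq_along(blocks))
  strain_of <- setNames(rep(labels, lengths(blocks)), unlist(blocks))
  structure(list(
    strain_of = strain_of,
    strains = setNames(blocks, labels),
    supergroup = setNames(rep(NA_character_, length(blocks)), labels),
    hosts = setNames(vector("list", length(blocks)), labels),
    class = setNames(rep(NA_character_, length(blocks)), labels),
    thresholds = c(primary = primary_threshold, secondary = secondary_threshold)
  ), class = "strain_assignment")
}

#' @export
print.strain_assignment <- function(x, ...) {
  cat(sprintf("Strain assignment: %d sequences in %d strains\n",
              length(x$strain_of), length(x$strains)))
  for (s in names(x$strains)) {
    cat(sprintf("  %s [%s%s]: %s\n", s,
                ifelse(is.na(x$supergroup[s]), "-", x$supergroup[s]),
                ifelse(is.na(x$class[s]), "", paste0(", ", x$class[s])),
                paste(x$strains[[s]], collapse = ", ")))
  }
  invisible(x)
}

#' Assign supergroups to strains from labelled references
#'
#' A strain inherits supergroup `X` when the smallest clade containing
#' the strain and at least one reference tip holds references of only
#' supergroup `X`. Strains whose members are all shorter than
#' `min_classifiable_length` ungapped sites are unclassified (`UC`), as
#' are strains whose nearest references mix supergroups (with a
#' warning). Manual overrides (e.g. for alignment problems that cannot
#' be detected automatically) win over both rules.
#'
#' @param assignment a [cluster_strains()] result.
#' @param tree the rooted tree used for clustering (references
#'   included).
#' @param references named character vector: reference tip label ->
#'   supergroup (`"A"`/`"B"`).
#' @param min_classifiable_length minimum ungapped length (default
#'   400) below which a strain is `UC`; only applied when
#'   `ungapped_lengths` is given.
#' @param ungapped_lengths optional named vector of ungapped sequence
#'   lengths.
#' @param overrides optional named character vector strain ->
#'   supergroup label, applied last.
#' @return The assignment with `supergroup` filled in.
#' @export
assign_supergroup <- function(assignment, tree, references,
                              min_classifiable_length = 400,
                              ungapped_lengths = NULL, overrides = NULL) {
  if (is.null(references) || !length(references)) {
    sym_stop("symbio_no_references", "no labelled reference tips supplied")
  }
  refs <- references[names(references) %in% tree$tip.label]
  if (!length(refs)) {
    sym_stop("symbio_no_references", "none of the reference tips are on the tree")
  }
  clades <- clade_tips(tree)
  csize <- lengths(clades)
  for (s in names(assignment$strains)) {
    members <- assignment$strains[[s]]
    if (!is.null(ungapped_lengths) &&
        all(ungapped_lengths[members] < min_classifiable_length, na.rm = FALSE)) {
      assignment$supergroup[s] <- "UC"
      next
    }
    holds <- which(vapply(clades, function(cl) {
      all(members %in% cl) && any(names(refs) %in% cl)
    }, logical(1L)))
    if (!length(holds)) {  # root clade always qualifies on a rooted tree
      assignment$supergroup[s] <- "UC"
      next
    }
    cl <- clades[[holds[which.min(csize[holds])]]]
    groups <- unique(refs[names(refs)[names(refs) %in% cl]])
    if (length(groups) == 1L) {
      assignment$supergroup[s] <- groups
    } else {
      assignment$supergroup[s] <- "UC"
      warning(sprintf("strain %s sits among references of supergroups %s: unclassified",
                      s, paste(sort(groups), collapse = "/")))
    }
  }
  if (!is.null(overrides)) {
    assignment$supergroup[names(overrides)] <- overrides
  }
  assignment
}

#' Classify strains as specialists or generalists
#'
#' A strain infecting exactly one host species is a specialist; two or
#' more, a generalist.
#'
#' @param assignment a [cluster_strains()] result.
#' @param assoc host x strain association matrix (see
#'   [as_association()]); columns must cover all strains.
#' @return The assignment with `hosts` and `class` filled in.
#' @export
classify_specificity <- function(assignment, assoc) {
  assoc <- as_association(assoc)
  missing <- setdiff(names(assignment$strains), colnames(assoc))
  if (length(missing)) {
    sym_stop("symbio_unknown_strain", sprintf(
      "strain(s) absent from the association matrix: %s",
      paste(missing, collapse = ", ")))
  }
  for (s in names(assignment$strains)) {
    hosts <- rownames(assoc)[assoc[, s] == 1L]
    assignment$hosts[[s]] <- hosts
    assignment$class[s] <- if (length(hosts) == 1L) "specialist" else "generalist"
  }
  assignment
}

#' Collapse a sequence-level association to strain level
#'
#' Sequence-level screening links hosts to individual symbiont
#' sequences; after strain delimitation the association of interest is
#' hosts x strains. A host carries a strain iff it carries any of the
#' strain's member sequences.
#'
#' @param assoc host x sequence binary matrix.
#' @param assignment a [cluster_strains()] result covering the
#'   sequence columns.
#' @return Host x strain binary matrix (validated association).
#' @export
strain_association <- function(assoc, assignment) {
  assoc <- as_association(assoc)
  cols <- vapply(names(assignment$strains), function(s) {
    members <- intersect(assignment$strains[[s]], colnames(assoc))
    if (!length(members)) {
      sym_stop("symbio_unknown_strain",
               paste("no association columns for strain", s))
    }
    as.integer(rowSums(assoc[, members, drop = FALSE]) > 0)
  }, integer(nrow(assoc)))
  rownames(cols) <- rownames(assoc)
  as_association(cols)
}

#' Strain table export
#'
#' @param assignment a completed strain assignment.
#' @return Data frame with one row per sequence: `sequence`, `strain`,
#'   `supergroup`, `class`, `n_hosts`.
#' @export
strain_table <- function(assignment) {
  seqs <- names(assignment$strain_of)
  st <- unname(assignment$strain_of)
  data.frame(
    sequence = seqs,
    strain = st,
    supergroup = unname(assignment$supergroup[st]),
    class = unname(assignment$class[st]),
    n_hosts = vapply(assignment$hosts[st],
                     function(h) if (is.null(h)) NA_integer_ else length(h),
                     integer(1L)),
    stringsAsFactors = FALSE
  )
}
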