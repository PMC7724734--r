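#' Read a Newick tree with node support
#'
#' Trees are `ape::phylo` objects. Internal-node support values are
#' normalized to fractions in \eqn{[0, 1]} and stored in `node.label`:
#' labels written as integers 0--100 (the usual bootstrap-percentage
#' dialect) are divided by 100, labels already in \eqn{[0, 1]} are kept
#' as is. Both the support-as-internal-label dialect
#' (`"((A,B)90:1,C);"`) and the support-in-comment dialect
#' (`"((A,B)[90]:1,C);"` or `"((A,B):1[90],C);"`) are accepted;
#' [write_newick()] always writes support as internal labels.
#'
#' @param path file containing one Newick string (or the string itself,
#'   when it contains a semicolon).
#' @return A `phylo`; `node.label` holds support fractions (as
#'   characters), `""` where undefined.
#' @seealso [node_support()], [write_newick()]
#' @export
read_newick <- function(path) {
  txt <- if (grepl(";", path, fixed = TRUE)) path else
    paste(readLines(path, warn = FALSE), collapse = "")
  num <- "([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)"
  # "(...)[90]:1" -> "(...)90:1"  and  "(...):1[90]" -> "(...)90:1"
  txt <- gsub(paste0("\\)\\[", num, "\\]"), ")\\1", txt)
  txt <- gsub(paste0("\\)(:", num, ")\\[", num, "\\]"), ")\\4\\1", txt)
  txt <- gsub("\\[[^]]*\\]", "", txt)  # strip remaining comments
  if (nchar(gsub("[^(]", "", txt)) != nchar(gsub("[^)]", "", txt))) {
    sym_stop("symbio_bad_newick", "unbalanced parentheses in Newick string")
  }
  tree <- tryCatch(ape::read.tree(text = txt), error = function(e)
    sym_stop("symbio_bad_newick", paste("cannot parse Newick:", conditionMessage(e))))
  if (is.null(tree)) sym_stop("symbio_bad_newick", "cannot parse Newick string")
  if (anyDuplicated(tree$tip.label)) {
    sym_stop("symbio_duplicate_tips", sprintf(
      "duplicate tip label(s): %s",
      paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")
    ))
  }
  lab <- tree$node.label
  if (!is.null(lab)) {
    nonempty <- !is.na(lab) & lab != ""
    suppressWarnings(vals <- as.numeric(lab[nonempty]))
    if (length(vals) && !anyNA(vals)) {
      if (any(vals > 1)) vals <- vals / 100
      lab[nonempty] <- as.character(vals)
      tree$node.label <- lab
    }
  }
  tree
}

#' Write a tree to Newick
#'
#' Support fractions in `node.label` are written as percentages
#' (internal-label dialect), so a tree read from `"((A:1,B:1)90:2,C:3);"`
#' round-trips byte-identically. Branch lengths keep 10 significant
#' digits.
#'
#' @param tree a `phylo`.
#' @param path output file; if `NULL` the Newick string is returned.
#' @param support_scale `"percent"` (default) writes fractions times
#'   100; `"fraction"` writes them untouched.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, support_scale = c("percent", "fraction")) {
  support_scale <- match.arg(support_scale)
  sup <- node_support(tree)
  if (!all(is.na(sup))) {
    lab <- rep("", tree$Nnode)
    ok <- !is.na(sup)
    val <- if (support_scale == "percent") sup[ok] * 100 else sup[ok]
    lab[ok] <- sub("\\.?0+$", "", formatC(val, format = "f", digits = 6))
    tree$node.label <- lab
  }
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Node support values as fractions
#'
#' @param tree a `phylo` whose `node.label` carries support (see
#'   [read_newick()]).
#' @return Numeric vector of length `tree$Nnode`, `NA` where no support
#'   is recorded (e.g. the root).
#' @export
node_support <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(vals <- as.numeric(lab))
  if (any(vals > 1, na.rm = TRUE)) vals <- vals / 100
  vals
}

#' Set node support values
#'
#' @param tree a `phylo`.
#' @param value numeric vector of fractions (length `tree$Nnode`).
#' @return The tree with updated `node.label`.
#' @export
`node_support<-` <- function(tree, value) {
  stopifnot(length(value) == tree$Nnode)
  tree$node.label <- ifelse(is.na(value), "", as.character(value))
  tree
}
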