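EVENTS <- c("cospeciation", "duplication", "host_shift", "loss",
            "failure_to_diverge")

#' Event cost scheme
#'
#' Costs for the five cophylogenetic event types. The default
#' (0, 1, 2, 1, 1) is the usual regime: cospeciation free, host
#' shifts twice as expensive as duplications, losses and failures to
#' diverge cheap.
#'
#' @param cospeciation,duplication,host_shift,loss,failure_to_diverge
#'   non-negative event costs.
#' @return Named numeric vector of class `cost_scheme`.
#' @export
cost_scheme <- function(cospeciation = 0, duplication = 1, host_shift = 2,
                        loss = 1, failure_to_diverge = 1) {
  x <- c(cospeciation = cospeciation, duplication = duplication,
         host_shift = host_shift, loss = loss,
         failure_to_diverge = failure_to_diverge)
  if (any(!is.finite(x)) || any(x < 0)) {
    sym_stop("symbio_bad_costs", "event costs must be non-negative numbers")
  }
  structure(x, class = "cost_scheme")
}

#' Total reconciliation cost
#'
#' Weighted sum of event counts under a cost scheme.
#'
#' @param counts named (or five-element) non-negative integer vector
#'   of event counts, order/names as in [cost_scheme()].
#' @param scheme a [cost_scheme()].
#' @return Numeric scalar.
#' @examples
#' total_cost(c(cospeciation = 1, duplication = 3, host_shift = 7,
#'              loss = 29, failure_to_diverge = 6), cost_scheme())
#' @export
total_cost <- function(counts, scheme = cost_scheme()) {
  if (!is.null(names(counts))) {
    missing <- setdiff(EVENTS, names(counts))
    if (length(missing)) {
      sym_stop("symbio_bad_counts",
               paste("missing event count(s):", paste(missing, collapse = ", ")))
    }
    counts <- counts[EVENTS]
  } else if (length(counts) == length(EVENTS)) {
    names(counts) <- EVENTS
  } else {
    sym_stop("symbio_bad_counts", "counts must be named or have five elements")
  }
  if (any(counts < 0)) sym_stop("symbio_bad_counts", "event counts must be >= 0")
  sum(counts * unclass(scheme)[EVENTS])
}

# ---- host-tree indexing shared by the exact DP, the decoder and the GA ----
#
# Positions are host NODES in ape numbering; "a lineage at h" means it
# sits on the edge above node h (the root edge for h = root). Passing
# a host node downwards on one side = one loss.
host_index <- function(host) {
  n <- length(host$tip.label)
  N <- n + host$Nnode
  kids <- vector("list", N)
  for (e in seq_len(nrow(host$edge))) {
    kids[[host$edge[e, 1L]]] <- c(kids[[host$edge[e, 1L]]], host$edge[e, 2L])
  }
  if (any(lengths(kids[(n + 1L):N]) != 2L)) {
    sym_stop("symbio_not_binary", "host tree must be binary (rooted)")
  }
  desc <- matrix(FALSE, N, N)     # desc[a, b]: b in subtree of a (incl. a)
  depth <- integer(N)             # edges from root
  root <- n + 1L
  ord <- integer(0)               # preorder
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    for (w in kids[[v]]) { depth[w] <- depth[v] + 1L; stack <- c(stack, w) }
  }
  for (v in rev(ord)) {
    desc[v, v] <- TRUE
    for (w in kids[[v]]) desc[v, ] <- desc[v, ] | desc[w, ]
  }
  # edgedist[a, b] = depth difference when b is in subtree of a, else NA
  edgedist <- matrix(NA_integer_, N, N)
  for (a in seq_len(N)) {
    below <- which(desc[a, ])
    edgedist[a, below] <- depth[below] - depth[a]
  }
  incomparable <- !desc & !t(desc)
  list(n = n, N = N, root = root, kids = kids, desc = desc,
       depth = depth, edgedist = edgedist, incomparable = incomparable,
       preorder = ord, labels = host$tip.label)
}

# Expansion of a multi-host symbiont tip over the spanning subtree of
# its hosts: entry point = MRCA; every covered host node with both
# children covered is one failure to diverge, every covered node with
# an uncovered child one loss.
tip_expansion <- function(hidx, host_tips) {
  hs <- match(host_tips, hidx$labels)
  if (anyNA(hs)) {
    sym_stop("symbio_unknown_tip", "symbiont tip mapped to unknown host tip")
  }
  # mrca = deepest node ancestral to every associated host
  anc_all <- which(vapply(seq_len(hidx$N), function(v) all(hidx$desc[v, hs]),
                          logical(1L)))
  mrca <- anc_all[which.max(hidx$depth[anc_all])]
  # covered = nodes of the spanning subtree: below the mrca and above
  # (or equal to) at least one associated host tip
  covered <- which(hidx$desc[mrca, ] &
                     apply(hidx$desc[, hs, drop = FALSE], 1L, any))
  in_cov <- logical(hidx$N); in_cov[covered] <- TRUE
  ftd <- 0L; loss <- 0L
  ev_nodes_ftd <- integer(0); ev_nodes_loss <- integer(0)
  for (v in covered) {
    ch <- hidx$kids[[v]]
    if (!length(ch)) next
    cov_ch <- sum(in_cov[ch])
    if (cov_ch == 2L) { ftd <- ftd + 1L; ev_nodes_ftd <- c(ev_nodes_ftd, v) }
    else if (cov_ch == 1L) { loss <- loss + 1L; ev_nodes_loss <- c(ev_nodes_loss, v) }
  }
  list(mrca = mrca, ftd = ftd, loss = loss,
       ftd_nodes = ev_nodes_ftd, loss_nodes = ev_nodes_loss)
}

# symbiont-tree indexing (binary, rooted), postorder of internal nodes
symb_index <- function(symb) {
  n <- length(symb$tip.label)
  N <- n + symb$Nnode
  kids <- vector("list", N)
  for (e in seq_len(nrow(symb$edge))) {
    kids[[symb$edge[e, 1L]]] <- c(kids[[symb$edge[e, 1L]]], symb$edge[e, 2L])
  }
  if (any(lengths(kids[(n + 1L):N]) != 2L)) {
    sym_stop("symbio_not_binary", "symbiont tree must be binary (rooted)")
  }
  post <- integer(0)
  walk <- function(v) {
    for (w in kids[[v]]) walk(w)
    post <<- c(post, v)
  }
  walk(n + 1L)
  list(n = n, N = N, root = n + 1L, kids = kids, postorder = post,
       labels = symb$tip.label)
}

recon_inputs <- function(host, symb, assoc, scheme) {
  if (!ape::is.rooted(host) || !ape::is.rooted(symb)) {
    sym_stop("symbio_unrooted", "both trees must be rooted")
  }
  assoc <- as_association(assoc)
  if (!all(rownames(assoc) %in% host$tip.label)) {
    sym_stop("symbio_label_mismatch", "association hosts must be host-tree tips")
  }
  if (!setequal(colnames(assoc), symb$tip.label)) {
    sym_stop("symbio_label_mismatch",
             "association strains must match the symbiont-tree tips")
  }
  hidx <- host_index(host)
  sidx <- symb_index(symb)
  tips <- lapply(symb$tip.label, function(s) {
    hs <- rownames(assoc)[assoc[, s] == 1L]
    if (!length(hs)) {
      sym_stop("symbio_bad_association", paste("symbiont tip without host:", s))
    }
    tip_expansion(hidx, hs)
  })
  names(tips) <- symb$tip.label
  list(hidx = hidx, sidx = sidx, tips = tips, assoc = assoc,
       scheme = unclass(scheme)[EVENTS])
}

# ---------------------------------------------------------------- exact DP --
# E[p, h]: min cost of the symbiont subtree at p with p's event at host
# position h. D[p, h]: p's lineage enters at the edge above h and may
# sink lower, one loss per host node passed.
reconcile_exact <- function(ri) {
  hidx <- ri$hidx; sidx <- ri$sidx; sch <- ri$scheme
  HN <- hidx$N
  INF <- .Machine$double.xmax / 4
  E <- matrix(INF, sidx$N, HN)
  D <- matrix(INF, sidx$N, HN)
  # backpointers
  bp_event <- matrix("", sidx$N, HN)         # event chosen at E[p, h]
  bp_arg <- vector("list", sidx$N)           # per-node list of choice details
  for (p in seq_len(sidx$N)) bp_arg[[p]] <- vector("list", HN)
  sinkto <- matrix(NA_integer_, sidx$N, HN)  # D backpointer: final position

  host_post <- rev(hidx$preorder)
  best_incomp <- function(p) {
    vapply(seq_len(HN), function(h) {
      cand <- which(hidx$incomparable[h, ])
      if (!length(cand)) INF else min(D[p, cand])
    }, numeric(1L))
  }
  for (p in sidx$postorder) {
    if (p <= sidx$n) {
      te <- ri$tips[[sidx$labels[p]]]
      E[p, te$mrca] <- te$ftd * sch["failure_to_diverge"] + te$loss * sch["loss"]
      bp_event[p, te$mrca] <- "tip"
    } else {
      q1 <- sidx$kids[[p]][1L]; q2 <- sidx$kids[[p]][2L]
      bi1 <- best_incomp(q1); bi2 <- best_incomp(q2)
      for (h in seq_len(HN)) {
        best <- INF; ev <- ""; arg <- NULL
        if (h > hidx$n) {  # cospeciation at internal host node
          hl <- hidx$kids[[h]][1L]; hr <- hidx$kids[[h]][2L]
          v <- sch["cospeciation"] + D[q1, hl] + D[q2, hr]
          if (v < best) { best <- v; ev <- "cospeciation"; arg <- c(q1, hl, q2, hr) }
          v <- sch["cospeciation"] + D[q1, hr] + D[q2, hl]
          if (v < best) { best <- v; ev <- "cospeciation"; arg <- c(q1, hr, q2, hl) }
        }
        v <- sch["duplication"] + D[q1, h] + D[q2, h]
        if (v < best) { best <- v; ev <- "duplication"; arg <- c(q1, h, q2, h) }
        if (is.finite(bi2[h]) && bi2[h] < INF) {
          v <- sch["host_shift"] + D[q1, h] + bi2[h]
          if (v < best) {
            tgt <- which(hidx$incomparable[h, ])[which.min(D[q2, hidx$incomparable[h, ]])]
            best <- v; ev <- "host_shift"; arg <- c(q1, h, q2, tgt)
          }
        }
        if (is.finite(bi1[h]) && bi1[h] < INF) {
          v <- sch["host_shift"] + D[q2, h] + bi1[h]
          if (v < best) {
            tgt <- which(hidx$incomparable[h, ])[which.min(D[q1, hidx$incomparable[h, ]])]
            best <- v; ev <- "host_shift"; arg <- c(q2, h, q1, tgt)
          }
        }
        E[p, h] <- best; bp_event[p, h] <- ev; bp_arg[[p]][[h]] <- arg
      }
    }
    # D[p, ]: sink with losses, bottom-up over host nodes
    for (h in host_post) {
      best <- E[p, h]; to <- h
      for (c in hidx$kids[[h]]) {
        v <- sch["loss"] + D[p, c]
        if (v < best) { best <- v; to <- sinkto[p, c] }
      }
      D[p, h] <- best; sinkto[p, h] <- to
    }
  }
  hstar <- which.min(D[sidx$root, ])
  cost <- D[sidx$root, hstar]
  # --- backtrace ---
  events <- list()
  counts <- setNames(integer(5L), EVENTS)
  add <- function(type, p, h) {
    events[[length(events) + 1L]] <<- data.frame(
      type = type, symbiont_node = p, host_node = h, stringsAsFactors = FALSE)
    counts[type] <<- counts[type] + 1L
  }
  placement <- integer(sidx$N)
  place <- function(p, h_entry) {
    h <- sinkto[p, h_entry]
    # loss chain from h_entry down to h
    v <- h_entry
    while (v != h) {
      ch <- hidx$kids[[v]]
      add("loss", p, v)
      v <- if (hidx$desc[ch[1L], h]) ch[1L] else ch[2L]
    }
    placement[p] <<- h
    if (p <= sidx$n) {
      te <- ri$tips[[sidx$labels[p]]]
      for (x in te$ftd_nodes) add("failure_to_diverge", p, x)
      for (x in te$loss_nodes) add("loss", p, x)
      return(invisible())
    }
    ev <- bp_event[p, h]; arg <- bp_arg[[p]][[h]]
    add(ev, p, h)
    place(arg[1L], arg[2L])
    place(arg[3L], arg[4L])
  }
  place(sidx$root, hstar)
  events <- do.call(rbind, events)
  stopifnot(abs(sum(counts[EVENTS] * sch[EVENTS]) - cost) < 1e-9)
  list(cost = cost, counts = counts, events = events, placement = placement)
}

#' Reconcile a symbiont tree with its host tree
#'
#' Finds a least-cost embedding of the symbiont tree into the host
#' tree under the five-event model: cospeciation (symbiont divergence
#' at a host speciation), duplication (within-host divergence),
#' duplication with host shift (one daughter jumps to a host edge
#' neither ancestral nor descendant of the source), loss (the
#' symbiont misses one daughter at a host speciation), and failure to
#' diverge (the host speciates while one symbiont lineage persists in
#' both daughters; it arises from symbiont tips associated with
#' several hosts, whose lineage covers the spanning host subtree).
#'
#' `mode = "exact"` runs dynamic programming over (symbiont node,
#' host position) and is provably minimal under this (untimed) event
#' model. `mode = "heuristic"` runs a population-based search over
#' placement vectors (uniform crossover, per-gene mutation, 10%
#' elitism) and returns the best candidate found, never better but
#' possibly worse than the exact optimum; use it when the trees are
#' too large for comfort with the DP's quadratic host-position sweep.
#'
#' @param host,symb rooted binary `phylo` trees.
#' @param assoc host x strain association matrix; every symbiont tip
#'   needs at least one host.
#' @param scheme a [cost_scheme()].
#' @param mode `"exact"` (default) or `"heuristic"`.
#' @param generations,population search parameters for the heuristic
#'   (defaults 100 and 300).
#' @param seed integer seed (heuristic mode).
#' @return A `reconciliation`: list with `cost`, `counts` (per event
#'   type), `events` (data frame: type, symbiont node, host node),
#'   `placement` (symbiont node -> host node), `optimal` (TRUE for
#'   exact mode), `scheme`.
#' @export
reconcile <- function(host, symb, assoc, scheme = cost_scheme(),
                      mode = c("exact", "heuristic"),
                      generations = 100, population = 300, seed = NULL) {
  mode <- match.arg(mode)
  if (length(symb$tip.label) == 1L) {
    # a single symbiont lineage: the reconciliation is its expansion
    if (!ape::is.rooted(host)) sym_stop("symbio_unrooted", "host tree must be rooted")
    assoc <- as_association(assoc)
    hidx <- host_index(host)
    hs <- rownames(assoc)[assoc[, symb$tip.label] == 1L]
    te <- tip_expansion(hidx, hs)
    sch <- unclass(scheme)[EVENTS]
    counts <- setNames(c(0L, 0L, 0L, te$loss, te$ftd), EVENTS)
    events <- rbind(
      if (te$ftd) data.frame(type = "failure_to_diverge", symbiont_node = 1L,
                             host_node = te$ftd_nodes),
      if (te$loss) data.frame(type = "loss", symbiont_node = 1L,
                              host_node = te$loss_nodes))
    return(structure(list(
      cost = unname(sum(counts * sch)), counts = counts,
      events = events %||% data.frame(type = character(0),
                                      symbiont_node = integer(0),
                                      host_node = integer(0)),
      placement = te$mrca, optimal = TRUE, scheme = scheme, mode = mode),
      class = "reconciliation"))
  }
  ri <- recon_inputs(host, symb, assoc, scheme)
  res <- if (mode == "exact") reconcile_exact(ri)
         else reconcile_ga(ri, generations, population, seed)
  structure(c(res, list(optimal = mode == "exact", scheme = scheme,
                        mode = mode)),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("Reconciliation (%s%s): total cost %g\n", x$mode,
              if (x$optimal) ", optimal" else "", x$cost))
  for (e in EVENTS) cat(sprintf("  %-19s %d\n", e, x$counts[[e]]))
  invisible(x)
}

#' Random tip mapping significance test
#'
#' Re-draws the host-symbiont association `n_iter` times (each
#' symbiont keeps its number of hosts; hosts are redrawn uniformly
#' without replacement), reconciles each randomized association, and
#' reports the fraction of randomizations with cost strictly lower
#' than the observed reconciliation. A fraction at or below 0.05 is
#' conventionally read as support for cospeciation.
#'
#' @inheritParams reconcile
#' @param n_iter number of randomizations (default 50).
#' @param seed integer seed.
#' @param ... passed on to [reconcile()].
#' @return List with `fraction`, `observed_cost`, `random_costs`,
#'   `n_iter`, `supported` (fraction <= 0.05).
#' @export
random_tip_mapping_test <- function(host, symb, assoc, scheme = cost_scheme(),
                                    n_iter = 50, seed = NULL,
                                    mode = "exact", ...) {
  assoc <- as_association(assoc)
  obs <- reconcile(host, symb, assoc, scheme, mode = mode, ...)
  if (!is.null(seed)) set.seed(seed)
  hosts <- rownames(assoc)
  costs <- vapply(seq_len(n_iter), function(it) {
    Ar <- matrix(0L, nrow(assoc), ncol(assoc), dimnames = dimnames(assoc))
    for (j in seq_len(ncol(assoc))) {
      k <- sum(assoc[, j])
      Ar[sample(seq_along(hosts), k), j] <- 1L
    }
    reconcile(host, symb, Ar, scheme, mode = mode, ...)$cost
  }, numeric(1L))
  fraction <- mean(costs < obs$cost)
  list(fraction = fraction, observed_cost = obs$cost, random_costs = costs,
       n_iter = n_iter, supported = fraction <= 0.05)
}
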