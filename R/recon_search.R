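# ---- placement decoder -----------------------------------------------------
# A candidate solution assigns every internal symbiont node a host
# position (tips are pinned to the MRCA of their hosts). The decoder
# returns the cheapest event reading consistent with the placement:
# children on opposite strict sides of an internal host node may be
# read as cospeciation or duplication (the cheaper wins), children
# inside the subtree as duplication, one inside + one incomparable as
# a host shift. A child placed on an ancestor of its parent's
# position, or both children incomparable, is infeasible.
RECON_INFEASIBLE <- 1e9

decode_placement <- function(ri, pos, detail = FALSE) {
  hidx <- ri$hidx; sidx <- ri$sidx; sch <- ri$scheme
  cost <- 0
  counts <- setNames(integer(5L), EVENTS)
  events <- if (detail) list() else NULL
  add <- function(type, p, h, times = 1L) {
    counts[type] <<- counts[type] + times
    if (detail && times > 0L) {
      events[[length(events) + 1L]] <<- data.frame(
        type = rep(type, times), symbiont_node = p, host_node = h,
        stringsAsFactors = FALSE)
    }
  }
  for (s in seq_len(sidx$n)) {
    te <- ri$tips[[sidx$labels[s]]]
    add("failure_to_diverge", s, te$mrca, te$ftd)
    add("loss", s, te$mrca, te$loss)
    cost <- cost + te$ftd * sch["failure_to_diverge"] + te$loss * sch["loss"]
  }
  for (p in rev(sidx$postorder)) {
    if (p <= sidx$n) next
    hp <- pos[p]
    ch <- sidx$kids[[p]]
    hc <- pos[ch]
    inside <- hidx$desc[hp, hc]
    incomp <- hidx$incomparable[hp, hc]
    if (any(!inside & !incomp)) return(list(cost = RECON_INFEASIBLE))
    if (all(inside)) {
      dup <- sch["duplication"] +
        sch["loss"] * (hidx$edgedist[hp, hc[1L]] + hidx$edgedist[hp, hc[2L]])
      best <- dup; ev <- "duplication"; nloss <- hidx$edgedist[hp, hc[1L]] +
        hidx$edgedist[hp, hc[2L]]
      if (hp > hidx$n) {
        hl <- hidx$kids[[hp]][1L]; hr <- hidx$kids[[hp]][2L]
        for (sw in 1:2) {
          a <- hc[sw]; b <- hc[3L - sw]
          if (hidx$desc[hl, a] && hidx$desc[hr, b]) {
            nl <- hidx$edgedist[hl, a] + hidx$edgedist[hr, b]
            v <- sch["cospeciation"] + sch["loss"] * nl
            if (v < best) { best <- v; ev <- "cospeciation"; nloss <- nl }
          }
        }
      }
      cost <- cost + best
      add(ev, p, hp); add("loss", p, hp, as.integer(nloss))
    } else if (sum(inside) == 1L) {
      stay <- which(inside)
      nl <- hidx$edgedist[hp, hc[stay]]
      cost <- cost + sch["host_shift"] + sch["loss"] * nl
      add("host_shift", p, hp); add("loss", p, hp, as.integer(nl))
    } else {
      return(list(cost = RECON_INFEASIBLE))
    }
  }
  out <- list(cost = unname(cost), counts = counts)
  if (detail) {
    out$events <- if (length(events)) do.call(rbind, events) else
      data.frame(type = character(0), symbiont_node = integer(0),
                 host_node = integer(0))
    out$placement <- pos
  }
  out
}

# greedy seed: every internal node at the host MRCA of the hosts used
# below it
seed_placement <- function(ri) {
  hidx <- ri$hidx; sidx <- ri$sidx
  pos <- integer(sidx$N)
  hostset <- vector("list", sidx$N)
  for (p in sidx$postorder) {
    if (p <= sidx$n) {
      te <- ri$tips[[sidx$labels[p]]]
      pos[p] <- te$mrca
      hostset[[p]] <- which(hidx$desc[te$mrca, ] &
                              seq_len(hidx$N) <= hidx$n)
    } else {
      hs <- unique(c(hostset[[sidx$kids[[p]][1L]]],
                     hostset[[sidx$kids[[p]][2L]]]))
      anc <- which(vapply(seq_len(hidx$N), function(v) all(hidx$desc[v, hs]),
                          logical(1L)))
      pos[p] <- anc[which.max(hidx$depth[anc])]
      hostset[[p]] <- hs
    }
  }
  pos
}

# population-based search over placement vectors: 10% elitism,
# tournament selection, uniform crossover, per-gene mutation
reconcile_ga <- function(ri, generations = 100, population = 300,
                         seed = NULL, mutation_rate = 0.2) {
  if (!is.null(seed)) set.seed(seed)
  sidx <- ri$sidx; hidx <- ri$hidx
  internal <- which(seq_len(sidx$N) > sidx$n)
  ng <- length(internal)
  base <- seed_placement(ri)
  pop <- matrix(sample.int(hidx$N, population * ng, replace = TRUE),
                population, ng)
  pop[1L, ] <- base[internal]
  fitness <- function(row) {
    pos <- base
    pos[internal] <- row
    decode_placement(ri, pos)$cost
  }
  fit <- apply(pop, 1L, fitness)
  n_elite <- max(1L, floor(population / 10))
  for (g in seq_len(generations)) {
    ord <- order(fit)
    pop <- pop[ord, , drop = FALSE]; fit <- fit[ord]
    nxt <- pop
    for (i in (n_elite + 1L):population) {
      p1 <- pop[min(sample.int(population, 2L)), ]
      p2 <- pop[min(sample.int(population, 2L)), ]
      child <- ifelse(runif(ng) < 0.5, p1, p2)
      mut <- runif(ng) < mutation_rate
      child[mut] <- sample.int(hidx$N, sum(mut), replace = TRUE)
      nxt[i, ] <- child
    }
    changed <- (n_elite + 1L):population
    pop <- nxt
    fit[changed] <- apply(pop[changed, , drop = FALSE], 1L, fitness)
  }
  best <- which.min(fit)
  pos <- base
  pos[internal] <- pop[best, ]
  out <- decode_placement(ri, pos, detail = TRUE)
  list(cost = out$cost, counts = out$counts, events = out$events,
       placement = out$placement)
}
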