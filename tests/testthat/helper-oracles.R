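# Independent oracles used to cross-check the package implementations.
# They share no code with the functions under test.

# scalar K2P closed form from transition/transversion proportions
oracle_k2p <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)

# mean pairwise patristic distance by explicit double loop
oracle_ps <- function(D, hosts) {
  tot <- 0; np <- 0
  for (i in seq_along(hosts)) {
    for (j in seq_along(hosts)) {
      if (j > i) { tot <- tot + D[hosts[i], hosts[j]]; np <- np + 1 }
    }
  }
  tot / np
}

# Cochran's Q by direct evaluation of the defining formula
oracle_cochran_q <- function(m) {
  k <- ncol(m)
  C <- colSums(m); R <- rowSums(m)
  (k - 1) * (k * sum(C^2) - sum(C)^2) / (k * sum(R) - sum(R^2))
}

# ParaFit global statistic by brute-force quadruple summation
oracle_parafit_stat <- function(A, B, C) {
  tot <- 0
  for (a in seq_len(ncol(C))) {
    for (b in seq_len(ncol(B))) {
      s <- 0
      for (i in seq_len(nrow(A))) {
        for (j in seq_len(ncol(A))) {
          s <- s + C[i, a] * A[i, j] * B[j, b]
        }
      }
      tot <- tot + s^2
    }
  }
  tot
}

# ------------------------------------------------------------------
# Brute-force reconciliation: enumerate EVERY placement of the
# internal symbiont nodes on host nodes and take the cheapest legal
# event reading. No dynamic programming, no code shared with
# reconcile().
# costs: cospeciation, duplication, host shift, loss, failure to diverge
oracle_recon_min_cost <- function(host, symb, assoc,
                                  costs = c(0, 1, 2, 1, 1)) {
  nH <- length(host$tip.label); NH <- nH + host$Nnode
  anc <- phangorn::Ancestors(host, seq_len(NH), "all")
  depth <- lengths(anc)
  desc <- matrix(FALSE, NH, NH)  # desc[a, b]: a is ancestor-or-self of b
  for (b in seq_len(NH)) desc[c(b, anc[[b]]), b] <- TRUE
  kidsH <- lapply(seq_len(NH), function(v) host$edge[host$edge[, 1] == v, 2])
  ed <- outer(depth, depth, function(a, b) b - a)

  tipinfo <- function(hs) {
    cand <- which(apply(desc[, hs, drop = FALSE], 1, all))
    m <- cand[which.max(depth[cand])]
    cov <- which(desc[m, ] & apply(desc[, hs, drop = FALSE], 1, any))
    ftd <- 0; loss <- 0
    for (v in cov) {
      k <- kidsH[[v]]
      if (!length(k)) next
      cc <- sum(k %in% cov)
      if (cc == 2) ftd <- ftd + 1 else if (cc == 1) loss <- loss + 1
    }
    list(pos = m, cost = ftd * costs[5] + loss * costs[4])
  }

  nS <- length(symb$tip.label); NS <- nS + symb$Nnode
  kidsS <- lapply(seq_len(NS), function(v) symb$edge[symb$edge[, 1] == v, 2])
  tinfo <- lapply(symb$tip.label, function(s) {
    hs <- match(rownames(assoc)[assoc[, s] == 1], host$tip.label)
    tipinfo(hs)
  })
  base_cost <- sum(vapply(tinfo, `[[`, numeric(1), "cost"))
  tip_pos <- vapply(tinfo, `[[`, numeric(1), "pos")
  if (nS == 1) return(base_cost)

  # event cost of an internal symbiont node at hp with children at h1, h2
  EC <- array(Inf, c(NH, NH, NH))
  for (hp in seq_len(NH)) {
    k <- kidsH[[hp]]
    for (h1 in seq_len(NH)) {
      for (h2 in seq_len(NH)) {
        in1 <- desc[hp, h1]; in2 <- desc[hp, h2]
        val <- Inf
        if (in1 && in2) {
          val <- costs[2] + costs[4] * (ed[hp, h1] + ed[hp, h2])
          if (length(k) == 2) {
            if (desc[k[1], h1] && desc[k[2], h2])
              val <- min(val, costs[1] + costs[4] * (ed[k[1], h1] + ed[k[2], h2]))
            if (desc[k[1], h2] && desc[k[2], h1])
              val <- min(val, costs[1] + costs[4] * (ed[k[1], h2] + ed[k[2], h1]))
          }
        } else if (in1 && !desc[h2, hp]) {
          val <- costs[3] + costs[4] * ed[hp, h1]
        } else if (in2 && !desc[h1, hp]) {
          val <- costs[3] + costs[4] * ed[hp, h2]
        }
        EC[hp, h1, h2] <- val
      }
    }
  }

  internal <- (nS + 1):NS
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(NH)), length(internal))))
  pos <- matrix(0L, nrow(grid), NS)
  pos[, seq_len(nS)] <- matrix(tip_pos, nrow(grid), nS, byrow = TRUE)
  pos[, internal] <- grid
  total <- rep(base_cost, nrow(grid))
  for (p in internal) {
    c1 <- kidsS[[p]][1]; c2 <- kidsS[[p]][2]
    total <- total + EC[cbind(pos[, p], pos[, c1], pos[, c2])]
  }
  min(total)
}
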