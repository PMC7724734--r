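#' Simulate a joint host-symbiont history
#'
#' Grows a host tree under a Yule (pure-birth) process and tracks
#' symbiont lineages along it. A symbiont lineage occupies one or
#' more host lineages. At every host speciation, each resident
#' symbiont lineage independently draws one of three fates with the
#' normalized `cospeciation` / `loss` / `failure_to_diverge` rates:
#' cospeciate (the lineage diverges, one daughter per host daughter),
#' loss (it follows one daughter, chosen uniformly), or failure to
#' diverge (it persists undivided in both daughters). After each
#' speciation, every symbiont lineage independently duplicates within
#' one of its hosts with probability `duplication`, and founds a copy
#' on a uniformly chosen other currently-living host lineage with
#' probability `host_shift` (a duplication with host shift; targets
#' are contemporaneous, hence never ancestors or descendants of the
#' source). Symbiont extinction can only arise through loss, and a
#' lineage always retains at least one host here, so realizations
#' never go extinct; the retry cap guards degenerate inputs.
#'
#' Default rates mirror the regime reported for mosquito-*Wolbachia*
#' systems: losses and host shifts common, cospeciation rare.
#'
#' @param n_host_tips number of extant host species (>= 2).
#' @param rates named vector/list of the five per-opportunity
#'   probabilities; `cospeciation`, `loss`, `failure_to_diverge` are
#'   normalized to a categorical draw, `duplication` and `host_shift`
#'   are independent per-interval probabilities.
#' @param seed integer seed.
#' @return A `cophylogeny_sim` list: `host` (phylo, tips `H1..`),
#'   `symb` (phylo, tips `S1..`), `assoc` (hosts x symbionts binary),
#'   `events` (data frame log: time, type, symbiont lineage, host
#'   lineage), `counts` (per event type), `rates`, `seed`.
#' @export
simulate_cophylogeny <- function(n_host_tips,
                                 rates = c(cospeciation = 0.2,
                                           duplication = 0.05,
                                           host_shift = 0.25,
                                           loss = 0.6,
                                           failure_to_diverge = 0.2),
                                 seed = NULL) {
  stopifnot(n_host_tips >= 2)
  rates <- unlist(rates)[EVENTS]
  names(rates) <- EVENTS
  if (anyNA(rates) || any(rates < 0) ||
      any(rates[c("duplication", "host_shift")] > 1)) {
    sym_stop("symbio_bad_rates", "rates must be probabilities named by event type")
  }
  trio <- rates[c("cospeciation", "loss", "failure_to_diverge")]
  if (sum(trio) <= 0) {
    sym_stop("symbio_bad_rates",
             "cospeciation + loss + failure_to_diverge must sum > 0")
  }
  trio <- trio / sum(trio)
  if (!is.null(seed)) set.seed(seed)

  # host lineages: parent, birth time, children (0 or 2)
  h_parent <- NA_integer_; h_birth <- 0; h_kids <- list(integer(0))
  alive_h <- 1L
  t_now <- 0
  spec_log <- list()
  while (length(alive_h) < n_host_tips) {
    t_now <- t_now + rexp(1L, rate = length(alive_h))
    splitting <- if (length(alive_h) == 1L) alive_h else sample(alive_h, 1L)
    k1 <- length(h_parent) + 1L; k2 <- k1 + 1L
    h_parent[c(k1, k2)] <- splitting
    h_birth[c(k1, k2)] <- t_now
    h_kids[[splitting]] <- c(k1, k2)
    h_kids[[k1]] <- h_kids[[k2]] <- integer(0)
    alive_h <- c(setdiff(alive_h, splitting), k1, k2)
    spec_log[[length(spec_log) + 1L]] <- list(time = t_now, host = splitting,
                                              kids = c(k1, k2))
  }
  t_end <- t_now + rexp(1L, rate = length(alive_h))

  # symbiont lineages: parent, birth, children; residency: lineage -> hosts
  s_parent <- NA_integer_; s_birth <- 0; s_kids <- list(integer(0))
  residency <- list(`1` = 1L)
  events <- list()
  counts <- setNames(integer(5L), EVENTS)
  log_event <- function(type, time, symb, host) {
    events[[length(events) + 1L]] <<- data.frame(
      time = time, type = type, symbiont = symb, host = host,
      stringsAsFactors = FALSE)
    counts[type] <<- counts[type] + 1L
  }
  diverge <- function(sid, time) {  # returns the two child ids
    c1 <- length(s_parent) + 1L; c2 <- c1 + 1L
    s_parent[c(c1, c2)] <<- sid
    s_birth[c(c1, c2)] <<- time
    s_kids[[sid]] <<- c(c1, c2)
    s_kids[[c1]] <<- s_kids[[c2]] <<- integer(0)
    c(c1, c2)
  }
  alive_hosts <- 1L
  for (ev in spec_log) {
    h <- ev$host; hk <- ev$kids; tm <- ev$time
    alive_hosts <- c(setdiff(alive_hosts, h), hk)
    residents <- names(residency)[vapply(residency, function(r) h %in% r,
                                         logical(1L))]
    for (sid in residents) {
      fate <- sample(names(trio), 1L, prob = trio)
      other <- setdiff(residency[[sid]], h)
      id <- as.integer(sid)
      if (fate == "cospeciation") {
        ch <- diverge(id, tm)
        residency[[as.character(ch[1L])]] <- c(other, hk[1L])
        residency[[as.character(ch[2L])]] <- hk[2L]
        residency[[sid]] <- NULL
        log_event("cospeciation", tm, id, h)
      } else if (fate == "loss") {
        residency[[sid]] <- c(other, sample(hk, 1L))
        log_event("loss", tm, id, h)
      } else {
        residency[[sid]] <- c(other, hk)
        log_event("failure_to_diverge", tm, id, h)
      }
    }
    # duplication / host-shift opportunities in this interval
    current_hosts <- alive_hosts
    for (sid in names(residency)) {
      if (runif(1L) < rates[["duplication"]]) {
        inhost <- if (length(residency[[sid]]) == 1L) residency[[sid]] else
          sample(residency[[sid]], 1L)
        ch <- diverge(as.integer(sid), tm)
        residency[[as.character(ch[1L])]] <- residency[[sid]]
        residency[[as.character(ch[2L])]] <- inhost
        residency[[sid]] <- NULL
        log_event("duplication", tm, s_parent[ch[1L]], inhost)
        sid <- as.character(ch[1L])
      }
      targets <- setdiff(current_hosts, residency[[sid]])
      if (length(targets) && runif(1L) < rates[["host_shift"]]) {
        target <- if (length(targets) == 1L) targets else sample(targets, 1L)
        ch <- diverge(as.integer(sid), tm)
        residency[[as.character(ch[1L])]] <- residency[[sid]]
        residency[[as.character(ch[2L])]] <- target
        residency[[sid]] <- NULL
        log_event("host_shift", tm, s_parent[ch[1L]], target)
      }
    }
  }

  host_tip_ids <- which(lengths(h_kids) == 0L)
  host <- assemble_phylo(h_parent, h_birth, h_kids, t_end, "H")
  symb <- assemble_phylo(s_parent, s_birth, s_kids, t_end, "S")
  symb_tip_ids <- which(lengths(s_kids) == 0L)
  assoc <- matrix(0L, length(host_tip_ids), length(symb_tip_ids),
                  dimnames = list(paste0("H", seq_along(host_tip_ids)),
                                  paste0("S", seq_along(symb_tip_ids))))
  for (j in seq_along(symb_tip_ids)) {
    hs <- residency[[as.character(symb_tip_ids[j])]]
    assoc[match(hs, host_tip_ids), j] <- 1L
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(0), type = character(0), symbiont = integer(0),
               host = integer(0))
  structure(list(host = host, symb = symb, assoc = assoc, events = events,
                 counts = counts, rates = rates, seed = seed),
            class = "cophylogeny_sim")
}

#' @export
print.cophylogeny_sim <- function(x, ...) {
  cat(sprintf("Cophylogeny simulation: %d hosts, %d symbionts, %d links\n",
              length(x$host$tip.label),
              if (is.null(x$symb)) 1L else length(x$symb$tip.label),
              sum(x$assoc)))
  cat("True event counts:",
      paste(sprintf("%s=%d", EVENTS, x$counts[EVENTS]), collapse = ", "), "\n")
  invisible(x)
}

# Assemble a phylo from birth-death-free lineage records: childless
# lineages are extant tips (named prefix1, prefix2, ... in id order),
# a lineage with children diverged when they were born.
assemble_phylo <- function(parent, birth, kids, t_end, prefix) {
  tip_ids <- which(lengths(kids) == 0L)
  tip_name <- setNames(paste0(prefix, seq_along(tip_ids)), tip_ids)
  build <- function(id) {
    if (!length(kids[[id]])) {
      return(sprintf("%s:%.10g", tip_name[[as.character(id)]],
                     t_end - birth[id]))
    }
    ch <- kids[[id]]
    sprintf("(%s,%s):%.10g", build(ch[1L]), build(ch[2L]),
            birth[ch[1L]] - birth[id])
  }
  root <- which(is.na(parent))[1L]
  txt <- if (!length(kids[[root]])) {
    sprintf("(%s:%.10g);", tip_name[[as.character(root)]], t_end)
  } else {
    inner <- build(root)
    paste0(sub(":[0-9.eE+-]+$", "", inner), ";")
  }
  ape::read.tree(text = txt)
}

#' Evolve sequences along a tree under the two-parameter model
#'
#' The root sequence is uniform over \{A, C, G, T\}; each site evolves
#' independently along every branch under the Kimura two-parameter
#' rate matrix with instantaneous transition rate `transition_rate`
#' and per-target transversion rate `transversion_rate`. With the
#' default rates (0.5, 0.25) the total substitution rate is 1, so
#' branch lengths are expected substitutions per site and the K2P
#' distance between two tips estimates their patristic distance.
#'
#' @param tree `phylo` with branch lengths.
#' @param n_sites number of sites (> 0).
#' @param transition_rate instantaneous rate of transitions (alpha).
#' @param transversion_rate instantaneous rate of each of the two
#'   transversions (beta); total rate is `alpha + 2 beta`.
#' @param seed integer seed.
#' @return A [alignment()] with one sequence per tip.
#' @export
simulate_sequences <- function(tree, n_sites, transition_rate = 0.5,
                               transversion_rate = 0.25, seed = NULL) {
  if (n_sites < 1L) sym_stop("symbio_bad_value", "n_sites must be positive")
  if (is.null(tree$edge.length)) {
    sym_stop("symbio_no_lengths", "tree needs branch lengths")
  }
  if (!is.null(seed)) set.seed(seed)
  a <- transition_rate; b <- transversion_rate
  bases <- c("A", "G", "C", "T")
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_partners <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))
  evolve <- function(seq, t) {
    # K2P transition probabilities after time t
    e1 <- exp(-4 * b * t); e2 <- exp(-2 * (a + b) * t)
    p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
    p_tv <- 0.25 - 0.25 * e1          # each of the two transversions
    u <- runif(length(seq))
    out <- seq
    to_ts <- u < p_ts
    to_tv1 <- !to_ts & u < p_ts + p_tv
    to_tv2 <- !to_ts & !to_tv1 & u < p_ts + 2 * p_tv
    out[to_ts] <- ts_partner[seq[to_ts]]
    for (bb in bases) {
      i1 <- to_tv1 & seq == bb
      i2 <- to_tv2 & seq == bb
      out[i1] <- tv_partners[[bb]][1L]
      out[i2] <- tv_partners[[bb]][2L]
    }
    out
  }
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  seqs <- vector("list", N)
  root <- n + 1L
  seqs[[root]] <- sample(bases, n_sites, replace = TRUE)
  preord <- integer(0)
  stack <- root
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (e in kids[[as.character(v)]]) {
      preord <- c(preord, e)
      stack <- c(stack, tree$edge[e, 2L])
    }
  }
  for (e in preord) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    seqs[[ch]] <- evolve(seqs[[p]], tree$edge.length[e])
  }
  mat <- do.call(rbind, seqs[seq_len(n)])
  rownames(mat) <- tree$tip.label
  alignment(mat)
}

#' Parameters for the specimen-table simulator
#'
#' Defaults emulate a tropical mosquito screening survey: 40 species
#' of about 7 individuals each, roughly half the species uninfected,
#' species-level prevalence of the infected ones spread over
#' (0.15, 1), a male/female infection odds ratio of 0.434, tissue
#' positivity given infection of 0.95 / 0.12 / 0.07
#' (reproductive / gut / leg), a 10% internal-control failure rate
#' and 12 collection localities.
#'
#' @param species species names.
#' @param n_per_species integer vector (recycled) of sample sizes.
#' @param prevalence per-species infection probability (recycled).
#' @param sex_or male-versus-female odds ratio on infection (> 0).
#' @param tissue_probs named vector: P(tissue positive | infected)
#'   for `reproductive`, `gut`, `leg`.
#' @param control_fail_rate probability the internal control fails.
#' @param localities locality codes sampled uniformly per specimen.
#' @return List of class `specimen_sim_params`.
#' @export
specimen_sim_params <- function(species = sprintf("Species_%02d", 1:40),
                                n_per_species = 7L,
                                prevalence = NULL,
                                sex_or = 0.434,
                                tissue_probs = c(reproductive = 0.95,
                                                 gut = 0.12, leg = 0.07),
                                control_fail_rate = 0.1,
                                localities = sprintf("L%02d", 1:12)) {
  if (is.null(prevalence)) {
    k <- length(species)
    prevalence <- rep(0, k)
    infected <- seq_len(k) %% 2L == 1L  # every other species infected
    prevalence[infected] <- seq(0.15, 1, length.out = sum(infected))
  }
  stopifnot(sex_or > 0, all(prevalence >= 0 & prevalence <= 1),
            all(tissue_probs >= 0 & tissue_probs <= 1),
            control_fail_rate >= 0 && control_fail_rate <= 1)
  structure(list(species = species,
                 n_per_species = rep_len(n_per_species, length(species)),
                 prevalence = rep_len(prevalence, length(species)),
                 sex_or = sex_or,
                 tissue_probs = tissue_probs[c("reproductive", "gut", "leg")],
                 control_fail_rate = control_fail_rate,
                 localities = localities),
            class = "specimen_sim_params")
}

#' Simulate a specimen screening table
#'
#' Per specimen: sex is Bernoulli(1/2); infection is Bernoulli with
#' log-odds `logit(prevalence) + 1[male] * log(OR)`; tissue calls are
#' drawn independently given infection (uninfected specimens are
#' negative in every tissue); internal-control failures are injected
#' at the stated rate. The overall call is positive iff any tissue
#' is, so the realized prevalence is slightly below the latent one
#' (imperfect tissue-level detection).
#'
#' @param params a [specimen_sim_params()] list.
#' @param seed integer seed.
#' @return A `specimen_table` (see [as_specimen_table()]).
#' @export
simulate_specimens <- function(params = specimen_sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  rows <- list()
  id <- 0L
  for (s in seq_along(p$species)) {
    n <- p$n_per_species[s]
    lo <- qlogis(p$prevalence[s])
    for (i in seq_len(n)) {
      id <- id + 1L
      male <- runif(1L) < 0.5
      pr <- plogis(lo + as.numeric(male) * log(p$sex_or))
      infected <- runif(1L) < pr
      calls <- if (infected) {
        ifelse(runif(3L) < p$tissue_probs, "positive", "negative")
      } else rep("negative", 3L)
      rows[[id]] <- data.frame(
        specimen_id = sprintf("SP%05d", id),
        species = p$species[s],
        locality = sample(p$localities, 1L),
        sex = if (male) "M" else "F",
        reproductive = calls[1L], gut = calls[2L], leg = calls[3L],
        control_pass = runif(1L) >= p$control_fail_rate,
        stringsAsFactors = FALSE)
    }
  }
  as_specimen_table(do.call(rbind, rows))
}
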