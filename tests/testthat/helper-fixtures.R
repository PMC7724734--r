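# fixture builders shared across test files

# random rooted host/symbiont instance for reconciliation tests
rand_recon_instance <- function(seed, max_hosts = 5, max_symb = 5,
                                multi_host_prob = 0.3) {
  set.seed(seed)
  nh <- sample(3:max_hosts, 1)
  ns <- sample(2:max_symb, 1)
  host <- ape::rtree(nh, rooted = TRUE)
  host$tip.label <- paste0("H", seq_len(nh))
  symb <- ape::rtree(ns, rooted = TRUE)
  symb$tip.label <- paste0("S", seq_len(ns))
  assoc <- matrix(0L, nh, ns,
                  dimnames = list(host$tip.label, symb$tip.label))
  for (j in seq_len(ns)) {
    k <- if (runif(1) < multi_host_prob) min(2L, nh) else 1L
    assoc[sample(nh, k), j] <- 1L
  }
  list(host = host, symb = symb, assoc = assoc)
}

# random tree whose node labels are random bootstrap percentages
rand_supported_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = TRUE)
  tr$node.label <- as.character(sample(0:100, tr$Nnode, replace = TRUE) / 100)
  tr
}

# small specimen table built by hand
tiny_specimens <- function() {
  as_specimen_table(data.frame(
    specimen_id = paste0("SP", 1:6),
    species = c("A", "A", "A", "B", "B", "B"),
    locality = "L1",
    sex = c("F", "M", "F", "M", "F", "M"),
    leg = c("negative", "negative", "positive", "negative", "negative", "negative"),
    gut = c("negative", "positive", "negative", "negative", "negative", "negative"),
    reproductive = c("positive", "positive", "negative", "negative", "positive", "negative"),
    control_pass = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  ))
}
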