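test_that("pure cospeciation gives isomorphic trees and identity links", {
  s <- simulate_cophylogeny(6, rates = c(cospeciation = 1, duplication = 0,
                                         host_shift = 0, loss = 0,
                                         failure_to_diverge = 0), seed = 11)
  st <- s$symb; st$tip.label <- sub("S", "H", st$tip.label)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(st), ape::unroot(s$host))), 0)
  expect_true(all(s$assoc == diag(nrow(s$assoc))))
  expect_equal(unname(s$counts["cospeciation"]), s$host$Nnode)
})

test_that("loss-only histories collapse to a single symbiont tip", {
  s <- simulate_cophylogeny(5, rates = c(cospeciation = 0, duplication = 0,
                                         host_shift = 0, loss = 1,
                                         failure_to_diverge = 0), seed = 3)
  expect_equal(length(s$symb$tip.label), 1L)
  expect_equal(sum(s$assoc), 1L)
})

test_that("the same seed reproduces trees, associations and logs", {
  s1 <- simulate_cophylogeny(7, seed = 99)
  s2 <- simulate_cophylogeny(7, seed = 99)
  expect_equal(write_newick(s1$host), write_newick(s2$host))
  expect_equal(write_newick(s1$symb), write_newick(s2$symb))
  expect_equal(s1$assoc, s2$assoc)
  expect_equal(s1$events, s2$events)
})

test_that("the event log is internally consistent", {
  for (seed in 1:5) {
    s <- simulate_cophylogeny(6, seed = seed)
    tab <- table(factor(s$events$type, levels = names(s$counts)))
    expect_equal(as.integer(tab), unname(s$counts))
    # association columns match surviving symbiont tips
    expect_setequal(colnames(s$assoc), s$symb$tip.label)
    expect_true(all(colSums(s$assoc) >= 1))
  }
})

test_that("sequence evolution is seed-stable and length-zero branches copy", {
  tr <- read_newick("(A:0,B:0.4);")
  a1 <- simulate_sequences(tr, 500, seed = 5)
  a2 <- simulate_sequences(tr, 500, seed = 5)
  expect_identical(unclass(a1), unclass(a2))
  root_half <- unclass(a1)["A", ]  # zero-length branch: equals the root
  expect_true(mean(root_half != unclass(a1)["B", ]) > 0.1)
})

test_that("the K2P estimator is consistent on simulated cherries", {
  tr <- read_newick("(A:0.1,B:0.1);")
  aln <- simulate_sequences(tr, 20000, seed = 3)
  expect_lt(abs(k2p_distance(aln)[1, 2] - 0.2), 0.02)
})

test_that("equal rates yield the 1:2 transition:transversion ratio", {
  tr <- read_newick("(A:0,B:0.3);")
  aln <- simulate_sequences(tr, 30000, transition_rate = 1 / 3,
                            transversion_rate = 1 / 3, seed = 4)
  x <- unclass(aln)
  pur <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  d <- x[1, ] != x[2, ]
  ts <- sum(d & pur[x[1, ]] == pur[x[2, ]])
  tv <- sum(d) - ts
  expect_equal(ts / tv, 0.5, tolerance = 0.1)
})

test_that("zero prevalence produces no positives anywhere", {
  t <- simulate_specimens(specimen_sim_params(species = paste0("sp", 1:5),
                                              n_per_species = 20,
                                              prevalence = 0), seed = 1)
  expect_true(all(t$overall == "negative"))
  expect_true(all(t$leg == "negative" & t$gut == "negative" &
                    t$reproductive == "negative"))
})

test_that("strong tissue tropism is detected by Cochran's Q at alpha 0.001", {
  t <- simulate_specimens(specimen_sim_params(
    species = paste0("sp", 1:10), n_per_species = 100,
    prevalence = 0.44, sex_or = 1, control_fail_rate = 0), seed = 12)
  tt <- tissue_tropism(t)
  expect_lt(tt$q$p, 0.001)
  # positivity ordering reproductive >> gut ~ leg
  cnt <- setNames(tt$counts$positive, tt$counts$tissue)
  expect_gt(cnt[["reproductive"]], 3 * cnt[["gut"]])
})

test_that("specimen tables validate and respect the overall-call invariant", {
  t <- simulate_specimens(seed = 8)
  expect_s3_class(t, "specimen_table")
  any_pos <- t$leg == "positive" | t$gut == "positive" |
    t$reproductive == "positive"
  expect_equal(t$overall == "positive", any_pos)
})

test_that("reconciled cost never exceeds the generating log's cost (no FTD)", {
  for (seed in 1:8) {
    s <- simulate_cophylogeny(6, rates = c(cospeciation = 0.7, duplication = 0.05,
                                           host_shift = 0.1, loss = 0.3,
                                           failure_to_diverge = 0), seed = seed)
    r <- reconcile(s$host, s$symb, s$assoc)
    expect_lte(r$cost, total_cost(s$counts, cost_scheme()))
  }
})
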