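test_that("total cost is the weighted sum, with validation", {
  sch <- cost_scheme(0, 1, 2, 1, 1)
  expect_equal(total_cost(c(cospeciation = 1, duplication = 3, host_shift = 7,
                            loss = 29, failure_to_diverge = 6), sch), 52)
  expect_equal(total_cost(c(0, 0, 0, 0, 0), sch), 0)
  expect_equal(total_cost(c(5, 0, 0, 0, 0), sch), 0)  # cospeciation is free
  expect_error(total_cost(c(-1, 0, 0, 0, 0), sch), class = "symbio_bad_counts")
  expect_error(cost_scheme(loss = -1), class = "symbio_bad_costs")
})

test_that("perfect congruence reconciles to all-cospeciation at cost zero", {
  host <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  symb <- read_newick("((a:1,b:1):1,(c:1,d:1):1);")
  A <- diag(4); dimnames(A) <- list(c("A", "B", "C", "D"), c("a", "b", "c", "d"))
  r <- reconcile(host, symb, A)
  expect_equal(r$cost, 0)
  expect_equal(unname(r$counts["cospeciation"]), 3L)
  expect_true(r$optimal)
})

test_that("a one-lineage symbiont on two hosts is one failure to diverge", {
  host <- read_newick("(A:1,B:1);")
  symb <- ape::read.tree(text = "(s:1);")
  A <- matrix(1L, 2, 1, dimnames = list(c("A", "B"), "s"))
  r <- reconcile(host, symb, A)
  expect_equal(r$cost, 1)
  expect_equal(unname(r$counts["failure_to_diverge"]), 1L)
})

test_that("the two-symbiont example attains the enumerated minimum of 2", {
  host <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  symb <- read_newick("(s1:1,s2:1);")
  A <- matrix(0L, 4, 2, dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  A["A", "s1"] <- 1L; A["C", "s2"] <- 1L
  r <- reconcile(host, symb, A)
  expect_equal(r$cost, oracle_recon_min_cost(host, symb, A))
  expect_equal(r$cost, 2)
})

test_that("exact mode equals the brute-force enumerator on random instances", {
  for (seed in 1:60) {
    inst <- rand_recon_instance(seed)
    r <- reconcile(inst$host, inst$symb, inst$assoc)
    expect_equal(r$cost, oracle_recon_min_cost(inst$host, inst$symb, inst$assoc),
                 info = paste("seed", seed))
    # reported counts always reprice to the reported cost
    expect_equal(total_cost(r$counts, cost_scheme()), r$cost)
  }
})

test_that("heuristic mode never beats exact mode", {
  for (seed in c(2, 7, 13, 21)) {
    inst <- rand_recon_instance(seed, max_hosts = 6, max_symb = 6)
    ex <- reconcile(inst$host, inst$symb, inst$assoc)
    he <- reconcile(inst$host, inst$symb, inst$assoc, mode = "heuristic",
                    generations = 30, population = 60, seed = seed)
    expect_gte(he$cost, ex$cost)
    expect_false(he$optimal)
    expect_equal(total_cost(he$counts, cost_scheme()), he$cost)
  }
})

test_that("simulated cospeciation-only histories reconcile to cost zero", {
  for (seed in 1:5) {
    s <- simulate_cophylogeny(6, rates = c(cospeciation = 1, duplication = 0,
                                           host_shift = 0, loss = 0,
                                           failure_to_diverge = 0), seed = seed)
    r <- reconcile(s$host, s$symb, s$assoc)
    expect_equal(r$cost, 0)
    expect_equal(unname(r$counts["cospeciation"]), s$symb$Nnode)
  }
})

test_that("input validation: unrooted trees and hostless symbionts", {
  host <- ape::unroot(read_newick("((A:1,B:1):1,(C:1,D:1):1);"))
  symb <- read_newick("(s1:1,s2:1);")
  A <- matrix(1L, 4, 2, dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  expect_error(reconcile(host, symb, A), class = "symbio_unrooted")
  host2 <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  A2 <- A; A2[, 2] <- 0L
  expect_error(reconcile(host2, symb, A2), class = "symbio_bad_association")
})

test_that("random tip mapping: congruent systems have fraction 0", {
  host <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  symb <- read_newick("((a:1,b:1):1,(c:1,d:1):1);")
  A <- diag(4); dimnames(A) <- list(c("A", "B", "C", "D"), c("a", "b", "c", "d"))
  rt <- random_tip_mapping_test(host, symb, A, n_iter = 20, seed = 3)
  expect_equal(rt$fraction, 0)
  expect_true(rt$supported)
  expect_length(rt$random_costs, 20L)
})

test_that("random tip mapping on random associations sits in the central band", {
  set.seed(40)
  host <- ape::rtree(7); host$tip.label <- paste0("H", 1:7)
  symb <- ape::rtree(6); symb$tip.label <- paste0("S", 1:6)
  A <- matrix(0L, 7, 6, dimnames = list(host$tip.label, symb$tip.label))
  for (j in 1:6) A[sample(7, 1), j] <- 1L
  rt <- random_tip_mapping_test(host, symb, A, n_iter = 50, seed = 8)
  expect_gte(rt$fraction, 0.02)
  expect_lte(rt$fraction, 0.98)
})
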