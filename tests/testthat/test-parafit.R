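test_that("PCoA reproduces Euclidean configurations without correction", {
  x <- c(0, 1, 3, 6)  # four points on a line
  D <- abs(outer(x, x, "-"))
  dimnames(D) <- list(letters[1:4], letters[1:4])
  p <- pcoa_cailliez(D)
  expect_equal(p$cailliez, 0)
  rec <- as.matrix(dist(p$vectors))
  expect_equal(unname(rec), unname(D), tolerance = 1e-8)
})

test_that("Cailliez correction removes negative eigenvalues and scales", {
  D <- matrix(c(0, 1, 1, 1.9,
                1, 0, 1.9, 1,
                1, 1.9, 0, 1,
                1.9, 1, 1, 0), 4, dimnames = list(letters[1:4], letters[1:4]))
  # make it clearly non-Euclidean
  D[1, 2] <- D[2, 1] <- 3.5
  p <- pcoa_cailliez(D)
  expect_gt(p$cailliez, 0)
  Dc <- D + p$cailliez; diag(Dc) <- 0
  G <- -0.5 * Dc^2
  G <- sweep(sweep(G, 1, rowMeans(G)), 2, colMeans(G) - mean(G))
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(abs(ev)))
  # doubling distances doubles the constant and the coordinates
  p2 <- pcoa_cailliez(2 * D)
  expect_equal(p2$cailliez, 2 * p$cailliez, tolerance = 1e-6)
  expect_equal(abs(p2$vectors[, 1]), 2 * abs(p$vectors[, 1]), tolerance = 1e-6)
})

test_that("PCoA agrees with the ape reference implementation", {
  set.seed(11)
  D <- as.matrix(dist(matrix(rnorm(24), 6)))
  D[1, 2] <- D[2, 1] <- D[1, 2] * 3
  dimnames(D) <- list(letters[1:6], letters[1:6])
  mine <- pcoa_cailliez(D)
  ref <- ape::pcoa(as.dist(D), correction = "cailliez")
  cc <- as.numeric(sub(".*D [+] (\\d+\\.\\d+).*", "\\1",
                       gsub(".*\\(D \\+ ([0-9.]+) .*", "\\1", ref$note)))
  expect_equal(mine$cailliez, cc, tolerance = 1e-6)
})

test_that("global statistic matches the brute-force quadruple sum", {
  for (seed in 1:5) {
    set.seed(seed)
    nh <- sample(4:6, 1); ns <- sample(3:6, 1)
    hD <- patristic_distances(ape::rtree(nh))
    sD <- patristic_distances(ape::rtree(ns))
    A <- matrix(0L, nh, ns, dimnames = list(rownames(hD), rownames(sD)))
    for (j in seq_len(ns)) A[sample(nh, sample(1:2, 1)), j] <- 1L
    su <- symbiophy:::parafit_setup(hD, sD, A)
    expect_equal(symbiophy:::parafit_stat(su$A, su$B, su$C),
                 oracle_parafit_stat(su$A, su$B, su$C),
                 tolerance = 1e-9)
  }
})

test_that("the statistic is invariant to joint host relabelling", {
  set.seed(12)
  hD <- patristic_distances(ape::rtree(6))
  sD <- patristic_distances(ape::rtree(4))
  A <- matrix(0L, 6, 4, dimnames = list(rownames(hD), rownames(sD)))
  for (j in 1:4) A[sample(6, 1), j] <- 1L
  g1 <- parafit_global(hD, sD, A, n_perm = 0)
  perm <- sample(rownames(hD))
  g2 <- parafit_global(hD[perm, perm], sD, A[perm, , drop = FALSE], n_perm = 0)
  expect_equal(g1$global, g2$global, tolerance = 1e-9)
})

test_that("congruent trees reject; fixed seeds reproduce", {
  set.seed(21)
  tr <- ape::rcoal(8)
  tr2 <- tr; tr2$tip.label <- paste0("s_", tr$tip.label)
  A <- diag(8); dimnames(A) <- list(tr$tip.label, tr2$tip.label)
  hD <- patristic_distances(tr); sD <- patristic_distances(tr2)
  g1 <- parafit_global(hD, sD, A, n_perm = 999, seed = 5)
  expect_lte(g1$p, 0.05)
  g2 <- parafit_global(hD, sD, A, n_perm = 999, seed = 5)
  expect_equal(g1$p, g2$p)
})

test_that("link tests: single link equals global; incongruent link is weakest", {
  set.seed(31)
  tr <- ape::rcoal(6)
  tr2 <- tr; tr2$tip.label <- paste0("s_", tr$tip.label)
  hD <- patristic_distances(tr); sD <- patristic_distances(tr2)
  A1 <- matrix(0L, 6, 6, dimnames = list(tr$tip.label, tr2$tip.label))
  A1[3, 3] <- 1L
  A1 <- A1[, colSums(A1) > 0, drop = FALSE]
  l1 <- parafit_links(hD, sD, A1, n_perm = 199, seed = 2)
  expect_equal(l1$links$stat, l1$global)
  expect_true(l1$links$undefined)
  # congruent system: all links contribute positively; a deliberately
  # incongruent extra link contributes least
  A <- diag(6); dimnames(A) <- list(tr$tip.label, tr2$tip.label)
  lc <- parafit_links(hD, sD, A, n_perm = 99, seed = 3)
  expect_true(all(lc$links$stat > 0))
  D <- patristic_distances(tr)
  far <- which(D == max(D), arr.ind = TRUE)[1, ]
  Ax <- A
  Ax[far[1], far[2]] <- 1L  # link a host to the symbiont of its farthest relative
  lx <- parafit_links(hD, sD, Ax, n_perm = 99, seed = 3)
  bad <- which(lx$links$host == rownames(D)[far[1]] &
                 lx$links$strain == colnames(Ax)[far[2]])
  expect_equal(which.min(lx$links$stat), bad)
})
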