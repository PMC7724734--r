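test_that("prevalence percentages follow the survey convention", {
  df <- data.frame(species = "X", infected = 4, screened = 10)
  pt <- prevalence_table(df)
  expect_equal(pt$percent, 40.0)
  expect_equal(pct(67, 159), 42.1)
  expect_equal(pct(9, 159), 5.7)
  expect_equal(pct(5, 159), 3.1)
})

test_that("aggregation is record-order invariant and sums to the totals", {
  t <- simulate_specimens(specimen_sim_params(species = paste0("sp", 1:6),
                                              n_per_species = 15), seed = 2)
  pt1 <- prevalence_table(t)
  t2 <- t[sample(nrow(t)), ]
  pt2 <- prevalence_table(t2)
  expect_equal(pt1, pt2, ignore_attr = TRUE)
  expect_equal(sum(pt1$infected), unname(attr(pt1, "total")["infected"]))
  expect_equal(sum(pt1$screened), unname(attr(pt1, "total")["screened"]))
  expect_error(prevalence_table(t, by = "banana"), class = "symbio_bad_columns")
})

test_that("empty groups are omitted", {
  df <- data.frame(species = c("X", "Y"), infected = c(1, 0),
                   screened = c(5, 0))
  pt <- prevalence_table(df)
  expect_equal(pt$species, "X")
})

test_that("Cochran's Q matches hand computation and the brute-force formula", {
  m <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 0, 0))
  q <- cochran_q(m)
  expect_equal(q$Q, 2 * 14 / 6)   # C=(3,1,0), R=(1,1,2,0)
  expect_equal(q$df, 2L)
  expect_equal(q$n_informative, 3L)
  set.seed(6)
  for (r in 1:20) {
    m <- matrix(rbinom(60, 1, 0.4), ncol = 3)
    if (all(rowSums(m) %in% c(0, 3))) next
    expect_equal(cochran_q(m)$Q, oracle_cochran_q(m), tolerance = 1e-12)
    # duplicating every subject: recomputed value equals the formula again
    m2 <- rbind(m, m)
    expect_equal(cochran_q(m2)$Q, oracle_cochran_q(m2), tolerance = 1e-12)
  }
})

test_that("Q is zero on identical rows and undefined with no informative rows", {
  m <- matrix(1, 5, 3)
  m[4:5, ] <- 0
  q <- cochran_q(m)
  expect_true(q$undefined)
  m2 <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 1, 1))
  expect_false(cochran_q(m2)$undefined)
})

test_that("with two conditions Q equals the uncorrected McNemar chi-square", {
  set.seed(9)
  for (r in 1:10) {
    m <- matrix(rbinom(40, 1, 0.5), ncol = 2)
    b <- sum(m[, 1] == 1 & m[, 2] == 0)
    cc <- sum(m[, 1] == 0 & m[, 2] == 1)
    if (b + cc == 0) next
    expect_equal(cochran_q(m)$Q, (b - cc)^2 / (b + cc), tolerance = 1e-12)
    mc <- mcnemar_pairwise(m, method = "chisq")
    expect_equal(mc$statistic, (b - cc)^2 / (b + cc))
  }
})

test_that("exact McNemar handles the binomial tails and degenerate pairs", {
  m <- cbind(a = c(rep(1, 10), 0, 1), b = c(rep(0, 10), 0, 1))
  out <- mcnemar_pairwise(m)
  expect_equal(out$p, 2 * 0.5^10)
  # b = c gives P = 1 by symmetry
  m2 <- cbind(a = c(1, 0, 1, 0), b = c(0, 1, 1, 0))
  expect_equal(mcnemar_pairwise(m2)$p, 1)
  m3 <- cbind(a = c(1, 1, 0), b = c(1, 1, 0))
  out3 <- mcnemar_pairwise(m3)
  expect_true(out3$degenerate)
  expect_equal(out3$p, 1)
})

test_that("tissue tropism excludes control failures and unassessed tissues", {
  t <- tiny_specimens()
  tt <- tissue_tropism(t)
  expect_equal(tt$n, 5L)  # the control failure is excluded
  expect_equal(tt$counts$positive[tt$counts$tissue == "reproductive"], 3L)
})

test_that("the sex balance rule is inclusive at the boundary", {
  mk <- function(species, nF, nM) {
    data.frame(specimen_id = paste0(species, seq_len(nF + nM)),
               species = species, locality = "L", sex = rep(c("F", "M"), c(nF, nM)),
               leg = "negative", gut = "negative",
               reproductive = rep(c("positive", "negative"),
                                  length.out = nF + nM),
               control_pass = TRUE, stringsAsFactors = FALSE)
  }
  t <- as_specimen_table(rbind(mk("keep", 10, 6), mk("drop", 10, 5),
                               mk("onesex", 0, 8)))
  out <- sex_balance_subset(t, 0.6)
  expect_equal(attr(out, "species_kept"), "keep")
  expect_true(all(out$species == "keep"))
})

test_that("the logistic sex effect matches the 2x2 closed form", {
  n <- 100
  df <- data.frame(
    specimen_id = paste0("s", 1:(2 * n)),
    species = "X", locality = "L",
    sex = rep(c("F", "M"), each = n),
    leg = "negative", gut = "negative",
    reproductive = c(rep(c("positive", "negative"), c(30, 70)),
                     rep(c("positive", "negative"), c(15, 85))),
    control_pass = TRUE, stringsAsFactors = FALSE)
  t <- as_specimen_table(df)
  r <- logistic_sex_effect(t)
  or_hand <- (15 * 70) / (85 * 30)
  expect_equal(r$odds_ratio, or_hand, tolerance = 1e-6)
  expect_equal(r$coefficient, log(or_hand), tolerance = 1e-6)
  expect_equal(r$df, 2 * n - 2L)
  expect_lt(r$p, 0.05)
})

test_that("equal rates give an odds ratio near one; separation is flagged", {
  df <- data.frame(
    specimen_id = paste0("s", 1:80), species = "X", locality = "L",
    sex = rep(c("F", "M"), 40),
    leg = "negative", gut = "negative",
    reproductive = rep(c("positive", "negative"), each = 2, length.out = 80),
    control_pass = TRUE, stringsAsFactors = FALSE)
  r <- logistic_sex_effect(as_specimen_table(df))
  expect_equal(r$odds_ratio, 1, tolerance = 1e-6)
  df2 <- df
  df2$reproductive <- ifelse(df2$sex == "M", "positive", "negative")
  r2 <- logistic_sex_effect(as_specimen_table(df2))
  expect_true(r2$separation)
  expect_true(is.na(r2$odds_ratio))
})
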