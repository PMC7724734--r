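test_that("supported clades become strains; the 0.90 band merges; zero support isolates", {
  # clade (s1..s4) support 0.99 -> one strain of 4
  t1 <- read_newick("(((s1:.1,s2:.1):.1,(s3:.1,s4:.1):.1)99:.1,refA:.3);")
  a1 <- cluster_strains(t1, paste0("s", 1:4))
  expect_equal(lengths(a1$strains)[["Wol 1"]], 4L)
  # support 0.92, between thresholds: merged by the fallback rule
  t2 <- read_newick("((s1:.1,s2:.1)92:.1,refA:.3);")
  a2 <- cluster_strains(t2, c("s1", "s2"))
  expect_equal(length(a2$strains), 1L)
  expect_setequal(a2$strains[[1]], c("s1", "s2"))
  # all supports zero: singletons
  t3 <- read_newick("((s1:.1,s2:.1)0:.1,(s3:.1,refA:.1)0:.1)0;")
  a3 <- cluster_strains(t3, c("s1", "s2", "s3"))
  expect_equal(length(a3$strains), 3L)
  expect_true(all(lengths(a3$strains) == 1L))
})

test_that("the strain map is a partition of the study sequences", {
  for (seed in 1:10) {
    tr <- rand_supported_tree(12, seed)
    study <- sample(tr$tip.label, 8)
    asn <- cluster_strains(tr, study)
    members <- unlist(asn$strains)
    expect_setequal(members, study)
    expect_equal(anyDuplicated(members), 0L)
  }
})

test_that("raising the primary threshold only refines the partition", {
  part_of <- function(asn) {
    lapply(asn$strains, sort)
  }
  refines <- function(fine, coarse) {
    all(vapply(fine, function(b) {
      any(vapply(coarse, function(B) all(b %in% B), logical(1)))
    }, logical(1)))
  }
  for (seed in 1:15) {
    tr <- rand_supported_tree(14, seed)
    study <- sample(tr$tip.label, 10)
    lo <- cluster_strains(tr, study, primary_threshold = 0.92)
    hi <- cluster_strains(tr, study, primary_threshold = 0.99)
    expect_true(refines(part_of(hi), part_of(lo)))
  }
})

test_that("k perfectly supported clades give exactly k strains", {
  t1 <- read_newick(paste0("(((s1:.1,s2:.1)100:.2,(s3:.1,s4:.1)100:.2)0:.1,",
                           "((s5:.1,s6:.1)100:.2,refA:.3)0:.1)0;"))
  asn <- cluster_strains(t1, paste0("s", 1:6))
  expect_equal(length(asn$strains), 3L)
})

test_that("supergroups come from the nearest references; short strains are UC", {
  tr <- read_newick(paste0("(((s1:.1,s2:.1)99:.1,refA1:.2)80:.1,",
                           "((s3:.1,refB1:.1)95:.1,refA2:.3)70:.1)0;"))
  asn <- cluster_strains(tr, c("s1", "s2", "s3"),
                         primary_threshold = 0.97, secondary_threshold = 0.9)
  refs <- c(refA1 = "A", refA2 = "A", refB1 = "B")
  asn1 <- assign_supergroup(asn, tr, refs)
  st <- asn1$supergroup
  expect_equal(unname(st[asn1$strain_of["s1"]]), "A")
  expect_equal(unname(st[asn1$strain_of["s3"]]), "B")
  # too-short members force UC regardless of placement
  asn2 <- assign_supergroup(asn, tr, refs,
                            ungapped_lengths = c(s1 = 350, s2 = 350, s3 = 600),
                            min_classifiable_length = 400)
  expect_equal(unname(asn2$supergroup[asn1$strain_of["s1"]]), "UC")
  expect_equal(unname(asn2$supergroup[asn1$strain_of["s3"]]), "B")
  expect_error(assign_supergroup(asn, tr, character(0)),
               class = "symbio_no_references")
})

test_that("mixed reference neighbourhoods are UC with a warning", {
  tr <- read_newick("(((s1:.1,s2:.1)99:.1,(refA:.1,refB:.1)90:.1)80:.1,refC:.4)0;")
  asn <- cluster_strains(tr, c("s1", "s2"))
  expect_warning(out <- assign_supergroup(asn, tr, c(refA = "A", refB = "B")),
                 "supergroups A/B")
  expect_equal(unname(out$supergroup[["Wol 1"]]), "UC")
})

test_that("specificity classes follow host counts, with invariant errors", {
  tr <- read_newick("((s1:.1,s2:.1)99:.1,(s3:.1,refA:.1)99:.1)0;")
  asn <- cluster_strains(tr, c("s1", "s2", "s3"))
  A <- matrix(0L, 3, 2, dimnames = list(c("H1", "H2", "H3"),
                                        names(asn$strains)))
  A[1, 1] <- 1L; A[1:3, 2] <- 1L
  out <- classify_specificity(asn, A)
  expect_equal(unname(out$class), c("specialist", "generalist"))
  expect_equal(length(out$hosts[[2]]), 3L)
  # absent strain column
  expect_error(classify_specificity(asn, A[, 1, drop = FALSE]),
               class = "symbio_unknown_strain")
  # all-zero column is an association invariant violation
  A2 <- A; A2[, 2] <- 0L
  expect_error(classify_specificity(asn, A2),
               class = "symbio_bad_association")
})
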