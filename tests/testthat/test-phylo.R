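# Distances, neighbour joining against exhaustive least-squares oracles,
# bootstrap supports, outgroup rooting.

test_that("p-distances use pairwise deletion; Poisson corrects them", {
  msa <- c(a = "AAAA", b = "AAAT", c = "AAAA")
  D <- distance_matrix(msa)
  expect_equal(D["a", "b"], 0.25)
  expect_equal(D["a", "c"], 0)
  expect_equal(D, t(D))

  gapped <- c(a = "AA--", b = "AT--", c = "ATAA")
  Dg <- distance_matrix(gapped)
  expect_equal(Dg["a", "b"], 0.5)  # 2 comparable sites, 1 mismatch

  expect_equal(distance_matrix(c(a = "AC", b = "AC"),
                               model = "poisson")["a", "b"], 0)
  p <- 0.25
  expect_equal(distance_matrix(msa, model = "poisson")["a", "b"], -log(1 - p))
  expect_error(distance_matrix(c(a = "A-", b = "-A")), "comparable")
})

test_that("3-taxon NJ reproduces the closed-form branch lengths", {
  dm <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phy <- neighbor_joining(dm)
  expect_identical(ape::Ntip(phy), 3L)
  # v_A = (dAB + dAC - dBC)/2 = 1, v_B = 2, v_C = 4
  lens <- stats::setNames(phy$edge.length,
                          phy$tip.label[phy$edge[, 2]])
  expect_equal(unname(lens[c("A", "B", "C")]), c(1, 2, 4))
  expect_error(neighbor_joining(dm[1:2, 1:2]), "3 taxa")
})

test_that("NJ recovers additive trees and matches the LS oracle (n=4,5)", {
  set.seed(11)
  for (n in c(4L, 5L)) {
    topos <- enumerate_topologies(n)
    for (tr in topos) {
      lens <- stats::runif(nrow(tr$edges), 0.5, 3)
      labels <- paste0("t", seq_len(n))
      dm <- additive_matrix(tr$edges, n, lens, labels)
      phy <- neighbor_joining(dm)
      true_splits <- topo_splits(tr$edges, n, labels)
      expect_identical(phylo_splits(phy), true_splits)
      expect_identical(ls_best_splits(dm), true_splits)
    }
  }
})

test_that("NJ recovers 6-taxon additive trees exactly", {
  set.seed(12)
  topos <- enumerate_topologies(6L)
  for (tr in topos) {
    lens <- stats::runif(nrow(tr$edges), 0.5, 3)
    labels <- paste0("t", 1:6)
    dm <- additive_matrix(tr$edges, 6L, lens, labels)
    expect_identical(phylo_splits(neighbor_joining(dm)),
                     topo_splits(tr$edges, 6L, labels))
  }
})

test_that("NJ topology agrees with the independent ape implementation", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(4:7, 1L)
    topos <- enumerate_topologies(n)
    tr <- topos[[sample(length(topos), 1L)]]
    dm <- additive_matrix(tr$edges, n, stats::runif(nrow(tr$edges), 0.5, 2))
    expect_identical(phylo_splits(neighbor_joining(dm)),
                     sort(unname(tree_splits(ape::nj(dm)))))
  }
})

test_that("negative branch estimates are clamped to zero", {
  # a non-additive matrix known to produce a negative NJ estimate
  dm <- matrix(c(0, 1, 6, 6,
                 1, 0, 6, 6,
                 6, 6, 0, 1,
                 6, 6, 1, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm["A", "B"] <- dm["B", "A"] <- 5.9
  phy <- neighbor_joining(dm)
  expect_true(all(phy$edge.length >= 0))
})

test_that("bootstrap supports are reproducible and bounded", {
  set.seed(3)
  blocks <- c(a = "AAAACCCC", b = "AAAACCCG", c = "TTTTGGGG", d = "TTTTGGGA")
  bt <- bootstrap_support(blocks, n_reps = 60L, seed = 9L)
  expect_identical(bt$node.label,
                   bootstrap_support(blocks, n_reps = 60L, seed = 9L)$node.label)
  sup <- attr(bt, "bootstrap")
  expect_true(all(sup >= 0 & sup <= 100))

  # every column carries the same split signal -> support must be 100
  dup <- c(a = strrep("A", 12), b = strrep("A", 12),
           c = strrep("T", 12), d = strrep("T", 12))
  dup["b"] <- paste0(strrep("A", 11), "C")
  dup["d"] <- paste0(strrep("T", 11), "G")
  bt2 <- bootstrap_support(dup, n_reps = 40L, seed = 5L)
  sup2 <- attr(bt2, "bootstrap")
  expect_true(all(sup2 == 100))
})

test_that("strong-signal families give the true split maximum support", {
  set.seed(8)
  tpl <- strsplit(paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                        collapse = ""), "")[[1]]
  mutate <- function(v, k) {
    pos <- sample(seq_along(v), k)
    v[pos] <- vapply(v[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
    v
  }
  cladeA <- mutate(tpl, 40)
  cladeB <- mutate(tpl, 40)
  msa <- vapply(list(mutate(cladeA, 3), mutate(cladeA, 3),
                     mutate(cladeB, 3), mutate(cladeB, 3),
                     mutate(mutate(cladeB, 25), 3)),
                paste, character(1L), collapse = "")
  names(msa) <- paste0("t", 1:5)
  bt <- bootstrap_support(msa, n_reps = 100L, seed = 4L)
  sup <- attr(bt, "bootstrap")
  true_key <- split_key(c("t1", "t2"), names(msa))
  expect_true(true_key %in% names(sup))
  expect_equal(unname(sup[true_key]), max(sup))
})

test_that("outgroup rooting preserves topology and supports", {
  set.seed(14)
  msa <- c(o = "TTTTTTGGGGGG", a = "AAAAAACCCCCC", b = "AAAAAACCCCCG",
           c = "AAAATACCCCCC", d = "AAAATACCGCCC")
  bt <- bootstrap_support(msa, n_reps = 50L, seed = 2L)
  rooted <- root_with_outgroup(bt, "o")
  expect_true(ape::is.rooted(rooted))
  # the outgroup hangs off the root
  root_children <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1L, 2]
  expect_true(match("o", rooted$tip.label) %in% root_children)
  # unrooting recovers the unrooted topology
  expect_identical(sort(unname(tree_splits(ape::unroot(rooted)))),
                   sort(unname(tree_splits(bt))))
  expect_error(root_with_outgroup(bt, "nope"), "unknown")
})
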