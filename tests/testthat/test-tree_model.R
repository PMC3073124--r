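test_that("newick parsing and bipartitions handle the basic shapes", {
  tr <- parse_newick("((A,B),(C,D));")
  bp <- bipartitions(tr)
  expect_equal(length(bp), 1L)
  expect_equal(bp[[1L]], c("A", "B"))
  expect_equal(length(bipartitions(parse_newick("(A,B);"))), 0L)
  star <- parse_newick("(A,B,C,D,E);")
  expect_equal(length(bipartitions(star)), 0L)
  # fully resolved unrooted n-leaf tree has n-3 non-trivial splits
  tr5 <- ape::unroot(ape::rtree(5))
  expect_equal(length(bipartitions(tr5)), 2L)
  expect_error(parse_newick("((A,B),(C,A));"), "duplicate")
  expect_error(parse_newick("((A,B),(C,D);"), "malformed")
})

test_that("split counts match an independent per-edge recount", {
  for (i in 1:10) {
    set.seed(i)
    tr <- ape::unroot(ape::rtree(12))
    bp <- bipartitions(tr)
    # oracle: internal edges = edges whose child is internal
    n <- length(tr$tip.label)
    internal_edges <- sum(tr$edge[, 2L] > n)
    expect_equal(length(bp), internal_edges)
    expect_equal(length(bp), n - 3L)
  }
})

test_that("canonical newick round-trips topology and is order-stable", {
  set.seed(7)
  tr <- ape::unroot(ape::rtree(78))
  txt <- write_newick(tr)
  tr2 <- parse_newick(txt)
  expect_identical(sort(names(bipartitions(tr2))),
                   sort(names(bipartitions(tr))))
  # shuffling leaves/rotating nodes does not change the canonical string
  tr3 <- ape::rotateConstr(tr, sample(tr$tip.label))
  expect_identical(write_newick(tr3), txt)
})

test_that("rerooting on an outgroup separates it and preserves splits", {
  tr <- parse_newick("((A,B),(C,D));")
  r <- reroot_on_outgroup(tr, "A")
  expect_true(ape::is.rooted(r))
  expect_true(contains_clade(r, c("B", "C", "D")))
  set.seed(3)
  tr8 <- ape::unroot(ape::rtree(8))
  out <- tr8$tip.label[1:2]
  before <- sort(names(bipartitions(tr8)))
  r8 <- reroot_on_outgroup(tr8, tr8$tip.label[ape::prop.part(tr8)[[2L]]][1:2])
  expect_identical(sort(names(bipartitions(r8, universe = tr8$tip.label))),
                   before)
})

test_that("unresolvable outgroups fall back with a warning", {
  tr <- parse_newick("((A,C),(B,D),(E,F));")
  expect_warning(reroot_on_outgroup(tr, c("A", "B")), "paraphyly")
})

test_that("topology keys are injective on distinct resolved topologies", {
  set.seed(11)
  seen <- character(0)
  trees <- list()
  for (i in 1:25) {
    tr <- ape::unroot(ape::rtree(7))
    key <- topology_key(tr)
    for (j in seq_along(trees))
      expect_equal(key == seen[j],
                   phangorn::RF.dist(tr, trees[[j]]) == 0)
    seen <- c(seen, key); trees <- c(trees, list(tr))
  }
})
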