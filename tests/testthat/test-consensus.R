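test_that("strict consensus of identical trees is that tree", {
  set.seed(1)
  tr <- ape::unroot(ape::rtree(8))
  cons <- strict_consensus(list(tr, tr, tr))
  expect_identical(sort(names(bipartitions(cons))),
                   sort(names(bipartitions(tr))))
})

test_that("strict consensus keeps exactly the shared splits", {
  t1 <- parse_newick("((A,B),(C,(D,E)));")
  t2 <- parse_newick("((A,B),(D,(C,E)));")
  cons <- strict_consensus(list(t1, t2))
  bp <- bipartitions(cons)
  expect_identical(names(bp), split_key(c("A", "B"), LETTERS[1:5])[1L])
  expect_error(strict_consensus(list(t1, parse_newick("((A,B),(C,X));"))),
               "leaf set")
})

test_that("consensus splits equal the intersection of per-tree split sets", {
  skip_if_no_phangorn()
  set.seed(33)
  for (i in 1:100) {
    trees <- lapply(1:3, function(j) ape::unroot(ape::rtree(8)))
    for (j in 2:3) trees[[j]]$tip.label <- trees[[1L]]$tip.label
    cons <- strict_consensus(trees)
    # independent oracle: ape's strict consensus must carry the same
    # unrooted split set (RF distance 0 iff identical splits)
    oracle <- ape::consensus(trees, p = 1)
    expect_equal(phangorn::RF.dist(ape::unroot(cons), oracle), 0)
    expect_identical(sort(as.character(names(bipartitions(cons)))),
                     sort(as.character(names(bipartitions(oracle)))))
  }
})

test_that("majority rule includes splits by frequency threshold", {
  t1 <- parse_newick("((A,B),(C,(D,E)));")
  t2 <- parse_newick("((A,B),(C,(D,E)));")
  t3 <- parse_newick("((A,C),(B,(D,E)));")
  mr <- majority_rule(list(t1, t2, t3))
  fr <- attr(mr, "frequencies")
  ab <- split_key(c("A", "B"), LETTERS[1:5])[1L]
  de <- split_key(c("D", "E"), LETTERS[1:5])[1L]
  expect_setequal(fr$split, c(ab, de, split_key(c("C","D","E"), LETTERS[1:5])[1L]))
  expect_equal(fr$frequency[fr$split == ab], 2 / 3, tolerance = 1e-9)
  expect_equal(fr$frequency[fr$split == de], 1)
  # all-identical input: input topology with all frequencies 1
  mr2 <- majority_rule(list(t1, t2))
  expect_identical(sort(names(bipartitions(mr2))),
                   sort(names(bipartitions(t1))))
  expect_true(all(attr(mr2, "frequencies")$frequency == 1))
})

test_that("majority frequencies match brute-force split counting", {
  set.seed(44)
  trees <- lapply(1:7, function(i) ape::unroot(ape::rtree(7)))
  for (j in 2:7) trees[[j]]$tip.label <- trees[[1L]]$tip.label
  mr <- majority_rule(trees)
  fr <- attr(mr, "frequencies")
  counts <- table(unlist(lapply(trees, function(tr)
    names(bipartitions(tr)))))
  for (i in seq_len(nrow(fr)))
    expect_equal(fr$frequency[i],
                 as.numeric(counts[fr$split[i]]) / 7)
})

test_that("both Bremer methods agree with full enumeration on small instances", {
  skip_if_no_phangorn()
  for (s in 1:4) {
    cfg <- sim_config(n_taxa = 8, n_char = 25, states_per_char = 2,
                      changes_per_char = 1, seed = 600 + s)
    m <- simulate_matrix(simulate_tree(cfg), cfg)$matrix
    bb <- branch_and_bound(m)
    cons <- strict_consensus(bb$trees)
    clades <- bipartitions(cons)
    if (!length(clades)) next
    sweep <- bremer_support(m, bb, clades = clades, method = "sweep",
                            sweep_max = 8)
    constr <- bremer_support(m, bb, clades = clades, method = "constraint",
                             config = search_config(replicates = 6, seed = s))
    # oracle: decay from an independent enumeration of all 10395 topologies
    all_trees <- phangorn::allTrees(8, tip.label = m$taxa)
    pd <- phangorn_data(m)
    lens <- vapply(all_trees, function(tr) phangorn::fitch(tr, pd), 0)
    for (i in seq_along(clades)) {
      lacking <- !vapply(all_trees, contains_clade, TRUE,
                         clade = clades[[i]])
      k_true <- min(lens[lacking]) - bb$best_length
      expect_equal(sweep$bremer[i], k_true)
      expect_equal(constr$bremer[i], k_true)
      expect_gte(sweep$bremer[i], 1L)  # consensus clades are in all MPTs
      expect_equal(sweep$frequency[i], 1)
    }
  }
})

test_that("suboptimal pools can only shrink reported decay", {
  # monotonicity: decay to the best tree lacking the clade can not grow
  # when more trees are admitted to the pool
  cfg <- sim_config(n_taxa = 7, n_char = 20, changes_per_char = 1.5,
                    seed = 9)
  m <- simulate_matrix(simulate_tree(cfg), cfg)$matrix
  bb <- branch_and_bound(m)
  clades <- bipartitions(strict_consensus(bb$trees))
  skip_if(length(clades) == 0L, "degenerate instance")
  k_small <- bremer_support(m, bb, clades = clades[1L], method = "sweep",
                            sweep_max = 4)$bremer
  k_large <- bremer_support(m, bb, clades = clades[1L], method = "sweep",
                            sweep_max = 8)$bremer
  expect_lte(k_large, k_small)
})
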