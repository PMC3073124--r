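test_that("a clade-confined derived state maps once to the stem", {
  m <- parse_matrix(c("A 0", "B 1", "C 1", "D 0", "E 0"))
  tr <- parse_newick("(((B,C),A),(D,E));")
  rt <- reroot_on_outgroup(tr, "E")
  mp <- map_synapomorphies(rt, m, "acctran")
  expect_equal(nrow(mp), 1L)
  expect_identical(mp$clade[[1L]], c("B", "C"))
  expect_equal(mp$from, "0")
  expect_equal(mp$to, "1")
  expect_false(mp$homoplastic)
})

test_that("ACCTRAN and DELTRAN totals equal tree length; unambiguous is a subset", {
  for (s in 1:8) {
    cfg <- sim_config(n_taxa = 8, n_char = 15, states_per_char = 3,
                      changes_per_char = 2, seed = 700 + s)
    tr <- simulate_tree(cfg)
    m <- simulate_matrix(tr, cfg)$matrix
    len <- fitch_length(tr, m)$total
    acc <- map_synapomorphies(tr, m, "acctran")
    del <- map_synapomorphies(tr, m, "deltran")
    una <- map_synapomorphies(tr, m, "unambiguous")
    expect_equal(nrow(acc), len)
    expect_equal(nrow(del), len)
    expect_lte(nrow(una), len)
    # unambiguous changes appear in both full resolutions (same branch/char)
    key <- function(x) paste(x$node, x$char)
    expect_true(all(key(una) %in% key(acc)))
    expect_true(all(key(una) %in% key(del)))
  }
})

test_that("homoplasy flags follow s_i > m_i", {
  m <- parse_matrix(c("A 01", "B 01", "C 00", "D 10", "E 10"))
  tr <- reroot_on_outgroup(parse_newick("((A,B),(C,(D,E)));"), "C")
  mp <- map_synapomorphies(tr, m, "acctran")
  s <- fitch_length(tr, m)$per_char
  b <- char_bounds(m)
  for (j in unique(mp$char))
    expect_equal(unique(mp$homoplastic[mp$char == j]),
                 s[j] > b$min_steps[j])
})

test_that("clade diagnostics return the stem entries with character names", {
  fix <- arminid_matrix()
  groups <- arminid_groups()
  sub <- subset_matrix(fix, groups$taxon[groups$group %in%
                                           c("armina", "dermatobranchus",
                                             "histiomena")])
  res <- heuristic_search(sub, search_config(replicates = 2, seed = 1,
                                             plateau = 50))
  rt <- reroot_on_outgroup(res$trees[[1L]], "Histiomena_marginata")
  mp <- map_synapomorphies(rt, sub, "acctran")
  derm <- sort(groups$taxon[groups$group == "dermatobranchus"])
  if (contains_clade(rt, derm)) {
    dd <- clade_diagnostics(mp, derm)
    expect_true(all(vapply(dd$clade, identical, TRUE, derm)))
    expect_true(all(dd$char_name %in% arminid_characters()$name))
  }
  expect_error(clade_diagnostics(mp, c("Armina_aoteana",
                                       "Dermatobranchus_albus",
                                       "Histiomena_marginata")),
               "not present")
})

test_that("a hand-computed six-taxon instance maps as worked out", {
  # char 1 diagnoses (C,D) with state 1; char 2 diagnoses (E,F) with
  # state 2; everything else is 0.  Each change has a unique optimal
  # placement on the clade stem, so all three resolutions agree.
  m <- parse_matrix(c("A 00", "B 00", "C 10", "D 10", "E 02", "F 02"))
  tr <- reroot_on_outgroup(parse_newick("((A,B),((C,D),(E,F)));"),
                           c("A", "B"))
  for (res in c("acctran", "deltran", "unambiguous")) {
    mp <- map_synapomorphies(tr, m, res)
    expect_equal(nrow(mp), 2L)
    expect_setequal(vapply(mp$clade, paste, "", collapse = ""),
                    c("CD", "EF"))
    expect_setequal(mp$to, c("1", "2"))
    expect_true(all(mp$from == "0"))
    expect_false(any(mp$homoplastic))
  }
})
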