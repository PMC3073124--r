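test_that("bespoke parsing resolves cell kinds and state sets", {
  m <- toy_matrix()
  expect_identical(m$taxa, c("A", "B", "C", "D", "E"))
  expect_equal(m$n_char, 5L)
  k <- cell_kinds(m)
  expect_equal(unname(k["A", 5L]), "missing")
  expect_equal(unname(k["B", 5L]), "inapplicable")
  expect_equal(unname(k["C", 4L]), "determinate")
  expect_equal(unname(k["C", 3L]), "polymorphic")
  expect_equal(unname(k["D", 5L]), "polymorphic")
  # determinate cells are singletons
  det <- m$states[k == "determinate"]
  expect_true(all(vapply(det, function(x) length(mask_to_states(x)), 1L) == 1L))
  # '?' and '-' resolve to the observed column states
  expect_equal(unname(mask_to_states(m$states["A", 5L])), c(0L, 2L))
  expect_equal(unname(mask_to_states(m$states["B", 5L])), c(0L, 2L))
  # no empty effective sets anywhere
  expect_true(all(m$states > 0L))
})

test_that("the '&' glyph follows the configured policy", {
  obs <- toy_matrix(amb = "observed")
  expect_equal(unname(mask_to_states(obs$states["D", 5L])), c(0L, 2L))
  pair <- toy_matrix(amb = c(0L, 1L))
  expect_equal(unname(mask_to_states(pair$states["D", 5L])), c(0L, 1L))
})

test_that("gap newstate policy gives '-' its own state", {
  m <- toy_matrix(gap = "newstate")
  expect_equal(unname(mask_to_states(m$states["B", 5L])), 4L)
})

test_that("validation errors name the offending taxon and cell", {
  expect_error(parse_matrix(c("A 001", "B 0011")), "ragged.*'B'.*4")
  expect_error(parse_matrix(c("A 001", "A 010")), "duplicate taxon")
  expect_error(parse_matrix(c("A 0z1", "B 001")), "illegal symbol 'z'.*'A'")
  expect_error(parse_matrix(""), "empty")
})

test_that("write/parse round-trips preserve taxa, kinds and state sets", {
  set.seed(42)
  for (i in 1:10) {
    cfg <- sim_config(n_taxa = 6, n_char = 10, states_per_char = 3,
                      changes_per_char = 2, missing_frac = 0.1,
                      inapplicable_frac = 0.05, polymorphic_frac = 0.05,
                      seed = i)
    m <- simulate_matrix(simulate_tree(cfg), cfg)$matrix
    for (d in c("bespoke", "nexus", "tnt")) {
      m2 <- parse_matrix(write_matrix(m, dialect = d), dialect = d)
      expect_identical(m2$taxa, m$taxa)
      expect_identical(unname(m2$states), unname(m$states))
      expect_identical(unname(cell_kinds(m2)), unname(cell_kinds(m)))
    }
  }
  expect_error(write_matrix(char_matrix(matrix("0", 0, 1),
                                        taxa = character(0))),
               "no taxa")
})

test_that("NEXUS export declares the matrix dimensions", {
  m <- toy_matrix()
  txt <- write_matrix(m, dialect = "nexus")
  expect_match(txt, "DIMENSIONS NTAX=5 NCHAR=5")
  expect_match(txt, "MISSING=\\? GAP=-")
})

test_that("informative characters match a brute-force column scan", {
  # constant and autapomorphic columns are uninformative
  m <- parse_matrix(c("A 0010", "B 0010", "C 0110", "D 0100"))
  expect_identical(informative_characters(m), 2L)
  # oracle: tally determinate singleton states per column
  fix <- arminid_matrix()
  oracle <- which(vapply(seq_len(fix$n_char), function(j) {
    col <- fix$symbols[, j]
    tab <- table(col[col %in% c("0", "1", "2", "3")])
    sum(tab >= 2) >= 2
  }, logical(1L)))
  expect_identical(informative_characters(fix), oracle)
})

test_that("subsetting preserves rows and resolves aliases", {
  fix <- arminid_matrix()
  s3 <- subset_matrix(fix, c("Armina_aoteana", "Dermatobranchus_albus",
                             "Histiomena_marginata"))
  expect_equal(length(s3$taxa), 3L)
  expect_identical(unname(s3$symbols["Armina_aoteana", ]),
                   unname(fix$symbols["Armina_aoteana", ]))
  # identity subset
  all78 <- subset_matrix(fix, fix$taxa)
  expect_identical(all78$symbols, fix$symbols)
  # alias resolution and near-miss reporting
  al <- arminid_aliases()
  s1 <- subset_matrix(fix, "Dermatobranchus_tongshanensis", aliases = al)
  expect_identical(s1$taxa, "Dermatobranchus_tongashanensis")
  expect_error(subset_matrix(fix, "Armina_aoteanaX"), "closest")
})

test_that("the packaged fixture matches its canonical transcription", {
  fix <- arminid_matrix()
  expect_equal(length(fix$taxa), 78L)
  expect_equal(fix$n_char, 43L)
  path <- system.file("extdata", "arminid_matrix.txt", package = "mpclad")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  raw <- do.call(rbind, strsplit(lines, "\t"))
  expect_identical(fix$taxa, raw[, 1L])
  expect_identical(unname(apply(fix$symbols, 1L, paste, collapse = "")),
                   raw[, 2L])
  # the two ambiguous glyphs sit where the printed table has them
  expect_equal(unname(fix$symbols["Dermatobranchus_fasciatus", 22L]), "&")
  expect_equal(unname(fix$symbols["Dermatobranchus_caeruleomaculatus", 25L]), "&")
  # 43 packaged character definitions
  expect_equal(nrow(arminid_characters()), 43L)
  expect_identical(arminid_characters()$index, 1:43)
})
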