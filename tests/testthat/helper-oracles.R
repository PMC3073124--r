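# Shared fixtures and independent oracles for the test suite.

# small bespoke matrix used across parsing tests
toy_text <- function() {
  c("# toy matrix",
    "A  0011?",
    "B  0012-",
    "C  01{01}20",
    "D  1112&",
    "E  0?112")
}

toy_matrix <- function(...) parse_matrix(toy_text(), dialect = "bespoke", ...)

# a random binary rooted tree and a random bitmask matrix over its leaves
random_instance <- function(n_taxa, n_char, n_states = 3, seed = 1,
                            amb_frac = 0) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = TRUE)
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  sym <- matrix(sample(as.character(0:(n_states - 1)),
                       n_taxa * n_char, replace = TRUE), n_taxa)
  if (amb_frac > 0)
    sym[matrix(runif(length(sym)) < amb_frac, nrow(sym))] <- "?"
  rownames(sym) <- tr$tip.label
  list(tree = tr, matrix = char_matrix(sym, provenance = "test"))
}

# exhaustive minimum-changes oracle: tries every assignment of states to
# internal nodes of a rooted tree for one character (masks = leaf bitmasks)
exhaustive_fitch_oracle <- function(tree, masks, n_states = 4) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  internals <- sort(unique(edge[, 1L]))
  grid <- do.call(expand.grid, rep(list(0:(n_states - 1L)),
                                   length(internals)))
  best <- Inf
  leaf_opts <- lapply(seq_len(n), function(i) mask_to_states(masks[i]))
  for (g in seq_len(nrow(grid))) {
    assign <- as.integer(grid[g, ])
    names(assign) <- internals
    changes <- 0L
    for (e in seq_len(nrow(edge))) {
      p <- edge[e, 1L]; c <- edge[e, 2L]
      sp <- assign[[as.character(p)]]
      if (c <= n) {
        if (!sp %in% leaf_opts[[c]]) changes <- changes + 1L
      } else if (sp != assign[[as.character(c)]]) changes <- changes + 1L
    }
    best <- min(best, changes)
    if (best == 0L) break
  }
  best
}

# phangorn phyDat for a char_matrix under the package's glyph conventions
# (independent scoring path for cross-checks)
phangorn_data <- function(m) {
  contrast <- rbind(diag(4), matrix(1, 2, 4, byrow = TRUE))
  rownames(contrast) <- c("0", "1", "2", "3", "?", "-")
  colnames(contrast) <- c("0", "1", "2", "3")
  sym <- m$symbols
  # explicit sets are not handled by the base contrast table; expand any
  # '&' cells and braced sets into extra contrast rows
  specials <- setdiff(unique(as.vector(sym)), rownames(contrast))
  for (sp in specials) {
    states <- if (sp == "&") mask_to_states(m$states[which(sym == sp)[1L]])
              else as.integer(strsplit(gsub("[{}()]", "", sp), "")[[1L]])
    newrow <- as.integer(0:3 %in% states)
    contrast <- rbind(contrast, newrow)
    rownames(contrast)[nrow(contrast)] <- sp
  }
  phangorn::phyDat(sym, type = "USER", contrast = contrast)
}

skip_if_no_phangorn <- function() testthat::skip_if_not_installed("phangorn")
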