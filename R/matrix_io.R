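# Character-matrix container, parsing, validation and writing.
#
# A `char_matrix` stores the raw cell glyphs alongside per-cell effective
# state-sets (integer bitmasks, bit k = state k).  Missing ('?') and, under
# the default gap policy, inapplicable ('-') cells resolve to the set of
# states observed among determinate cells of the same column, so that they
# are free to take any observed state during optimization.

MAX_STATES <- 5L  # states 0..3 plus an optional gap-as-new-state

#' Construct a character matrix object
#'
#' Low-level constructor; most users will call [parse_matrix()] or
#' [arminid_matrix()] instead.
#'
#' @param symbols character matrix (taxa x characters) of cell glyphs:
#'   `"0".."3"`, `"?"` (missing), `"-"` (inapplicable), `"&"` (ambiguous
#'   glyph of unknown states), or a braced set such as `"{01}"`
#'   (polymorphic/uncertain).
#' @param taxa taxon names (unique, one per row).
#' @param defs optional data frame of character metadata with columns
#'   `index` and `name` (see [arminid_characters()]).
#' @param gap treatment of `-`: `"missing"` (resolve to the observed column
#'   states, the usual treatment for standard data) or `"newstate"` (a fifth
#'   state of its own).
#' @param amb treatment of the bare `&` glyph: `"observed"` (ambiguous over
#'   all states observed in the column) or an integer vector of explicit
#'   states, e.g. `c(0, 1)`.
#' @param provenance free-text source tag.
#' @return an object of class `char_matrix` with elements `taxa`, `symbols`,
#'   `states` (bitmask matrix), `n_char`, `defs`, `policy`, `provenance`.
#' @export
char_matrix <- function(symbols, taxa = rownames(symbols), defs = NULL,
                        gap = c("missing", "newstate"), amb = "observed",
                        provenance = "constructed") {
  gap <- match.arg(gap)
  if (is.null(taxa)) stop("taxon names are required")
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa))
    stop("duplicate taxon name: ", taxa[duplicated(taxa)][1L])
  if (!is.matrix(symbols)) symbols <- matrix(symbols, nrow = length(taxa))
  if (nrow(symbols) != length(taxa))
    stop("symbols must have one row per taxon")
  rownames(symbols) <- taxa
  m <- structure(
    list(taxa = taxa, symbols = symbols, n_char = ncol(symbols),
         states = NULL, defs = defs,
         policy = list(gap = gap, amb = amb),
         provenance = provenance),
    class = "char_matrix")
  m$states <- resolve_states(m)
  validate_matrix(m)
  m
}

# glyph -> candidate state integers, NA for policy-dependent glyphs
.cell_states <- function(glyph) {
  if (grepl("^[0-9]$", glyph)) return(as.integer(glyph))
  if (grepl("^[{(][0-9]+[})]$", glyph))
    return(as.integer(strsplit(gsub("[{}()]", "", glyph), "")[[1L]]))
  NA_integer_
}

#' Cell kinds of a character matrix
#'
#' @param m a `char_matrix`.
#' @return character matrix with entries `"determinate"`, `"polymorphic"`,
#'   `"missing"`, `"inapplicable"`.
#' @export
cell_kinds <- function(m) {
  k <- m$symbols
  k[] <- "determinate"
  k[m$symbols == "?"] <- "missing"
  k[m$symbols == "-"] <- "inapplicable"
  k[m$symbols == "&" | grepl("^[{(]", m$symbols)] <- "polymorphic"
  k
}

# Resolve every cell to a non-empty effective state-set bitmask.
resolve_states <- function(m) {
  sym <- m$symbols
  n <- nrow(sym); nc <- ncol(sym)
  states <- matrix(0L, n, nc, dimnames = list(m$taxa, NULL))
  gap_new <- identical(m$policy$gap, "newstate")
  amb <- m$policy$amb
  for (j in seq_len(nc)) {
    col <- sym[, j]
    det <- grepl("^[0-9]$", col)
    obs <- sort(unique(as.integer(col[det])))
    if (gap_new && any(col == "-")) obs <- sort(unique(c(obs, 4L)))
    if (any(obs > 4L)) stop("state symbol > 4 in character ", j)
    obs_mask <- if (length(obs)) sum(bitwShiftL(1L, obs)) else 1L
    for (i in seq_len(n)) {
      g <- col[i]
      mask <- if (grepl("^[0-9]$", g)) {
        bitwShiftL(1L, as.integer(g))
      } else if (g == "?") {
        obs_mask
      } else if (g == "-") {
        if (gap_new) bitwShiftL(1L, 4L) else obs_mask
      } else if (g == "&") {
        if (identical(amb, "observed")) obs_mask
        else sum(bitwShiftL(1L, as.integer(amb)))
      } else if (grepl("^[{(][0-9]+[})]$", g)) {
        sum(bitwShiftL(1L, .cell_states(g)))
      } else {
        stop(sprintf("illegal symbol '%s' at taxon '%s', character %d",
                     g, m$taxa[i], j))
      }
      if (mask == 0L) stop("empty state set at taxon ", m$taxa[i],
                           ", character ", j)
      states[i, j] <- mask
    }
  }
  states
}

validate_matrix <- function(m) {
  stopifnot(length(m$taxa) == nrow(m$symbols),
            m$n_char == ncol(m$symbols))
  if (!is.null(m$defs)) {
    if (!all(c("index", "name") %in% names(m$defs)))
      stop("defs must have columns 'index' and 'name'")
    if (nrow(m$defs) != m$n_char)
      stop("defs has ", nrow(m$defs), " rows but the matrix has ",
           m$n_char, " characters")
  }
  invisible(m)
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("char_matrix: %d taxa x %d characters (%s)\n",
              length(x$taxa), x$n_char, x$provenance))
  kinds <- table(factor(cell_kinds(x),
                        c("determinate", "polymorphic", "missing",
                          "inapplicable")))
  cat(sprintf("  cells: %d determinate, %d polymorphic, %d missing, %d inapplicable\n",
              kinds[["determinate"]], kinds[["polymorphic"]],
              kinds[["missing"]], kinds[["inapplicable"]]))
  cat(sprintf("  policies: gap=%s, amb=%s\n", x$policy$gap,
              paste(x$policy$amb, collapse = ",")))
  invisible(x)
}

#' Parse a discrete character matrix
#'
#' Reads a taxon-by-character matrix in one of three dialects:
#' \describe{
#'   \item{bespoke}{one taxon per line: name, whitespace, contiguous symbol
#'     string.  Lines starting with `#` and blank lines are skipped.}
#'   \item{nexus}{a NEXUS `DATA`/`CHARACTERS` block with a `MATRIX`
#'     command (`MISSING=?`, `GAP=-`; `{..}`/`(..)` groups supported;
#'     non-interleaved).}
#'   \item{tnt}{a TNT `xread` block.}
#' }
#'
#' @param text matrix text (single string or character vector of lines), or
#'   a file path via `file`.
#' @param dialect input dialect.
#' @param file path to read instead of `text`.
#' @inheritParams char_matrix
#' @return a [char_matrix()].
#' @export
parse_matrix <- function(text = NULL, dialect = c("bespoke", "nexus", "tnt"),
                         file = NULL, gap = c("missing", "newstate"),
                         amb = "observed", defs = NULL,
                         provenance = NULL) {
  dialect <- match.arg(dialect)
  gap <- match.arg(gap)
  if (!is.null(file)) text <- readLines(file, warn = FALSE)
  if (is.null(text) || !length(text) || !any(nzchar(text)))
    stop("empty matrix text")
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  rows <- switch(dialect,
                 bespoke = .parse_bespoke(text),
                 nexus   = .parse_nexus(text),
                 tnt     = .parse_tnt(text))
  sym <- .rows_to_symbols(rows$taxa, rows$strings, rows$nchar_declared)
  char_matrix(sym, taxa = rows$taxa, defs = defs, gap = gap, amb = amb,
              provenance = provenance %||% paste0("parsed:", dialect))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split a contiguous symbol string into cell glyphs ({..}/(..)  kept whole)
.tokenize_cells <- function(s, taxon) {
  out <- character(0)
  i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- regexpr(close, substr(s, i, n), fixed = TRUE)
      if (j < 0) stop("unbalanced '", ch, "' in row for taxon '", taxon, "'")
      out <- c(out, substr(s, i, i + j - 1L))
      i <- i + j
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

.rows_to_symbols <- function(taxa, strings, nchar_declared = NULL) {
  if (anyDuplicated(taxa))
    stop("duplicate taxon name: ", taxa[duplicated(taxa)][1L])
  cells <- mapply(.tokenize_cells, strings, taxa, SIMPLIFY = FALSE)
  lens <- lengths(cells)
  nc <- nchar_declared %||% lens[1L]
  if (any(lens != nc)) {
    bad <- which(lens != nc)[1L]
    stop(sprintf("ragged matrix: taxon '%s' has %d cells, expected %d",
                 taxa[bad], lens[bad], nc))
  }
  sym <- do.call(rbind, cells)
  rownames(sym) <- taxa
  sym
}

.parse_bespoke <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty matrix text")
  parts <- regmatches(lines, regexpr("[ \t]+", lines), invert = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("cannot parse line: '", lines[bad][1L], "'")
  list(taxa = vapply(parts, `[`, "", 1L),
       strings = vapply(parts, `[`, "", 2L),
       nchar_declared = NULL)
}

.parse_nexus <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  if (!grepl("#NEXUS", txt, ignore.case = TRUE))
    stop("not a NEXUS file (missing #NEXUS header)")
  ntax <- .nexus_number(txt, "NTAX")
  nchar <- .nexus_number(txt, "NCHAR")
  mat <- regmatches(txt, regexpr("(?is)MATRIX\\s*\n.*?;", txt, perl = TRUE))
  if (!length(mat)) stop("no MATRIX command found")
  body <- sub("(?is)^MATRIX\\s*\n", "", mat, perl = TRUE)
  body <- sub(";\\s*$", "", body)
  rows <- strsplit(body, "\n")[[1L]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows) & !startsWith(rows, "[")]
  parts <- regmatches(rows, regexpr("[ \t]+", rows), invert = TRUE)
  if (any(lengths(parts) != 2L))
    stop("cannot parse NEXUS matrix row: '", rows[lengths(parts) != 2L][1L], "'")
  taxa <- gsub("^'(.*)'$", "\\1", vapply(parts, `[`, "", 1L))
  if (!is.null(ntax) && length(taxa) != ntax)
    stop("NEXUS declares NTAX=", ntax, " but matrix has ", length(taxa), " rows")
  list(taxa = taxa, strings = vapply(parts, `[`, "", 2L),
       nchar_declared = nchar)
}

.nexus_number <- function(txt, key) {
  m <- regmatches(txt, regexpr(paste0("(?i)", key, "\\s*=\\s*[0-9]+"), txt,
                               perl = TRUE))
  if (!length(m)) return(NULL)
  as.integer(sub(".*=\\s*", "", m))
}

.parse_tnt <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  m <- regmatches(txt, regexpr("(?is)xread.*?;", txt, perl = TRUE))
  if (!length(m)) stop("no xread block found")
  body <- sub("(?is)^xread\\s*", "", m, perl = TRUE)
  body <- sub("^'[^']*'\\s*", "", body)  # optional title
  body <- sub(";\\s*$", "", body)
  rows <- strsplit(body, "\n")[[1L]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]
  dims <- strsplit(rows[1L], "[ \t]+")[[1L]]
  if (length(dims) != 2L || anyNA(suppressWarnings(as.integer(dims))))
    stop("malformed xread dimensions line: '", rows[1L], "'")
  nchar <- as.integer(dims[1L]); ntax <- as.integer(dims[2L])
  rows <- rows[-1L]
  parts <- regmatches(rows, regexpr("[ \t]+", rows), invert = TRUE)
  if (any(lengths(parts) != 2L))
    stop("cannot parse xread row: '", rows[lengths(parts) != 2L][1L], "'")
  taxa <- vapply(parts, `[`, "", 1L)
  if (length(taxa) != ntax)
    stop("xread declares ", ntax, " taxa but has ", length(taxa), " rows")
  list(taxa = taxa, strings = vapply(parts, `[`, "", 2L),
       nchar_declared = nchar)
}

#' Write a character matrix
#'
#' Round-trip safe: `parse_matrix(write_matrix(m, dialect = d), dialect = d)`
#' recovers the same taxa, cell kinds and effective state-sets.  The bare
#' `&` glyph is preserved in the bespoke dialect and exported as the braced
#' set it resolves to in NEXUS and TNT.
#'
#' @param m a [char_matrix()].
#' @param dialect output dialect.
#' @param file optional path; when `NULL` the text is returned invisibly.
#' @return the matrix text, invisibly when written to a file.
#' @export
write_matrix <- function(m, dialect = c("nexus", "tnt", "bespoke"),
                         file = NULL) {
  dialect <- match.arg(dialect)
  if (!length(m$taxa)) stop("nothing to write: matrix has no taxa")
  sym <- m$symbols
  if (dialect != "bespoke" && any(sym == "&")) {
    # export resolved set explicitly so foreign readers see valid symbols
    for (i in which(sym == "&")) {
      col <- (i - 1L) %/% nrow(sym) + 1L; row <- (i - 1L) %% nrow(sym) + 1L
      ss <- mask_to_states(m$states[row, col])
      sym[row, col] <- paste0("{", paste(ss, collapse = ""), "}")
    }
  }
  rows <- apply(sym, 1L, paste, collapse = "")
  name_w <- max(nchar(m$taxa)) + 2L
  padded <- formatC(m$taxa, width = -name_w)
  body <- paste0(padded, rows)
  out <- switch(dialect,
    bespoke = body,
    nexus = c("#NEXUS", "BEGIN DATA;",
              sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(m$taxa), m$n_char),
              "  FORMAT DATATYPE=STANDARD SYMBOLS=\"0123\" MISSING=? GAP=-;",
              "  MATRIX", paste0("    ", body), "  ;", "END;"),
    tnt = c(sprintf("xread %d %d", m$n_char, length(m$taxa)), body, ";"))
  txt <- paste(out, collapse = "\n")
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}

#' States in a bitmask
#' @param mask integer bitmask.
#' @return integer vector of states.
#' @export
mask_to_states <- function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:4)) > 0L) - 1L

#' Parsimony-informative characters
#'
#' A character is parsimony-informative under unordered costs when at least
#' two of its determinate states are each present in at least two taxa.
#'
#' @param m a [char_matrix()].
#' @return integer vector of 1-based character indices.
#' @export
informative_characters <- function(m) {
  kinds <- cell_kinds(m)
  which(vapply(seq_len(m$n_char), function(j) {
    det <- kinds[, j] == "determinate"
    tab <- table(m$symbols[det, j])
    sum(tab >= 2L) >= 2L
  }, logical(1L)))
}

#' Subset a character matrix by taxa
#'
#' Preserves character order and metadata; effective state-sets are
#' recomputed relative to the states observed within the subset.
#'
#' @param m a [char_matrix()].
#' @param taxa taxon names to keep (aliases resolved via `aliases`).
#' @param aliases optional two-column data frame (`variant`, `canonical`).
#' @return a [char_matrix()] over the selected taxa.
#' @export
subset_matrix <- function(m, taxa, aliases = NULL) {
  taxa <- as.character(taxa)
  if (!is.null(aliases)) {
    hit <- match(taxa, aliases$variant)
    taxa[!is.na(hit)] <- aliases$canonical[hit[!is.na(hit)]]
  }
  missing <- setdiff(taxa, m$taxa)
  if (length(missing)) {
    near <- vapply(missing, function(x) {
      d <- adist(x, m$taxa)
      paste(m$taxa[order(d)][1:2], collapse = ", ")
    }, "")
    stop("unknown taxa: ",
         paste(sprintf("'%s' (closest: %s)", missing, near), collapse = "; "))
  }
  char_matrix(m$symbols[taxa, , drop = FALSE], taxa = taxa, defs = m$defs,
              gap = m$policy$gap, amb = m$policy$amb,
              provenance = paste0(m$provenance, ":subset"))
}

# ---- packaged Arminidae fixture --------------------------------------------

#' The packaged Arminidae character matrix
#'
#' Loads the 78-taxon, 43-character morphological matrix of the Arminidae
#' and their outgroups.  By default the two bare `&` cells (characters 22
#' and 25) are read as uncertainty between states 0 and 1, the
#' interpretation consistent with the published ensemble statistics of this
#' dataset; pass `amb = "observed"` for the conservative full-ambiguity
#' reading.
#'
#' @inheritParams char_matrix
#' @return a [char_matrix()] with 78 taxa and 43 characters.
#' @export
arminid_matrix <- function(amb = c(0L, 1L), gap = "missing") {
  path <- system.file("extdata", "arminid_matrix.txt", package = "mpclad",
                      mustWork = TRUE)
  parse_matrix(file = path, dialect = "bespoke", gap = gap, amb = amb,
               defs = arminid_characters(),
               provenance = "arminidae_table")
}

#' Character metadata for the Arminidae matrix
#' @return data frame with columns `index`, `name`, `states` (compact
#'   `"0=label; 1=label"` form), `n_states`.
#' @export
arminid_characters <- function() {
  path <- system.file("extdata", "characters.tsv", package = "mpclad",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Taxon group labels for the Arminidae matrix
#'
#' Families/suborders used in clade tests: the outgroup root, Doridina,
#' Tritoniidae, Proctonotidae, the remaining arminine outgroups, and the
#' three arminid partitions (Armina, Dermatobranchus, Histiomena).
#'
#' @return data frame with columns `taxon`, `group`.
#' @export
arminid_groups <- function() {
  path <- system.file("extdata", "taxon_groups.tsv", package = "mpclad",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Spelling aliases for Arminidae taxon names
#' @return data frame with columns `variant`, `canonical`.
#' @export
arminid_aliases <- function() {
  path <- system.file("extdata", "taxon_aliases.tsv", package = "mpclad",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
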