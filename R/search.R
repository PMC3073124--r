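# Heuristic and exact maximum-parsimony search: random-addition stepwise
# starting trees, TBR (or restricted SPR/NNI-like) branch swapping with a
# retained-tree buffer, and exact branch-and-bound for small taxon sets.

#' Search configuration
#'
#' @param replicates number of random-addition + branch-swapping replicates.
#' @param seed integer RNG seed; every stochastic choice (addition order,
#'   tie-breaks) derives from it.
#' @param swap branch-swapping neighborhood: `"tbr"` (bisect every edge,
#'   reconnect across every edge pair), `"spr"` (prune and regraft), or
#'   `"nni"` (regrafts restricted to edges adjacent to the original
#'   attachment).
#' @param maxtrees cap on the retained optimal-tree buffer.
#' @param auto_grow if `TRUE`, the buffer grows past `maxtrees` instead of
#'   flagging `hit_maxtrees`.
#' @param order taxon addition order: `"random"` or `"as-is"`.
#' @param plateau cap on the pool of equally parsimonious trees explored
#'   when branch swapping stalls (swapping continues on retained
#'   equal-length trees, which lets the search walk across plateaus); 0
#'   disables plateau exploration.
#' @return object of class `search_config`.
#' @export
search_config <- function(replicates = 10L, seed = 1L,
                          swap = c("tbr", "spr", "nni"),
                          maxtrees = 100L, auto_grow = FALSE,
                          order = c("random", "as-is"), plateau = 300L) {
  swap <- match.arg(swap); order <- match.arg(order)
  replicates <- as.integer(replicates); maxtrees <- as.integer(maxtrees)
  stopifnot(replicates >= 1L, maxtrees >= 1L, is.finite(seed))
  structure(list(replicates = replicates, seed = as.integer(seed),
                 swap = swap, maxtrees = maxtrees, auto_grow = auto_grow,
                 order = order, plateau = as.integer(plateau)),
            class = "search_config")
}

.swap_mode <- function(swap) match(swap, c("nni", "spr", "tbr")) - 1L

# build a phylo from an engine edge matrix
.engine_phylo <- function(edge, taxa) {
  n <- length(taxa)
  structure(list(edge = edge, Nnode = max(edge[, 1L]) - n,
                 tip.label = taxa),
            class = "phylo")
}

#' Stepwise-addition starting tree
#'
#' Builds a binary tree by inserting taxa one at a time at the attachment
#' edge minimizing the Fitch length, ties broken uniformly from the seeded
#' stream.
#'
#' @param m a [char_matrix()].
#' @param seed integer seed.
#' @param order `"random"` (seeded shuffle) or `"as-is"` (matrix row order).
#' @return a `phylo` with attribute `length` (its parsimony length).
#' @export
stepwise_addition <- function(m, seed = 1L, order = c("random", "as-is")) {
  order <- match.arg(order)
  n <- length(m$taxa)
  if (n < 3L) stop("need at least 3 taxa")
  ord <- if (order == "random") {
    set.seed(seed); sample.int(n)
  } else seq_len(n)
  res <- cpp_stepwise(m$states, ord - 1L, as.integer(seed))
  tr <- .engine_phylo(res$edge, m$taxa)
  attr(tr, "length") <- res$length
  tr
}

#' Heuristic maximum-parsimony search
#'
#' For each replicate, builds a random-addition starting tree and swaps
#' (TBR by default) to a local optimum; equally optimal distinct topologies
#' are pooled across replicates and the retained buffer is itself swapped
#' on until no new optimal topology appears or `maxtrees` is hit.
#'
#' @param m a [char_matrix()].
#' @param config a [search_config()].
#' @param forbid_clade optional character vector of taxa: the search is
#'   constrained to trees NOT containing that bipartition (used for Bremer
#'   decay).
#' @return object of class `mp_search`: `best_length`, `trees` (a
#'   `multiPhylo` of distinct optimal topologies), `hit_maxtrees`,
#'   `log` (per-replicate data frame), `config`.
#' @export
heuristic_search <- function(m, config = search_config(),
                             forbid_clade = NULL) {
  n <- length(m$taxa)
  if (n < 4L) {
    tr <- stepwise_addition(m, seed = config$seed, order = "as-is")
    return(structure(list(best_length = attr(tr, "length"),
                          trees = .as_multiphylo(list(tr)),
                          hit_maxtrees = FALSE,
                          log = data.frame(), config = config),
                     class = "mp_search"))
  }
  forbid0 <- integer(0)
  if (!is.null(forbid_clade)) {
    forbid0 <- match(forbid_clade, m$taxa)
    if (anyNA(forbid0)) stop("forbid_clade contains unknown taxa")
    forbid0 <- forbid0 - 1L
  }
  set.seed(config$seed)
  rep_seeds <- sample.int(2^20, config$replicates)
  best <- Inf; best_trees <- list(); best_keys <- character(0)
  log <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    start <- stepwise_addition(m, seed = rep_seeds[r],
                               order = config$order)
    res <- cpp_tbr(m$states, start$edge, rep_seeds[r], forbid0,
                   mode = .swap_mode(config$swap),
                   plateau_cap = config$plateau)
    log[[r]] <- data.frame(replicate = r, seed = rep_seeds[r],
                           start_length = res$start_length,
                           end_length = res$length,
                           improvements = res$improvements,
                           examined = res$examined)
    if (res$length <= best) {
      tr <- .engine_phylo(res$edge, m$taxa)
      key <- topology_key(tr)
      if (res$length < best) {
        best <- res$length; best_trees <- list(tr); best_keys <- key
      } else if (!key %in% best_keys) {
        best_trees <- c(best_trees, list(tr)); best_keys <- c(best_keys, key)
      }
    }
  }
  hit <- FALSE
  if (is.null(forbid_clade)) {
    exp <- .expand_optimal(m, best_trees, best_keys, best, config)
    best_trees <- exp$trees; hit <- exp$hit
  }
  structure(list(best_length = as.integer(best),
                 trees = .as_multiphylo(best_trees),
                 hit_maxtrees = hit,
                 log = do.call(rbind, log), config = config),
            class = "mp_search")
}

# breadth-first expansion of the optimal set by equal-length TBR neighbors
.expand_optimal <- function(m, trees, keys, best, config) {
  cap <- if (config$auto_grow) .Machine$integer.max else config$maxtrees
  queue <- trees
  hit <- FALSE
  while (length(queue) && length(trees) < cap) {
    tr <- queue[[1L]]; queue <- queue[-1L]
    nb <- cpp_equal_neighbors(m$states, tr$edge, as.integer(best),
                              cap = 4L * config$maxtrees)
    for (e in nb) {
      cand <- .engine_phylo(e, m$taxa)
      key <- topology_key(cand)
      if (!key %in% keys) {
        keys <- c(keys, key)
        trees <- c(trees, list(cand))
        queue <- c(queue, list(cand))
        if (length(trees) >= cap) { hit <- TRUE; break }
      }
    }
  }
  if (length(queue)) hit <- TRUE
  list(trees = trees, keys = keys, hit = hit && !config$auto_grow)
}

.as_multiphylo <- function(trees) {
  class(trees) <- "multiPhylo"
  trees
}

#' @export
print.mp_search <- function(x, ...) {
  cat(sprintf("mp_search: best length %d, %d retained tree%s%s\n",
              x$best_length, length(x$trees),
              if (length(x$trees) == 1L) "" else "s",
              if (x$hit_maxtrees) " (maxtrees cap hit)" else ""))
  if (nrow(x$log))
    cat(sprintf("  %d replicate(s), end lengths %s\n", nrow(x$log),
                paste(sort(unique(x$log$end_length)), collapse = ", ")))
  invisible(x)
}

#' Exact search by branch and bound
#'
#' Provably finds all optimal unrooted binary topologies by depth-first
#' taxon insertion with length-bound pruning.  Guarded to small taxon sets;
#' use [heuristic_search()] beyond the guard.
#'
#' @param m a [char_matrix()].
#' @param max_taxa guard rail (default 12).
#' @param maxtrees cap on the collected optimal set.
#' @return an `mp_search` with attribute `exact = TRUE`.
#' @export
branch_and_bound <- function(m, max_taxa = 12L, maxtrees = 100000L) {
  n <- length(m$taxa)
  if (n > max_taxa)
    stop(n, " taxa exceed the branch-and-bound guard (", max_taxa,
         "); use heuristic_search()")
  if (n < 3L) stop("need at least 3 taxa")
  # achievable upper bound from a quick heuristic pass
  upper <- if (n >= 4L) {
    start <- stepwise_addition(m, seed = 1L, order = "as-is")
    cpp_tbr(m$states, start$edge, 1L, integer(0), mode = 2L)$length
  } else {
    attr(stepwise_addition(m, seed = 1L, order = "as-is"), "length")
  }
  res <- cpp_branch_and_bound(m$states, as.integer(upper),
                              as.integer(maxtrees))
  trees <- lapply(res$trees, .engine_phylo, taxa = m$taxa)
  out <- structure(list(best_length = res$best,
                        trees = .as_multiphylo(trees),
                        hit_maxtrees = isTRUE(res$overflow),
                        log = data.frame(), config = NULL),
                   class = "mp_search")
  attr(out, "exact") <- TRUE
  out
}

#' Enumerate all topologies up to a length ceiling
#'
#' Exhaustive (pruned) enumeration of unrooted binary topologies whose
#' parsimony length does not exceed `ceiling`; the workhorse behind
#' sweep-style Bremer support and the small-instance oracles.
#'
#' @param m a [char_matrix()].
#' @param ceiling maximum length to retain.
#' @param max_taxa guard rail (default 10).
#' @param maxtrees cap on the collected set.
#' @return list with `lengths` (integer vector) and `trees` (`multiPhylo`).
#' @export
enumerate_trees <- function(m, ceiling, max_taxa = 10L, maxtrees = 500000L) {
  n <- length(m$taxa)
  if (n > max_taxa)
    stop(n, " taxa exceed the enumeration guard (", max_taxa, ")")
  res <- cpp_enumerate_le(m$states, as.integer(ceiling),
                          as.integer(maxtrees))
  if (isTRUE(res$overflow))
    warning("enumeration hit the maxtrees cap; results are incomplete")
  list(lengths = res$lengths,
       trees = .as_multiphylo(lapply(res$trees, .engine_phylo,
                                     taxa = m$taxa)))
}
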