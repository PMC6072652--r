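# ---- tradeable sets ---------------------------------------------------------

#' Tradeable sets of a pair of adjacency sets
#'
#' For a pair of nodes (i, j) the elements that a trade may move are those in
#' one out-/neighbour set but not the other, excluding the partner node itself
#' so that no self-loop can ever be created:
#' `A_i \ (A_j U {j})` and `A_j \ (A_i U {i})`.
#' For bipartite rows the exclusion terms are dropped (`i = j = NULL`): rows
#' and columns are disjoint node classes, so a self-loop is impossible.
#'
#' @param a_i,a_j integer vectors, the two adjacency sets.
#' @param i,j the indices owning the sets, or `NULL` for bipartite rows.
#' @return A list with components `i` and `j`, the two tradeable sets.
#' @examples
#' tradeable_sets(c(1, 2, 3, 4), c(3, 4, 5, 6, 7, 9), i = 9, j = 8)
#' @export
tradeable_sets <- function(a_i, a_j, i = NULL, j = NULL) {
  if (!is.null(i) && !is.null(j) && i == j)
    stop("invalid pair: i and j must differ")
  a_i <- as.integer(a_i); a_j <- as.integer(a_j)
  list(i = setdiff(a_i, c(a_j, as.integer(j))),
       j = setdiff(a_j, c(a_i, as.integer(i))))
}

# ---- trade proposals --------------------------------------------------------

new_trade_proposal <- function(kind, i, j, old_i, old_j, t_i, t_j,
                               new_i, new_j) {
  structure(
    list(kind = kind, i = i, j = j,
         old_i = sort.int(old_i), old_j = sort.int(old_j),
         tradeable_i = sort.int(t_i), tradeable_j = sort.int(t_j),
         new_i = sort.int(new_i), new_j = sort.int(new_j),
         size = length(setdiff(t_i, new_i))),
    class = "trade_proposal")
}

#' @export
print.trade_proposal <- function(x, ...) {
  cat(sprintf("<%s trade on pair (%d, %d), size %d>\n", x$kind, x$i, x$j, x$size))
  cat("  B_i:", paste(x$new_i, collapse = " "), "\n")
  cat("  B_j:", paste(x$new_j, collapse = " "), "\n")
  invisible(x)
}

# Shared trade core. `exchange`: NULL for a full Curveball trade (uniform
# subset draw), or list(a, b) to force the size-one exchange a <-> b.
propose_trade <- function(graph, i, j, exchange = NULL) {
  kind <- graph_kind(graph)
  n_pick <- if (kind == "bipartite") graph$n_rows else graph$n_nodes
  if (i == j) stop("invalid pair: i and j must differ")
  if (i < 1L || j < 1L || i > n_pick || j > n_pick)
    stop("pair index out of range")
  a <- adj_sets(graph)
  a_i <- a[[i]]; a_j <- a[[j]]
  ts <- if (kind == "bipartite") tradeable_sets(a_i, a_j)
        else tradeable_sets(a_i, a_j, i, j)
  t_i <- ts$i; t_j <- ts$j
  u <- c(t_i, t_j)
  k <- length(t_i)
  if (is.null(exchange)) {
    s <- if (length(u)) u[sample.int(length(u), k)] else integer(0)
  } else {
    stopifnot(exchange$a %in% t_i, exchange$b %in% t_j)
    s <- c(setdiff(t_i, exchange$a), exchange$b)
  }
  new_i <- c(setdiff(a_i, t_i), s)
  new_j <- c(setdiff(a_j, t_j), setdiff(u, s))
  new_trade_proposal(kind, i, j, a_i, a_j, t_i, t_j, new_i, new_j)
}

#' Curveball trades
#'
#' One randomization move of the Curveball family. Two adjacency sets are
#' compared, their tradeable elements pooled, and a uniformly chosen subset of
#' the pool (of the size node i contributed) becomes the new holding of i; j
#' keeps the rest. Degrees are preserved exactly and no self-loop or duplicate
#' edge can arise. The draw may re-select the status quo, giving a trade of
#' size zero (the chain repeats the current network).
#'
#' `directed_trade()` operates on out-neighbour sets; `undirected_trade()`
#' additionally records the symmetric repairs (each node traded from j to i
#' must replace j by i in its own neighbour set, and vice versa), which
#' [apply_trade()] commits; `bipartite_trade()` trades row sets of a
#' biadjacency matrix with no self-loop exclusions.
#'
#' Randomness is drawn from R's global RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param graph the graph to trade on (not modified).
#' @param state a [bipartite_state()].
#' @param i,j node (or row) indices of the selected pair, `i != j`.
#' @param r1,r2 row indices for the bipartite case.
#' @return A `trade_proposal`: the pair, the tradeable sets, the proposed new
#'   sets `new_i`/`new_j`, and the trade `size` (number of elements changing
#'   owner). Commit with [apply_trade()].
#' @seealso [tradeable_sets()], [apply_trade()], [run_chain()]
#' @examples
#' set.seed(1)
#' g <- directed_graph(list(c(2, 3), c(3, 4), 4, 1))
#' p <- directed_trade(g, 1, 2)
#' degrees(apply_trade(g, p))
#' @export
directed_trade <- function(graph, i, j) {
  stopifnot(inherits(graph, "directed_graph"))
  propose_trade(graph, i, j)
}

#' @rdname directed_trade
#' @export
undirected_trade <- function(graph, i, j) {
  stopifnot(inherits(graph, "undirected_graph"))
  propose_trade(graph, i, j)
}

#' @rdname directed_trade
#' @export
bipartite_trade <- function(state, r1, r2) {
  stopifnot(inherits(state, "bipartite_state"))
  propose_trade(state, r1, r2)
}

#' Commit a trade proposal
#'
#' Writes the proposal's new sets into a copy of the graph. For undirected
#' graphs the symmetric repair step is performed: every node k traded from j
#' to i replaces j by i in its own set A_k, and conversely. The proposal must
#' have been generated from the current state of `graph`; a mismatch raises a
#' consistency error.
#'
#' @param graph the graph the proposal was computed from.
#' @param proposal a `trade_proposal`.
#' @return A new graph with the trade applied.
#' @export
apply_trade <- function(graph, proposal) {
  stopifnot(inherits(proposal, "trade_proposal"))
  if (graph_kind(graph) != proposal$kind)
    stop("proposal kind does not match graph kind")
  a <- adj_sets(graph)
  i <- proposal$i; j <- proposal$j
  if (!identical(sort.int(a[[i]]), proposal$old_i) ||
      !identical(sort.int(a[[j]]), proposal$old_j))
    stop("stale proposal: adjacency sets no longer match the proposal's origin")
  a[[i]] <- proposal$new_i
  a[[j]] <- proposal$new_j
  if (proposal$kind == "undirected") {
    gained_i <- setdiff(proposal$new_i, proposal$old_i)
    gained_j <- setdiff(proposal$new_j, proposal$old_j)
    for (k in gained_i) { s <- a[[k]]; s[s == j] <- i; a[[k]] <- sort.int(s) }
    for (k in gained_j) { s <- a[[k]]; s[s == i] <- j; a[[k]] <- sort.int(s) }
  }
  adj_sets(graph) <- a
  graph
}

#' Invert a trade proposal
#'
#' Constructs the proposal that, applied to the traded graph, restores the
#' original: the same pair is selected and the original sets are re-drawn from
#' the (unchanged) tradeable pool. Its existence for every executed trade is
#' the reversibility property underlying the chains' unbiasedness.
#'
#' @param proposal a `trade_proposal`.
#' @return The inverse `trade_proposal`.
#' @export
reverse_proposal <- function(proposal) {
  t_i_new <- setdiff(proposal$new_i, c(proposal$new_j,
                     if (proposal$kind != "bipartite") proposal$j))
  t_j_new <- setdiff(proposal$new_j, c(proposal$new_i,
                     if (proposal$kind != "bipartite") proposal$i))
  if (!setequal(c(t_i_new, t_j_new),
                c(proposal$tradeable_i, proposal$tradeable_j)) ||
      length(t_i_new) != length(proposal$tradeable_i))
    stop("proposal is not reversible: tradeable pool changed")
  new_trade_proposal(proposal$kind, proposal$i, proposal$j,
                     proposal$new_i, proposal$new_j, t_i_new, t_j_new,
                     proposal$old_i, proposal$old_j)
}

# ---- classic switches -------------------------------------------------------

new_switch <- function(kind, before, after) {
  dimnames(before) <- dimnames(after) <- NULL
  structure(list(kind = kind, before = before, after = after),
            class = "cb_switch")
}

#' @export
print.cb_switch <- function(x, ...) {
  fmt <- function(m) paste(sprintf("(%d,%d)", m[, 1L], m[, 2L]), collapse = " ")
  cat(sprintf("<%s switch: %s -> %s>\n", x$kind, fmt(x$before), fmt(x$after)))
  invisible(x)
}

#' Enumerate all valid switches of a graph
#'
#' A switch replaces two edges (x, y), (u, v) by (x, v), (u, y) provided no
#' self-loop and no duplicate edge results. Directed switches keep arc
#' directions; each unordered pair of arcs yields at most one switch. For
#' undirected graphs both re-pairings of each edge pair are examined. For
#' bipartite states a switch swaps the column entries of two rows (the classic
#' checkerboard swap).
#'
#' @param graph a `cb_graph`.
#' @return A list of `cb_switch` objects, each holding `before` and `after`
#'   two-row edge matrices. Empty when no switch is possible (for example on
#'   the oriented triangle).
#' @export
enumerate_switches <- function(graph) {
  kind <- graph_kind(graph)
  e <- edge_set(graph)
  m <- nrow(e)
  out <- list()
  if (m < 2L) return(out)
  keys <- paste(e[, 1L], e[, 2L])
  has <- function(a, b) paste(a, b) %in% keys
  has_und <- function(a, b) has(min(a, b), max(a, b))
  for (p in seq_len(m - 1L)) for (q in seq.int(p + 1L, m)) {
    e1 <- e[p, ]; e2 <- e[q, ]
    if (kind == "undirected") {
      a <- e1[1L]; b <- e1[2L]; c_ <- e2[1L]; d <- e2[2L]
      # two re-pairings: {a,c}{b,d} and {a,d}{b,c}
      for (rp in list(list(c(a, c_), c(b, d)), list(c(a, d), c(b, c_)))) {
        f1 <- rp[[1L]]; f2 <- rp[[2L]]
        if (f1[1L] == f1[2L] || f2[1L] == f2[2L]) next
        if (has_und(f1[1L], f1[2L]) || has_und(f2[1L], f2[2L])) next
        if (setequal(f1, f2)) next
        out[[length(out) + 1L]] <- new_switch(
          kind, rbind(e1, e2, deparse.level = 0),
          rbind(sort.int(f1), sort.int(f2), deparse.level = 0))
      }
    } else {
      # ordered arcs / (row, col) pairs: single re-pairing
      x <- e1[1L]; y <- e1[2L]; u <- e2[1L]; v <- e2[2L]
      ok <- if (kind == "directed") x != v && u != y else x != u && y != v
      if (!ok) next
      if (has(x, v) || has(u, y)) next
      out[[length(out) + 1L]] <- new_switch(
        kind, rbind(e1, e2, deparse.level = 0),
        rbind(c(x, v), c(u, y), deparse.level = 0))
    }
  }
  out
}

#' Apply a switch to a graph
#'
#' @param graph the graph the switch was enumerated from.
#' @param switch a `cb_switch`.
#' @return A new graph with the two edges replaced.
#' @export
apply_switch <- function(graph, switch) {
  stopifnot(inherits(switch, "cb_switch"))
  a <- adj_sets(graph)
  und <- graph_kind(graph) == "undirected"
  for (r in 1:2) {
    x <- switch$before[r, 1L]; y <- switch$before[r, 2L]
    a[[x]] <- setdiff(a[[x]], y)
    if (und) a[[y]] <- setdiff(a[[y]], x)
  }
  for (r in 1:2) {
    x <- switch$after[r, 1L]; y <- switch$after[r, 2L]
    a[[x]] <- sort.int(c(a[[x]], y))
    if (und) a[[y]] <- sort.int(c(a[[y]], x))
  }
  adj_sets(graph) <- a
  graph
}

# ---- switches as size-one trades --------------------------------------------

#' Enumerate the size-one trades realizing a switch
#'
#' Given two graphs that differ by exactly one switch, exhaustively searches
#' all node pairs and all single-element exchanges for trades of size one that
#' transform `g` into `g_prime`. In an undirected network every switch is
#' realized by exactly two distinct trades (the pair owning the switched
#' endpoints, or the pair of switched endpoints trading their owners); in a
#' directed network by at least one.
#'
#' @param g,g_prime two graphs of the same kind with identical degree
#'   sequences differing by one switch. Identical graphs yield an empty list.
#' @return A list of `trade_proposal` objects, each verified to map `g` to
#'   `g_prime`.
#' @export
trades_realizing_switch <- function(g, g_prime) {
  kind <- graph_kind(g)
  if (kind != graph_kind(g_prime)) stop("graphs differ in kind")
  if (!degrees_equal(degrees(g), degrees(g_prime)))
    stop("precondition violated: degree sequences differ")
  if (graph_identical(g, g_prime)) return(list())
  k1 <- edge_keys(g); k2 <- edge_keys(g_prime)
  removed <- setdiff(k1, k2); added <- setdiff(k2, k1)
  if (length(removed) != 2L || length(added) != 2L)
    stop("precondition violated: graphs do not differ by exactly one switch")
  ends <- function(k) unlist(strsplit(k, " ", fixed = TRUE))
  if (!identical(sort(ends(removed)), sort(ends(added))))
    stop("precondition violated: edge difference is not a switch")

  a1 <- adj_sets(g); a2 <- adj_sets(g_prime)
  diff_rows <- which(vapply(seq_along(a1),
                            function(r) !setequal(a1[[r]], a2[[r]]), logical(1)))
  n_pick <- if (kind == "bipartite") g$n_rows else length(a1)
  out <- list()
  for (i in seq_len(n_pick - 1L)) for (j in seq.int(i + 1L, n_pick)) {
    ts <- if (kind == "bipartite") tradeable_sets(a1[[i]], a1[[j]])
          else tradeable_sets(a1[[i]], a1[[j]], i, j)
    if (!length(ts$i) || !length(ts$j)) next
    for (a_el in ts$i) for (b_el in ts$j) {
      if (!all(diff_rows %in% c(i, j, if (kind == "undirected") c(a_el, b_el))))
        next
      p <- propose_trade(g, i, j, exchange = list(a = a_el, b = b_el))
      if (p$size != 1L) next
      cand <- apply_trade(g, p)
      if (graph_identical(cand, g_prime)) out[[length(out) + 1L]] <- p
    }
  }
  out
}
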