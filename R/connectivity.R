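# Directed 3-cycles whose orientation no switch sequence can reverse block
# the switch/trade chains from part of the realization space. They are
# detected before a chain run and re-oriented at random so the directed
# sampler covers every realization.

# ---- detection --------------------------------------------------------------

new_triangle <- function(a, b, c) {
  structure(list(nodes = c(a, b, c),
                 arcs = rbind(c(a, b), c(b, c), c(c, a))),
            class = "cb_triangle")
}

#' @export
print.cb_triangle <- function(x, ...) {
  cat(sprintf("<directed 3-cycle %d -> %d -> %d -> %d>\n",
              x$nodes[1L], x$nodes[2L], x$nodes[3L], x$nodes[1L]))
  invisible(x)
}

#' Find all directed 3-cycles
#'
#' Enumerates every directed 3-cycle a -> b -> c -> a, reported once in the
#' canonical rotation starting at its smallest node. A triple carrying both
#' orientations (possible only with reciprocal arcs) yields two triangles.
#'
#' @param graph a [directed_graph()].
#' @return A list of `cb_triangle` objects.
#' @export
find_directed_3cycles <- function(graph) {
  stopifnot(inherits(graph, "directed_graph"))
  adj <- graph$adj
  n <- graph$n_nodes
  rev_adj <- rep(list(integer(0)), n)
  for (v in seq_len(n)) for (w in adj[[v]])
    rev_adj[[w]] <- c(rev_adj[[w]], v)
  out <- list()
  for (a in seq_len(n)) for (b in adj[[a]]) {
    if (b < a) next
    # closing nodes c with b -> c and c -> a; canonical when a is smallest
    for (c_ in intersect(adj[[b]], rev_adj[[a]])) {
      if (c_ > a) out[[length(out) + 1L]] <- new_triangle(a, b, c_)
    }
  }
  out
}

# ---- frozen test ------------------------------------------------------------

#' Is a directed 3-cycle frozen (non-switchable)?
#'
#' A local surrogate criterion: a 3-cycle is reported frozen when (i) its
#' reversal would still be a simple graph (no reciprocal arc pre-exists) and
#' (ii) none of its three arcs participates in any valid switch with any arc
#' of the graph. For an isolated oriented triangle this is exactly the
#' blocked situation in which no switch or trade can act; on general graphs
#' it is a conservative local test, certified in this package by agreement
#' with the brute-force [reachability_oracle()] on all enumerable test
#' instances rather than by a closed-form theorem.
#'
#' @param triangle a `cb_triangle` from [find_directed_3cycles()].
#' @param graph the [directed_graph()] containing it.
#' @return logical.
#' @export
is_frozen <- function(triangle, graph) {
  stopifnot(inherits(triangle, "cb_triangle"),
            inherits(graph, "directed_graph"))
  e <- edge_set(graph)
  keys <- paste(e[, 1L], e[, 2L])
  tri_keys <- paste(triangle$arcs[, 1L], triangle$arcs[, 2L])
  if (!all(tri_keys %in% keys))
    stop("triangle is not present in the graph")
  # a pre-existing reciprocal arc makes the reversed orientation non-simple:
  # the reversed realization does not exist, so nothing is blocked
  rev_keys <- paste(triangle$arcs[, 2L], triangle$arcs[, 1L])
  if (any(rev_keys %in% keys)) return(FALSE)
  has <- function(a, b) paste(a, b) %in% keys
  for (r in 1:3) {
    x <- triangle$arcs[r, 1L]; y <- triangle$arcs[r, 2L]
    for (q in seq_len(nrow(e))) {
      u <- e[q, 1L]; v <- e[q, 2L]
      if (u == x && v == y) next
      if (x != v && u != y && !has(x, v) && !has(u, y)) return(FALSE)
    }
  }
  TRUE
}

# ---- re-orientation ---------------------------------------------------------

#' Re-orient frozen directed 3-cycles
#'
#' One-shot preprocessing for the directed Curveball chain: every frozen
#' 3-cycle (see [is_frozen()]) independently keeps or reverses its
#' orientation with probability 1/2. Triangles are processed in canonical
#' order against the current state, so overlapping cycles cannot produce an
#' invalid graph; in- and out-degrees are unchanged. Running the chain after
#' this step can reach realizations that switches and trades alone cannot.
#' For purely topological statistics (motifs, nestedness, C-score and the
#' like) the step may be skipped, since those are insensitive to reversing a
#' 3-cycle.
#'
#' @param graph a [directed_graph()].
#' @param seed optional integer seed.
#' @return A graph of the same degrees with frozen triangles randomly
#'   re-oriented.
#' @export
reorient_frozen_triangles <- function(graph, seed = NULL) {
  stopifnot(inherits(graph, "directed_graph"))
  if (!is.null(seed)) set.seed(seed)
  tris <- find_directed_3cycles(graph)
  for (tr in tris) {
    a <- adj_sets(graph)
    present <- all(vapply(1:3, function(r)
      tr$arcs[r, 2L] %in% a[[tr$arcs[r, 1L]]], logical(1)))
    if (!present) next
    if (!is_frozen(tr, graph)) next
    if (sample.int(2L, 1L) == 1L) next  # keep orientation with prob 1/2
    for (r in 1:3) {
      x <- tr$arcs[r, 1L]; y <- tr$arcs[r, 2L]
      a[[x]] <- setdiff(a[[x]], y)
      a[[y]] <- sort.int(c(a[[y]], x))
    }
    adj_sets(graph) <- a
  }
  graph
}

# ---- brute-force reachability -----------------------------------------------

#' Partition a realization space into switch-connectivity classes
#'
#' Exhaustively enumerates every realization of the graph's degree sequence
#' (see [enumerate_realizations()]) and groups them into classes connected by
#' single switches, by breadth-first exploration. This is the independent
#' oracle against which the local [is_frozen()] criterion is certified: a
#' frozen triangle's reversal must land in a different class.
#'
#' Brute force only: refuses instances beyond `max_nodes` nodes or
#' `max_edges` edges.
#'
#' @param graph a `cb_graph` (any kind).
#' @param max_nodes,max_edges instance-size limits.
#' @return A `cb_reachability` list: `space` (the [enumerate_realizations()]
#'   result), `classes` (integer class id per realization), `n_classes`, and
#'   `start_index` (the class containing `graph`).
#' @export
reachability_oracle <- function(graph, max_nodes = 10L, max_edges = 20L) {
  n <- n_pick_of(graph)
  m <- nrow(edge_set(graph))
  if (n > max_nodes || m > max_edges)
    stop(sprintf("instance too large for brute force (%d nodes, %d edges; ",
                 n, m), sprintf("limits %d, %d)", max_nodes, max_edges))
  space <- enumerate_realizations(degrees(graph),
                                  max_nodes = max_nodes,
                                  max_rows = max_nodes, max_cols = max_nodes)
  keys <- space$keys
  classes <- integer(length(keys))
  cls <- 0L
  for (s in seq_along(keys)) {
    if (classes[s] != 0L) next
    cls <- cls + 1L
    queue <- s
    classes[s] <- cls
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      for (sw in enumerate_switches(space$realizations[[cur]])) {
        nb <- apply_switch(space$realizations[[cur]], sw)
        idx <- match(state_key(nb), keys)
        if (is.na(idx)) stop("internal: switch left the realization space")
        if (classes[idx] == 0L) {
          classes[idx] <- cls
          queue <- c(queue, idx)
        }
      }
    }
  }
  start <- match(state_key(graph), keys)
  if (is.na(start)) stop("graph is not a realization of its own degrees?")
  structure(list(space = space, classes = classes, n_classes = cls,
                 start_index = start),
            class = "cb_reachability")
}

#' @export
print.cb_reachability <- function(x, ...) {
  cat(sprintf("<switch reachability: %d realizations in %d class(es)>\n",
              length(x$classes), x$n_classes))
  invisible(x)
}
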