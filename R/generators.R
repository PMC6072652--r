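# ---- random ensembles -------------------------------------------------------

#' Erdős–Rényi G(n, m) networks
#'
#' Samples `m` distinct edges (arcs) uniformly at random among the simple
#' self-loop-free possibilities, via [igraph::sample_gnm()], returned in this
#' package's adjacency-list representation.
#'
#' @param n number of nodes.
#' @param m number of edges; must not exceed the simple-graph capacity
#'   (`n(n-1)/2` undirected, `n(n-1)` directed).
#' @param kind `"directed"` or `"undirected"`.
#' @param seed optional integer seed.
#' @return A [directed_graph()] or [undirected_graph()].
#' @export
er_gnm <- function(n, m, kind = c("directed", "undirected"), seed = NULL) {
  kind <- match.arg(kind)
  cap <- if (kind == "directed") n * (n - 1) else n * (n - 1) / 2
  if (m > cap)
    stop(sprintf("m = %d exceeds the %s simple-graph capacity %d for n = %d",
                 m, kind, cap, n))
  if (!is.null(seed)) set.seed(seed)
  ig <- igraph::sample_gnm(n, m, directed = kind == "directed")
  adj <- igraph::as_adj_list(ig, mode = if (kind == "directed") "out" else "all")
  g <- new_cb_graph(paste0(kind, "_graph"),
                    lapply(adj, as.integer), n, labels = NULL)
  g
}

#' Preferential-attachment networks with low out-degree
#'
#' Sequential attachment emulating the power-law ensembles used for the
#' mixing-time comparison: growth starts from a triangle (oriented for the
#' directed case), and every subsequent node draws its out-degree uniformly
#' from \{1, 2, 3\} and attaches to that many distinct existing nodes with
#' probability proportional to in-degree + 1 (directed) or degree + 1
#' (undirected). All out-degrees therefore lie in \{1, 2, 3\}, which keeps
#' most Curveball trades small — the regime where the Curveball's advantage
#' over single swaps narrows.
#'
#' @param n number of nodes, at least 4.
#' @param kind `"directed"` or `"undirected"`.
#' @param seed optional integer seed.
#' @return A graph of the requested kind.
#' @export
ba_network <- function(n, kind = c("directed", "undirected"), seed = NULL) {
  kind <- match.arg(kind)
  if (n < 4) stop("ba_network requires n >= 4")
  if (!is.null(seed)) set.seed(seed)
  directed <- kind == "directed"
  adj <- rep(list(integer(0)), n)
  adj[[1L]] <- 2L; adj[[2L]] <- 3L; adj[[3L]] <- 1L
  if (!directed) {
    adj[[1L]] <- c(2L, 3L); adj[[2L]] <- c(1L, 3L); adj[[3L]] <- c(1L, 2L)
  }
  in_deg <- rep(0L, n)
  in_deg[1:3] <- if (directed) 1L else 2L
  for (t in 4:n) {
    k <- sample.int(3L, 1L)
    existing <- seq_len(t - 1L)
    w <- in_deg[existing] + 1
    targets <- existing[sample.int(t - 1L, k, prob = w)]
    adj[[t]] <- sort.int(targets)
    in_deg[targets] <- in_deg[targets] + 1L
    if (!directed) {
      for (u in targets) adj[[u]] <- c(adj[[u]], t)
      in_deg[t] <- k
    }
  }
  if (directed) directed_graph(adj, n) else undirected_graph(adj, n)
}

# ---- degree-sequence realization -------------------------------------------

#' Construct one realization of a degree sequence
#'
#' Builds a simple network with exactly the given degrees, after checking the
#' classical realizability condition: Erdős–Gallai (undirected), Gale–Ryser
#' (bipartite), or the Fulkerson-type condition checked constructively by the
#' Kleitman–Wang greedy procedure (directed). Construction is greedy
#' highest-degree-first (Havel–Hakimi and relatives), so the output is
#' deterministic; it is intended as an initial state for the chains, not as a
#' random sample.
#'
#' @param ds a [degree_sequence()] (or the result of [degrees()]).
#' @return A graph whose [degrees()] equal `ds`.
#' @export
realize_degree_sequence <- function(ds) {
  stopifnot(inherits(ds, "cb_degrees"))
  switch(ds$kind,
         undirected = realize_undirected(ds$degree),
         directed = realize_directed(ds$out_degree, ds$in_degree),
         bipartite = realize_bipartite(ds$row_sums, ds$col_sums))
}

realize_undirected <- function(d) {
  d <- as.integer(d); n <- length(d)
  if (sum(d) %% 2L != 0L)
    stop("unrealizable degree sequence: odd degree sum (parity condition)")
  if (any(d > n - 1L))
    stop("unrealizable degree sequence: a degree exceeds n - 1")
  ds <- sort(d, decreasing = TRUE)
  for (k in seq_len(n)) {
    lhs <- sum(ds[seq_len(k)])
    rhs <- k * (k - 1L) + sum(pmin(ds[-seq_len(k)], k))
    if (lhs > rhs)
      stop(sprintf(
        "unrealizable degree sequence: Erdős–Gallai condition fails at k = %d", k))
  }
  # Havel-Hakimi on original indices
  adj <- rep(list(integer(0)), n)
  res <- d
  repeat {
    v <- which.max(res)
    if (res[v] == 0L) break
    others <- setdiff(order(res, decreasing = TRUE), v)
    targets <- setdiff(others, adj[[v]])
    targets <- targets[res[targets] > 0L][seq_len(res[v])]
    if (anyNA(targets)) stop("internal: Havel-Hakimi ran out of targets")
    for (u in targets) {
      adj[[v]] <- c(adj[[v]], u); adj[[u]] <- c(adj[[u]], v)
    }
    res[targets] <- res[targets] - 1L
    res[v] <- 0L
  }
  undirected_graph(adj, n)
}

realize_directed <- function(out_d, in_d) {
  out_d <- as.integer(out_d); in_d <- as.integer(in_d)
  n <- length(out_d)
  if (sum(out_d) != sum(in_d))
    stop("unrealizable degree sequence: sum(out) != sum(in)")
  if (any(out_d > n - 1L) || any(in_d > n - 1L))
    stop("unrealizable degree sequence: a degree exceeds n - 1")
  # Kleitman-Wang: connect each positive out-degree to the targets that are
  # largest in residual in-degree, ties broken by larger residual out-degree
  # (the lexicographic order the theorem requires); succeeds iff the sequence
  # is digraphical (Fulkerson-Chen-Anstee condition).
  adj <- rep(list(integer(0)), n)
  res_in <- in_d
  res_out <- out_d
  ord <- order(out_d, decreasing = TRUE)
  for (v in ord) {
    k <- out_d[v]
    if (k == 0L) next
    res_out[v] <- 0L
    cand <- setdiff(seq_len(n), v)
    cand <- cand[res_in[cand] > 0L]
    cand <- cand[order(res_in[cand], res_out[cand], decreasing = TRUE)]
    if (length(cand) < k)
      stop("unrealizable degree sequence: Fulkerson-type condition violated ",
           "(Kleitman-Wang construction failed)")
    targets <- cand[seq_len(k)]
    adj[[v]] <- sort.int(targets)
    res_in[targets] <- res_in[targets] - 1L
  }
  if (any(res_in != 0L))
    stop("unrealizable degree sequence: Fulkerson-type condition violated")
  g <- directed_graph(adj, n)
  stopifnot(degrees_equal(degrees(g),
                          degree_sequence("directed", out_degree = out_d,
                                          in_degree = in_d)))
  g
}

realize_bipartite <- function(r, cs) {
  r <- as.integer(r); cs <- as.integer(cs)
  if (sum(r) != sum(cs))
    stop("unrealizable margins: sum(row_sums) != sum(col_sums)")
  if (any(r > length(cs)) || any(cs > length(r)))
    stop("unrealizable margins: a margin exceeds the opposite dimension")
  rs <- sort(r, decreasing = TRUE)
  for (k in seq_along(rs)) {
    if (sum(rs[seq_len(k)]) > sum(pmin(cs, k)))
      stop(sprintf(
        "unrealizable margins: Gale–Ryser condition fails at k = %d", k))
  }
  rows <- vector("list", length(r))
  res <- cs
  for (i in order(r, decreasing = TRUE)) {
    if (r[i] == 0L) { rows[[i]] <- integer(0); next }
    cand <- order(res, decreasing = TRUE)
    cand <- cand[res[cand] > 0L]
    rows[[i]] <- sort.int(cand[seq_len(r[i])])
    res[rows[[i]]] <- res[rows[[i]]] - 1L
  }
  bipartite_state(rows, length(cs))
}

# ---- named fixtures ---------------------------------------------------------

#' Small named example networks
#'
#' A collection of hand-built graphs used throughout the documentation and
#' tests: the oriented triangle (the minimal network on which no switch or
#' trade can act), adjacency pairs reconstructing the worked trade examples
#' (the directed pair exposes tradeable nodes \{1, 2, 5, 6, 7\} for the pair
#' `(8, 9)`; the undirected pair exposes \{1, 2, 4, 5\} for the pair
#' `(6, 7)`), and the small enumerable realization spaces used by the
#' uniformity diagnostics.
#'
#' @return A named list of graphs. Elements with a `pair` attribute mark the
#'   node pair the example trade selects.
#' @export
curveball_fixtures <- function() {
  fig1 <- directed_graph(c(rep(list(integer(0)), 7),
                           list(c(1L, 2L, 3L, 4L), c(8L, 3L, 4L, 5L, 6L, 7L))))
  attr(fig1, "pair") <- c(8L, 9L)
  fig2 <- undirected_graph(list(6L, 6L, c(6L, 7L), 7L, 7L,
                                c(7L, 3L, 1L, 2L), c(6L, 3L, 4L, 5L)))
  attr(fig2, "pair") <- c(6L, 7L)
  list(
    oriented_triangle = directed_graph(list(2L, 3L, 1L)),
    reversed_triangle = directed_graph(list(3L, 1L, 2L)),
    fig1_directed_pair = fig1,
    fig2_undirected_pair = fig2,
    two_triangles = directed_graph(list(2L, 3L, 1L, 5L, 6L, 4L)),
    triangle_plus_arc = directed_graph(list(2L, 3L, 1L, 5L, integer(0))),
    triangle_plus_out_arc = directed_graph(list(c(2L, 4L), 3L, 1L, integer(0))),
    bip_3x3_diagonal = bipartite_state(list(1L, 2L, 3L), 3L),
    und_5cycle = undirected_graph(list(c(2L, 5L), c(1L, 3L), c(2L, 4L),
                                       c(3L, 5L), c(4L, 1L))),
    dir_4cycle = directed_graph(list(2L, 3L, 4L, 1L)))
}
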