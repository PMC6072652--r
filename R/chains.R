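# ---- low-level step loops ---------------------------------------------------

# Advance a Curveball / size-1-restricted chain on an adjacency-set list.
# Every pair draw is one step; size-0 outcomes repeat the current state.
# Returns list(sets, sizes) where sizes is per-step (only if collect_sizes).
chain_steps <- function(sets, n_pick, n_steps, kind, variant,
                        collect_sizes = FALSE) {
  restricted <- variant == "restricted_size1"
  unimode <- kind != "bipartite"
  undirected <- kind == "undirected"
  sizes <- if (collect_sizes) integer(n_steps) else NULL
  for (step in seq_len(n_steps)) {
    p <- sample.int(n_pick, 2L)
    i <- p[1L]; j <- p[2L]
    a_i <- sets[[i]]; a_j <- sets[[j]]
    if (unimode) {
      t_i <- a_i[!(a_i %in% a_j) & a_i != j]
      t_j <- a_j[!(a_j %in% a_i) & a_j != i]
    } else {
      t_i <- a_i[!(a_i %in% a_j)]
      t_j <- a_j[!(a_j %in% a_i)]
    }
    ni <- length(t_i); nj <- length(t_j)
    if (ni == 0L || nj == 0L) next
    if (restricted) {
      s_i <- c(t_i[-sample.int(ni, 1L)], t_j[sample.int(nj, 1L)])
      sz <- 1L
    } else {
      u <- c(t_i, t_j)
      s_i <- u[sample.int(ni + nj, ni)]
      sz <- sum(!(t_i %in% s_i))
      if (sz == 0L) { if (collect_sizes) sizes[step] <- 0L; next }
    }
    keep_i <- a_i[!(a_i %in% t_i)]
    pool <- c(t_i, t_j)
    s_j <- pool[!(pool %in% s_i)]
    sets[[i]] <- c(keep_i, s_i)
    sets[[j]] <- c(a_j[!(a_j %in% t_j)], s_j)
    if (undirected) {
      gained_i <- s_i[s_i %in% t_j]
      gained_j <- s_j[s_j %in% t_i]
      for (k in gained_i) { s <- sets[[k]]; s[s == j] <- i; sets[[k]] <- s }
      for (k in gained_j) { s <- sets[[k]]; s[s == i] <- j; sets[[k]] <- s }
    }
    if (collect_sizes) sizes[step] <- sz
  }
  list(sets = sets, sizes = sizes)
}

# Advance a classic switching chain on an edge matrix. Every attempt is one
# step; invalid proposals leave the state unchanged. `accepted` records, per
# step, 1 for a committed switch and 0 for a rejection.
switch_steps <- function(edges, n_steps, kind, collect_sizes = FALSE) {
  m <- nrow(edges)
  sizes <- if (collect_sizes) integer(n_steps) else NULL
  if (m < 2L) return(list(edges = edges, sizes = sizes))
  e1 <- edges[, 1L]; e2 <- edges[, 2L]
  for (step in seq_len(n_steps)) {
    p <- sample.int(m, 2L)
    x <- e1[p[1L]]; y <- e2[p[1L]]
    u <- e1[p[2L]]; v <- e2[p[2L]]
    if (kind == "undirected") {
      # a--b, c--d sampled with random orientation, rewired to a--d, c--b
      if (sample.int(2L, 1L) == 1L) { t <- x; x <- y; y <- t }
      if (sample.int(2L, 1L) == 1L) { t <- u; u <- v; v <- t }
    }
    if (kind == "directed" || kind == "undirected") {
      if (x == v || u == y) next
    } else {
      if (x == u || y == v) next
    }
    if (kind == "undirected") {
      a1 <- min(x, v); b1 <- max(x, v)
      a2 <- min(u, y); b2 <- max(u, y)
      if (any(e1 == a1 & e2 == b1) || any(e1 == a2 & e2 == b2)) next
      if (a1 == a2 && b1 == b2) next
      e1[p[1L]] <- a1; e2[p[1L]] <- b1
      e1[p[2L]] <- a2; e2[p[2L]] <- b2
    } else {
      if (any(e1 == x & e2 == v) || any(e1 == u & e2 == y)) next
      e2[p[1L]] <- v
      e2[p[2L]] <- y
    }
    if (collect_sizes) sizes[step] <- 1L
  }
  list(edges = cbind(e1, e2, deparse.level = 0), sizes = sizes)
}

graph_from_sets <- function(template, sets) {
  if (inherits(template, "bipartite_state")) {
    template$rows <- lapply(sets, sort.int)
  } else {
    template$adj <- lapply(sets, sort.int)
  }
  template
}

graph_from_edges <- function(template, edges) {
  und <- inherits(template, "undirected_graph")
  n <- if (inherits(template, "bipartite_state")) template$n_rows
       else template$n_nodes
  sets <- rep(list(integer(0)), n)
  for (r in seq_len(nrow(edges))) {
    sets[[edges[r, 1L]]] <- c(sets[[edges[r, 1L]]], edges[r, 2L])
    if (und) sets[[edges[r, 2L]]] <- c(sets[[edges[r, 2L]]], edges[r, 1L])
  }
  graph_from_sets(template, sets)
}

n_pick_of <- function(graph) {
  if (inherits(graph, "bipartite_state")) graph$n_rows else graph$n_nodes
}

# fraction of the reference's adjacency entries missing from `sets`
sets_perturbation <- function(ref_sets, sets) {
  total <- sum(lengths(ref_sets))
  if (total == 0L) return(0)
  miss <- 0L
  for (v in seq_along(ref_sets))
    miss <- miss + sum(!(ref_sets[[v]] %in% sets[[v]]))
  miss / total
}

# ---- single exported steps --------------------------------------------------

#' Single baseline moves
#'
#' `switching_step()` attempts one classic switch: two edges are drawn
#' uniformly at random and their ends rewired if and only if the result is
#' still a simple graph; a rejected attempt returns the graph unchanged but
#' counts as a step. `restricted_size1_step()` draws a node pair exactly as
#' the Curveball does, but exchanges exactly one uniformly chosen element of
#' each tradeable set (size-one trade), or does nothing when either set is
#' empty — a swap baseline in trade clothing, used to isolate the benefit of
#' multi-element trades in mixing comparisons.
#'
#' @param graph a `cb_graph`.
#' @return The graph after one step.
#' @export
switching_step <- function(graph) {
  e <- edge_set(graph)
  r <- switch_steps(e, 1L, graph_kind(graph))
  graph_from_edges(graph, r$edges)
}

#' @rdname switching_step
#' @export
restricted_size1_step <- function(graph) {
  r <- chain_steps(adj_sets(graph), n_pick_of(graph), 1L, graph_kind(graph),
                   "restricted_size1")
  graph_from_sets(graph, r$sets)
}

# ---- chain runner -----------------------------------------------------------

#' Run a randomization Markov chain
#'
#' Runs `n_steps` moves of a degree-preserving chain on a copy of `graph`.
#' Variants:
#' * `"curveball"` — full trades between uniformly drawn unordered pairs of
#'   node (row) adjacency sets;
#' * `"restricted_size1"` — same pair selection, but at most one element is
#'   exchanged per step;
#' * `"switching"` — classic edge switching on uniformly drawn edge pairs.
#'
#' Every attempt is one step, including size-zero trades and rejected
#' switches, so perturbation traces of different variants are comparable at
#' equal step counts. The chain has no hidden state: the same seed and input
#' always reproduce the same result.
#'
#' @param graph the starting network (not modified).
#' @param n_steps number of steps; 0 returns a copy of the input.
#' @param variant `"curveball"`, `"restricted_size1"` or `"switching"`.
#' @param record_every if not `NULL`, record the perturbation score
#'   ([perturbation_score()]) against the starting network every this many
#'   steps; must not exceed `n_steps`.
#' @param seed optional integer seed applied via [set.seed()].
#' @return A `chain_result` list: `final_graph`, `trace` (data frame with
#'   `step`, `score`, or `NULL`), `accepted_sizes` (table of per-step trade
#'   sizes; for the switching variant 1 = accepted, 0 = rejected), and
#'   `n_zero_trades`.
#' @examples
#' g <- er_gnm(30, 60, kind = "directed", seed = 7)
#' res <- run_chain(g, 500, variant = "curveball", record_every = 100, seed = 1)
#' res$trace
#' @export
run_chain <- function(graph, n_steps,
                      variant = c("curveball", "restricted_size1", "switching"),
                      record_every = NULL, seed = NULL) {
  variant <- match.arg(variant)
  kind <- graph_kind(graph)
  stopifnot(n_steps >= 0)
  if (!is.null(record_every)) {
    stopifnot(record_every >= 1)
    if (record_every > n_steps)
      stop("record_every exceeds n_steps: no steps would be recorded")
  }
  if (!is.null(seed)) set.seed(seed)

  use_edges <- variant == "switching"
  ref_sets <- adj_sets(graph)
  state <- if (use_edges) edge_set(graph) else ref_sets
  n_pick <- n_pick_of(graph)
  sizes <- integer(0)
  trace_steps <- integer(0); trace_scores <- numeric(0)

  chunk <- record_every %||% n_steps
  done <- 0L
  while (done < n_steps) {
    k <- min(chunk, n_steps - done)
    if (use_edges) {
      r <- switch_steps(state, k, kind, collect_sizes = TRUE)
      state <- r$edges
    } else {
      r <- chain_steps(state, n_pick, k, kind, variant, collect_sizes = TRUE)
      state <- r$sets
    }
    sizes <- c(sizes, r$sizes)
    done <- done + k
    if (!is.null(record_every) && done %% record_every == 0L) {
      cur <- if (use_edges) adj_sets(graph_from_edges(graph, state)) else state
      trace_steps <- c(trace_steps, done)
      trace_scores <- c(trace_scores, sets_perturbation(ref_sets, cur))
    }
  }

  final <- if (use_edges) graph_from_edges(graph, state)
           else graph_from_sets(graph, state)
  structure(
    list(final_graph = final,
         trace = if (is.null(record_every)) NULL
                 else data.frame(step = trace_steps, score = trace_scores),
         accepted_sizes = table(sizes),
         n_zero_trades = sum(sizes == 0L)),
    class = "chain_result")
}

#' @export
print.chain_result <- function(x, ...) {
  cat("<chain_result>\n")
  print(x$final_graph)
  cat("  zero-size steps:", x$n_zero_trades, "\n")
  if (!is.null(x$trace))
    cat("  final perturbation:", x$trace$score[nrow(x$trace)], "\n")
  invisible(x)
}

# ---- samplers for uniformity testing ---------------------------------------

#' Samplers over the realization space
#'
#' `chain_sampler()` returns a closure that walks a single chain and yields
#' its state every `spacing` steps after an initial `burn_in` — the standard
#' way to collect near-independent samples from one long run.
#' `independent_sampler()` yields one network per call by re-running the full
#' sampling procedure from the start graph: optional random re-orientation of
#' frozen directed 3-cycles ([reorient_frozen_triangles()]) followed by
#' `n_steps` chain steps. The independent form is required whenever the
#' re-orientation preprocessing is part of the procedure, since that step is
#' performed once per sample, not once per chain step.
#'
#' @param graph the starting network.
#' @param variant chain variant, as in [run_chain()].
#' @param burn_in steps discarded before the first sample.
#' @param spacing steps between successive samples.
#' @param n_steps chain steps per independent sample.
#' @param reorient logical; re-orient frozen triangles before each sample
#'   (directed graphs only).
#' @return A function of no arguments returning a graph.
#' @seealso [uniformity_test()]
#' @export
chain_sampler <- function(graph, variant = "curveball", burn_in = 1000L,
                          spacing = 10L) {
  kind <- graph_kind(graph)
  n_pick <- n_pick_of(graph)
  sets <- adj_sets(graph)
  warmed <- FALSE
  function() {
    if (!warmed) {
      sets <<- chain_steps(sets, n_pick, burn_in, kind, variant)$sets
      warmed <<- TRUE
    }
    sets <<- chain_steps(sets, n_pick, spacing, kind, variant)$sets
    graph_from_sets(graph, sets)
  }
}

#' @rdname chain_sampler
#' @export
independent_sampler <- function(graph, variant = "curveball", n_steps = 100L,
                                reorient = FALSE) {
  kind <- graph_kind(graph)
  n_pick <- n_pick_of(graph)
  function() {
    g <- if (reorient) reorient_frozen_triangles(graph) else graph
    sets <- chain_steps(adj_sets(g), n_pick, n_steps, kind, variant)$sets
    graph_from_sets(g, sets)
  }
}
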