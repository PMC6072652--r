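# ---- perturbation score -----------------------------------------------------

#' Perturbation score between two same-degree networks
#'
#' The convergence proxy used by the mixing diagnostics: the fraction of the
#' original network's edges that are absent from the randomized network.
#' Pairs are ordered for directed graphs, unordered for undirected graphs and
#' (row, column) for bipartite states. Because both graphs have the same
#' number of edges, the score is symmetric in its arguments.
#'
#' @param original,randomized two graphs of the same kind with identical
#'   degree sequences (anything else is a precondition error).
#' @return A fraction in \[0, 1\] (0 for an edgeless pair).
#' @export
perturbation_score <- function(original, randomized) {
  if (graph_kind(original) != graph_kind(randomized))
    stop("precondition violated: graphs differ in kind")
  if (!degrees_equal(degrees(original), degrees(randomized)))
    stop("precondition violated: degree sequences differ")
  k1 <- edge_keys(original)
  if (!length(k1)) return(0)
  sum(!(k1 %in% edge_keys(randomized))) / length(k1)
}

# ---- state-space enumeration ------------------------------------------------

#' Enumerate all realizations of a degree sequence
#'
#' Exhaustively lists every simple network with exactly the given degrees:
#' 0/1 matrices with the given margins (bipartite), zero-diagonal 0/1
#' matrices with the given out/in sums (directed), or symmetric zero-diagonal
#' matrices with the given degrees (undirected). Realizations are returned in
#' a canonical order (sorted by their flattened-matrix bit-string key), so
#' indices are stable across runs. Intended as the uniformity oracle; refuses
#' instances beyond the brute-force limits.
#'
#' @param ds a [degree_sequence()].
#' @param max_rows,max_cols bipartite size limits (default 4 x 4).
#' @param max_nodes unimode node limit (default 7).
#' @return A `cb_state_space` list: `kind`, `degree_sequence`,
#'   `realizations` (list of graphs) and `keys` (canonical key per
#'   realization). An unrealizable sequence yields an empty space.
#' @export
enumerate_realizations <- function(ds, max_rows = 4L, max_cols = 4L,
                                   max_nodes = 7L) {
  stopifnot(inherits(ds, "cb_degrees"))
  graphs <- switch(ds$kind,
    bipartite = {
      if (length(ds$row_sums) > max_rows || length(ds$col_sums) > max_cols)
        stop("instance exceeds the bipartite enumeration limits")
      enum_margin_rows(ds$row_sums, ds$col_sums, forbid_diag = FALSE,
                       build = function(rows)
                         bipartite_state(rows, length(ds$col_sums)))
    },
    directed = {
      if (length(ds$out_degree) > max_nodes)
        stop("instance exceeds the unimode enumeration limit")
      enum_margin_rows(ds$out_degree, ds$in_degree, forbid_diag = TRUE,
                       build = function(rows)
                         directed_graph(rows, length(ds$out_degree)))
    },
    undirected = {
      if (length(ds$degree) > max_nodes)
        stop("instance exceeds the unimode enumeration limit")
      enum_undirected(ds$degree)
    })
  keys <- vapply(graphs, state_key, character(1))
  ord <- order(keys, method = "radix")
  structure(list(kind = ds$kind, degree_sequence = ds,
                 realizations = graphs[ord], keys = keys[ord]),
            class = "cb_state_space")
}

#' @export
print.cb_state_space <- function(x, ...) {
  cat(sprintf("<%s realization space: %d realization(s)>\n", x$kind,
              length(x$realizations)))
  invisible(x)
}

# Recursive row-by-row enumeration of 0/1 matrices with fixed row and column
# sums; `forbid_diag` excludes cell (i, i) (directed out-lists).
enum_margin_rows <- function(row_sums, col_sums, forbid_diag, build) {
  n_rows <- length(row_sums); n_cols <- length(col_sums)
  out <- list()
  rows <- vector("list", n_rows)
  recurse <- function(i, res) {
    if (i > n_rows) {
      if (all(res == 0L)) out[[length(out) + 1L]] <<- build(rows)
      return(invisible())
    }
    cand <- which(res > 0L)
    if (forbid_diag) cand <- setdiff(cand, i)
    k <- row_sums[i]
    if (length(cand) < k) return(invisible())
    for (sel in combinations(cand, k)) {
      res2 <- res
      res2[sel] <- res2[sel] - 1L
      # remaining rows can still absorb every residual column sum
      if (max(res2) > n_rows - i) next
      rows[[i]] <<- sel
      recurse(i + 1L, res2)
    }
  }
  recurse(1L, as.integer(col_sums))
  out
}

# all k-subsets of v as a list (k = 0 gives the empty selection);
# the length(v) == k case also guards combn's scalar-v interpretation
combinations <- function(v, k) {
  if (k == 0L) return(list(integer(0)))
  if (length(v) < k) return(list())
  if (length(v) == k) return(list(v))
  m <- utils::combn(v, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

enum_undirected <- function(deg) {
  n <- length(deg)
  out <- list()
  adj <- rep(list(integer(0)), n)
  recurse <- function(i, res) {
    if (i > n) {
      if (all(res == 0L)) out[[length(out) + 1L]] <<- undirected_graph(adj, n)
      return(invisible())
    }
    # res[i] must be covered by neighbours among j > i
    cand <- which(res > 0L)
    cand <- cand[cand > i]
    k <- res[i]
    if (length(cand) < k) return(invisible())
    for (sel in combinations(cand, k)) {
      res2 <- res
      res2[sel] <- res2[sel] - 1L
      res2[i] <- 0L
      old <- adj[c(i, sel)]
      adj[[i]] <<- c(adj[[i]], sel)
      for (u in sel) adj[[u]] <<- c(adj[[u]], i)
      recurse(i + 1L, res2)
      adj[c(i, sel)] <<- old
    }
  }
  recurse(1L, as.integer(deg))
  out
}

# ---- uniformity testing -----------------------------------------------------

#' Chi-square uniformity test over an enumerated realization space
#'
#' Draws `n_samples` networks from a sampler (see [chain_sampler()] and
#' [independent_sampler()]), maps each to its index in the enumerated space,
#' and tests the counts against the uniform expectation with Pearson's
#' chi-square. A sample that is not a member of the space raises a
#' contamination error — it signals a broken move, never a statistical
#' fluctuation.
#'
#' @param sampler a function of no arguments returning a graph.
#' @param space a `cb_state_space` from [enumerate_realizations()].
#' @param n_samples number of retained samples.
#' @param seed optional integer seed.
#' @return A `cb_uniformity` list: `counts`, `expected`, `statistic`, `df`,
#'   `p_value`, `n_samples`.
#' @export
uniformity_test <- function(sampler, space, n_samples, seed = NULL) {
  stopifnot(inherits(space, "cb_state_space"), n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- length(space$keys)
  counts <- integer(k)
  for (s in seq_len(n_samples)) {
    g <- sampler()
    idx <- match(state_key(g), space$keys)
    if (is.na(idx))
      stop("contamination: sampler produced a graph outside the realization ",
           "space (degree sequence or simplicity violated)")
    counts[idx] <- counts[idx] + 1L
  }
  expected <- rep(n_samples / k, k)
  stat <- sum((counts - expected)^2 / expected)
  df <- k - 1L
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(counts = counts, expected = expected, statistic = stat,
                 df = df, p_value = p, n_samples = n_samples),
            class = "cb_uniformity")
}

#' @export
print.cb_uniformity <- function(x, ...) {
  cat(sprintf("<uniformity: X^2 = %.3f on %d df, p = %.4g, n = %d>\n",
              x$statistic, x$df, x$p_value, x$n_samples))
  cat("  counts:", paste(x$counts, collapse = " "), "\n")
  invisible(x)
}

# ---- convergence experiment -------------------------------------------------

#' Perturbation-trace comparison of Curveball and size-one chains
#'
#' For each replicate network of a generated ensemble, runs the Curveball
#' chain and the size-one-restricted baseline from the same start, recording
#' the perturbation score against the start every `record_every` steps. The
#' long-format trace table and its per-variant mean/sd summary reproduce the
#' mixing comparison at a configurable scale.
#'
#' @param model `"er"` or `"ba"`.
#' @param kind `"directed"` or `"undirected"`.
#' @param n_range integer interval for the node count, e.g. `c(100, 1000)`.
#' @param d_range integer interval for the ER edges-per-node multiplier
#'   (edges = d * n); ignored for `"ba"`.
#' @param replicates number of networks.
#' @param n_steps,record_every chain length and recording interval.
#' @param seed integer seed driving network generation and both chains.
#' @param variants chain variants to compare.
#' @return A `cb_convergence` list: `traces` (data frame `network_id`,
#'   `variant`, `step`, `score`), `summary` (mean and sd per variant and
#'   step) and `networks` (one row per generated network).
#' @export
convergence_experiment <- function(model = c("er", "ba"),
                                   kind = c("directed", "undirected"),
                                   n_range = c(100L, 1000L),
                                   d_range = c(5L, 50L),
                                   replicates = 10L,
                                   n_steps = 25000L, record_every = 100L,
                                   seed = NULL,
                                   variants = c("curveball",
                                                "restricted_size1")) {
  model <- match.arg(model)
  kind <- match.arg(kind)
  if (record_every > n_steps)
    stop("record_every exceeds n_steps: the requested trace would be empty")
  if (!is.null(seed)) set.seed(seed)
  chain_seeds <- matrix(sample.int(.Machine$integer.max,
                                   replicates * length(variants)),
                        nrow = replicates)
  traces <- vector("list", replicates * length(variants))
  nets <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    n <- if (n_range[1L] == n_range[2L]) n_range[1L]
         else sample(seq.int(n_range[1L], n_range[2L]), 1L)
    if (model == "er") {
      d <- if (d_range[1L] == d_range[2L]) d_range[1L]
           else sample(seq.int(d_range[1L], d_range[2L]), 1L)
      m <- min(d * n, if (kind == "directed") n * (n - 1L) else n * (n - 1L) %/% 2L)
      g <- er_gnm(n, m, kind)
    } else {
      g <- ba_network(n, kind)
      m <- nrow(edge_set(g))
    }
    nets[[r]] <- data.frame(network_id = r, model = model, kind = kind,
                            n = n, m = m)
    for (vi in seq_along(variants)) {
      res <- run_chain(g, n_steps, variant = variants[vi],
                       record_every = record_every,
                       seed = chain_seeds[r, vi])
      tr <- res$trace
      tr$network_id <- r
      tr$variant <- variants[vi]
      traces[[(r - 1L) * length(variants) + vi]] <- tr
    }
  }
  traces <- do.call(rbind, traces)[, c("network_id", "variant", "step", "score")]
  agg_m <- stats::aggregate(score ~ variant + step, traces, mean)
  agg_s <- stats::aggregate(score ~ variant + step, traces, stats::sd)
  names(agg_m)[3L] <- "mean_score"
  agg_m$sd_score <- agg_s$score
  structure(list(traces = traces, summary = agg_m,
                 networks = do.call(rbind, nets)),
            class = "cb_convergence")
}

#' @export
print.cb_convergence <- function(x, ...) {
  cat(sprintf("<convergence experiment: %d network(s), %d variant(s), %d recorded step(s)>\n",
              nrow(x$networks), length(unique(x$traces$variant)),
              length(unique(x$traces$step))))
  invisible(x)
}
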