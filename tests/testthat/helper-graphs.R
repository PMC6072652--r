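# Shared helpers: small random graphs and invariant assertions.

random_graph <- function(kind, n = 10L, m = NULL) {
  if (kind == "bipartite") {
    nr <- n; nc <- n
    rows <- lapply(seq_len(nr), function(i) {
      k <- sample.int(nc - 1L, 1L)
      sort.int(sample.int(nc, k))
    })
    bipartite_state(rows, nc)
  } else {
    if (is.null(m))
      m <- sample.int(if (kind == "directed") n * (n - 1L) %/% 3L
                      else n * (n - 1L) %/% 4L, 1L)
    er_gnm(n, max(m, 2L), kind)
  }
}

random_pair <- function(graph) {
  n <- if (graph_kind(graph) == "bipartite") graph$n_rows else graph$n_nodes
  sample.int(n, 2L)
}

random_trade <- function(graph, pair = random_pair(graph)) {
  switch(graph_kind(graph),
         directed = directed_trade(graph, pair[1L], pair[2L]),
         undirected = undirected_trade(graph, pair[1L], pair[2L]),
         bipartite = bipartite_trade(graph, pair[1L], pair[2L]))
}

expect_valid <- function(graph) {
  rep <- validate_graph(graph)
  expect_true(rep$ok, info = paste(rep$violations, collapse = "; "))
}
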