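test_that("tradeable_sets applies the self-loop exclusions", {
  # reconstruction of the directed worked example: A_i on nodes 1..4,
  # A_j containing i plus 3..7; the tradeable pool is {1, 2} vs {5, 6, 7}
  ts <- tradeable_sets(c(1L, 2L, 3L, 4L), c(9L, 3L, 4L, 5L, 6L, 7L),
                       i = 9L, j = 8L)
  expect_equal(ts$i, c(1L, 2L))
  expect_equal(ts$j, c(5L, 6L, 7L))
  expect_setequal(c(ts$i, ts$j), c(1L, 2L, 5L, 6L, 7L))

  expect_equal(tradeable_sets(c(1L, 2L), c(1L, 2L), 3L, 4L),
               list(i = integer(0), j = integer(0)))
  # j itself is never tradeable
  expect_equal(tradeable_sets(4L, integer(0), i = 3L, j = 4L),
               list(i = integer(0), j = integer(0)))
  expect_error(tradeable_sets(1L, 2L, i = 5L, j = 5L), "invalid pair")
})

test_that("directed trade reproduces the worked example when the draw picks 5 and 7", {
  fx <- curveball_fixtures()$fig1_directed_pair
  found <- FALSE
  set.seed(101)
  for (rep in 1:200) {
    p <- directed_trade(fx, 8L, 9L)
    expect_equal(length(p$new_i), 4L)
    expect_equal(length(p$new_j), 6L)
    if (setequal(p$new_i, c(3L, 4L, 5L, 7L))) {
      found <- TRUE
      expect_setequal(p$new_j, c(8L, 3L, 4L, 6L, 1L, 2L))
      expect_equal(p$size, 2L)
    }
  }
  expect_true(found)  # the {5,7} draw has probability C(2,2)... ~1/10 per rep
})

test_that("an empty tradeable pool yields a size-zero proposal, not an error", {
  tri <- curveball_fixtures()$oriented_triangle
  p <- directed_trade(tri, 1L, 2L)
  expect_equal(p$size, 0L)
  expect_equal(p$new_i, p$old_i)
  expect_equal(p$new_j, p$old_j)
  expect_true(graph_identical(apply_trade(tri, p), tri))
})

test_that("undirected trade keeps mutual adjacency fixed and repairs symmetry", {
  fx <- curveball_fixtures()$fig2_undirected_pair
  set.seed(7)
  for (rep in 1:50) {
    p <- undirected_trade(fx, 6L, 7L)
    # i and j are adjacent: the mutual entries are never traded
    expect_true(7L %in% p$new_i)
    expect_true(6L %in% p$new_j)
    g2 <- apply_trade(fx, p)
    expect_valid(g2)
  }
  # force the size-one exchange 1 <-> 4 from the worked example
  p14 <- curveballr:::propose_trade(fx, 6L, 7L, exchange = list(a = 1L, b = 4L))
  expect_equal(p14$size, 1L)
  g2 <- apply_trade(fx, p14)
  expect_setequal(g2$adj[[6L]], c(7L, 3L, 2L, 4L))
  expect_setequal(g2$adj[[7L]], c(6L, 3L, 5L, 1L))
  # step (d): node 4 now lists 6 (was 7), node 1 lists 7 (was 6)
  expect_equal(g2$adj[[4L]], 6L)
  expect_equal(g2$adj[[1L]], 7L)
  expect_valid(g2)
})

test_that("bipartite trades have no exclusion terms", {
  s <- bipartite_state(list(c(1L, 2L), c(2L, 3L)), 3L)
  set.seed(5)
  outcomes <- character(0)
  for (rep in 1:100) {
    p <- bipartite_trade(s, 1L, 2L)
    expect_equal(p$tradeable_i, 1L)
    expect_equal(p$tradeable_j, 3L)
    outcomes <- c(outcomes, paste(p$new_i, collapse = ","))
  }
  # the pool {1, 3} is redistributed: either the status quo or the swap
  expect_setequal(unique(outcomes), c("1,2", "2,3"))
  # 3x3 identity, rows 1 and 2: the only move swaps the two entries
  idd <- curveball_fixtures()$bip_3x3_diagonal
  p <- bipartite_trade(idd, 1L, 2L)
  expect_setequal(c(p$tradeable_i, p$tradeable_j), c(1L, 2L))
})

test_that("apply_trade rejects stale proposals", {
  g <- er_gnm(10, 20, "directed", seed = 2)
  p <- directed_trade(g, 1L, 2L)
  h <- g
  h$adj[[1L]] <- h$adj[[1L]][-1L]  # row 1 no longer matches the proposal
  expect_error(apply_trade(h, p), "stale")
  expect_error(apply_trade(bipartite_state(list(1L, 2L), 2L), p),
               "kind does not match")
})

test_that("trades preserve degrees, simplicity and symmetry (property)", {
  set.seed(17)
  for (kind in c("directed", "undirected", "bipartite")) {
    g <- random_graph(kind, n = 12L)
    d0 <- degrees(g)
    for (rep in 1:300) {
      p <- random_trade(g)
      g <- apply_trade(g, p)
    }
    expect_valid(g)
    expect_equal(degrees(g), d0)
  }
})

test_that("every executed trade is reversible through the same pair (property)", {
  set.seed(23)
  for (kind in c("directed", "undirected", "bipartite")) {
    g <- random_graph(kind, n = 10L)
    for (rep in 1:100) {
      p <- random_trade(g)
      h <- apply_trade(g, p)
      inv <- reverse_proposal(p)
      expect_true(graph_identical(apply_trade(h, inv), g))
      g <- h
    }
  }
})

test_that("the subset draw is uniform over all k-subsets of the pool", {
  # pool {1,2} u {5,6,7}: C(5,2) = 10 possible new holdings for i
  g <- directed_graph(c(rep(list(integer(0)), 7),
                        list(c(1L, 2L, 3L, 4L), c(8L, 3L, 4L, 5L, 6L, 7L))))
  set.seed(29)
  n_draws <- 100000L
  counts <- table(vapply(seq_len(n_draws), function(r) {
    p <- directed_trade(g, 8L, 9L)
    paste(setdiff(p$new_i, c(3L, 4L)), collapse = ",")
  }, character(1)))
  expect_length(counts, 10L)
  expected <- n_draws / 10
  stat <- sum((as.numeric(counts) - expected)^2 / expected)
  p_val <- pchisq(stat, df = 9, lower.tail = FALSE)
  expect_gt(p_val, 0.001)
})

test_that("switch enumeration matches brute-force facts", {
  fx <- curveball_fixtures()
  expect_length(enumerate_switches(fx$oriented_triangle), 0L)
  # two disjoint arcs: exactly one switch
  two <- directed_graph(list(2L, integer(0), 4L, integer(0)))
  sw <- enumerate_switches(two)
  expect_length(sw, 1L)
  expect_equal(sw[[1L]]$after, rbind(c(1L, 4L), c(3L, 2L)))
  # labelled 4-cycle: the two opposite edge pairs each admit the diagonal
  # re-pairing (the adjacent pairs all collide)
  c4 <- undirected_graph(list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(3L, 1L)))
  sw4 <- enumerate_switches(c4)
  expect_length(sw4, 2L)
  for (s in sw4) {
    g2 <- apply_switch(c4, s)
    expect_valid(g2)
    expect_equal(degrees(g2), degrees(c4))
  }
})

test_that("switches applied to random graphs stay valid and degree-preserving", {
  set.seed(37)
  for (kind in c("directed", "undirected")) {
    for (rep in 1:20) {
      g <- random_graph(kind, n = 8L)
      sw <- enumerate_switches(g)
      if (!length(sw)) next
      g2 <- apply_switch(g, sw[[sample.int(length(sw), 1L)]])
      expect_valid(g2)
      expect_equal(degrees(g2), degrees(g))
    }
  }
})

test_that("each undirected switch is realized by exactly two size-one trades", {
  set.seed(41)
  for (rep in 1:30) {
    g <- random_graph("undirected", n = 9L)
    sw <- enumerate_switches(g)
    if (!length(sw)) next
    gp <- apply_switch(g, sw[[sample.int(length(sw), 1L)]])
    trades <- trades_realizing_switch(g, gp)
    expect_length(trades, 2L)
    for (p in trades) {
      expect_equal(p$size, 1L)
      expect_true(graph_identical(apply_trade(g, p), gp))
    }
  }
})

test_that("each directed switch is realized by at least one size-one trade", {
  set.seed(43)
  for (rep in 1:30) {
    g <- random_graph("directed", n = 9L)
    sw <- enumerate_switches(g)
    if (!length(sw)) next
    gp <- apply_switch(g, sw[[sample.int(length(sw), 1L)]])
    trades <- trades_realizing_switch(g, gp)
    expect_gte(length(trades), 1L)
  }
})

test_that("trades_realizing_switch guards its precondition", {
  g <- er_gnm(8, 14, "directed", seed = 5)
  expect_length(trades_realizing_switch(g, g), 0L)
  h <- run_chain(g, 200, "curveball", seed = 6)$final_graph
  ek <- function(x) { e <- edge_set(x); paste(e[, 1L], e[, 2L]) }
  if (length(setdiff(ek(h), ek(g))) > 2) {
    expect_error(trades_realizing_switch(g, h), "precondition")
  } else {
    succeed("short chain stayed within one switch of the start")
  }
  g2 <- er_gnm(8, 13, "directed", seed = 7)
  expect_error(trades_realizing_switch(g, g2), "degree sequences differ")
})
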