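# ---- constructors -----------------------------------------------------------

#' Graph objects with fixed degrees
#'
#' The package operates on three kinds of simple networks, all stored as
#' adjacency lists of integer index sets (1-based, contiguous):
#'
#' * `undirected_graph()` — each undirected edge \{i, j\} is represented twice,
#'   as `j` in the neighbour set of `i` and `i` in the neighbour set of `j`.
#' * `directed_graph()` — the set for node `v` holds its out-neighbours.
#' * `bipartite_state()` — the rows of a binary biadjacency matrix, each row
#'   stored as the set of column indices holding a 1.
#'
#' Self-loops and duplicate edges are forbidden throughout; constructors
#' validate by default (see [validate_graph()]).
#'
#' @param adjacency list of integer vectors, one neighbour (or out-neighbour)
#'   set per node.
#' @param n_nodes number of nodes; defaults to `length(adjacency)`.
#' @param labels optional character vector of node labels, kept for write-back
#'   of edge lists read from files.
#' @param rows list of integer vectors, one set of column indices per row.
#' @param n_cols number of columns of the biadjacency matrix.
#' @param row_labels,col_labels optional label vectors for rows and columns.
#' @param validate if `TRUE` (default) the invariants are checked and a
#'   violation raises an error.
#'
#' @return An object of class `undirected_graph`, `directed_graph` or
#'   `bipartite_state` (all also of class `cb_graph`).
#' @seealso [degrees()], [edge_set()], [validate_graph()], [read_edge_list()]
#' @examples
#' # the oriented triangle 1 -> 2 -> 3 -> 1
#' tri <- directed_graph(list(2L, 3L, 1L))
#' degrees(tri)
#' @export
undirected_graph <- function(adjacency, n_nodes = length(adjacency),
                             labels = NULL, validate = TRUE) {
  g <- new_cb_graph("undirected_graph", adjacency, n_nodes, labels)
  if (validate) assert_valid(g)
  g
}

#' @rdname undirected_graph
#' @export
directed_graph <- function(adjacency, n_nodes = length(adjacency),
                           labels = NULL, validate = TRUE) {
  g <- new_cb_graph("directed_graph", adjacency, n_nodes, labels)
  if (validate) assert_valid(g)
  g
}

#' @rdname undirected_graph
#' @export
bipartite_state <- function(rows, n_cols, row_labels = NULL, col_labels = NULL,
                            validate = TRUE) {
  stopifnot(is.list(rows), length(n_cols) == 1L, n_cols >= 1L)
  g <- structure(
    list(n_rows = length(rows), n_cols = as.integer(n_cols),
         rows = lapply(rows, as_index_set),
         row_labels = row_labels, col_labels = col_labels),
    class = c("bipartite_state", "cb_graph"))
  if (validate) assert_valid(g)
  g
}

new_cb_graph <- function(class, adjacency, n_nodes, labels) {
  stopifnot(is.list(adjacency), n_nodes >= length(adjacency))
  adjacency <- lapply(adjacency, as_index_set)
  if (n_nodes > length(adjacency))
    adjacency <- c(adjacency, rep(list(integer(0)), n_nodes - length(adjacency)))
  structure(list(n_nodes = as.integer(n_nodes), adj = adjacency, labels = labels),
            class = c(class, "cb_graph"))
}

as_index_set <- function(x) {
  x <- as.integer(x)
  sort.int(unique(x))
}

#' Which kind of network is this?
#'
#' @param graph a `cb_graph` object.
#' @return `"undirected"`, `"directed"` or `"bipartite"`.
#' @export
graph_kind <- function(graph) {
  if (inherits(graph, "undirected_graph")) return("undirected")
  if (inherits(graph, "directed_graph")) return("directed")
  if (inherits(graph, "bipartite_state")) return("bipartite")
  stop("not a cb_graph object")
}

# adjacency accessor shared by all kinds: the list the trade operates on
adj_sets <- function(graph) {
  if (inherits(graph, "bipartite_state")) graph$rows else graph$adj
}

`adj_sets<-` <- function(graph, value) {
  if (inherits(graph, "bipartite_state")) graph$rows <- value else graph$adj <- value
  graph
}

# ---- validation -------------------------------------------------------------

#' Check graph invariants
#'
#' Verifies that a graph object is a valid simple network: indices in range,
#' no self-loops, no duplicate entries, and (for undirected graphs) symmetric
#' adjacency. Violations are returned as data, not raised.
#'
#' @param graph a `cb_graph` object.
#' @return A list with `ok` (logical) and `violations` (character vector, one
#'   message per violation found).
#' @examples
#' validate_graph(directed_graph(list(2L, 3L, 1L)))$ok
#' @export
validate_graph <- function(graph) {
  v <- character(0)
  if (inherits(graph, "bipartite_state")) {
    for (i in seq_along(graph$rows)) {
      r <- graph$rows[[i]]
      if (anyDuplicated(r))
        v <- c(v, sprintf("row %d contains duplicate column indices", i))
      if (length(r) && (min(r) < 1L || max(r) > graph$n_cols))
        v <- c(v, sprintf("row %d has column index out of 1..%d", i, graph$n_cols))
    }
  } else {
    n <- graph$n_nodes
    a <- graph$adj
    if (length(a) != n) v <- c(v, "adjacency length differs from n_nodes")
    for (i in seq_along(a)) {
      ai <- a[[i]]
      if (anyDuplicated(ai))
        v <- c(v, sprintf("node %d has duplicate entries (multiple edges)", i))
      if (i %in% ai) v <- c(v, sprintf("self-loop at node %d", i))
      if (length(ai) && (min(ai) < 1L || max(ai) > n))
        v <- c(v, sprintf("node %d has neighbour index out of 1..%d", i, n))
    }
    if (inherits(graph, "undirected_graph") && !length(v)) {
      for (i in seq_along(a)) for (j in a[[i]]) {
        if (!(i %in% a[[j]]))
          v <- c(v, sprintf("asymmetry: %d in A_%d but %d not in A_%d", j, i, i, j))
      }
    }
  }
  list(ok = length(v) == 0L, violations = v)
}

assert_valid <- function(graph) {
  r <- validate_graph(graph)
  if (!r$ok)
    stop("invalid ", graph_kind(graph), " graph: ",
         paste(r$violations, collapse = "; "), call. = FALSE)
  invisible(graph)
}

# ---- degrees ----------------------------------------------------------------

#' Degree sequences
#'
#' `degrees()` extracts the degree sequence preserved by every move in the
#' package: per-node degrees for undirected graphs, (out, in) pairs for
#' directed graphs, and row/column sums for bipartite states.
#' `degree_sequence()` builds one directly, checking the basic consistency
#' conditions (non-negative integers; even sum for undirected; equal in/out
#' and row/column totals otherwise).
#'
#' @param graph a `cb_graph` object.
#' @param kind one of `"undirected"`, `"directed"`, `"bipartite"`.
#' @param degree,out_degree,in_degree,row_sums,col_sums integer vectors,
#'   depending on `kind`.
#' @return An object of class `cb_degrees`: a list with `kind` and the
#'   relevant components.
#' @examples
#' degrees(directed_graph(list(2L, 3L, 1L)))
#' @export
degrees <- function(graph) UseMethod("degrees")

#' @export
degrees.undirected_graph <- function(graph) {
  new_degrees("undirected", degree = lengths(graph$adj))
}

#' @export
degrees.directed_graph <- function(graph) {
  out <- lengths(graph$adj)
  targets <- unlist(graph$adj, use.names = FALSE) %||% integer(0)
  inn <- tabulate(targets, nbins = graph$n_nodes)
  new_degrees("directed", out_degree = out, in_degree = as.integer(inn))
}

#' @export
degrees.bipartite_state <- function(graph) {
  rs <- lengths(graph$rows)
  cols <- unlist(graph$rows, use.names = FALSE) %||% integer(0)
  cs <- tabulate(cols, nbins = graph$n_cols)
  new_degrees("bipartite", row_sums = rs, col_sums = as.integer(cs))
}

new_degrees <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "cb_degrees")
}

#' @rdname degrees
#' @export
degree_sequence <- function(kind = c("undirected", "directed", "bipartite"),
                            degree = NULL, out_degree = NULL, in_degree = NULL,
                            row_sums = NULL, col_sums = NULL) {
  kind <- match.arg(kind)
  chk <- function(x, what) {
    if (is.null(x)) stop("missing ", what, " for kind '", kind, "'")
    x <- as.integer(x)
    if (any(x < 0L)) stop(what, " must be non-negative")
    x
  }
  ds <- switch(kind,
    undirected = {
      d <- chk(degree, "degree")
      if (sum(d) %% 2L != 0L) stop("undirected degree sum must be even")
      new_degrees("undirected", degree = d)
    },
    directed = {
      o <- chk(out_degree, "out_degree"); i <- chk(in_degree, "in_degree")
      if (length(o) != length(i)) stop("out_degree and in_degree differ in length")
      if (sum(o) != sum(i)) stop("sum(out_degree) must equal sum(in_degree)")
      new_degrees("directed", out_degree = o, in_degree = i)
    },
    bipartite = {
      r <- chk(row_sums, "row_sums"); cs <- chk(col_sums, "col_sums")
      if (sum(r) != sum(cs)) stop("sum(row_sums) must equal sum(col_sums)")
      new_degrees("bipartite", row_sums = r, col_sums = cs)
    })
  ds
}

#' @export
print.cb_degrees <- function(x, ...) {
  cat("<", x$kind, " degree sequence>\n", sep = "")
  for (nm in setdiff(names(x), "kind"))
    cat(" ", nm, ": ", paste(x[[nm]], collapse = " "), "\n", sep = "")
  invisible(x)
}

degrees_equal <- function(a, b) {
  identical(a$kind, b$kind) &&
    all(vapply(setdiff(names(a), "kind"),
               function(nm) identical(as.integer(a[[nm]]), as.integer(b[[nm]])),
               logical(1)))
}

# ---- edge sets --------------------------------------------------------------

#' Edge set of a graph
#'
#' Directed graphs yield ordered pairs, undirected graphs each unordered edge
#' once (smaller index first), bipartite states (row, column) pairs.
#'
#' @param graph a `cb_graph` object.
#' @return A two-column integer matrix (`from`/`to` or `row`/`col`), zero rows
#'   for an edgeless graph.
#' @export
edge_set <- function(graph) {
  a <- adj_sets(graph)
  from <- rep.int(seq_along(a), lengths(a))
  to <- unlist(a, use.names = FALSE)
  if (is.null(to)) to <- integer(0)
  m <- cbind(from = from, to = to)
  if (inherits(graph, "undirected_graph")) m <- m[m[, 1L] < m[, 2L], , drop = FALSE]
  if (inherits(graph, "bipartite_state")) colnames(m) <- c("row", "col")
  storage.mode(m) <- "integer"
  m
}

# character keys for fast membership tests
edge_keys <- function(graph) {
  m <- edge_set(graph)
  paste(m[, 1L], m[, 2L])
}

#' Test two graphs for equality of structure
#'
#' Same kind, node count and edge set (labels are ignored).
#' @param a,b `cb_graph` objects.
#' @return logical.
#' @export
graph_identical <- function(a, b) {
  if (graph_kind(a) != graph_kind(b)) return(FALSE)
  sa <- adj_sets(a); sb <- adj_sets(b)
  length(sa) == length(sb) &&
    all(vapply(seq_along(sa),
               function(i) identical(unname(sort.int(as.integer(sa[[i]]))),
                                     unname(sort.int(as.integer(sb[[i]])))),
               logical(1)))
}

# canonical state key: the flattened 0/1 matrix as a bit-string
state_key <- function(graph) {
  a <- adj_sets(graph)
  paste(vapply(a, function(s) paste(sort.int(s), collapse = ","), character(1)),
        collapse = ";")
}

#' @export
print.cb_graph <- function(x, ...) {
  kind <- graph_kind(x)
  m <- edge_set(x)
  if (kind == "bipartite") {
    cat(sprintf("<bipartite_state: %d x %d, %d ones>\n",
                x$n_rows, x$n_cols, nrow(m)))
  } else {
    cat(sprintf("<%s_graph: %d nodes, %d %s>\n", kind, x$n_nodes, nrow(m),
                if (kind == "directed") "arcs" else "edges"))
  }
  invisible(x)
}

# ---- file I/O ---------------------------------------------------------------

#' Read a network from a two-column edge list
#'
#' Plain-text format: one edge per line, two whitespace-separated node labels;
#' lines whose first non-blank character is `#` are comments. Labels are
#' arbitrary strings, mapped to contiguous 1-based indices in order of first
#' appearance (the mapping is kept in the graph's `labels` field and used by
#' [write_edge_list()]). Undirected input is symmetrized; duplicate edges are
#' collapsed with a warning reporting their count; self-loops are rejected.
#'
#' @param path file path.
#' @param kind `"directed"` or `"undirected"`.
#' @return A [directed_graph()] or [undirected_graph()].
#' @export
read_edge_list <- function(path, kind = c("directed", "undirected")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad))
    stop(sprintf("parse error at line %d: expected 2 tokens, found %d",
                 idx[bad[1L]], lengths(toks)[bad[1L]]))
  from_lab <- vapply(toks, `[`, character(1), 1L)
  to_lab <- vapply(toks, `[`, character(1), 2L)
  loops <- from_lab == to_lab
  if (any(loops))
    stop(sprintf("self-loop on node '%s' at line %d", from_lab[loops][1L],
                 idx[loops][1L]))
  labels <- unique(c(rbind(from_lab, to_lab)))
  from <- match(from_lab, labels)
  to <- match(to_lab, labels)
  n <- length(labels)
  if (kind == "undirected") {
    lo <- pmin(from, to); hi <- pmax(from, to)
    key <- paste(lo, hi)
  } else {
    key <- paste(from, to)
  }
  dup <- duplicated(key)
  if (any(dup))
    warning(sprintf("collapsed %d duplicate edge(s)", sum(dup)))
  from <- from[!dup]; to <- to[!dup]
  adj <- rep(list(integer(0)), n)
  if (kind == "undirected") {
    for (e in seq_along(from)) {
      adj[[from[e]]] <- c(adj[[from[e]]], to[e])
      adj[[to[e]]] <- c(adj[[to[e]]], from[e])
    }
    undirected_graph(adj, n, labels = labels)
  } else {
    for (e in seq_along(from)) adj[[from[e]]] <- c(adj[[from[e]]], to[e])
    directed_graph(adj, n, labels = labels)
  }
}

#' Write a network as a two-column edge list
#'
#' One edge per line using the original labels (or the index itself when the
#' graph was built in memory without labels). Undirected edges are emitted
#' once with their endpoints in label order; lines are sorted, so output is
#' deterministic and byte-stable.
#'
#' @param graph a directed or undirected graph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, c("directed_graph", "undirected_graph")))
  lab <- graph$labels %||% as.character(seq_len(graph$n_nodes))
  m <- edge_set(graph)
  if (nrow(m) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  a <- lab[m[, 1L]]; b <- lab[m[, 2L]]
  if (inherits(graph, "undirected_graph")) {
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  lines <- paste(a, b, sep = "\t")
  writeLines(sort(lines, method = "radix"), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write biadjacency matrices
#'
#' `read_biadjacency()` reads a rectangular TSV of 0/1 entries into a
#' [bipartite_state()]; with `header = TRUE` the first row and first column
#' are taken as column and row labels. `write_biadjacency()` writes the
#' matching format back.
#'
#' @param path file path.
#' @param header logical; skip one label row and column.
#' @param state a `bipartite_state`.
#' @return `read_biadjacency()`: a [bipartite_state()];
#'   `write_biadjacency()`: `path`, invisibly.
#' @export
read_biadjacency <- function(path, header = FALSE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  col_labels <- row_labels <- NULL
  if (header) {
    col_labels <- cells[[1L]][-1L]
    row_labels <- vapply(cells[-1L], `[`, character(1), 1L)
    cells <- lapply(cells[-1L], `[`, -1L)
  }
  widths <- lengths(cells)
  if (length(unique(widths)) > 1L)
    stop(sprintf("ragged rows: row %d has %d cells, expected %d",
                 which(widths != widths[1L])[1L], widths[widths != widths[1L]][1L],
                 widths[1L]))
  n_cols <- widths[1L]
  rows <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    vals <- cells[[i]]
    bad <- !(vals %in% c("0", "1"))
    if (any(bad))
      stop(sprintf("non-binary entry '%s' at row %d, column %d",
                   vals[bad][1L], i, which(bad)[1L]))
    rows[[i]] <- which(vals == "1")
  }
  bipartite_state(rows, n_cols, row_labels = row_labels, col_labels = col_labels)
}

#' @rdname read_biadjacency
#' @export
write_biadjacency <- function(state, path, header = FALSE) {
  stopifnot(inherits(state, "bipartite_state"))
  mat <- matrix(0L, state$n_rows, state$n_cols)
  for (i in seq_len(state$n_rows)) mat[i, state$rows[[i]]] <- 1L
  lines <- apply(mat, 1L, paste, collapse = "\t")
  if (header) {
    rl <- state$row_labels %||% paste0("r", seq_len(state$n_rows))
    cl <- state$col_labels %||% paste0("c", seq_len(state$n_cols))
    lines <- c(paste(c("", cl), collapse = "\t"), paste(rl, lines, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
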