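#' Neighborhood adjacency graphs
#'
#' A `nbhd_graph` stores the contiguity structure of the study neighborhoods:
#' integer node ids, an undirected edge list (binary contiguity weights), and,
#' for lattice-built graphs, unit-square cell outlines used for choropleth
#' export. The graph carries the intrinsic conditional-autoregressive (CAR)
#' prior of the spatial models: each neighborhood effect is conditionally
#' Normal around the mean of its graph neighbors.
#'
#' @param edges a data frame (or 2-column matrix) of undirected edges between
#'   node ids. Edges are symmetrized and de-duplicated; self-loops are an
#'   error.
#' @param node_ids optional vector of node ids; defaults to the ids appearing
#'   in `edges`. Ids absent from any edge make the graph disconnected and are
#'   rejected unless `allow_islands = TRUE`.
#' @param cells optional tibble of unit-cell outlines (`node_id`, `row`,
#'   `col`) as produced by [make_lattice()].
#' @param allow_islands keep disconnected graphs instead of erroring. The
#'   intrinsic CAR prior is only identified (up to its sum-to-zero constraint)
#'   on a connected graph, so islands are rejected by default.
#' @return an object of class `nbhd_graph`.
#' @seealso [make_lattice()], [read_adjacency()], [sample_car_field()]
#' @export
nbhd_graph <- function(edges, node_ids = NULL, cells = NULL,
                       allow_islands = FALSE) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) {
    abort_recwalk("`edges` must have two columns (from, to).", "invalid_argument")
  }
  from <- as.integer(edges[[1L]])
  to <- as.integer(edges[[2L]])
  if (anyNA(from) || anyNA(to)) {
    abort_recwalk("edge endpoints must be integer node ids.", "invalid_argument")
  }
  if (any(from == to)) {
    abort_recwalk("self-loops are not allowed in a contiguity graph.", "invalid_argument")
  }
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  keep <- !duplicated(cbind(lo, hi))
  edges <- tibble::tibble(from = lo[keep], to = hi[keep])
  edges <- edges[order(edges$from, edges$to), ]
  if (is.null(node_ids)) node_ids <- sort(unique(c(edges$from, edges$to)))
  node_ids <- sort(unique(as.integer(node_ids)))
  if (!all(c(edges$from, edges$to) %in% node_ids)) {
    abort_recwalk("edges reference node ids not in `node_ids`.", "invalid_argument")
  }
  g <- structure(
    list(node_ids = node_ids, edges = edges, cells = cells),
    class = "nbhd_graph"
  )
  if (!allow_islands && !graph_is_connected(g)) {
    abort_recwalk(
      "adjacency graph is disconnected (islands); the intrinsic CAR prior requires a connected graph.",
      "island"
    )
  }
  g
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges,
    directed = FALSE,
    vertices = data.frame(name = graph$node_ids)
  )
}

graph_is_connected <- function(graph) {
  if (n_nodes(graph) <= 1L) return(TRUE)
  if (nrow(graph$edges) == 0L) return(FALSE)
  igraph::is_connected(as_igraph(graph))
}

#' @export
print.nbhd_graph <- function(x, ...) {
  cat(sprintf(
    "<nbhd_graph> %d neighborhoods, %d contiguity edges%s\n",
    n_nodes(x), nrow(x$edges),
    if (!is.null(x$cells)) " (lattice cells attached)" else ""
  ))
  invisible(x)
}

#' Number of neighborhoods in an adjacency graph
#' @param graph a [nbhd_graph()].
#' @return integer count of nodes.
#' @export
n_nodes <- function(graph) length(graph$node_ids)

# 0-based concatenated adjacency lists, car.normal style, in node_ids order
graph_adjacency_lists <- function(graph) {
  idx <- match(c(graph$edges$from, graph$edges$to), graph$node_ids)
  nb <- split(
    c(match(graph$edges$to, graph$node_ids), match(graph$edges$from, graph$node_ids)),
    factor(idx, levels = seq_len(n_nodes(graph)))
  )
  nb <- lapply(nb, function(v) sort(v) - 1L)
  list(
    adj = as.integer(unlist(nb, use.names = FALSE)),
    start = c(0L, cumsum(lengths(nb)))
  )
}

# graph Laplacian (degree matrix minus adjacency), dense
graph_laplacian <- function(graph) {
  J <- n_nodes(graph)
  L <- matrix(0, J, J)
  i <- match(graph$edges$from, graph$node_ids)
  k <- match(graph$edges$to, graph$node_ids)
  for (e in seq_along(i)) {
    L[i[e], k[e]] <- L[i[e], k[e]] - 1
    L[k[e], i[e]] <- L[k[e], i[e]] - 1
    L[i[e], i[e]] <- L[i[e], i[e]] + 1
    L[k[e], k[e]] <- L[k[e], k[e]] + 1
  }
  L
}

#' Build a regular lattice contiguity graph
#'
#' Constructs a rows x cols grid of unit-square neighborhoods with rook
#' (edge-sharing) or queen (edge- or corner-sharing) contiguity. Stands in
#' for a census-tract contiguity map in simulation studies.
#'
#' @param rows,cols positive lattice dimensions; `rows * cols >= 2`.
#' @param scheme `"rook"` (default) or `"queen"` contiguity.
#' @return a [nbhd_graph()] with cell outlines attached; node ids run
#'   row-major from 1.
#' @examples
#' g <- make_lattice(3, 3)
#' n_nodes(g)
#' @export
make_lattice <- function(rows, cols, scheme = c("rook", "queen")) {
  scheme <- match.arg(scheme)
  if (length(rows) != 1L || length(cols) != 1L ||
      is.na(rows) || is.na(cols) || rows < 1L || cols < 1L ||
      rows != as.integer(rows) || cols != as.integer(cols)) {
    abort_recwalk("`rows` and `cols` must be positive integers.", "invalid_argument")
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows * cols < 2L) {
    abort_recwalk("lattice must contain at least 2 cells.", "invalid_argument")
  }
  id <- function(r, c) (r - 1L) * cols + c
  r <- rep(seq_len(rows), each = cols)
  c <- rep(seq_len(cols), times = rows)
  edges <- list()
  right <- c < cols
  edges$h <- cbind(id(r[right], c[right]), id(r[right], c[right] + 1L))
  down <- r < rows
  edges$v <- cbind(id(r[down], c[down]), id(r[down] + 1L, c[down]))
  if (scheme == "queen") {
    dr <- r < rows & c < cols
    edges$d1 <- cbind(id(r[dr], c[dr]), id(r[dr] + 1L, c[dr] + 1L))
    dl <- r < rows & c > 1L
    edges$d2 <- cbind(id(r[dl], c[dl]), id(r[dl] + 1L, c[dl] - 1L))
  }
  em <- do.call(rbind, edges)
  cells <- tibble::tibble(node_id = id(r, c), row = r, col = c)
  nbhd_graph(em, node_ids = cells$node_id, cells = cells)
}

#' Read / write an adjacency edge list
#'
#' Plain two-column whitespace-delimited text, one undirected edge per line.
#'
#' @param path file path.
#' @param graph a [nbhd_graph()].
#' @return `read_adjacency()` returns a [nbhd_graph()]; `write_adjacency()`
#'   returns `path` invisibly.
#' @export
read_adjacency <- function(path) {
  edges <- utils::read.table(path, header = FALSE,
                             col.names = c("from", "to"))
  nbhd_graph(edges)
}

#' @rdname read_adjacency
#' @export
write_adjacency <- function(graph, path) {
  utils::write.table(graph$edges, path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
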