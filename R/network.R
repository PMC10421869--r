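#' Build an interaction network from an edge table
#'
#' Constructs the undirected, simple protein-interaction network used by every
#' downstream stage. Self-loops and duplicate edges (including reversed
#' duplicates) are dropped, since both the restart walk and graphlet orbit
#' counting assume a simple graph.
#'
#' @param edges A data frame whose first two columns are interaction partner
#'   ids (coerced to character). Extra columns are ignored.
#' @return A `clock_network` object: an igraph-backed container with a fixed
#'   node order. Use [as_edge_tibble()] to get the canonical edge table back.
#' @examples
#' net <- clock_network(data.frame(a = c("p1", "p2"), b = c("p2", "p3")))
#' net
#' @export
clock_network <- function(edges) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  if (nrow(edges) == 0) stop("edge table is empty")
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  if (anyNA(a) || anyNA(b)) stop("edge table contains missing ids")

  n_in <- length(a)
  keep <- a != b
  n_loops <- sum(!keep)
  a <- a[keep]; b <- b[keep]
  # canonical unordered orientation, then dedupe
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  lo <- lo[!dup]; hi <- hi[!dup]
  if (length(lo) == 0) stop("no edges remain after removing self-loops/duplicates")
  if (n_loops > 0 || n_dup > 0) {
    message(sprintf("clock_network: dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_loops, n_dup))
  }
  nodes <- sort(unique(c(lo, hi)))
  g <- igraph::graph_from_edgelist(cbind(lo, hi), directed = FALSE)
  # graph_from_edgelist orders vertices by first appearance; impose sorted order
  g <- igraph::permute(g, match(igraph::V(g)$name, nodes))
  new_clock_network(g)
}

new_clock_network <- function(g) {
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- character(0)
  structure(list(graph = g, nodes = nodes), class = "clock_network")
}

#' @export
print.clock_network <- function(x, ...) {
  cat(sprintf("<clock_network> %d nodes, %d edges\n",
              length(x$nodes), igraph::ecount(x$graph)))
  invisible(x)
}

#' @export
format.clock_network <- function(x, ...) {
  sprintf("<clock_network> %d nodes, %d edges", length(x$nodes), igraph::ecount(x$graph))
}

#' Edge table of a network
#'
#' @param net A [clock_network()].
#' @return A tibble with columns `from`, `to` in canonical (sorted) order.
#' @export
as_edge_tibble <- function(net) {
  stopifnot(inherits(net, "clock_network"))
  el <- igraph::as_edgelist(net$graph)
  if (nrow(el) == 0) return(tibble::tibble(from = character(), to = character()))
  tibble::tibble(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2])) |>
    dplyr::arrange(.data$from, .data$to)
}

#' Node degrees
#'
#' @param net A [clock_network()].
#' @return A tibble with columns `node`, `degree`.
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "clock_network"))
  tibble::tibble(node = net$nodes,
                 degree = as.integer(igraph::degree(net$graph)))
}

#' Read an interaction network from a file
#'
#' Supports a whitespace/tab separated two-column edge list (lines starting
#' with `#` ignored) and the simple interaction format (SIF:
#' `source relation target`).
#'
#' @param path Path to the network file.
#' @param fmt `"tsv"` (default) or `"sif"`.
#' @return A [clock_network()].
#' @export
read_edge_list <- function(path, fmt = c("tsv", "sif")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  dat <- lines[keep]
  lineno <- which(keep)
  if (length(dat) == 0) stop("network file has no data rows: ", path)
  fields <- strsplit(trimws(dat), "\\s+")
  nf <- lengths(fields)
  need <- if (fmt == "sif") 3L else 2L
  bad <- which(nf < need)
  if (length(bad) > 0) {
    stop(sprintf("malformed %s row at line %d of %s (expected >= %d fields)",
                 fmt, lineno[bad[1]], path, need))
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", if (fmt == "sif") 3L else 2L)
  clock_network(data.frame(from = a, to = b))
}

#' Remove low-degree nodes
#'
#' Single-pass degree filter: all nodes whose degree in the *input* network is
#' below `k` are removed simultaneously, together with their incident edges.
#' Degrees are not recomputed iteratively, so a node kept by the filter may end
#' up with fewer than `k` edges afterwards. Current interactomes are known to
#' be incomplete in their sparse periphery, which is why the graphlet branch
#' drops nodes of degree below three before computing wiring signatures.
#'
#' @param net A [clock_network()].
#' @param k Minimum degree to keep (`k = 0` is the identity).
#' @return A `clock_network`; possibly with zero edges (an error is only raised
#'   when no nodes remain at all, since an empty network cannot be represented).
#' @export
filter_min_degree <- function(net, k) {
  stopifnot(inherits(net, "clock_network"), k >= 0)
  if (k == 0) return(net)
  deg <- igraph::degree(net$graph)
  drop <- which(deg < k)
  g <- igraph::delete_vertices(net$graph, drop)
  new_clock_network(g)
}

#' Column-stochastic transition operator
#'
#' Entry (i, j) is `1/degree(j)` when i and j interact, else 0; each column of
#' a positive-degree node sums to one. Isolated nodes give an all-zero column
#' (the walk cannot leave them); a warning is raised because restart mass
#' parked on such a node leaks out of the system.
#'
#' @param net A [clock_network()].
#' @return A sparse `dgCMatrix` with dimnames set to the node order.
#' @export
transition_operator <- function(net) {
  stopifnot(inherits(net, "clock_network"))
  n <- length(net$nodes)
  if (n == 0) stop("network is empty")
  deg <- igraph::degree(net$graph)
  if (any(deg == 0)) {
    warning(sprintf("%d isolated node(s): their transition column is zero", sum(deg == 0)))
  }
  el <- igraph::as_edgelist(net$graph, names = FALSE)
  i <- c(el[, 1], el[, 2])
  j <- c(el[, 2], el[, 1])
  W <- Matrix::sparseMatrix(i = i, j = j, x = 1 / deg[j], dims = c(n, n),
                            dimnames = list(net$nodes, net$nodes))
  W
}

#' Map seed proteins onto a network
#'
#' Partitions the requested ids into those present in the network (in input
#' order), those absent, and those present but removed by the minimum-degree
#' rule applied to seeds.
#'
#' @param net A [clock_network()].
#' @param ids Character vector of seed protein ids.
#' @param min_degree Seeds with degree below this are set aside (default 3,
#'   matching the degree rule applied before wiring-signature analysis).
#' @return A `seed_set` list with elements `mapped`, `unmapped`,
#'   `dropped_low_degree`.
#' @export
map_seeds <- function(net, ids, min_degree = 3) {
  stopifnot(inherits(net, "clock_network"), length(ids) > 0)
  ids <- as.character(ids)
  in_net <- ids %in% net$nodes
  unmapped <- ids[!in_net]
  present <- ids[in_net]
  deg <- igraph::degree(net$graph)[match(present, net$nodes)]
  dropped <- present[deg < min_degree]
  mapped <- present[deg >= min_degree]
  if (length(mapped) == 0) {
    stop("no seed protein could be mapped to the network (at min_degree = ",
         min_degree, ")")
  }
  structure(list(mapped = mapped, unmapped = unmapped,
                 dropped_low_degree = dropped),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d mapped, %d unmapped, %d dropped (low degree)\n",
              length(x$mapped), length(x$unmapped), length(x$dropped_low_degree)))
  invisible(x)
}

seed_ids <- function(seeds) {
  if (inherits(seeds, "seed_set")) seeds$mapped else as.character(seeds)
}
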