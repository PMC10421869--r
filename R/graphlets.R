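#' Orbit ids treated as non-redundant
#'
#' Of the 15 automorphism orbits of 2-4 node graphlets, four (the triangle
#' orbit and the three orbits of the densest graphlets: both diamond orbits
#' and K4) are linearly determined by the remaining eleven, which are the
#' conventional non-redundant signature.
#'
#' @return Integer vector of 11 orbit ids.
#' @export
nonredundant_orbits <- function() c(0L, 1L, 2L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L)

#' Enumerate the 2-4 node graphlet catalog
#'
#' Generates every connected non-isomorphic graph on 2, 3 and 4 nodes and
#' computes each graphlet's automorphism orbits by brute-force enumeration of
#' node permutations. Graphlets are ordered by (size, edge count, maximum
#' degree) and orbits within a graphlet by representative degree, which
#' reproduces the standard literature numbering: edge = 0; P3 ends/mid = 1/2;
#' triangle = 3; P4 ends/mids = 4/5; claw leaves/center = 6/7; C4 = 8; paw
#' tail/cycle/apex = 9/10/11; diamond = 12/13; K4 = 14.
#'
#' @return A tibble with one row per orbit: `graphlet` (index 0-8), `size`,
#'   `n_edges`, `orbit` (0-14), `degree` (of the orbit's nodes), `nodes`
#'   (list-column of member node indices within the graphlet), and `edges`
#'   (list-column: the graphlet's edge matrix).
#' @export
build_catalog <- function() {
  graphs <- list()
  for (k in 2:4) {
    pairs <- utils::combn(k, 2)
    m <- ncol(pairs)
    for (mask in seq_len(2^m) - 1L) {
      sel <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
      if (!any(sel)) next
      em <- t(pairs[, sel, drop = FALSE])
      g <- igraph::graph_from_edgelist(em, directed = FALSE)
      g <- igraph::add_vertices(g, k - igraph::vcount(g))
      if (!igraph::is_connected(g)) next
      if (any(vapply(graphs, function(h) {
        igraph::vcount(h) == k && igraph::isomorphic(h, g)
      }, logical(1)))) next
      graphs[[length(graphs) + 1L]] <- g
    }
  }
  ord <- order(vapply(graphs, igraph::vcount, 0),
               vapply(graphs, igraph::ecount, 0),
               vapply(graphs, function(g) max(igraph::degree(g)), 0))
  graphs <- graphs[ord]

  rows <- list()
  orbit_id <- 0L
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    k <- igraph::vcount(g)
    orbits <- automorphism_orbits(g)
    deg <- igraph::degree(g)
    orbits <- orbits[order(vapply(orbits, function(o) deg[o[1]], 0))]
    for (o in orbits) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        graphlet = gi - 1L, size = k, n_edges = igraph::ecount(g),
        orbit = orbit_id, degree = as.integer(deg[o[1]]),
        nodes = list(o), edges = list(igraph::as_edgelist(g)))
      orbit_id <- orbit_id + 1L
    }
  }
  dplyr::bind_rows(rows)
}

# Partition a small graph's vertices into automorphism orbits by testing
# every permutation of labels for edge preservation.
automorphism_orbits <- function(g) {
  k <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  perms <- all_permutations(k)
  rep_of <- seq_len(k)
  for (p in perms) {
    if (all(A[p, p] == A)) {
      # union-find-lite: map each vertex to the min label in its orbit
      for (v in seq_len(k)) {
        a <- min(rep_of[v], rep_of[p[v]])
        rep_of[rep_of == rep_of[v] | rep_of == rep_of[p[v]]] <- a
      }
    }
  }
  unname(split(seq_len(k), rep_of))
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' Graphlet degree vectors for a set of nodes
#'
#' Counts, for each requested node, the connected induced subgraphs on 2-4
#' nodes that contain it, classified by the node's automorphism orbit
#' (ids 0-14; see [build_catalog()]). Orbit 0 equals the node degree.
#'
#' @param net A [clock_network()].
#' @param nodes Character vector of node ids (default: all nodes).
#' @return A tibble with column `node` followed by integer columns
#'   `o0` ... `o14`.
#' @export
gdv_matrix <- function(net, nodes = NULL) {
  stopifnot(inherits(net, "clock_network"))
  if (is.null(nodes)) nodes <- net$nodes
  idx <- match(nodes, net$nodes)
  if (anyNA(idx)) {
    stop("node(s) not in network: ", paste(nodes[is.na(idx)], collapse = ", "))
  }
  el <- igraph::as_edgelist(net$graph, names = FALSE)
  counts <- cpp_count_orbits(length(net$nodes),
                             as.integer(el[, 1] - 1L), as.integer(el[, 2] - 1L),
                             as.integer(idx - 1L))
  colnames(counts) <- paste0("o", 0:14)
  dplyr::bind_cols(tibble::tibble(node = nodes), tibble::as_tibble(counts))
}

#' Orbit signature of a single node
#'
#' @param net A [clock_network()].
#' @param node A node id.
#' @return Named integer vector of length 15 (`o0` ... `o14`).
#' @export
count_orbits <- function(net, node) {
  row <- gdv_matrix(net, node)
  v <- as.integer(row[1, -1])
  setNames(v, paste0("o", 0:14))
}

#' Graphlet-degree-vector similarity
#'
#' `1 - sum(|u - v|) / sum(u + v)` over the orbit coordinates: 1 for
#' identically wired nodes, 0 for disjoint signatures. By default the
#' comparison uses the 11 non-redundant orbits.
#'
#' @param u,v Orbit-count vectors of equal length (length 15 vectors are
#'   reduced when `use_reduced`).
#' @param use_reduced Compare on the non-redundant orbits (default TRUE).
#' @return A number in `[0, 1]`; two all-zero signatures compare as 1.
#' @export
gdv_similarity <- function(u, v, use_reduced = TRUE) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (use_reduced) {
    if (length(u) == 15) u <- u[nonredundant_orbits() + 1L]
    if (length(v) == 15) v <- v[nonredundant_orbits() + 1L]
  }
  if (length(u) != length(v)) stop("orbit vectors have different lengths")
  tot <- sum(u + v)
  if (tot == 0) return(1)
  1 - sum(abs(u - v)) / tot
}

#' All seed-by-node similarity records
#'
#' @param gdv Orbit-count tibble from [gdv_matrix()].
#' @param seeds A `seed_set` or character vector of seed ids present in `gdv`.
#' @param use_reduced Compare on the non-redundant orbits (default TRUE).
#' @return A tibble with columns `seed`, `node`, `s_gdv` (one row per pair,
#'   self pairs excluded).
#' @export
gdv_similarity_table <- function(gdv, seeds, use_reduced = TRUE) {
  ids <- seed_ids(seeds)
  stopifnot(all(ids %in% gdv$node))
  cols <- if (use_reduced) paste0("o", nonredundant_orbits()) else paste0("o", 0:14)
  M <- as.matrix(gdv[, cols])
  rownames(M) <- gdv$node
  purrr::map_dfr(ids, function(s) {
    u <- M[s, ]
    diff <- abs(sweep(M, 2, u, "-"))
    tot <- sweep(M, 2, u, "+")
    s_gdv <- 1 - rowSums(diff) / pmax(rowSums(tot), .Machine$double.eps)
    s_gdv[rowSums(tot) == 0] <- 1
    tibble::tibble(seed = s, node = gdv$node, s_gdv = as.numeric(s_gdv))
  }) |>
    dplyr::filter(.data$seed != .data$node)
}

#' Adaptive similarity threshold
#'
#' Walks a percent-point grid down from `start` and returns the largest value
#' at which every seed has at least one non-seed node with similarity at or
#' above it. This mirrors the published calibration: start at 0.96 and lower
#' the cutoff until each seed protein has a wiring match.
#'
#' @param sims Similarity table from [gdv_similarity_table()].
#' @param seeds A `seed_set` or character vector of seed ids.
#' @param start Initial threshold (default 0.96).
#' @param step Grid step (default 0.01).
#' @return The selected threshold.
#' @export
select_threshold <- function(sims, seeds, start = 0.96, step = 0.01) {
  stopifnot(start > 0, start <= 1, step > 0)
  ids <- seed_ids(seeds)
  eligible <- dplyr::filter(sims, !(.data$node %in% ids))
  best <- dplyr::summarise(dplyr::group_by(eligible, .data$seed),
                           best = max(.data$s_gdv), .groups = "drop")
  if (!setequal(best$seed, ids) || nrow(eligible) == 0) {
    stop("similarity table lacks non-seed records for some seed")
  }
  t <- start
  repeat {
    if (min(best$best) >= t - 1e-12) return(t)
    t <- t - step
    if (t < 0) stop("no threshold in the grid gives every seed a match")
  }
}

#' Raw candidates from wiring similarity
#'
#' All non-seed nodes whose similarity to at least one seed reaches the
#' threshold; each candidate records its best-matching seed.
#'
#' @param sims Similarity table from [gdv_similarity_table()].
#' @param seeds A `seed_set` or character vector of seed ids.
#' @param threshold Similarity cutoff (inclusive).
#' @return A tibble with columns `node`, `best_seed`, `s_gdv`, `threshold`;
#'   the full set of qualifying pairs is attached as attribute `"pairs"`.
#' @export
raw_gdv_candidates <- function(sims, seeds, threshold) {
  ids <- seed_ids(seeds)
  pairs <- dplyr::filter(sims, !(.data$node %in% ids),
                         .data$s_gdv >= threshold - 1e-12)
  out <- pairs |>
    dplyr::group_by(.data$node) |>
    dplyr::slice_max(.data$s_gdv, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(node = .data$node, best_seed = .data$seed,
                     s_gdv = .data$s_gdv, threshold = threshold) |>
    dplyr::arrange(dplyr::desc(.data$s_gdv), .data$node)
  attr(out, "pairs") <- pairs
  out
}

#' Run the full GDV stage on a network
#'
#' Applies the minimum-degree filter, computes orbit signatures and seed
#' similarities, calibrates the threshold, and extracts raw candidates.
#'
#' @param net A [clock_network()].
#' @param seeds A `seed_set` or character vector of seed ids.
#' @param min_degree Degree filter applied before signature computation
#'   (default 3).
#' @param start,step Threshold grid (see [select_threshold()]).
#' @param use_reduced Compare on the non-redundant orbits (default TRUE).
#' @return A list with `network` (filtered), `gdv`, `sims`, `threshold`,
#'   `raw` (candidate tibble).
#' @export
gdv_stage <- function(net, seeds, min_degree = 3, start = 0.96, step = 0.01,
                      use_reduced = TRUE) {
  fnet <- filter_min_degree(net, min_degree)
  ids <- seed_ids(seeds)
  missing <- setdiff(ids, fnet$nodes)
  if (length(missing) > 0) {
    stop("seed(s) removed by the degree filter: ", paste(missing, collapse = ", "))
  }
  gdv <- gdv_matrix(fnet)
  sims <- gdv_similarity_table(gdv, ids, use_reduced)
  threshold <- select_threshold(sims, ids, start, step)
  raw <- raw_gdv_candidates(sims, ids, threshold)
  list(network = fnet, gdv = gdv, sims = sims, threshold = threshold, raw = raw)
}
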