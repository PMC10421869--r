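# Independent oracles and small fixtures used across the suite.

# --- small named graphs ------------------------------------------------------

edge_df <- function(a, b) data.frame(from = a, to = b)

net_k2 <- function() clock_network(edge_df("a", "b"))
net_path3 <- function() clock_network(edge_df(c("a", "b"), c("b", "c")))
net_triangle <- function() clock_network(edge_df(c("a", "b", "c"), c("b", "c", "a")))
net_claw <- function() clock_network(edge_df(rep("c", 3), c("l1", "l2", "l3")))
net_k4 <- function() {
  clock_network(edge_df(c("a", "a", "a", "b", "b", "c"),
                        c("b", "c", "d", "c", "d", "d")))
}
net_cycle <- function(n) {
  v <- sprintf("v%02d", seq_len(n))
  clock_network(edge_df(v, c(v[-1], v[1])))
}

# Erdos-Renyi fixture; nodes without any edge simply do not appear.
rand_gnp <- function(n, p, seed) {
  set.seed(seed)
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  if (!any(keep)) keep[sample(ncol(pairs), 2)] <- TRUE
  v <- sprintf("n%02d", seq_len(n))
  clock_network(data.frame(from = v[pairs[1, keep]], to = v[pairs[2, keep]]))
}

# --- brute-force orbit oracle ------------------------------------------------

# Orbit of a vertex in a connected induced subgraph on <= 4 nodes, looked up
# by (size, edge count, sorted degree sequence, vertex degree).  The table is
# derived by hand from the nine graphlet drawings; it shares nothing with the
# package's enumerator.
.orbit_table <- c(
  "2|1|11|1" = 0L,
  "3|2|112|1" = 1L, "3|2|112|2" = 2L,
  "3|3|222|2" = 3L,
  "4|3|1122|1" = 4L, "4|3|1122|2" = 5L,
  "4|3|1113|1" = 6L, "4|3|1113|3" = 7L,
  "4|4|2222|2" = 8L,
  "4|4|1223|1" = 9L, "4|4|1223|2" = 10L, "4|4|1223|3" = 11L,
  "4|5|2233|2" = 12L, "4|5|2233|3" = 13L,
  "4|6|3333|3" = 14L
)

# Exhaustive subset enumeration over all C(n, k) subsets, k = 2..4.  A subset
# on <= 4 nodes is connected iff it has >= size-1 edges and no degree-0
# vertex (the only >= size-1 edge layout failing this is triangle+isolate).
oracle_gdv <- function(net) {
  A <- as.matrix(igraph::as_adjacency_matrix(net$graph))
  n <- nrow(A)
  counts <- matrix(0L, n, 15, dimnames = list(net$nodes, paste0("o", 0:14)))
  for (size in 2:4) {
    if (n < size) next
    subs <- utils::combn(n, size)
    for (j in seq_len(ncol(subs))) {
      s <- subs[, j]
      B <- A[s, s, drop = FALSE]
      deg <- rowSums(B)
      ne <- sum(B) / 2
      if (ne < size - 1 || any(deg == 0)) next
      key <- paste(size, ne, paste(sort(deg), collapse = ""), sep = "|")
      for (i in seq_len(size)) {
        orb <- .orbit_table[[paste(key, deg[i], sep = "|")]]
        counts[s[i], orb + 1L] <- counts[s[i], orb + 1L] + 1L
      }
    }
  }
  counts
}

# Isomorphism-based orbit check for one induced subgraph: maps it onto a
# hand-labelled reference graphlet with igraph's VF2 and reads off the
# orbit of each vertex.  Used to cross-validate the degree-keyed table.
.reference_graphlets <- list(
  list(el = rbind(c(1, 2)), orbits = c(0, 0)),
  list(el = rbind(c(1, 2), c(2, 3)), orbits = c(1, 2, 1)),
  list(el = rbind(c(1, 2), c(2, 3), c(1, 3)), orbits = c(3, 3, 3)),
  list(el = rbind(c(1, 2), c(2, 3), c(3, 4)), orbits = c(4, 5, 5, 4)),
  list(el = rbind(c(1, 2), c(1, 3), c(1, 4)), orbits = c(7, 6, 6, 6)),
  list(el = rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)), orbits = c(8, 8, 8, 8)),
  list(el = rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4)), orbits = c(10, 10, 11, 9)),
  list(el = rbind(c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4)),
       orbits = c(12, 12, 13, 13)),
  list(el = rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4)),
       orbits = c(14, 14, 14, 14))
)

oracle_orbits_by_isomorphism <- function(subgraph) {
  k <- igraph::vcount(subgraph)
  for (ref in .reference_graphlets) {
    if (max(ref$el) != k) next
    refg <- igraph::graph_from_edgelist(ref$el, directed = FALSE)
    maps <- igraph::isomorphisms(subgraph, refg)
    if (length(maps) > 0) {
      # maps[[1]][i] is the subgraph vertex corresponding to reference vertex i
      m <- as.integer(maps[[1]])
      out <- integer(k)
      out[m] <- ref$orbits
      return(out)
    }
  }
  NULL
}

# --- exact hypergeometric oracle ---------------------------------------------

# Direct upper-tail summation from log binomial coefficients; shares no code
# path with the phyper-based implementation.
oracle_enrichment_score <- function(N, M, n, m, cap = 300) {
  if (m == 0) return(0)
  k <- m:n
  terms <- lchoose(M, k) + lchoose(N - M, n - k) - lchoose(N, n)
  p <- sum(exp(terms))
  min(cap, -log10(min(1, p)))
}
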