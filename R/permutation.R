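#' Null-ensemble configuration
#'
#' @param n_permutations Number of null replicates (default 1000).
#' @param swaps_per_edge Attempted double-edge swaps per edge when rewiring
#'   (default 10, a standard mixing heuristic).
#' @param rng_seed Integer seed; every null draw derives from it, so the same
#'   seed reproduces the ensemble bit for bit.
#' @return A `null_config` list.
#' @export
null_config <- function(n_permutations = 1000L, swaps_per_edge = 10L,
                        rng_seed = 1L) {
  stopifnot(n_permutations >= 1, swaps_per_edge >= 1)
  structure(list(n_permutations = as.integer(n_permutations),
                 swaps_per_edge = as.integer(swaps_per_edge),
                 rng_seed = as.integer(rng_seed)),
            class = "null_config")
}

# One derived stream per permutation so each branch replays independently.
derive_streams <- function(rng_seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(rng_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Uniform random seed sets
#'
#' Draws `n_permutations` node sets of the given size, uniformly without
#' replacement from all network nodes: the null model for the restart-walk
#' branch.
#'
#' @param net A [clock_network()].
#' @param size Seed-set size (the number of mapped seed proteins).
#' @param cfg A [null_config()].
#' @return A list of character vectors.
#' @export
random_seed_sets <- function(net, size, cfg = null_config()) {
  stopifnot(inherits(net, "clock_network"))
  n <- length(net$nodes)
  if (size > n) stop("seed-set size exceeds the number of nodes")
  streams <- derive_streams(cfg$rng_seed, cfg$n_permutations)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  lapply(streams, function(s) {
    set.seed(s)
    sample(net$nodes, size)
  })
}

#' Permutation FDR for the restart-walk branch
#'
#' For each raw candidate g, re-runs the restart walk from each random seed
#' set and counts how often the null stationary probability of g strictly
#' exceeds the observed one: `p(g) = theta / n_permutations`.
#'
#' @param net A [clock_network()].
#' @param seeds Observed `seed_set` or character vector.
#' @param raw Raw-candidate tibble from [threshold_raw_candidates()] (columns
#'   `node`, `probability`).
#' @param cfg A [null_config()].
#' @param rwr_cfg An [rwr_config()].
#' @return A tibble with columns `node`, `branch`, `theta`, `n`, `p_value`.
#' @export
rwr_permutation_fdr <- function(net, seeds, raw, cfg = null_config(),
                                rwr_cfg = rwr_config()) {
  stopifnot(all(c("node", "probability") %in% names(raw)))
  if (nrow(raw) == 0) {
    return(tibble::tibble(node = character(), branch = character(),
                          theta = integer(), n = integer(), p_value = numeric()))
  }
  W <- transition_operator(net)
  sets <- random_seed_sets(net, length(seed_ids(seeds)), cfg)
  idx <- match(raw$node, net$nodes)
  theta <- integer(nrow(raw))
  for (s in sets) {
    p0 <- initial_distribution(net, s)
    p <- rwr_iterate(W, p0, rwr_cfg)
    theta <- theta + (p[idx] > raw$probability)
  }
  tibble::tibble(node = raw$node, branch = "RWR", theta = as.integer(theta),
                 n = cfg$n_permutations,
                 p_value = theta / cfg$n_permutations)
}

#' Degree-preserving null-network ensemble
#'
#' Returns an iterator over rewired copies of the network. Each copy is
#' produced by `swaps_per_edge * |E|` attempted double-edge swaps (two edges
#' {a,b}, {c,d} become {a,d}, {c,b} when that creates no self-loop or
#' duplicate), so node labels and the exact degree sequence are preserved.
#' Networks are generated lazily, one per call, and never stored.
#'
#' @param net A [clock_network()].
#' @param cfg A [null_config()].
#' @return A function: each call returns the next rewired `clock_network`, or
#'   `NULL` after `n_permutations` networks.
#' @export
degree_preserving_ensemble <- function(net, cfg = null_config()) {
  stopifnot(inherits(net, "clock_network"))
  if (igraph::ecount(net$graph) < 2) stop("rewiring needs at least 2 edges")
  streams <- derive_streams(cfg$rng_seed, cfg$n_permutations)
  niter <- cfg$swaps_per_edge * igraph::ecount(net$graph)
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > cfg$n_permutations) return(NULL)
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old))
    set.seed(streams[i])
    g <- igraph::rewire(net$graph, igraph::keeping_degseq(loops = FALSE,
                                                          niter = niter))
    new_clock_network(g)
  }
}

#' Permutation FDR for the wiring-similarity branch
#'
#' For each raw candidate g with best-matching seed c*, counts the null
#' networks in which the (c*, g) similarity strictly exceeds the observed
#' one. Orbit signatures are recomputed on each rewired network, but only for
#' the nodes involved in the comparisons.
#'
#' @param net The degree-filtered [clock_network()] used for the observed run.
#' @param raw Raw-candidate tibble from [raw_gdv_candidates()] (columns
#'   `node`, `best_seed`, `s_gdv`).
#' @param cfg A [null_config()].
#' @param use_reduced Compare on the non-redundant orbits (default TRUE).
#' @param progress Print a dot every 50 null networks (default FALSE).
#' @return A tibble with columns `node`, `branch`, `theta`, `n`, `p_value`.
#' @export
gdv_permutation_fdr <- function(net, raw, cfg = null_config(),
                                use_reduced = TRUE, progress = FALSE) {
  stopifnot(all(c("node", "best_seed", "s_gdv") %in% names(raw)))
  if (nrow(raw) == 0) {
    return(tibble::tibble(node = character(), branch = character(),
                          theta = integer(), n = integer(), p_value = numeric()))
  }
  if (anyNA(raw$best_seed)) stop("candidate without a recorded best seed")
  involved <- unique(c(raw$node, raw$best_seed))
  ens <- degree_preserving_ensemble(net, cfg)
  theta <- integer(nrow(raw))
  k <- 0L
  repeat {
    nullnet <- ens()
    if (is.null(nullnet)) break
    k <- k + 1L
    gdv <- gdv_matrix(nullnet, involved)
    cols <- if (use_reduced) paste0("o", nonredundant_orbits()) else paste0("o", 0:14)
    M <- as.matrix(gdv[, cols])
    rownames(M) <- gdv$node
    u <- M[raw$best_seed, , drop = FALSE]
    v <- M[raw$node, , drop = FALSE]
    tot <- rowSums(u + v)
    s_null <- ifelse(tot == 0, 1, 1 - rowSums(abs(u - v)) / pmax(tot, 1))
    theta <- theta + (s_null > raw$s_gdv + 1e-12)
    if (progress && k %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  tibble::tibble(node = raw$node, branch = "GDV", theta = as.integer(theta),
                 n = cfg$n_permutations,
                 p_value = theta / cfg$n_permutations)
}

#' Keep statistically significant candidates
#'
#' Candidates with empirical FDR strictly below `alpha` survive.
#'
#' @param results Tibble from [rwr_permutation_fdr()] or
#'   [gdv_permutation_fdr()].
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return The filtered tibble with a `significant` column added (all TRUE in
#'   the returned rows).
#' @export
filter_significant <- function(results, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  results |>
    dplyr::mutate(significant = .data$p_value < alpha) |>
    dplyr::filter(.data$significant)
}
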