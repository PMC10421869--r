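#' Random-walk-with-restart configuration
#'
#' @param restart Restart probability r in (0, 1]; at every step the walker
#'   returns to the seed distribution with probability r. Default 0.8, which
#'   keeps the probability mass tightly concentrated around the seeds.
#' @param l1_tolerance Convergence tolerance on the Manhattan (L1) distance
#'   between successive probability vectors. Default `1e-6`.
#' @param raw_threshold Probability cutoff above which a node is declared a
#'   raw candidate. Default `1e-5`.
#' @param max_iterations Safety bound on iterations. Default 10000.
#' @return An `rwr_config` list.
#' @export
rwr_config <- function(restart = 0.8, l1_tolerance = 1e-6,
                       raw_threshold = 1e-5, max_iterations = 10000L) {
  stopifnot(restart > 0, restart <= 1, l1_tolerance > 0,
            raw_threshold > 0, max_iterations >= 1)
  structure(list(restart = restart, l1_tolerance = l1_tolerance,
                 raw_threshold = raw_threshold,
                 max_iterations = as.integer(max_iterations)),
            class = "rwr_config")
}

#' Initial seed distribution
#'
#' Each mapped seed receives mass `1/n_seeds`; every other node zero.
#'
#' @param net A [clock_network()].
#' @param seeds A `seed_set` (from [map_seeds()]) or character vector of node
#'   ids present in the network.
#' @return A named numeric vector over the network's node order, summing to 1.
#' @export
initial_distribution <- function(net, seeds) {
  stopifnot(inherits(net, "clock_network"))
  ids <- seed_ids(seeds)
  if (length(ids) == 0) stop("seed set is empty")
  if (!all(ids %in% net$nodes)) {
    stop("seed id(s) not in network: ",
         paste(setdiff(ids, net$nodes), collapse = ", "))
  }
  p0 <- setNames(numeric(length(net$nodes)), net$nodes)
  p0[ids] <- 1 / length(ids)
  p0
}

#' Iterate the restart walk to convergence
#'
#' Updates `P <- (1 - r) * W %*% P + r * P0` until the L1 distance between
#' successive vectors drops below the tolerance. With a column-stochastic W
#' the map is a contraction with factor (1 - r), so convergence is geometric.
#'
#' @param W Column-stochastic transition matrix from [transition_operator()].
#' @param p0 Initial distribution from [initial_distribution()].
#' @param cfg An [rwr_config()].
#' @return A named numeric vector (the stationary distribution) with
#'   attributes `iterations` and `l1_gaps` (the L1 distance after each
#'   update, ending with the one below tolerance).
#' @export
rwr_iterate <- function(W, p0, cfg = rwr_config()) {
  r <- cfg$restart
  if (r == 1) {
    return(structure(p0, iterations = 1L, l1_gaps = numeric(0)))
  }
  p <- p0
  gaps <- numeric(0)
  for (i in seq_len(cfg$max_iterations)) {
    p_next <- as.numeric((1 - r) * (W %*% p)) + r * p0
    gap <- sum(abs(p_next - p))
    gaps[i] <- gap
    p <- p_next
    if (gap < cfg$l1_tolerance) {
      return(structure(setNames(p, names(p0)), iterations = i, l1_gaps = gaps))
    }
  }
  stop(sprintf("restart walk did not converge in %d iterations (last L1 gap %.3g)",
               cfg$max_iterations, gap))
}

#' Closed-form stationary distribution of the restart walk
#'
#' Solves `(I - (1 - r) W) P = r P0` with a dense linear solve. Intended as an
#' exact cross-check for [rwr_iterate()] on small networks; the dense solve
#' does not scale to interactome size.
#'
#' @inheritParams rwr_iterate
#' @param r Restart probability in (0, 1].
#' @return A named numeric vector.
#' @export
rwr_solve_direct <- function(W, p0, r = 0.8) {
  stopifnot(r > 0, r <= 1)
  if (r == 1) return(p0)
  n <- length(p0)
  A <- diag(n) - (1 - r) * as.matrix(W)
  setNames(as.numeric(solve(A, r * p0)), names(p0))
}

#' Threshold the stationary distribution into raw candidates
#'
#' Nodes with stationary probability strictly greater than the threshold are
#' raw candidates, ranked by descending probability. Seeds are excluded by
#' default: the walk trivially concentrates on them, and the object of
#' interest is the proteins *associated with* the seeds.
#'
#' @param p Stationary distribution (named numeric) from [rwr_iterate()].
#' @param tau Probability threshold (strict `>`).
#' @param seeds Seed set or character vector (used when `exclude_seeds`).
#' @param exclude_seeds Drop seed nodes from the candidate list (default TRUE).
#' @return A tibble with columns `node`, `probability`, `is_seed`, `rank`.
#' @export
threshold_raw_candidates <- function(p, tau = 1e-5, seeds = character(),
                                     exclude_seeds = TRUE) {
  ids <- seed_ids(seeds)
  out <- tibble::tibble(node = names(p), probability = as.numeric(p),
                        is_seed = names(p) %in% ids)
  out <- dplyr::filter(out, .data$probability > tau)
  if (exclude_seeds) out <- dplyr::filter(out, !.data$is_seed)
  out <- dplyr::arrange(out, dplyr::desc(.data$probability), .data$node)
  dplyr::mutate(out, rank = dplyr::row_number())
}

#' Run the full RWR stage on a network
#'
#' Convenience wrapper: builds the transition operator and seed distribution,
#' iterates to convergence, and thresholds into raw candidates.
#'
#' @param net A [clock_network()].
#' @param seeds A `seed_set` or character vector of seed ids.
#' @param cfg An [rwr_config()].
#' @param exclude_seeds Passed to [threshold_raw_candidates()].
#' @return A list with `stationary` (named vector), `raw` (tibble),
#'   `iterations`.
#' @export
rwr_stage <- function(net, seeds, cfg = rwr_config(), exclude_seeds = TRUE) {
  W <- transition_operator(net)
  p0 <- initial_distribution(net, seeds)
  p <- rwr_iterate(W, p0, cfg)
  raw <- threshold_raw_candidates(p, cfg$raw_threshold, seeds, exclude_seeds)
  list(stationary = p, raw = raw, iterations = attr(p, "iterations"))
}
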