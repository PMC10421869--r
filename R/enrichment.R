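#' Closed neighborhood of a node
#'
#' @param net A [clock_network()].
#' @param g A node id.
#' @return Character vector: the node and its immediate interactors.
#' @export
neighborhood <- function(net, g) {
  stopifnot(inherits(net, "clock_network"))
  if (!(g %in% net$nodes)) stop("node not in network: ", g)
  nb <- igraph::neighbors(net$graph, g)$name
  unique(c(g, nb))
}

#' Hypergeometric neighborhood-enrichment score
#'
#' Upper-tail hypergeometric probability that at least `m` of the `n`
#' neighborhood proteins carry an annotation held by `M` of the `N` network
#' proteins, returned as `-log10(P)`. The tail is evaluated in log space; a
#' cap (default 300) bounds scores when the tail underflows, because the
#' downstream cosine similarity is scale-sensitive and unbounded spikes would
#' dominate it.
#'
#' @param N Total network proteins.
#' @param M Network proteins annotated with the term.
#' @param n Size of the closed neighborhood `H(g)`.
#' @param m Annotated proteins inside `H(g)`.
#' @param cap Upper bound on the returned score (default 300).
#' @return A nonnegative score (vectorized over its arguments).
#' @export
enrichment_score <- function(N, M, n, m, cap = 300) {
  bad <- m < 0 | n < m | N < n | M < 0 | M > N | m > M
  if (any(bad)) {
    stop("invalid hypergeometric bounds: need 0 <= m <= min(n, M), n <= N, M <= N")
  }
  logp <- phyper(m - 1, M, N - M, n, lower.tail = FALSE, log.p = TRUE)
  score <- -logp / log(10)
  score[m == 0] <- 0
  pmin(score, cap)
}

#' Enrichment profile of a gene
#'
#' Computes `S(g, A)` for annotation terms against the gene's closed
#' neighborhood. By default the term universe is the set of terms annotating
#' at least one neighborhood member (other terms necessarily score 0).
#'
#' @param net A [clock_network()].
#' @param ann An [annotation_map()].
#' @param g A node id.
#' @param term_universe Optional character vector of terms to score.
#' @param cap Passed to [enrichment_score()].
#' @return A tibble with columns `gene`, `namespace`, `term`, `score`.
#' @export
enrichment_vector <- function(net, ann, g, term_universe = NULL, cap = 300) {
  stopifnot(inherits(ann, "annotation_map"))
  scores <- es_profile(net, ann, g, term_universe, cap)
  tibble::tibble(gene = g, namespace = ann$namespace,
                 term = names(scores), score = as.numeric(scores))
}

# Named score vector over the neighborhood-positive terms (internal).
es_profile <- function(net, ann, g, term_universe = NULL, cap = 300) {
  H <- neighborhood(net, g)
  n <- length(H)
  N <- length(net$nodes)
  h_terms <- unlist(ann$gene_to_terms[intersect(H, names(ann$gene_to_terms))],
                    use.names = FALSE)
  if (is.null(term_universe)) term_universe <- sort(unique(h_terms))
  if (length(term_universe) == 0) return(setNames(numeric(0), character(0)))
  m <- table(factor(h_terms, levels = term_universe))
  M <- vapply(term_universe, function(tm) {
    sum(ann$term_to_genes[[tm]] %in% net$nodes)
  }, 0L)
  setNames(enrichment_score(N, as.integer(M), n, as.integer(m), cap), term_universe)
}

#' Functional similarity between two enrichment profiles
#'
#' Cosine of the two genes' enrichment vectors, aligned on the union of their
#' term sets with absent terms scored 0. Scores are nonnegative, so the value
#' lies in `[0, 1]`; it is 0 when either profile is all-zero.
#'
#' @param es1,es2 Enrichment tibbles from [enrichment_vector()] (or named
#'   numeric score vectors). Namespaces must match.
#' @return Cosine similarity in `[0, 1]`.
#' @export
functional_similarity <- function(es1, es2) {
  v1 <- as_score_vector(es1)
  v2 <- as_score_vector(es2)
  ns1 <- attr(v1, "namespace"); ns2 <- attr(v2, "namespace")
  if (!is.null(ns1) && !is.null(ns2) && !identical(ns1, ns2)) {
    stop("cannot compare enrichment profiles across namespaces (",
         ns1, " vs ", ns2, ")")
  }
  terms <- union(names(v1), names(v2))
  a <- setNames(numeric(length(terms)), terms)
  b <- a
  a[names(v1)] <- v1
  b[names(v2)] <- v2
  cosine(a, b)
}

as_score_vector <- function(es) {
  if (is.data.frame(es)) {
    v <- setNames(es$score, es$term)
    attr(v, "namespace") <- es$namespace[1]
    v
  } else {
    es
  }
}

cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  min(1, sum(a * b) / (na * nb))
}

#' Maximum-annotation-similarity filter
#'
#' For each candidate, MAS in a namespace is the largest cosine similarity
#' between the candidate's enrichment profile and any seed's profile. A
#' candidate survives when MAS reaches the threshold in *both* the GO and the
#' pathway namespace — functional coupling must be supported by two
#' independent annotation sources.
#'
#' @param candidates Character vector of candidate node ids (or a tibble with
#'   a `node` column).
#' @param seeds A `seed_set` or character vector of seed ids.
#' @param net A [clock_network()].
#' @param ann_go,ann_pathway [annotation_map()] objects for the two
#'   namespaces.
#' @param threshold MAS cutoff, inclusive (default 0.75).
#' @param cap Passed to [enrichment_score()].
#' @return A tibble with columns `node`, `mas_go`, `mas_pathway`,
#'   `best_seed_go`, `best_seed_pathway`, `kept`.
#' @export
mas_filter <- function(candidates, seeds, net, ann_go, ann_pathway,
                       threshold = 0.75, cap = 300) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (is.data.frame(candidates)) candidates <- candidates$node
  candidates <- unique(as.character(candidates))
  ids <- seed_ids(seeds)
  if (length(candidates) == 0) {
    return(tibble::tibble(node = character(), mas_go = numeric(),
                          mas_pathway = numeric(), best_seed_go = character(),
                          best_seed_pathway = character(), kept = logical()))
  }
  one_ns <- function(ann) {
    profs <- lapply(setNames(nm = unique(c(candidates, ids))), function(g) {
      if (g %in% net$nodes) es_profile(net, ann, g, cap = cap) else numeric(0)
    })
    purrr::map_dfr(candidates, function(g) {
      gam <- vapply(ids, function(s) {
        vs <- profs[[s]]
        vg <- profs[[g]]
        if (length(vs) == 0 || length(vg) == 0) return(0)
        functional_similarity(vg, vs)
      }, 0)
      best <- if (all(gam == 0)) NA_character_ else ids[which.max(gam)]
      tibble::tibble(node = g, mas = max(c(gam, 0)), best_seed = best)
    })
  }
  go <- one_ns(ann_go)
  pw <- one_ns(ann_pathway)
  tibble::tibble(node = candidates,
                 mas_go = go$mas, mas_pathway = pw$mas,
                 best_seed_go = go$best_seed, best_seed_pathway = pw$best_seed,
                 kept = go$mas >= threshold & pw$mas >= threshold)
}
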