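#' Benchmark generator configuration
#'
#' Defaults describe a desk-scale stand-in for a plant interactome: a
#' scale-free preferential-attachment backbone of 800 proteins, a 30-protein
#' densely wired "clock" module containing the 9 seed proteins, and two
#' annotation namespaces whose module terms are strongly enriched inside the
#' module (0.8 per node-term) against a sparse background (0.05).
#'
#' @param n_nodes Number of proteins (default 800).
#' @param attach_edges Edges added per node by preferential attachment
#'   (default 3, so almost every node clears the degree-3 filter).
#' @param module_size Size of the planted module (default 30).
#' @param n_seeds Number of seed proteins inside the module (default 9).
#' @param intra_module_p Extra wiring probability per module node pair
#'   (default 0.3).
#' @param n_go_terms,n_pathway_terms Terms per namespace (defaults 30, 15).
#' @param n_module_terms Terms per namespace reserved as module ("clock-like")
#'   terms (default 5).
#' @param module_term_p Probability that a module node carries a module term
#'   (default 0.8).
#' @param background_p Background annotation probability per node-term pair
#'   (default 0.05).
#' @param rng_seed Integer seed (default 1).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_nodes = 800L, attach_edges = 3L,
                             module_size = 30L, n_seeds = 9L,
                             intra_module_p = 0.3,
                             n_go_terms = 30L, n_pathway_terms = 15L,
                             n_module_terms = 5L,
                             module_term_p = 0.8, background_p = 0.05,
                             rng_seed = 1L) {
  stopifnot(module_size < n_nodes, n_seeds >= 1,
            intra_module_p >= 0, intra_module_p <= 1,
            module_term_p >= 0, module_term_p <= 1,
            background_p >= 0, background_p <= 1,
            n_module_terms <= n_go_terms, n_module_terms <= n_pathway_terms)
  if (module_size < n_seeds + 3) {
    stop("module_size must be at least n_seeds + 3")
  }
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a planted-module benchmark instance
#'
#' Builds a scale-free network by preferential attachment, densifies a
#' randomly chosen module whose members all clear the degree-3 filter,
#' designates part of the module as seeds and the rest as planted truth, and
#' annotates module nodes with enriched "clock-like" terms in both the GO and
#' the pathway namespace.
#'
#' @param cfg A [generator_config()].
#' @return A `benchmark_instance` list: `network`, `seeds` (character),
#'   `planted` (character), `module` (seeds + planted), `annotations_go`,
#'   `annotations_pathway`, `config`.
#' @export
generate_benchmark <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(cfg$rng_seed)

  g <- igraph::sample_pa(cfg$n_nodes, power = 1, m = cfg$attach_edges,
                         directed = FALSE)
  names <- sprintf("prot%04d", seq_len(cfg$n_nodes))
  igraph::V(g)$name <- names

  deg <- igraph::degree(g)
  eligible <- names[deg >= 3]
  if (length(eligible) < cfg$module_size) {
    stop("backbone too sparse to host the module; increase attach_edges")
  }
  module <- sort(sample(eligible, cfg$module_size))

  # densify the module
  pairs <- utils::combn(module, 2)
  pick <- stats::runif(ncol(pairs)) < cfg$intra_module_p
  if (any(pick)) {
    new_e <- pairs[, pick, drop = FALSE]
    have <- igraph::are_adjacent
    add <- new_e[, !apply(new_e, 2, function(e) have(g, e[1], e[2])),
                 drop = FALSE]
    if (ncol(add) > 0) g <- igraph::add_edges(g, as.vector(add))
  }

  seeds <- sort(sample(module, cfg$n_seeds))
  planted <- setdiff(module, seeds)

  ann_go <- synth_annotations(names, module, "GO", cfg$n_go_terms,
                              cfg$n_module_terms, cfg$module_term_p,
                              cfg$background_p)
  ann_pw <- synth_annotations(names, module, "pathway", cfg$n_pathway_terms,
                              cfg$n_module_terms, cfg$module_term_p,
                              cfg$background_p)

  structure(list(network = new_clock_network(igraph::simplify(g)),
                 seeds = seeds, planted = planted, module = module,
                 annotations_go = ann_go, annotations_pathway = ann_pw,
                 config = cfg),
            class = "benchmark_instance")
}

synth_annotations <- function(nodes, module, namespace, n_terms,
                              n_module_terms, module_p, background_p) {
  prefix <- if (namespace == "GO") "GO:%07d" else "map%05d"
  terms <- sprintf(prefix, seq_len(n_terms))
  module_terms <- terms[seq_len(n_module_terms)]
  rows <- list()
  for (tm in terms) {
    p <- setNames(rep(background_p, length(nodes)), nodes)
    if (tm %in% module_terms) p[module] <- module_p
    hit <- nodes[stats::runif(length(nodes)) < p]
    if (length(hit) > 0) {
      rows[[length(rows) + 1L]] <- tibble::tibble(gene = hit, term = tm)
    }
  }
  annotation_map(dplyr::bind_rows(rows), namespace)
}

#' @export
print.benchmark_instance <- function(x, ...) {
  cat(sprintf(paste0("<benchmark_instance> %d nodes, %d edges; module %d ",
                     "(%d seeds + %d planted)\n"),
              length(x$network$nodes), igraph::ecount(x$network$graph),
              length(x$module), length(x$seeds), length(x$planted)))
  invisible(x)
}

#' Precision and recall of a candidate set against the planted truth
#'
#' @param instance A `benchmark_instance`.
#' @param final_candidates Character vector (or tibble with a `node` column)
#'   of final candidates.
#' @return A one-row tibble: `n_final`, `n_planted`, `n_hit`, `precision`,
#'   `recall`.
#' @export
evaluate_recovery <- function(instance, final_candidates) {
  stopifnot(inherits(instance, "benchmark_instance"))
  if (is.data.frame(final_candidates)) final_candidates <- final_candidates$node
  final <- unique(as.character(final_candidates))
  hit <- length(intersect(final, instance$planted))
  tibble::tibble(
    n_final = length(final),
    n_planted = length(instance$planted),
    n_hit = hit,
    precision = if (length(final) == 0) 0 else hit / length(final),
    recall = if (length(instance$planted) == 0) 0 else hit / length(instance$planted)
  )
}

#' Write a benchmark instance to plain-text files
#'
#' Writes `net.tsv` (edge list), `seeds.txt`, `go.gmt`, `pathway.gmt` and
#' `truth.txt` (planted ids) into a directory.
#'
#' @param instance A `benchmark_instance`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(instance, dir) {
  stopifnot(inherits(instance, "benchmark_instance"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  edges <- as_edge_tibble(instance$network)
  utils::write.table(edges, file.path(dir, "net.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(instance$seeds, file.path(dir, "seeds.txt"))
  write_gmt(instance$annotations_go, file.path(dir, "go.gmt"))
  write_gmt(instance$annotations_pathway, file.path(dir, "pathway.gmt"))
  writeLines(instance$planted, file.path(dir, "truth.txt"))
  invisible(dir)
}
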