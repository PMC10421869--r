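#' Pipeline configuration
#'
#' Bundles every stage's parameters. Defaults are the published operating
#' point of the method: restart 0.8, L1 tolerance 1e-6, raw threshold 1e-5,
#' similarity grid starting at 0.96 in steps of 0.01, degree filter 3, 1000
#' permutations at alpha 0.05, MAS threshold 0.75.
#'
#' @param restart,l1_tolerance,raw_threshold,max_iterations See [rwr_config()].
#' @param gdv_start,gdv_step Similarity threshold grid (see
#'   [select_threshold()]).
#' @param min_degree Degree filter for the wiring branch and for seed mapping
#'   (default 3).
#' @param rwr_min_degree Degree filter applied to the network before the
#'   restart walk (default 0: the walk runs on the full network).
#' @param n_permutations,swaps_per_edge See [null_config()].
#' @param alpha Permutation-FDR significance level (default 0.05).
#' @param mas_threshold Dual-namespace MAS cutoff (default 0.75).
#' @param exclude_seeds Drop seeds from raw candidate lists (default TRUE).
#' @param use_reduced Compare wiring signatures on the 11 non-redundant
#'   orbits (default TRUE).
#' @param rng_seed Root seed for all randomized stages (default 1).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(restart = 0.8, l1_tolerance = 1e-6,
                            raw_threshold = 1e-5, max_iterations = 10000L,
                            gdv_start = 0.96, gdv_step = 0.01,
                            min_degree = 3L, rwr_min_degree = 0L,
                            n_permutations = 1000L, swaps_per_edge = 10L,
                            alpha = 0.05, mas_threshold = 0.75,
                            exclude_seeds = TRUE, use_reduced = TRUE,
                            rng_seed = 1L) {
  structure(list(
    rwr = rwr_config(restart, l1_tolerance, raw_threshold, max_iterations),
    gdv_start = gdv_start, gdv_step = gdv_step,
    min_degree = as.integer(min_degree),
    rwr_min_degree = as.integer(rwr_min_degree),
    null = null_config(n_permutations, swaps_per_edge, rng_seed),
    alpha = alpha, mas_threshold = mas_threshold,
    exclude_seeds = exclude_seeds, use_reduced = use_reduced,
    rng_seed = as.integer(rng_seed)
  ), class = "pipeline_config")
}

#' Combine the two branch outputs
#'
#' Union of the final candidate sets with per-branch provenance flags.
#'
#' @param rwr_final,gdv_final Character vectors (or tibbles with a `node`
#'   column) of final candidates from each branch.
#' @return A tibble with columns `node`, `in_rwr`, `in_gdv`; attribute
#'   `"overlap"` holds the intersection size.
#' @export
combine_branches <- function(rwr_final, gdv_final) {
  if (is.data.frame(rwr_final)) rwr_final <- rwr_final$node
  if (is.data.frame(gdv_final)) gdv_final <- gdv_final$node
  rwr_final <- unique(as.character(rwr_final))
  gdv_final <- unique(as.character(gdv_final))
  nodes <- union(rwr_final, gdv_final)
  out <- tibble::tibble(node = nodes,
                        in_rwr = nodes %in% rwr_final,
                        in_gdv = nodes %in% gdv_final)
  attr(out, "overlap") <- length(intersect(rwr_final, gdv_final))
  out
}

#' Run the full prioritization pipeline
#'
#' Executes both branches end to end: restart-walk propagation, raw
#' thresholding, random-seed permutation FDR, and MAS filtering on one side;
#' degree filtering, orbit signatures, adaptive similarity threshold,
#' rewired-network permutation FDR, and MAS filtering on the other; then
#' combines the survivors.
#'
#' @param net A [clock_network()].
#' @param seeds Character vector of seed ids (mapped internally with
#'   [map_seeds()]) or a ready `seed_set`.
#' @param ann_go,ann_pathway [annotation_map()] objects.
#' @param config A [pipeline_config()].
#' @param progress Log stage messages (default FALSE).
#' @return A `clockrank_result`: list with `candidates` (the combined
#'   candidate table), `report` (named list of stage counts and parameters),
#'   and per-branch detail tables (`rwr`, `gdv`).
#' @export
run_pipeline <- function(net, seeds, ann_go, ann_pathway,
                         config = pipeline_config(), progress = FALSE) {
  stopifnot(inherits(net, "clock_network"), inherits(config, "pipeline_config"))
  say <- function(...) if (progress) message(sprintf(...))

  seeds <- if (inherits(seeds, "seed_set")) seeds else
    map_seeds(net, seeds, config$min_degree)
  ids <- seeds$mapped
  say("seeds: %d mapped, %d unmapped, %d dropped", length(ids),
      length(seeds$unmapped), length(seeds$dropped_low_degree))

  # --- RWR branch -----------------------------------------------------------
  rwr_net <- if (config$rwr_min_degree > 0) {
    filter_min_degree(net, config$rwr_min_degree)
  } else net
  stage <- rwr_stage(rwr_net, ids, config$rwr, config$exclude_seeds)
  raw_rwr <- stage$raw
  say("RWR: %d raw candidates (%d iterations)", nrow(raw_rwr), stage$iterations)

  null_cfg <- null_config(config$null$n_permutations, config$null$swaps_per_edge,
                          config$rng_seed)
  fdr_rwr <- rwr_permutation_fdr(rwr_net, ids, raw_rwr, null_cfg, config$rwr)
  cand_rwr <- filter_significant(fdr_rwr, config$alpha)
  say("RWR: %d candidates at alpha %.2f", nrow(cand_rwr), config$alpha)

  mas_rwr <- mas_filter(cand_rwr$node, ids, net, ann_go, ann_pathway,
                        config$mas_threshold)
  final_rwr <- dplyr::filter(mas_rwr, .data$kept)$node
  say("RWR: %d final after MAS", length(final_rwr))

  # --- GDV branch -----------------------------------------------------------
  gstage <- gdv_stage(net, ids, config$min_degree, config$gdv_start,
                      config$gdv_step, config$use_reduced)
  say("GDV: threshold %.2f, %d raw candidates", gstage$threshold,
      nrow(gstage$raw))

  gdv_null_cfg <- null_config(config$null$n_permutations,
                              config$null$swaps_per_edge,
                              config$rng_seed + 1L)
  fdr_gdv <- gdv_permutation_fdr(gstage$network, gstage$raw, gdv_null_cfg,
                                 config$use_reduced)
  cand_gdv <- filter_significant(fdr_gdv, config$alpha)
  say("GDV: %d candidates at alpha %.2f", nrow(cand_gdv), config$alpha)

  mas_gdv <- mas_filter(cand_gdv$node, ids, net, ann_go, ann_pathway,
                        config$mas_threshold)
  final_gdv <- dplyr::filter(mas_gdv, .data$kept)$node
  say("GDV: %d final after MAS", length(final_gdv))

  # --- combine --------------------------------------------------------------
  combined <- combine_branches(final_rwr, final_gdv)
  candidates <- combined |>
    dplyr::left_join(dplyr::select(raw_rwr, "node", rwr_probability = "probability"),
                     by = "node") |>
    dplyr::left_join(dplyr::select(fdr_rwr, "node", rwr_p = "p_value"), by = "node") |>
    dplyr::left_join(dplyr::select(gstage$raw, "node", "s_gdv"), by = "node") |>
    dplyr::left_join(dplyr::select(fdr_gdv, "node", gdv_p = "p_value"), by = "node") |>
    dplyr::left_join(dplyr::select(mas_all(mas_rwr, mas_gdv), "node",
                                   "mas_go", "mas_pathway"), by = "node") |>
    dplyr::mutate(final = TRUE)

  report <- list(
    n_nodes = length(net$nodes),
    n_edges = igraph::ecount(net$graph),
    n_seeds_mapped = length(ids),
    n_seeds_unmapped = length(seeds$unmapped),
    n_seeds_dropped = length(seeds$dropped_low_degree),
    raw_rwr = nrow(raw_rwr),
    candidate_rwr = nrow(cand_rwr),
    final_rwr = length(final_rwr),
    gdv_threshold = gstage$threshold,
    raw_gdv = nrow(gstage$raw),
    candidate_gdv = nrow(cand_gdv),
    final_gdv = length(final_gdv),
    overlap = attr(combined, "overlap"),
    final_union = nrow(combined),
    n_permutations = config$null$n_permutations,
    alpha = config$alpha,
    mas_threshold = config$mas_threshold,
    rng_seed = config$rng_seed
  )

  structure(list(
    candidates = candidates, report = report, seeds = seeds,
    rwr = list(raw = raw_rwr, fdr = fdr_rwr, mas = mas_rwr,
               stationary = stage$stationary),
    gdv = list(raw = gstage$raw, fdr = fdr_gdv, mas = mas_gdv,
               threshold = gstage$threshold),
    config = config
  ), class = "clockrank_result")
}

mas_all <- function(mas_rwr, mas_gdv) {
  dplyr::bind_rows(mas_rwr, mas_gdv) |>
    dplyr::group_by(.data$node) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' @export
print.clockrank_result <- function(x, ...) {
  r <- x$report
  cat("<clockrank_result>\n")
  cat(sprintf("  network: %d nodes, %d edges; seeds mapped: %d\n",
              r$n_nodes, r$n_edges, r$n_seeds_mapped))
  cat(sprintf("  RWR: %d raw -> %d significant -> %d final\n",
              r$raw_rwr, r$candidate_rwr, r$final_rwr))
  cat(sprintf("  GDV (threshold %.2f): %d raw -> %d significant -> %d final\n",
              r$gdv_threshold, r$raw_gdv, r$candidate_gdv, r$final_gdv))
  cat(sprintf("  union: %d candidates (%d in both branches)\n",
              r$final_union, r$overlap))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes per-stage TSVs (`rwr_raw.tsv`, `rwr_candidates.tsv`, `gdv_raw.tsv`,
#' `gdv_candidates.tsv`, `final_candidates.tsv`) and a machine-readable
#' `manifest.json` with every stage count and parameter.
#'
#' @param result A `clockrank_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "clockrank_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(result$rwr$raw, "rwr_raw.tsv")
  wt(result$rwr$fdr, "rwr_candidates.tsv")
  wt(result$gdv$raw, "gdv_raw.tsv")
  wt(result$gdv$fdr, "gdv_candidates.tsv")
  wt(result$candidates, "final_candidates.tsv")
  jsonlite::write_json(result$report, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
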