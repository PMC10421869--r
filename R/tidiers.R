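#' Tidy a pipeline result
#'
#' @param x A `clockrank_result`.
#' @param ... Unused.
#' @return The combined candidate table: one row per final candidate with
#'   branch flags, branch statistics, and MAS values.
#' @method tidy clockrank_result
#' @export
tidy.clockrank_result <- function(x, ...) {
  x$candidates
}

#' One-row summary of a pipeline run
#'
#' @param x A `clockrank_result`.
#' @param ... Unused.
#' @return A one-row tibble of stage counts and key parameters.
#' @method glance clockrank_result
#' @export
glance.clockrank_result <- function(x, ...) {
  tibble::as_tibble(x$report)
}

#' Stage-count funnel plot for a pipeline run
#'
#' Shows how each branch narrows from raw candidates through the permutation
#' filter to the final MAS survivors.
#'
#' @param object A `clockrank_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clockrank_result
#' @export
autoplot.clockrank_result <- function(object, ...) {
  r <- object$report
  df <- tibble::tibble(
    branch = rep(c("RWR", "GDV"), each = 3),
    stage = factor(rep(c("raw", "significant", "final"), 2),
                   levels = c("raw", "significant", "final")),
    count = c(r$raw_rwr, r$candidate_rwr, r$final_rwr,
              r$raw_gdv, r$candidate_gdv, r$final_gdv)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$count,
                                   fill = .data$branch)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count),
                       position = ggplot2::position_dodge(width = 0.9),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "candidates",
                  title = "Candidate funnel by branch",
                  subtitle = sprintf("union: %d (%d shared)",
                                     r$final_union, r$overlap)) +
    ggplot2::theme_minimal()
}

#' Stationary-probability plot for the restart-walk stage
#'
#' Ranks nodes by stationary probability and marks the raw-candidate
#' threshold; seeds are highlighted.
#'
#' @param p Stationary distribution (named numeric) from [rwr_iterate()].
#' @param seeds Seed ids (character or `seed_set`).
#' @param tau Raw-candidate threshold drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_rwr_ranks <- function(p, seeds = character(), tau = 1e-5) {
  ids <- seed_ids(seeds)
  df <- tibble::tibble(node = names(p), probability = as.numeric(p),
                       is_seed = names(p) %in% ids) |>
    dplyr::arrange(dplyr::desc(.data$probability)) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$probability,
                                   colour = .data$is_seed)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = tau, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "rank", y = "stationary probability",
                  colour = "seed") +
    ggplot2::theme_minimal()
}
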