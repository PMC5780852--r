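#' Plot marker counts across an e-value sweep
#'
#' @param sweep A tibble from [evalue_sweep()].
#' @return A ggplot: marker count against the e-value cutoff (log scale).
#' @export
plot_evalue_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$cutoff, y = .data$n_markers)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "e-value cutoff", y = "single-copy markers") +
    ggplot2::theme_minimal()
}

#' Heatmap of a copy-number matrix
#'
#' @param object A `copy_matrix` from [build_copy_matrix()].
#' @param max_profiles Cap on the number of profile columns drawn (most
#'   frequent first) to keep the panel readable.
#' @param ... Unused.
#' @return A ggplot tile heatmap of genome-by-profile copy numbers.
#' @method autoplot copy_matrix
#' @export
autoplot.copy_matrix <- function(object, max_profiles = 60, ...) {
  m <- unclass(object)
  if (ncol(m) > max_profiles) {
    keep <- order(colSums(m > 0), decreasing = TRUE)[seq_len(max_profiles)]
    m <- m[, sort(keep), drop = FALSE]
  }
  df <- as_tibble(as.table(m), .name_repair = ~c("genome_id", "profile_acc", "n"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$profile_acc, y = .data$genome_id,
                                   fill = factor(.data$n))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_d(name = "copies") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Bar chart of COG category counts
#'
#' @param categorization A `cog_categorization` from
#'   [categorize_markers()], or its `category_counts` tibble.
#' @return A ggplot bar chart of marker counts per one-letter category.
#' @export
plot_category_counts <- function(categorization) {
  counts <- if (inherits(categorization, "cog_categorization")) {
    categorization$category_counts
  } else {
    categorization
  }
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = stats::reorder(.data$category,
                                                  -.data$n_markers),
                               y = .data$n_markers)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "COG category", y = "markers") +
    ggplot2::theme_minimal()
}

#' Plot a pipeline run
#'
#' @param object A `marker_run` from [run_pipeline()].
#' @param type `"trimming"` (per-marker retained vs input alignment
#'   widths) or `"categories"` (COG category counts; requires the COG
#'   inputs to have been given).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot marker_run
#' @export
autoplot.marker_run <- function(object, type = c("trimming", "categories"),
                                ...) {
  type <- match.arg(type)
  if (type == "categories") {
    if (is.null(object$cogs)) {
      abort("run had no COG inputs; nothing to plot")
    }
    return(plot_category_counts(object$cogs))
  }
  if (is.null(object$trimmed)) {
    abort("run was not trimmed; nothing to plot")
  }
  df <- object$trimmed$report |>
    tidyr::pivot_longer(c("input_width", "retained_width"),
                        names_to = "stage", values_to = "columns")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$profile_acc,
                                   y = .data$columns,
                                   fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "alignment columns") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
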