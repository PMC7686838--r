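# ggplot2 views of the main result types.

#' Plot per-query hit counts
#'
#' Bar chart of unique-compound hit counts per structural query, facetted by
#' library.
#'
#' @param hits Hit tibble from [substructure_screen()].
#' @return A ggplot object.
#' @export
plot_hit_counts <- function(hits) {
  counts <- hits |>
    dplyr::group_by(.data$library, .data$smarts) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$inchikey), .groups = "drop") |>
    dplyr::mutate(query = factor(
      paste0("Q", as.integer(factor(.data$smarts))),
      levels = paste0("Q", seq_along(unique(.data$smarts)))))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$query, y = .data$n)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::facet_wrap(ggplot2::vars(.data$library)) +
    ggplot2::labs(x = "structural query", y = "unique compounds hit") +
    ggplot2::theme_minimal()
}

#' Plot the pX distribution with the activity cutoff
#'
#' @param data Labeled activity tibble (needs `px`, `label`).
#' @param cutoff The pX cutoff drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_px_distribution <- function(data, cutoff = 9) {
  df <- dplyr::filter(data, !is.na(.data$px))
  df$labelled <- factor(ifelse(is.na(df$label), "unlabeled",
                               ifelse(df$label == 1, "active", "inactive")),
                        levels = c("active", "inactive", "unlabeled"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$px, fill = .data$labelled)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.85, position = "identity") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(active = "#228833",
                                          inactive = "#aaaaaa",
                                          unlabeled = "#ddcc77")) +
    ggplot2::labs(x = "pX (-log10 molar activity)", y = "measurements",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot method for scaffold clusterings
#'
#' Cluster sizes per target: one bar per cluster, height = member scaffolds.
#'
#' @param object An `sq_clustering` from [cluster_scaffold_table()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot sq_clustering
#' @export
autoplot.sq_clustering <- function(object, ...) {
  sizes <- object |>
    dplyr::group_by(.data$uniprot_id, .data$cluster_id) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop")
  ggplot2::ggplot(sizes, ggplot2::aes(x = factor(.data$cluster_id),
                                      y = .data$n)) +
    ggplot2::geom_col(fill = "#66ccee") +
    ggplot2::facet_wrap(ggplot2::vars(.data$uniprot_id), scales = "free_x") +
    ggplot2::labs(x = "cluster", y = "scaffolds",
                  title = sprintf("scaffold clusters (threshold %.2f, %s linkage)",
                                  attr(object, "threshold"),
                                  attr(object, "linkage"))) +
    ggplot2::theme_minimal()
}
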