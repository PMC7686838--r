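# broom-style accessors for the clustering result.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a scaffold clustering
#'
#' @param x An `sq_clustering` from [cluster_scaffold_table()].
#' @param ... Ignored.
#' @return One row per scaffold: `uniprot_id`, `scaffold`, `cluster_id`,
#'   `heavy_atoms`, `n_parents`.
#' @method tidy sq_clustering
#' @export
tidy.sq_clustering <- function(x, ...) {
  tibble::as_tibble(x)[c("uniprot_id", "scaffold", "cluster_id",
                         "heavy_atoms", "n_parents")]
}

#' Summarize a scaffold clustering in one row
#'
#' @inheritParams tidy.sq_clustering
#' @return One row: targets, scaffolds, clusters, singleton count, and the
#'   parameters used.
#' @method glance sq_clustering
#' @export
glance.sq_clustering <- function(x, ...) {
  per <- tibble::as_tibble(x) |>
    dplyr::count(.data$uniprot_id, .data$cluster_id)
  tibble::tibble(
    n_targets = dplyr::n_distinct(x$uniprot_id),
    n_scaffolds = nrow(x),
    n_clusters = nrow(per),
    n_singletons = sum(per$n == 1L),
    threshold = attr(x, "threshold"),
    linkage = attr(x, "linkage"))
}
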