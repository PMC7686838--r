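# One SMARTS structural query per scaffold cluster per target: the maximum
# common substructure over all cluster members, rendered in the
# element-number / explicit-bond dialect and verified against every member.

#' Read a SMARTS query file
#'
#' Tab-separated lines `cluster<TAB>smarts[<TAB>hits[<TAB>targets]]` or bare
#' SMARTS one per line; `#` comment lines are skipped. This is the exchange
#' format written by [write_query_file()] and shipped for the published
#' 18-query set (`system.file("extdata", "table2.smarts", package =
#' "scaffquery")`).
#'
#' @param path File path.
#' @return Tibble with `cluster`, `smarts`, and when present `hits`,
#'   `targets`.
#' @export
read_smarts_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (all(nfield == 1L)) {
    return(tibble::tibble(cluster = NA_character_, smarts = trimws(lines)))
  }
  if (all(nfield == 5L)) {          # write_query_file() layout
    return(tibble::tibble(
      uniprot_id = vapply(parts, `[`, character(1), 1),
      cluster = vapply(parts, `[`, character(1), 2),
      smarts = vapply(parts, `[`, character(1), 3),
      heavy_atoms = as.integer(vapply(parts, `[`, character(1), 4)),
      n_members = as.integer(vapply(parts, `[`, character(1), 5))))
  }
  tibble::tibble(
    cluster = vapply(parts, `[`, character(1), 1),
    smarts = vapply(parts, `[`, character(1), 2),
    hits = suppressWarnings(as.integer(vapply(parts, function(p) p[3] %||% NA_character_,
                                              character(1)))),
    targets = vapply(parts, function(p) p[4] %||% NA_character_, character(1))
  )
}

#' Write a SMARTS query table
#'
#' @param queries Tibble from [generate_queries()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_query_file <- function(queries, path) {
  hdr <- "# uniprot_id\tcluster_id\tsmarts\theavy_atoms\tn_members"
  body <- sprintf("%s\t%s\t%s\t%d\t%d", queries$uniprot_id,
                  queries$cluster_id, queries$smarts, queries$heavy_atoms,
                  queries$n_members)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' MCS query for one scaffold cluster
#'
#' A singleton cluster's query is the scaffold itself rendered as SMARTS; a
#' multi-member cluster's query is the multi-structure MCS, computed by
#' iterative pairwise folding in canonical-SMILES order and then verified to
#' match every member. Queries below `min_query_size` heavy atoms are
#' rejected (`NULL`) as vacuous.
#'
#' @param member_scaffolds Character vector of the cluster's scaffold SMILES.
#' @param min_query_size Minimum heavy-atom count for an emitted query.
#' @param timeout Per-fold MCS budget (seconds).
#' @return A list with `smarts`, `heavy_atoms`, `n_members`, `approximate`,
#'   or `NULL` when the MCS is below the size floor.
#' @export
cluster_mcs_query <- function(member_scaffolds, min_query_size = 3, timeout = 5) {
  members <- sort(unique(member_scaffolds))
  if (!length(members)) stop_sq("validation", "empty scaffold cluster")
  mols <- lapply(members, mol_from_smiles)
  approx <- FALSE
  if (length(mols) == 1L) {
    pat <- mol_to_pattern(mols[[1L]])
  } else {
    res <- mcs_graphs(mols[[1L]], mols[[2L]], timeout = timeout)
    approx <- approx || res$approximate
    pat <- mcs_pattern(mols[[1L]], res)
    if (length(mols) > 2L) {
      for (k in seq(3L, length(mols))) {
        if (is.null(pat)) break
        pm <- pattern_to_mol(pat)
        res <- mcs_graphs(pm, mols[[k]], timeout = timeout)
        approx <- approx || res$approximate
        pat <- mcs_pattern(pm, res)
      }
    }
  }
  if (is.null(pat) || pattern_n_atoms(pat) < min_query_size) return(NULL)
  smarts <- render_smarts(pat)
  reparsed <- parse_smarts(smarts)
  for (m in mols) {
    if (!length(match_pattern(reparsed, m))) {
      stop_sq("validation",
              sprintf("generated query '%s' fails to match member scaffold", smarts))
    }
  }
  list(smarts = smarts, heavy_atoms = pattern_n_atoms(pat),
       n_members = length(members), approximate = approx)
}

#' Generate structural queries for a clustered scaffold table
#'
#' At most one query per cluster, deduplicated by pattern within each target
#' (member counts summed).
#'
#' @param clusters An `sq_clustering` tibble (from [cluster_scaffold_table()]).
#' @inheritParams cluster_mcs_query
#' @return Tibble: `uniprot_id`, `cluster_id`, `smarts`, `heavy_atoms`,
#'   `n_members`, `approximate`.
#' @export
generate_queries <- function(clusters, min_query_size = 3, timeout = 5) {
  if (!nrow(clusters)) {
    return(tibble::tibble(uniprot_id = character(), cluster_id = integer(),
                          smarts = character(), heavy_atoms = integer(),
                          n_members = integer(), approximate = logical()))
  }
  stopifnot(all(c("uniprot_id", "cluster_id", "scaffold") %in% names(clusters)))
  per_cluster <- clusters |>
    dplyr::group_by(.data$uniprot_id, .data$cluster_id) |>
    dplyr::summarise(members = list(.data$scaffold), .groups = "drop")
  rows <- purrr::pmap(per_cluster, function(uniprot_id, cluster_id, members) {
    q <- cluster_mcs_query(members, min_query_size = min_query_size,
                           timeout = timeout)
    if (is.null(q)) return(NULL)
    tibble::tibble(uniprot_id = uniprot_id, cluster_id = cluster_id,
                   smarts = q$smarts, heavy_atoms = q$heavy_atoms,
                   n_members = q$n_members, approximate = q$approximate)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble::tibble(uniprot_id = character(), cluster_id = integer(),
                          smarts = character(), heavy_atoms = integer(),
                          n_members = integer(), approximate = logical()))
  }
  out |>
    dplyr::group_by(.data$uniprot_id, .data$smarts) |>
    dplyr::summarise(cluster_id = min(.data$cluster_id),
                     heavy_atoms = .data$heavy_atoms[1],
                     n_members = sum(.data$n_members),
                     approximate = any(.data$approximate),
                     .groups = "drop") |>
    dplyr::select("uniprot_id", "cluster_id", "smarts", "heavy_atoms",
                  "n_members", "approximate") |>
    dplyr::arrange(.data$uniprot_id, .data$cluster_id)
}
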