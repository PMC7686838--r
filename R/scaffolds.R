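# Bemis-Murcko scaffold extraction and per-target hierarchical clustering of
# scaffolds by maximum-common-substructure distance.
#
# The scaffold (framework) of a molecule is its ring systems plus the linker
# atoms connecting them, with all side chains removed; atoms attached to the
# framework by a double or triple bond (e.g. a carbonyl oxygen on a ring or
# linker) stay with it. A molecule without a ring has no framework.

#' Bemis-Murcko scaffold of a structure
#'
#' @param smiles A single SMILES string (standardized input expected).
#' @return Canonical SMILES of the framework, or `NA` when the structure has
#'   no ring.
#' @export
murcko_scaffold <- function(smiles) {
  mol <- if (is_mol(smiles)) smiles else mol_from_smiles(smiles)
  ring_atoms <- mol_ring_atoms(mol)
  if (!length(ring_atoms)) return(NA_character_)

  # rings + linkers: iteratively prune terminal non-ring atoms
  adj <- mol_adjacency(mol)
  keep <- rep(TRUE, n_atoms(mol))
  repeat {
    deg <- vapply(seq_len(n_atoms(mol)),
                  function(v) sum(keep[adj[[v]]]), integer(1))
    prune <- which(keep & deg <= 1L & !(seq_len(n_atoms(mol)) %in% ring_atoms))
    if (!length(prune)) break
    keep[prune] <- FALSE
  }
  framework <- which(keep)
  # atoms double/triple-bonded to the framework stay with it
  multi <- mol$bonds$order >= 2L & !mol$bonds$arom
  attach_i <- mol$bonds$i[multi]; attach_j <- mol$bonds$j[multi]
  extra <- c(attach_j[attach_i %in% framework & !(attach_j %in% framework)],
             attach_i[attach_j %in% framework & !(attach_i %in% framework)])
  scaffold <- mol_subgraph(clear_stereo(mol), sort(c(framework, extra)))
  mol_to_canonical(scaffold)
}

#' Is a scaffold too generic to query with?
#'
#' A framework consisting of a single ring (e.g. a lone benzene or pyridine)
#' carries no discriminative value for substructure screening.
#'
#' @param scaffold_smiles Scaffold SMILES.
#' @param max_generic_rings Frameworks with at most this many rings are
#'   flagged generic (default 1).
#' @return Logical scalar.
#' @export
is_too_generic <- function(scaffold_smiles, max_generic_rings = 1) {
  mol <- if (is_mol(scaffold_smiles)) scaffold_smiles
         else mol_from_smiles(scaffold_smiles)
  mol_ring_count(mol) <= max_generic_rings
}

#' Extract unique scaffolds per target
#'
#' Computes the Murcko scaffold of every compound, drops ring-free
#' structures, and groups to one row per (target, scaffold) with the
#' contributing compound keys.
#'
#' @param data Tibble with `uniprot_id`, `inchikey` and a structure column.
#' @param smiles_col Name of the structure column (default `std_smiles`).
#' @return Tibble: `uniprot_id`, `scaffold`, `heavy_atoms`, `ring_count`,
#'   `n_parents`, `parent_keys` (list-column).
#' @export
extract_scaffolds <- function(data, smiles_col = "std_smiles") {
  stopifnot(all(c("uniprot_id", "inchikey", smiles_col) %in% names(data)))
  scaff <- vapply(data[[smiles_col]], function(s) {
    if (is.na(s)) NA_character_ else murcko_scaffold(s)
  }, character(1), USE.NAMES = FALSE)
  out <- tibble::as_tibble(data[c("uniprot_id", "inchikey")])
  out$scaffold <- scaff
  out <- dplyr::filter(out, !is.na(.data$scaffold))
  out |>
    dplyr::group_by(.data$uniprot_id, .data$scaffold) |>
    dplyr::summarise(n_parents = dplyr::n_distinct(.data$inchikey),
                     parent_keys = list(sort(unique(.data$inchikey))),
                     .groups = "drop") |>
    dplyr::mutate(
      heavy_atoms = vapply(.data$scaffold,
                           function(s) mol_heavy_atoms(mol_from_smiles(s)),
                           integer(1), USE.NAMES = FALSE),
      ring_count = vapply(.data$scaffold,
                          function(s) mol_ring_count(mol_from_smiles(s)),
                          integer(1), USE.NAMES = FALSE)) |>
    dplyr::arrange(.data$uniprot_id, .data$scaffold)
}

#' Drop too-generic scaffolds
#'
#' @param data Output of [extract_scaffolds()].
#' @inheritParams is_too_generic
#' @return Filtered tibble.
#' @export
filter_generic_scaffolds <- function(data, max_generic_rings = 1) {
  dplyr::filter(data, .data$ring_count > max_generic_rings)
}

#' MCS distance matrix for a scaffold set
#'
#' Scaffolds are sorted by canonical SMILES before matrix construction so the
#' result is independent of input order.
#'
#' @param scaffolds Character vector of scaffold SMILES.
#' @param formula,timeout Passed to [scaffold_distance()].
#' @return Symmetric matrix with zero diagonal, entries in `[0, 1]`, labeled
#'   by scaffold SMILES.
#' @export
scaffold_distance_matrix <- function(scaffolds, formula = "tanimoto",
                                     timeout = 5) {
  scaffolds <- sort(unique(scaffolds))
  n <- length(scaffolds)
  mols <- lapply(scaffolds, mol_from_smiles)
  d <- matrix(0, n, n, dimnames = list(scaffolds, scaffolds))
  if (n > 1L) {
    for (a in seq_len(n - 1L)) {
      for (b in seq((a + 1L), n)) {
        d[a, b] <- d[b, a] <-
          scaffold_distance(mols[[a]], mols[[b]], formula = formula,
                            timeout = timeout)
      }
    }
  }
  d
}

#' Cluster scaffolds by MCS distance
#'
#' Agglomerative hierarchical clustering of one target's scaffolds, cut at a
#' distance threshold. A single scaffold forms one singleton cluster without
#' any matrix computation. Cluster ids are assigned in order of each
#' cluster's first member (canonical-SMILES order), so the assignment is
#' deterministic and invariant to input row order.
#'
#' @param scaffolds Character vector of scaffold SMILES (one target).
#' @param threshold Distance cut height in (0, 1] (default 0.5).
#' @param linkage One of `"average"` (default), `"single"`, `"complete"`.
#' @param formula Distance formula, see [scaffold_distance()].
#' @return Tibble with `scaffold` and `cluster_id`.
#' @export
cluster_scaffolds <- function(scaffolds, threshold = 0.5,
                              linkage = c("average", "single", "complete"),
                              formula = "tanimoto") {
  linkage <- match.arg(linkage)
  if (is.na(threshold) || threshold <= 0 || threshold > 1) {
    stop_sq("validation", "threshold must lie in (0, 1]")
  }
  scaffolds <- sort(unique(scaffolds))
  if (!length(scaffolds)) {
    return(tibble::tibble(scaffold = character(), cluster_id = integer()))
  }
  if (length(scaffolds) == 1L) {
    return(tibble::tibble(scaffold = scaffolds, cluster_id = 1L))
  }
  d <- scaffold_distance_matrix(scaffolds, formula = formula)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  raw <- stats::cutree(hc, h = threshold)
  # renumber in order of first appearance along canonical-SMILES order
  ids <- match(raw, unique(raw))
  tibble::tibble(scaffold = scaffolds, cluster_id = as.integer(ids))
}

#' Cluster every target's scaffolds
#'
#' Runs [cluster_scaffolds()] independently per target (the per-target loop
#' of the pipeline) and returns the input with `cluster_id` attached.
#'
#' @param data Output of [extract_scaffolds()] (after generic filtering).
#' @inheritParams cluster_scaffolds
#' @return An `sq_clustering` tibble: input plus `cluster_id`, with the
#'   clustering parameters stored as attributes.
#' @export
cluster_scaffold_table <- function(data, threshold = 0.5, linkage = "average",
                                   formula = "tanimoto") {
  stopifnot(all(c("uniprot_id", "scaffold") %in% names(data)))
  assignments <- data |>
    dplyr::group_by(.data$uniprot_id) |>
    dplyr::group_modify(function(g, key) {
      cluster_scaffolds(g$scaffold, threshold = threshold, linkage = linkage,
                        formula = formula)
    }) |>
    dplyr::ungroup()
  out <- dplyr::left_join(tibble::as_tibble(data), assignments,
                          by = c("uniprot_id", "scaffold")) |>
    dplyr::arrange(.data$uniprot_id, .data$cluster_id, .data$scaffold)
  structure(out, class = c("sq_clustering", class(out)),
            threshold = threshold, linkage = linkage, formula = formula)
}
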