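# Bioactivity processing: negative-log (pX) transform, binary labeling at a
# configurable cutoff, per-(target, ligand) median aggregation, and merging of
# sources into one unique-actives-per-target table. Ki/IC50/Km-type endpoints
# are mixed on the common pX scale, as the source breakdowns of this kind of
# pipeline do.

# decade exponent of each unit relative to molar; kept as integers so
# to_pscale(1000, nM) and to_pscale(1, uM) are bit-identical
UNIT_DECADES <- c(M = 0, mM = -3, uM = -6, nM = -9, pM = -12)

#' Negative-log transform of a concentration measurement
#'
#' `pX = -log10(value in molar)`: 1 nM gives 9, 1 uM gives 6.
#'
#' @param value Numeric vector of measured values (must be positive).
#' @param unit Character vector of concentration units (M, mM, uM, nM, pM;
#'   recycled if length 1).
#' @return Numeric vector of pX values; `NA` where the value is non-positive
#'   or the unit unsupported.
#' @export
to_pscale <- function(value, unit) {
  if (length(unit) == 1L) unit <- rep(unit, length(value))
  stopifnot(length(unit) == length(value))
  dec <- UNIT_DECADES[unit]
  px <- suppressWarnings(-(log10(value) + dec))
  px[!is.finite(px) | is.na(dec) | value <= 0] <- NA_real_
  unname(px)
}

#' Binary activity label at a pX cutoff
#'
#' A compound is labeled active (1) when its pX is strictly greater than the
#' cutoff; at or below, inactive (0).
#'
#' @param px Numeric vector of pX values.
#' @param cutoff Activity cutoff on the pX scale (9 by default, i.e. < 1 nM).
#' @return Integer vector of 0/1 labels (`NA` where pX is unset).
#' @export
assign_label <- function(px, cutoff = 9) {
  ifelse(is.na(px), NA_integer_, as.integer(px > cutoff))
}

#' Add pX and activity labels to a bioactivity table
#'
#' Applies [to_pscale()] and [assign_label()], honouring the measurement
#' relation: "=" rows are always labeled; "<"-type rows are kept only when the
#' bound forces the label (e.g. "< 1 nM" at cutoff 9 is active however far
#' below the bound the true value lies), and ">"-type rows symmetrically for
#' inactivity; other rows get no label.
#'
#' @param data Data frame with `value`, `unit`, and optionally `relation`.
#' @param cutoff pX activity cutoff.
#' @return The table with `px` and `label` columns added.
#' @export
label_activities <- function(data, cutoff = 9) {
  out <- tibble::as_tibble(data)
  out$px <- to_pscale(out$value, out$unit)
  lab <- assign_label(out$px, cutoff)
  if ("relation" %in% names(out)) {
    rel <- ifelse(is.na(out$relation) | out$relation == "", "=", out$relation)
    px <- out$px
    # "< x" means the true value lies below x, so the true pX is strictly
    # greater than the bound's pX: active is forced when the bound already
    # reaches the cutoff. ">"-type bounds force inactivity symmetrically.
    forced1 <- !is.na(px) &
      ((rel == "<" & px >= cutoff) | (rel == "<=" & px > cutoff))
    forced0 <- !is.na(px) & rel %in% c(">", ">=") & px <= cutoff
    lab[rel != "="] <- NA_integer_
    lab[forced1] <- 1L
    lab[forced0] <- 0L
  }
  out$label <- lab
  out$cutoff_used <- cutoff
  out
}

#' Aggregate labels per target-ligand pair
#'
#' Groups by (`uniprot_id`, `inchikey`) and takes the exact median of the
#' binary labels; a pair is active iff the median equals 1 (an even 0/1 split
#' gives 0.5 and is not active).
#'
#' @param data Labeled bioactivity table (needs `uniprot_id`, `inchikey`,
#'   `label`; rows with `NA` label are excluded).
#' @return Tibble with `uniprot_id`, `inchikey`, `n_measurements`,
#'   `median_label`, `active`, `cutoff_used`, `sources`.
#' @export
aggregate_labels <- function(data) {
  stopifnot(all(c("uniprot_id", "inchikey", "label") %in% names(data)))
  data |>
    dplyr::filter(!is.na(.data$label), !is.na(.data$inchikey)) |>
    dplyr::group_by(.data$uniprot_id, .data$inchikey) |>
    dplyr::summarise(
      n_measurements = dplyr::n(),
      median_label = as.numeric(stats::median(.data$label)),
      cutoff_used = .data$cutoff_used[1],
      sources = list(sort(unique(as.character(
        if ("source" %in% names(data)) .data$source else "unknown")))),
      .groups = "drop"
    ) |>
    dplyr::mutate(active = .data$median_label == 1)
}

#' Merge per-source actives with PDB-derived ligands
#'
#' Keeps only active (median label 1) ligands, adds PDB-derived ligands
#' regardless of label (they carry none), and deduplicates to one row per
#' (`uniprot_id`, `inchikey`) with full source provenance.
#'
#' @param label_tables A tibble from [aggregate_labels()] or a list of them
#'   (one per source).
#' @param pdb_ligands Optional tibble of PDB-derived ligands with
#'   `uniprot_id`, `inchikey` (and optionally `smiles`).
#' @return Tibble with one row per (`uniprot_id`, `inchikey`), `provenance`
#'   list-column, and `from_pdb` flag.
#' @export
merge_active_set <- function(label_tables, pdb_ligands = NULL) {
  if (is.data.frame(label_tables)) label_tables <- list(label_tables)
  labeled <- dplyr::bind_rows(label_tables)
  if (nrow(labeled)) {
    if (anyNA(labeled$inchikey)) {
      stop_sq("validation", "labeled ligand without InChIKey; standardize first")
    }
    actives <- labeled |>
      dplyr::filter(.data$active) |>
      dplyr::select("uniprot_id", "inchikey", "sources")
  } else {
    actives <- tibble::tibble(uniprot_id = character(), inchikey = character(),
                              sources = list())
  }
  if (!is.null(pdb_ligands) && nrow(pdb_ligands)) {
    if (anyNA(pdb_ligands$inchikey)) {
      stop_sq("validation", "PDB ligand without InChIKey; standardize first")
    }
    pdb <- tibble::tibble(uniprot_id = pdb_ligands$uniprot_id,
                          inchikey = pdb_ligands$inchikey,
                          sources = list("pdb"))
    actives <- dplyr::bind_rows(actives, pdb)
  }
  actives |>
    dplyr::group_by(.data$uniprot_id, .data$inchikey) |>
    dplyr::summarise(
      provenance = list(sort(unique(unlist(.data$sources)))),
      .groups = "drop"
    ) |>
    dplyr::mutate(from_pdb = purrr::map_lgl(.data$provenance, ~ "pdb" %in% .x)) |>
    dplyr::arrange(.data$uniprot_id, .data$inchikey)
}
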