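# Library I/O: SDF and SMILES tables in, standardized tables and SDF out.
# Format conversion is delegated to OpenBabel; the tables are tibbles.

#' Read a screening library
#'
#' Accepts SDF (V2000 multi-record; converted through OpenBabel) or a
#' SMILES CSV/TSV with configurable column names.
#'
#' @param path File path (`.sdf`, `.smi`, `.csv`, `.tsv`, `.txt`).
#' @param smiles_col,id_col,name_col Column names for tabular input.
#' @param library Library label attached to every record (defaults to the
#'   file name without extension).
#' @return Tibble with `library`, `compound_id`, `name`, `smiles`.
#' @export
read_compound_library <- function(path, smiles_col = "smiles",
                                  id_col = "compound_id", name_col = "name",
                                  library = NULL) {
  if (!file.exists(path)) stop_sq("validation", sprintf("no such file: %s", path))
  library <- library %||% tools::file_path_sans_ext(basename(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "sdf") {
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
    smi <- ChemmineOB::convertFormat("SDF", "SMI", source = paste0(text, "\n"))
    lines <- strsplit(smi, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- vapply(parts, function(p) trimws(p[2] %||% ""), character(1))
    ids[!nzchar(ids)] <- sprintf("MOL_%d", which(!nzchar(ids)))
    return(tibble::tibble(
      library = library, compound_id = ids, name = ids,
      smiles = vapply(parts, `[`, character(1), 1)))
  }
  if (ext == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "[\t ]+")
    ids <- vapply(parts, function(p) p[2] %||% NA_character_, character(1))
    ids[is.na(ids)] <- sprintf("MOL_%d", which(is.na(ids)))
    return(tibble::tibble(
      library = library, compound_id = ids, name = ids,
      smiles = vapply(parts, `[`, character(1), 1)))
  }
  delim <- if (ext == "tsv") "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  if (!smiles_col %in% names(raw)) {
    stop_sq("validation", sprintf("column '%s' not found in %s", smiles_col, path))
  }
  tibble::tibble(
    library = library,
    compound_id = if (id_col %in% names(raw)) as.character(raw[[id_col]])
                  else sprintf("MOL_%d", seq_len(nrow(raw))),
    name = if (name_col %in% names(raw)) as.character(raw[[name_col]])
           else NA_character_,
    smiles = as.character(raw[[smiles_col]]))
}

#' Write a standardized library as SDF
#'
#' @param data Tibble with a structure column and `compound_id`.
#' @param path Output SDF path.
#' @param smiles_col Structure column.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(data, path, smiles_col = "std_smiles") {
  ok <- !is.na(data[[smiles_col]])
  src <- paste0(paste(data[[smiles_col]][ok], "\t", data$compound_id[ok],
                      sep = "", collapse = "\n"), "\n")
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", source = src)
  writeLines(sdf, path)
  invisible(path)
}

#' Write the standardized identity table
#'
#' TSV with one row per compound: id, name, canonical SMILES, InChI,
#' InChIKey, stripped salt fragments and rejection reason.
#'
#' @param data Output of [standardize_compounds()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_identity_table <- function(data, path) {
  out <- tibble::tibble(
    compound_id = data[["compound_id"]] %||% sprintf("MOL_%d", seq_len(nrow(data))),
    name = data[["name"]] %||% NA_character_,
    std_smiles = data$std_smiles,
    inchi = data$inchi,
    inchikey = data$inchikey,
    salt_fragments = vapply(data$salt_fragments, paste, character(1),
                            collapse = ";"),
    rejected = data$rejected)
  readr::write_tsv(out, path)
  invisible(path)
}
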