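# Structure identity through OpenBabel (ChemmineOB): canonical SMILES, InChI,
# InChIKey. OpenBabel's aromaticity perception is the package's single
# perception model: every SMILES entering the graph layer is canonicalized
# first, so aromatic flags are assigned the same way everywhere.

ob_convert <- function(from, to, x) {
  if (!length(x)) return(character())
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & nzchar(trimws(x))
  if (!any(ok)) return(out)
  src <- paste0(paste(x[ok], collapse = "\n"), "\n")
  res <- tryCatch(
    ChemmineOB::convertFormat(from, to, source = src),
    error = function(e) NULL
  )
  lines <- if (is.null(res)) character() else {
    strsplit(res, "\n", fixed = TRUE)[[1]]
  }
  lines <- sub("\t.*$", "", lines)
  if (length(lines) == sum(ok)) {
    out[ok] <- ifelse(nzchar(lines), lines, NA_character_)
    return(out)
  }
  # batch failed or dropped records: convert one at a time
  idx <- which(ok)
  for (k in idx) {
    res1 <- tryCatch(
      ChemmineOB::convertFormat(from, to, source = paste0(x[k], "\n")),
      error = function(e) ""
    )
    line1 <- sub("\t.*$", "", strsplit(res1, "\n", fixed = TRUE)[[1]][1] %||% "")
    if (length(line1) == 1L && !is.na(line1) && nzchar(line1)) out[k] <- line1
  }
  out
}

#' Canonical SMILES via OpenBabel
#'
#' Vectorized; returns `NA` for strings OpenBabel cannot parse.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  ob_convert("SMI", "CAN", smiles)
}

#' InChI and InChIKey for SMILES input
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector (`NA` where the structure cannot be interpreted).
#' @export
smiles_to_inchi <- function(smiles) {
  ob_convert("SMI", "INCHI", smiles)
}

#' @rdname smiles_to_inchi
#' @export
smiles_to_inchikey <- function(smiles) {
  ob_convert("SMI", "INCHIKEY", smiles)
}

# Parse a SMILES into the internal graph model, normalizing through OpenBabel
# canonicalization so aromatic flags follow one perception model.
mol_from_smiles <- function(smiles, canonicalize = TRUE) {
  if (canonicalize) {
    can <- canonical_smiles(smiles)
    if (is.na(can)) stop_sq("unparseable", sprintf("OpenBabel rejected SMILES '%s'", smiles))
    parse_smiles(can)
  } else {
    parse_smiles(smiles)
  }
}

mol_to_canonical <- function(mol) {
  s <- write_smiles(mol)
  can <- canonical_smiles(s)
  if (is.na(can)) stop_sq("normalization_failure",
                          sprintf("written SMILES '%s' failed canonicalization", s))
  can
}
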