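# Six-step structure standardization: (1) strip stereochemistry, (2/3) strip
# salts and record the removed fragments, (4) neutralize charges, (5) element
# whitelist filter, (6) identity (canonical SMILES / InChI / InChIKey).
# Records that fail a stage are returned flagged, never dropped silently.

#' Remove stereochemistry from a structure
#'
#' Clears tetrahedral and double-bond stereo flags on the molecular graph and
#' re-canonicalizes; constitution (atoms, bonds, bond orders) is unchanged.
#'
#' @param smiles A single SMILES string.
#' @return SMILES of the stereo-free structure.
#' @export
remove_stereochemistry <- function(smiles) {
  mol <- mol_from_smiles(smiles)
  write_smiles(clear_stereo(mol))
}

# Default salt / solvent fragment list (canonical SMILES membership). Halides,
# alkali and alkaline-earth ions, ammonium, sulfate, nitrate, hydroxide,
# water and the common crystallization solvents.
DEFAULT_SALT_FRAGMENTS <- c(
  "Cl", "Br", "I", "F", "[Cl-]", "[Br-]", "[I-]", "[F-]",
  "[Na+]", "[K+]", "[Li+]", "[Ca+2]", "[Mg+2]", "[Zn+2]", "[NH4+]",
  "O", "[OH-]", "N",
  "OS(=O)(=O)O", "[O-]S(=O)(=O)[O-]", "OS(=O)(=O)[O-]",
  "O[N+](=O)[O-]", "[O-][N+](=O)[O-]",
  "CO", "CCO", "CC(C)O", "CS(=O)C", "C(Cl)Cl", "CC#N"
)

salt_canonical_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- unique(canonical_smiles(DEFAULT_SALT_FRAGMENTS))
    cache
  }
})

#' Strip salt and solvent fragments
#'
#' Splits a multi-fragment structure, removes fragments on the salt/solvent
#' list, and keeps the organic parent. When several non-salt fragments remain,
#' the one with the most heavy atoms is kept (ties: molecular weight, then
#' canonical SMILES order); everything removed is reported.
#'
#' @param smiles A single (possibly multi-fragment) SMILES string.
#' @param salt_list Character vector of fragment SMILES treated as salts.
#' @return A list with `parent` (SMILES) and `stripped` (character vector).
#' @export
strip_salts <- function(smiles, salt_list = NULL) {
  mol <- mol_from_smiles(smiles)
  comps <- mol_components(mol)
  if (length(comps) == 1L) {
    return(list(parent = write_smiles(mol), stripped = character()))
  }
  salts <- if (is.null(salt_list)) salt_canonical_set()
           else unique(canonical_smiles(salt_list))
  frags <- lapply(comps, function(cp) mol_subgraph(mol, cp))
  frag_smiles <- vapply(frags, write_smiles, character(1))
  frag_canon <- canonical_smiles(frag_smiles)
  is_salt <- frag_canon %in% salts
  if (all(is_salt)) {
    stop_sq("normalization_failure",
            sprintf("all fragments of '%s' are salts/solvents", smiles))
  }
  cand <- which(!is_salt)
  if (length(cand) > 1L) {
    heavy <- vapply(frags[cand], mol_heavy_atoms, integer(1))
    mw <- vapply(frags[cand], mol_weight, numeric(1))
    ord <- order(-heavy, -mw, frag_canon[cand])
    keep <- cand[ord[1L]]
  } else {
    keep <- cand
  }
  list(parent = frag_smiles[keep],
       stripped = frag_smiles[setdiff(seq_along(frags), keep)])
}

#' Neutralize formal charges
#'
#' Sets protonation-adjustable charges to zero by adding or removing
#' hydrogens. Charges that cannot be removed without changing bonds (e.g. a
#' quaternary nitrogen) are left intact and flagged.
#'
#' @param smiles A single-fragment SMILES string.
#' @return A list with `smiles` and `permanently_charged` (logical).
#' @export
neutralize_charges <- function(smiles) {
  mol <- mol_from_smiles(smiles)
  permanent <- FALSE
  for (k in seq_len(n_atoms(mol))) {
    ch <- mol$charge[k]
    if (ch == 0L) next
    el <- mol$elem[k]
    if (ch > 0L && el %in% c("N", "P", "O", "S") && mol$hcount[k] >= ch) {
      mol$hcount[k] <- mol$hcount[k] - ch
      mol$charge[k] <- 0L
      mol$hexp[k] <- TRUE
    } else if (ch < 0L && el %in% c("C", "N", "O", "P", "S")) {
      mol$hcount[k] <- mol$hcount[k] - ch       # ch negative: adds H
      mol$charge[k] <- 0L
      mol$hexp[k] <- TRUE
    } else {
      permanent <- TRUE
    }
  }
  # valence sanity after adjustment
  bs <- mol_bond_sums(mol)
  for (k in seq_len(n_atoms(mol))) {
    vals <- DEFAULT_VALENCES[[mol$elem[k]]]
    if (is.null(vals) || mol$charge[k] != 0L) next
    total <- bs[k] + mol$hcount[k] + if (mol$arom[k]) 1L else 0L
    if (total > max(vals)) {
      stop_sq("normalization_failure",
              sprintf("valence error on atom %d (%s) after neutralization of '%s'",
                      k, mol$elem[k], smiles))
    }
  }
  list(smiles = write_smiles(mol), permanently_charged = permanent)
}

#' Element whitelist check
#'
#' `TRUE` iff every atom is one of H, C, N, O, F, Br, I, Cl, P, S.
#'
#' @param smiles A single SMILES string.
#' @return Logical scalar.
#' @export
passes_element_filter <- function(smiles) {
  mol <- mol_from_smiles(smiles)
  all(mol$elem %in% ELEMENT_WHITELIST)
}

#' Standardize a table of compounds
#'
#' Runs the full standardization pipeline (stereo removal, salt stripping,
#' charge neutralization, element filter, identity generation) over a compound
#' table. Failing records are kept with a `rejected` reason; use
#' [quarantined()] to split them off.
#'
#' @param data A data frame with at least a `smiles` column (raw structures).
#' @param smiles_col Name of the structure column.
#' @param salt_list Optional custom salt fragment list for [strip_salts()].
#' @return A tibble: input columns plus `std_smiles`, `salt_fragments`
#'   (list-column), `permanently_charged`, `inchi`, `inchikey`, `rejected`.
#' @export
standardize_compounds <- function(data, smiles_col = "smiles", salt_list = NULL) {
  stopifnot(is.data.frame(data), smiles_col %in% names(data))
  raw <- data[[smiles_col]]
  out <- tibble::as_tibble(data)
  n <- nrow(out)
  std <- rep(NA_character_, n)
  salts <- vector("list", n)
  perm <- rep(FALSE, n)
  rejected <- rep(NA_character_, n)

  for (k in seq_len(n)) {
    res <- tryCatch({
      s1 <- remove_stereochemistry(raw[k])
      s2 <- strip_salts(s1, salt_list = salt_list)
      s3 <- neutralize_charges(s2$parent)
      if (!passes_element_filter(s3$smiles)) {
        stop_sq("element_filter",
                sprintf("'%s' contains atoms outside the element whitelist", raw[k]))
      }
      list(smiles = s3$smiles, salts = s2$stripped, perm = s3$permanently_charged)
    }, sq_error = function(e) e)
    if (inherits(res, "sq_error")) {
      reason <- sq_reason(res)
      rejected[k] <- if (reason %in% c("unparseable", "element_filter",
                                       "normalization_failure")) reason
                     else "unparseable"
      salts[k] <- list(character())
    } else {
      std[k] <- res$smiles
      salts[k] <- list(res$salts)
      perm[k] <- res$perm
    }
  }

  out$std_smiles <- canonical_smiles(std)
  out$salt_fragments <- salts
  out$permanently_charged <- perm
  out$inchi <- smiles_to_inchi(std)
  out$inchikey <- smiles_to_inchikey(std)
  out$rejected <- rejected
  out
}

#' Split off quarantined (rejected) records
#'
#' @param data Output of [standardize_compounds()].
#' @return A list of tibbles: `clean` and `quarantine`.
#' @export
quarantined <- function(data) {
  stopifnot("rejected" %in% names(data))
  list(clean = dplyr::filter(data, is.na(.data$rejected)),
       quarantine = dplyr::filter(data, !is.na(.data$rejected)))
}

#' Standardize a single structure
#'
#' Convenience scalar wrapper around [standardize_compounds()].
#'
#' @param smiles A single SMILES string.
#' @inheritParams standardize_compounds
#' @return One-row tibble (`smiles`, `std_smiles`, `inchikey`, ...).
#' @export
standardize_compound <- function(smiles, salt_list = NULL) {
  standardize_compounds(tibble::tibble(smiles = smiles), salt_list = salt_list)
}
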