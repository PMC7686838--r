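# Parsers for the five payload dialects the pipeline consumes. All are total
# on the fixture corpus: unknown extra keys are ignored, optional fields come
# back NA, and only structurally broken documents raise (typed) parse errors.

as_json <- function(doc) {
  if (is.list(doc)) return(doc)
  looks_like_text <- grepl("^\\s*[\\[{]", doc)
  if (length(doc) == 1L && !is.na(doc) && !looks_like_text &&
      nchar(doc) < 1000 && file.exists(doc)) {
    return(jsonlite::fromJSON(doc, simplifyVector = FALSE))
  }
  tryCatch(jsonlite::fromJSON(doc, simplifyVector = FALSE),
           error = function(e) stop_sq("parse", paste("invalid JSON:",
                                                      conditionMessage(e))))
}

as_xml <- function(doc) {
  if (inherits(doc, "xml_document")) return(doc)
  tryCatch(xml2::read_xml(doc),
           error = function(e) stop_sq("parse", paste("invalid XML:",
                                                      conditionMessage(e))))
}

#' Parse a disease-association payload
#'
#' Extracts one target per element of the top-level `data` array, reading the
#' target id, gene name and gene symbol from their documented JSON paths
#' (`$['data'][*]['target']['id']` and the `gene_info` fields), flattened to
#' one row per target.
#'
#' @param doc JSON text, a file path, or a parsed list.
#' @return Tibble of target records (`disease_id`, `target_id`, `gene_name`,
#'   `gene_symbol`, `association_score`).
#' @export
parse_association_payload <- function(doc) {
  x <- as_json(doc)
  if (is.null(x$data)) {
    stop_sq("parse", "association payload lacks the top-level 'data' array")
  }
  rows <- purrr::map(x$data, function(el) {
    tg <- el$target %||% list()
    gi <- tg$gene_info %||% list()
    score <- el$association_score
    overall <- if (is.list(score)) score$overall else score
    tibble::tibble(
      disease_id = as.character(el$disease$id %||% NA_character_),
      target_id = as.character(tg$id %||% NA_character_),
      gene_name = as.character(gi$name %||% NA_character_),
      gene_symbol = as.character(gi$symbol %||% NA_character_),
      association_score = as.numeric(overall %||% NA_real_)
    )
  })
  dplyr::bind_rows(rows)
}

#' Extract PDB cross-references from a protein entry document
#'
#' Returns the id attribute of every `dbReference` element whose `type` is
#' exactly `PDB`, in document order, deduplicated. Other cross-reference
#' types (PubMed, GO, InterPro, Pfam, ...) are ignored.
#'
#' @param doc XML text, file path, or `xml_document` (protein-entry schema).
#' @return Character vector of PDB identifiers.
#' @export
parse_uniprot_pdb_xrefs <- function(doc) {
  x <- as_xml(doc)
  nodes <- xml2::xml_find_all(
    x, ".//*[local-name() = 'dbReference'][@type = 'PDB']")
  unique(xml2::xml_attr(nodes, "id"))
}

#' Parse a best-structures mapping payload
#'
#' Collects every `pdb_id` value under each accession key, uppercased and
#' deduplicated per accession.
#'
#' @param doc JSON text, file path, or parsed list keyed by accession.
#' @return Tibble with `uniprot_id` and `pdb_id`.
#' @export
parse_best_structures <- function(doc) {
  x <- as_json(doc)
  collect_pdb_ids <- function(node) {
    if (is.list(node)) {
      ids <- unlist(lapply(node, collect_pdb_ids), use.names = FALSE)
      if (!is.null(node$pdb_id)) ids <- c(as.character(node$pdb_id), ids)
      return(ids)
    }
    character()
  }
  accs <- names(x) %||% character()
  rows <- purrr::map(accs, function(acc) {
    ids <- unique(toupper(collect_pdb_ids(x[[acc]])))
    if (!length(ids)) return(NULL)
    tibble::tibble(uniprot_id = acc, pdb_id = ids)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    if (length(accs)) warning("no pdb_id fields found in best-structures payload")
    return(tibble::tibble(uniprot_id = character(), pdb_id = character()))
  }
  out
}

# Default co-crystallization agent blocklist: buffers, cryoprotectants,
# common ions and detergents routinely deposited as "ligands".
DEFAULT_COCRYSTAL_BLOCKLIST <- c(
  "HOH", "DOD", "GOL", "EDO", "PEG", "PGE", "PG4", "MPD", "DMS", "ACT",
  "FMT", "CIT", "TRS", "MES", "EPE", "BME", "IMD", "SO4", "PO4", "NO3",
  "CL", "BR", "IOD", "NA", "K", "MG", "CA", "ZN", "MN", "NI", "CD", "NH4"
)

#' Extract bound nonpolymer components from a structure-entry payload
#'
#' Reads `$['rcsb_entry_info']['nonpolymer_bound_components']`; an entry
#' without the key legally has no co-resolved ligand and yields an empty
#' vector. Components on the co-crystallization blocklist are excluded.
#'
#' @param doc JSON text, file path, or parsed list (structure entry schema).
#' @param blocklist Component shortcodes to drop (buffers, cryoprotectants,
#'   retained co-crystallizing agents such as isonicotinamide).
#' @return Character vector of chemical-component shortcodes.
#' @export
parse_bound_ligands <- function(doc, blocklist = DEFAULT_COCRYSTAL_BLOCKLIST) {
  x <- as_json(doc)
  comps <- x$rcsb_entry_info$nonpolymer_bound_components
  if (is.null(comps)) return(character())
  comps <- as.character(unlist(comps, use.names = FALSE))
  setdiff(comps, blocklist)
}

#' Extract the SMILES descriptor from a chemical-component payload
#'
#' @param doc JSON text, file path, or parsed list (chemcomp schema).
#' @return SMILES string.
#' @export
parse_chemcomp_smiles <- function(doc) {
  x <- as_json(doc)
  s <- x$rcsb_chem_comp_descriptor$smiles
  if (is.null(s) || !nzchar(s)) {
    stop_sq("no_structure", "chemcomp payload carries no SMILES descriptor")
  }
  as.character(s)
}

#' Parse one page of a bioactivity XML response
#'
#' A page reports the target's `total_count` (constant across pages) plus the
#' per-activity fields of the documented output contract: activity comment,
#' assay description, molecule id and name, standard type/units/value/
#' relation, parent molecule id and document id. Rows without a standard
#' value are kept with `value_missing = TRUE`.
#'
#' @param doc XML text, file path, or `xml_document`.
#' @return List with `records` (tibble) and `total_count` (integer).
#' @export
parse_activity_page <- function(doc) {
  x <- as_xml(doc)
  tc_node <- xml2::xml_find_first(x, ".//total_count")
  if (inherits(tc_node, "xml_missing")) {
    stop_sq("parse", "activity page lacks the total_count element")
  }
  total_count <- as.integer(xml2::xml_text(tc_node))
  acts <- xml2::xml_find_all(x, ".//activities/activity")
  field <- function(node, name) {
    v <- xml2::xml_text(xml2::xml_find_first(node, name))
    if (is.na(v) || !nzchar(v)) NA_character_ else v
  }
  rows <- purrr::map(acts, function(a) {
    tibble::tibble(
      activity_comment = field(a, "activity_comment"),
      assay_description = field(a, "assay_description"),
      molecule_chembl_id = field(a, "molecule_chembl_id"),
      molecule_name = field(a, "molecule_pref_name"),
      smiles = field(a, "canonical_smiles"),
      endpoint = field(a, "standard_type"),
      unit = field(a, "standard_units"),
      value = suppressWarnings(as.numeric(field(a, "standard_value"))),
      relation = field(a, "standard_relation"),
      parent_molecule_chembl_id = field(a, "parent_molecule_chembl_id"),
      document_ref = field(a, "document_chembl_id")
    )
  })
  records <- dplyr::bind_rows(rows)
  if (!nrow(records)) {
    records <- tibble::tibble(
      activity_comment = character(), assay_description = character(),
      molecule_chembl_id = character(), molecule_name = character(),
      smiles = character(), endpoint = character(), unit = character(),
      value = numeric(), relation = character(),
      parent_molecule_chembl_id = character(), document_ref = character())
  }
  records$value_missing <- is.na(records$value)
  records$source <- rep("chembl", nrow(records))
  list(records = records, total_count = total_count)
}

#' Map a target to assay-database bioactivities via fixtures
#'
#' Follows the AID/CID chain of the assay database: the accession maps to
#' assay ids, each assay lists compounds with measurements, and compound
#' names that are foreign molecule identifiers (CHEMBL...) trigger a
#' secondary name lookup.
#'
#' @param uniprot_id Accession to map.
#' @param fixtures Directory with `pubchem_aids_<acc>.json`,
#'   `pubchem_aid_<aid>.json` and `chembl_name_<id>.json` files.
#' @return Tibble of bioactivity records (`source = "pubchem"`).
#' @export
map_pubchem_target <- function(uniprot_id, fixtures) {
  aid_file <- file.path(fixtures, sprintf("pubchem_aids_%s.json", uniprot_id))
  if (!file.exists(aid_file)) return(pubchem_empty())
  aids <- unlist(as_json(aid_file), use.names = FALSE)
  if (!length(aids)) return(pubchem_empty())
  rows <- purrr::map(aids, function(aid) {
    f <- file.path(fixtures, sprintf("pubchem_aid_%s.json", aid))
    if (!file.exists(f)) {
      warning(sprintf("assay %s has no compound fixture; skipped", aid))
      return(NULL)
    }
    cids <- as_json(f)
    purrr::map(cids, function(c_) {
      name <- as.character(c_$name %||% NA_character_)
      if (!is.na(name) && grepl("^CHEMBL[0-9]+$", name)) {
        nf <- file.path(fixtures, sprintf("chembl_name_%s.json", name))
        if (file.exists(nf)) {
          resolved <- as_json(nf)$pref_name
          if (!is.null(resolved)) name <- as.character(resolved)
        }
      }
      tibble::tibble(
        uniprot_id = uniprot_id,
        assay_id = as.character(aid),
        compound_id = as.character(c_$cid %||% NA_character_),
        molecule_name = name,
        smiles = as.character(c_$smiles %||% NA_character_),
        endpoint = as.character(c_$endpoint %||% NA_character_),
        value = as.numeric(c_$value %||% NA_real_),
        unit = as.character(c_$unit %||% NA_character_),
        relation = as.character(c_$relation %||% "="),
        document_ref = as.character(c_$pmid %||% NA_character_),
        source = "pubchem"
      )
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) pubchem_empty() else out
}

pubchem_empty <- function() {
  tibble::tibble(
    uniprot_id = character(), assay_id = character(), compound_id = character(),
    molecule_name = character(), smiles = character(), endpoint = character(),
    value = numeric(), unit = character(), relation = character(),
    document_ref = character(), source = character())
}

#' Extract structure properties from PDB-format text
#'
#' Reads experimental method (EXPDTA), resolution (REMARK 2), R-factor
#' (REMARK 3), space group (CRYST1) and model count (NUMMDL) from the header
#' records of a PDB-format file; unparseable headers leave NA fields.
#'
#' @param text PDB-format text or a file path.
#' @return One-row tibble of properties.
#' @export
read_pdb_properties <- function(text) {
  lines <- if (length(text) == 1L && file.exists(text)) readLines(text, warn = FALSE)
           else unlist(strsplit(text, "\n", fixed = TRUE))
  grab <- function(pattern, transform = identity) {
    hit <- grep(pattern, lines, value = TRUE)
    if (!length(hit)) return(NA)
    transform(hit[1])
  }
  method <- grab("^EXPDTA", function(x) trimws(substring(x, 11)))
  title <- grab("^TITLE", function(x) trimws(substring(x, 11)))
  resolution <- grab("^REMARK   2 RESOLUTION", function(x) {
    m <- regmatches(x, regexec("([0-9]+\\.[0-9]+) +ANGSTROM", x))[[1]]
    if (length(m)) as.numeric(m[2]) else NA_real_
  })
  r_factor <- grab("^REMARK   3   R VALUE", function(x) {
    m <- regmatches(x, regexec(":\\s*([0-9.]+)", x))[[1]]
    if (length(m)) as.numeric(m[2]) else NA_real_
  })
  space_group <- grab("^CRYST1", function(x) trimws(substring(x, 56, 66)))
  model_count <- grab("^NUMMDL", function(x) as.integer(trimws(substring(x, 11))))
  tibble::tibble(
    title = as.character(title), experimental_method = as.character(method),
    resolution = as.numeric(resolution), r_factor = as.numeric(r_factor),
    space_group = as.character(space_group),
    model_count = if (is.na(model_count)) 1L else as.integer(model_count))
}
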