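# API request construction, HTTP status classification, pagination planning,
# and the transport seam. Endpoint templates follow the published service
# URLs; parsers (retrieval-parsers.R) target the payload shapes those
# services return, so everything is testable on canned fixtures.

OT_ASSOCIATION_TEMPLATE <- paste0(
  "https://platform-api.opentargets.io/v3/platform/public/association/filter",
  "?disease=%s&size=%s&scorevalue_min=%s")
CHEMBL_ACTIVITY_TEMPLATE <- paste0(
  "https://www.ebi.ac.uk/chembl/api/data/activity",
  "?target_chembl_id=%s&limit=%s&offset=%s")
UNIPROT_ENTRY_TEMPLATE <- "https://www.uniprot.org/uniprot/%s.xml"
UNIPROT_COVID_TEMPLATE <-
  "https://www.ebi.ac.uk/uniprot/api/covid-19/uniprotkb/accession/%s.xml"
PDBE_BEST_STRUCTURES_TEMPLATE <-
  "https://www.ebi.ac.uk/pdbe/graph-api/mappings/best_structures/%s"
RCSB_ENTRY_TEMPLATE <- "https://data.rcsb.org/rest/v1/core/entry/%s"
RCSB_CHEMCOMP_TEMPLATE <- "https://data.rcsb.org/rest/v1/core/chemcomp/%s"
RCSB_PDB_FILE_TEMPLATE <- "https://files.rcsb.org/view/%s.pdb"
IUPHAR_TARGET_TEMPLATE <- "http://www.guidetopharmacology.org/services/targets/%d/%s"

# The services' own 2-second default is usually insufficient for full pages.
DEFAULT_TIMEOUT <- 60

new_api_request <- function(url, expected_content, timeout = DEFAULT_TIMEOUT) {
  if (timeout <= 2) stop_sq("validation", "timeout must exceed 2 seconds")
  tibble::tibble(url = url, timeout = timeout, expected_content = expected_content)
}

#' Build a disease-association request
#'
#' Target-prioritization query: all targets associated with a disease at or
#' above a minimum association score.
#'
#' @param disease_id Disease ontology identifier (e.g. `"Orphanet_71277"`,
#'   `"MONDO_0100096"`, `"EFO_0001360"`).
#' @param size Maximum number of targets returned.
#' @param min_score Minimum association score in `[0, 1]`.
#' @return One-row `ApiRequest` tibble (`url`, `timeout`, `expected_content`).
#' @export
build_association_request <- function(disease_id, size = 10000, min_score = 0.99) {
  if (!is.character(disease_id) || length(disease_id) != 1L || !nzchar(disease_id)) {
    stop_sq("validation", "disease_id must be a non-empty string")
  }
  if (min_score < 0 || min_score > 1) {
    stop_sq("validation", "min_score must lie in [0, 1]")
  }
  if (size < 1) stop_sq("validation", "size must be positive")
  new_api_request(
    sprintf(OT_ASSOCIATION_TEMPLATE, disease_id, format_num(size),
            format_num(min_score)),
    "json")
}

#' Build a paged bioactivity request
#'
#' @param target_chembl_id Target identifier of the form `CHEMBL<digits>`.
#' @param limit Page size (records per call).
#' @param offset Number of records to skip.
#' @return One-row `ApiRequest` tibble.
#' @export
build_activity_request <- function(target_chembl_id, limit = 1000, offset = 0) {
  if (!grepl("^CHEMBL[0-9]+$", target_chembl_id %||% "")) {
    stop_sq("validation",
            sprintf("malformed ChEMBL target id '%s'", target_chembl_id))
  }
  if (limit < 1) stop_sq("validation", "limit must be positive")
  if (offset < 0) stop_sq("validation", "offset must be non-negative")
  new_api_request(
    sprintf(CHEMBL_ACTIVITY_TEMPLATE, target_chembl_id, format_num(limit),
            format_num(offset)),
    "xml")
}

#' Build the pharmacology-database request pair
#'
#' One request for substrates, one for interactions (inhibitors), per the
#' service's target-centric endpoints; per-ligand structure requests are
#' constructed from each returned ligand id downstream.
#'
#' @param iuphar_target_id Positive integer target identifier.
#' @return Two-row `ApiRequest` tibble (substrates, then interactions).
#' @export
build_iuphar_requests <- function(iuphar_target_id) {
  id <- suppressWarnings(as.integer(iuphar_target_id))
  if (is.na(id) || id <= 0L) {
    stop_sq("validation", "iuphar_target_id must be a positive integer")
  }
  new_api_request(
    sprintf(IUPHAR_TARGET_TEMPLATE, id, c("substrates", "interactions")),
    "json")
}

#' Build a protein-entry request
#'
#' @param uniprot_id UniProt accession.
#' @param covid_prerelease Use the pre-release COVID-19 endpoint form?
#' @return One-row `ApiRequest` tibble.
#' @export
build_uniprot_request <- function(uniprot_id, covid_prerelease = FALSE) {
  if (!is_uniprot_accession(uniprot_id)) {
    stop_sq("validation", sprintf("'%s' is not a UniProt accession", uniprot_id))
  }
  tpl <- if (covid_prerelease) UNIPROT_COVID_TEMPLATE else UNIPROT_ENTRY_TEMPLATE
  new_api_request(sprintf(tpl, uniprot_id), "xml")
}

is_uniprot_accession <- function(x) {
  is.character(x) & !is.na(x) & grepl("^[A-Z0-9]{6}([A-Z0-9]{4})?$", x)
}

#' Classify an HTTP status code
#'
#' The five classes of HTTP status codes; only success-class responses
#' proceed downstream.
#'
#' @param code Integer vector of status codes in 100-599.
#' @return Character vector: `informational`, `success`, `redirect`,
#'   `client_error` or `server_error`.
#' @export
classify_status <- function(code) {
  if (any(is.na(code)) || any(code < 100 | code > 599)) {
    stop_sq("validation", "HTTP status codes must lie in 100-599")
  }
  c("informational", "success", "redirect", "client_error",
    "server_error")[code %/% 100 - 0L]
}

#' Plan complete paginated retrieval
#'
#' The number of calls is `ceiling(total_count / page_size)`; the k-th call
#' skips `(k - 1) * page_size` records, so executing one request per offset
#' retrieves every record exactly once.
#'
#' @param total_count Total number of records the service reports.
#' @param page_size Records per call.
#' @return A list with `total_count`, `page_size`, `offsets`, `n_pages`.
#' @export
plan_pagination <- function(total_count, page_size = 1000) {
  if (is.na(page_size) || page_size < 1) {
    stop_sq("validation", "page_size must be a positive integer")
  }
  if (is.na(total_count) || total_count < 0) {
    stop_sq("validation", "total_count must be non-negative")
  }
  n_pages <- as.integer(ceiling(total_count / page_size))
  offsets <- if (n_pages == 0L) integer() else (seq_len(n_pages) - 1L) * as.integer(page_size)
  list(total_count = as.integer(total_count), page_size = as.integer(page_size),
       offsets = offsets, n_pages = n_pages)
}

# ---- transport seam -------------------------------------------------------

# Map a URL to a fixture file name: scheme dropped, non-word characters
# collapsed to "_".
fixture_name_for_url <- function(url) {
  base <- sub("^[a-z]+://", "", url)
  paste0(gsub("_+", "_", gsub("[^A-Za-z0-9]", "_", base)), ".txt")
}

#' Execute an API request
#'
#' In fixture mode (the default for all tests and offline runs) the response
#' body is read from `fixtures/<mangled-url>.txt`. Live mode fetches over
#' HTTP with up to `retries` attempts and exponential backoff; non-success
#' responses drop the row with a warning rather than aborting the run.
#'
#' @param request One-row `ApiRequest` tibble.
#' @param fixtures Fixture directory (fixture mode) or `NULL` for live mode.
#' @param retries Live-mode attempt count.
#' @return Character scalar (response body) or `NA` when the row is dropped.
#' @export
fetch_api <- function(request, fixtures = NULL, retries = 3) {
  url <- request$url[1]
  if (!is.null(fixtures)) {
    path <- file.path(fixtures, fixture_name_for_url(url))
    if (!file.exists(path)) {
      warning(sprintf("no fixture for %s (expected %s); row dropped",
                      url, basename(path)))
      return(NA_character_)
    }
    return(paste(readLines(path, warn = FALSE), collapse = "\n"))
  }
  for (attempt in seq_len(retries)) {
    body <- tryCatch({
      con <- url(url)
      on.exit(close(con), add = TRUE)
      paste(readLines(con, warn = FALSE), collapse = "\n")
    }, error = function(e) NULL)
    if (!is.null(body)) return(body)
    Sys.sleep(2^(attempt - 1))
  }
  warning(sprintf("request failed after %d attempts: %s; row dropped",
                  retries, url))
  NA_character_
}

#' Read a bulk accession mapping table
#'
#' Reads the tab-separated export of the bulk UniProt-to-target-platform
#' mapping (the recommended route for large target sets).
#'
#' @param path TSV file with columns Entry, cross-reference id(s), Status.
#' @return Tibble with `uniprot_id`, `target_id`, `reviewed`.
#' @export
read_uniprot_mapping <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  names(raw) <- tolower(gsub("[^A-Za-z0-9]+", "_", names(raw)))
  id_col <- names(raw)[1]
  xref_col <- grep("opentargets|cross_reference|target", names(raw), value = TRUE)[1]
  rev_col <- grep("reviewed|status", names(raw), value = TRUE)[1]
  out <- tibble::tibble(
    uniprot_id = as.character(raw[[id_col]]),
    target_id = as.character(raw[[xref_col]]),
    reviewed = if (!is.na(rev_col)) as.character(raw[[rev_col]]) else NA_character_
  )
  # one gene may list several semicolon-separated cross-references
  out |>
    dplyr::mutate(target_id = strsplit(.data$target_id, ";\\s*")) |>
    tidyr::unnest("target_id") |>
    dplyr::filter(nzchar(.data$target_id))
}
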