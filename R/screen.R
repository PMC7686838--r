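# Substructure screening of compound libraries with the generated SMARTS
# queries: hit tables with matched atom indices, cross-library overlap,
# rediscovery accounting, and schematic SVG highlights.

#' Substructure-screen a library
#'
#' Matches every query against every library compound (standardized
#' beforehand, so screening uses the same aromaticity model as curation).
#' One row is produced per (compound, query) pair that matches; a compound
#' hit by k queries yields k rows.
#'
#' @param library A standardized compound tibble (needs `compound_id`,
#'   `inchikey`, and the structure column; `library` and `name` columns are
#'   carried through when present).
#' @param queries Query tibble from [generate_queries()] or
#'   [read_smarts_file()] (needs `smarts`; `uniprot_id`/`cluster_id` carried
#'   through).
#' @param smiles_col Structure column of `library`.
#' @return Hit tibble: `library`, `compound_id`, `compound_name`, `inchikey`,
#'   `uniprot_id`, `cluster_id`, `smarts`, `matched_atoms` (list-column),
#'   `rediscovered` (NA until flagged).
#' @export
substructure_screen <- function(library, queries, smiles_col = "std_smiles") {
  stopifnot(is.data.frame(library), is.data.frame(queries),
            smiles_col %in% names(library), "smarts" %in% names(queries))
  pats <- vector("list", nrow(queries))
  for (k in seq_len(nrow(queries))) {
    pats[[k]] <- tryCatch(parse_smarts(queries$smarts[k]), sq_error = function(e) e)
    if (inherits(pats[[k]], "sq_error")) {
      stop_sq("validation",
              sprintf("invalid query pattern '%s': %s", queries$smarts[k],
                      conditionMessage(pats[[k]])))
    }
  }
  lib_name <- if ("library" %in% names(library)) library$library
              else rep("library", nrow(library))
  cmp_name <- if ("name" %in% names(library)) library$name
              else rep(NA_character_, nrow(library))
  rows <- list()
  for (i in seq_len(nrow(library))) {
    s <- library[[smiles_col]][i]
    if (is.na(s)) next
    mol <- tryCatch(mol_from_smiles(s), sq_error = function(e) NULL)
    if (is.null(mol)) next
    cid <- as.character(library$compound_id[i])
    key <- library$inchikey[i]
    for (k in seq_len(nrow(queries))) {
      hit <- match_pattern(pats[[k]], mol, first_only = TRUE)
      if (!length(hit)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        library = lib_name[i],
        compound_id = cid,
        compound_name = cmp_name[i],
        inchikey = key,
        smiles = s,
        uniprot_id = if ("uniprot_id" %in% names(queries))
          queries$uniprot_id[k] else NA_character_,
        cluster_id = if ("cluster_id" %in% names(queries))
          queries$cluster_id[k] else NA_integer_,
        smarts = queries$smarts[k],
        matched_atoms = list(hit[[1L]]),
        rediscovered = NA
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(
      library = character(), compound_id = character(),
      compound_name = character(), inchikey = character(), smiles = character(),
      uniprot_id = character(), cluster_id = integer(), smarts = character(),
      matched_atoms = list(), rediscovered = logical())
  }
  out
}

#' Per-query and unique-compound hit counts
#'
#' Hit counts are ambiguous between (compound, query) pairs and unique
#' compounds; both are reported.
#'
#' @param hits Hit tibble from [substructure_screen()].
#' @return Tibble per query: `smarts`, `n_pairs`, `n_unique_compounds`.
#' @export
summarise_hits <- function(hits) {
  hits |>
    dplyr::group_by(.data$uniprot_id, .data$cluster_id, .data$smarts) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     n_unique_compounds = dplyr::n_distinct(.data$inchikey),
                     .groups = "drop")
}

#' Compounds hit in every screened library
#'
#' @param hits Hit tibble covering two or more libraries.
#' @param libraries Libraries that must all contain the compound; defaults to
#'   every library present in `hits`.
#' @return Tibble: `inchikey`, `libraries` (list), `queries` (list).
#' @export
cross_library_overlap <- function(hits, libraries = NULL) {
  required <- libraries %||% sort(unique(hits$library))
  if (length(required) < 2L) {
    warning("fewer than two libraries screened; overlap is empty")
    return(tibble::tibble(inchikey = character(), libraries = list(),
                          queries = list()))
  }
  hits |>
    dplyr::filter(.data$library %in% required) |>
    dplyr::group_by(.data$inchikey) |>
    dplyr::summarise(libraries = list(sort(unique(.data$library))),
                     queries = list(sort(unique(.data$smarts))),
                     .groups = "drop") |>
    dplyr::filter(purrr::map_lgl(.data$libraries,
                                 function(ls) all(required %in% ls))) |>
    dplyr::arrange(.data$inchikey)
}

#' Flag hits that were already in the active input set
#'
#' @param hits Hit tibble.
#' @param active_inchikeys InChIKeys of the active set the queries were built
#'   from.
#' @return A list: `hits` (annotated) and `rediscovery_fraction` (unique
#'   rediscovered compounds / unique hit compounds; `NA` when there are no
#'   hits).
#' @export
flag_rediscoveries <- function(hits, active_inchikeys) {
  hits$rediscovered <- hits$inchikey %in% active_inchikeys
  uniq <- unique(hits$inchikey)
  frac <- if (!length(uniq)) NA_real_ else mean(uniq %in% active_inchikeys)
  list(hits = hits, rediscovery_fraction = frac)
}

#' Render a hit as an SVG depiction with the match highlighted
#'
#' Schematic 2D depiction (force-directed layout of the molecular graph):
#' bonds as lines, heteroatoms labeled, matched atoms and bonds drawn in a
#' highlight color.
#'
#' @param smiles The hit compound's SMILES.
#' @param matched_atoms Integer atom indices of the query embedding.
#' @param path Output SVG path.
#' @param width,height Canvas size in pixels.
#' @return `path`, invisibly.
#' @export
render_highlight <- function(smiles, matched_atoms, path, width = 400,
                             height = 400) {
  mol <- mol_from_smiles(smiles)
  n <- n_atoms(mol)
  if (length(matched_atoms) &&
      (any(matched_atoms < 1L) || any(matched_atoms > n))) {
    stop_sq("validation", "matched atom index outside the molecule")
  }
  xy <- layout_mol(mol)
  pad <- 30
  rng <- apply(xy, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-6)
  px <- pad + (xy[, 1] - rng[1, 1]) / span[1] * (width - 2 * pad)
  py <- pad + (xy[, 2] - rng[1, 2]) / span[2] * (height - 2 * pad)

  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  svg <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    width, height, width, height),
    sprintf('<rect width="%d" height="%d" fill="white"/>', width, height))
  in_match <- seq_len(n) %in% matched_atoms
  for (b in seq_len(n_bonds(mol))) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    hl <- in_match[i] && in_match[j]
    col <- if (hl) "#e8550f" else "#444444"
    w <- if (mol$bonds$order[b] >= 2L && !mol$bonds$arom[b]) 3.5 else 1.8
    svg <- c(svg, sprintf(
      '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="%s" stroke-width="%.1f"/>',
      px[i], py[i], px[j], py[j], col, if (hl) w + 1.2 else w))
  }
  for (v in seq_len(n)) {
    col <- if (in_match[v]) "#e8550f" else "#222222"
    if (in_match[v]) {
      svg <- c(svg, sprintf(
        '<circle cx="%.1f" cy="%.1f" r="9" fill="#ffd9c2" stroke="%s"/>',
        px[v], py[v], col))
    }
    if (mol$elem[v] != "C" || mol$charge[v] != 0L) {
      svg <- c(svg, sprintf(
        '<text x="%.1f" y="%.1f" font-size="12" text-anchor="middle" fill="%s">%s</text>',
        px[v], py[v] + 4, col, esc(mol$elem[v])))
    }
  }
  svg <- c(svg, "</svg>")
  writeLines(svg, path)
  invisible(path)
}

# Deterministic force-directed 2D layout of the molecular graph.
layout_mol <- function(mol, iterations = 250) {
  n <- n_atoms(mol)
  if (n == 1L) return(matrix(0, 1, 2))
  adj <- mol_bond_lookup(mol) > 0
  # deterministic start: atoms on a circle in index order
  theta <- 2 * pi * (seq_len(n) - 1) / n
  pos <- cbind(cos(theta), sin(theta))
  k <- 1 / sqrt(n)
  temp <- 0.15
  for (it in seq_len(iterations)) {
    disp <- matrix(0, n, 2)
    for (v in seq_len(n - 1L)) {
      for (w in seq((v + 1L), n)) {
        delta <- pos[v, ] - pos[w, ]
        dist <- max(sqrt(sum(delta^2)), 1e-6)
        dir <- delta / dist
        f <- k^2 / dist                       # repulsion
        if (adj[v, w]) f <- f - dist^2 / k    # spring
        disp[v, ] <- disp[v, ] + dir * f
        disp[w, ] <- disp[w, ] - dir * f
      }
    }
    norm <- pmax(sqrt(rowSums(disp^2)), 1e-9)
    step <- pmin(norm, temp)
    pos <- pos + disp / norm * step
    temp <- temp * 0.985
  }
  pos
}
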