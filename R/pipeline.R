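# Pipeline orchestration: the fixture-driven retrieval pipeline and the
# fully synthetic ground-truth study used for validation.

#' Run the synthetic ground-truth study
#'
#' Generates a chemotype library with planted scaffold families and decoys,
#' simulates replicated bioactivities, then runs the full downstream
#' pipeline: standardization, pX labeling, median aggregation, scaffold
#' extraction, genericity filtering, clustering, query generation, and
#' substructure screening of both the input library (rediscovery) and a
#' freshly generated held-out library (recovery). Ground truth is known by
#' construction, so recall and false-positive counts are exact.
#'
#' @param rng_seed Integer seed driving every random draw.
#' @param spec A [chemotype_spec()]; its `rng_seed` is overridden by
#'   `rng_seed`.
#' @param cutoff pX activity cutoff (default 9, i.e. active below 1 nM).
#' @param threshold Scaffold-cluster distance threshold (default 0.5).
#' @param linkage Hierarchical clustering linkage.
#' @param min_query_size Minimum heavy atoms per emitted query.
#' @param replicates Bioactivity measurements per compound.
#' @return A list with the stage tables (`library`, `standardized`,
#'   `activities`, `actives`, `scaffolds`, `clusters`, `queries`,
#'   `hits_input`, `hits_heldout`) and a `metrics` list (queries per family,
#'   analog recall, decoy hits, rediscovery fractions).
#' @export
run_synthetic_study <- function(rng_seed = 1L,
                                spec = NULL,
                                cutoff = 9, threshold = 0.5,
                                linkage = "average", min_query_size = 3,
                                replicates = 3) {
  spec <- spec %||% chemotype_spec(rng_seed = as.integer(rng_seed))
  spec$rng_seed <- as.integer(rng_seed)

  gen <- generate_chemotype_library(spec)
  std <- standardize_compounds(gen$library)
  split <- quarantined(std)

  acts <- generate_bioactivity_table(gen$truth, replicates = replicates,
                                     rng_seed = spec$rng_seed)
  acts <- dplyr::left_join(acts,
                           split$clean[c("compound_id", "inchikey")],
                           by = "compound_id")
  labeled <- label_activities(acts, cutoff = cutoff)
  agg <- aggregate_labels(labeled)
  actives <- merge_active_set(agg)

  active_compounds <- dplyr::inner_join(
    split$clean, actives[c("uniprot_id", "inchikey")], by = "inchikey",
    relationship = "many-to-many")
  scaff <- extract_scaffolds(active_compounds)
  scaff <- filter_generic_scaffolds(scaff)
  clusters <- cluster_scaffold_table(scaff, threshold = threshold,
                                     linkage = linkage)
  queries <- generate_queries(clusters, min_query_size = min_query_size)

  hits_input <- substructure_screen(
    dplyr::mutate(split$clean, library = "input"), queries)
  redisc_input <- flag_rediscoveries(hits_input, actives$inchikey)

  heldout_spec <- spec
  heldout_spec$rng_seed <- spec$rng_seed + 1L
  gen2 <- generate_chemotype_library(heldout_spec)
  std2 <- standardize_compounds(gen2$library)
  clean2 <- quarantined(std2)$clean
  hits_heldout <- substructure_screen(
    dplyr::mutate(clean2, library = "heldout"), queries)
  redisc_heldout <- flag_rediscoveries(hits_heldout, actives$inchikey)

  # ground-truth accounting on the held-out library
  fam2 <- gen2$truth$family[match(clean2$compound_id, gen2$truth$compound_id)]
  analog_ids <- clean2$compound_id[fam2 != "decoy"]
  decoy_ids <- clean2$compound_id[fam2 == "decoy"]
  hit_ids <- unique(hits_heldout$compound_id)
  analog_recall <- if (length(analog_ids)) mean(analog_ids %in% hit_ids) else NA_real_
  decoy_hits <- sum(decoy_ids %in% hit_ids)

  # one query per planted family: does >= 1 query match the family seed?
  seed_scaffolds <- spec$seed_scaffolds
  fams_recovered <- vapply(seed_scaffolds, function(s) {
    any(vapply(queries$smarts, function(q) smarts_matches(q, s), logical(1)))
  }, logical(1))

  metrics <- list(
    n_compounds = nrow(gen$library),
    n_quarantined = nrow(split$quarantine),
    n_active_pairs = nrow(actives),
    n_scaffolds = nrow(scaff),
    n_clusters = dplyr::n_distinct(clusters$cluster_id),
    n_queries = nrow(queries),
    n_families = length(seed_scaffolds),
    families_recovered = sum(fams_recovered),
    analog_recall = analog_recall,
    decoy_hits = decoy_hits,
    rediscovery_fraction_input = redisc_input$rediscovery_fraction,
    rediscovery_fraction_heldout = redisc_heldout$rediscovery_fraction)

  list(library = gen$library, truth = gen$truth, standardized = std,
       activities = labeled, actives = actives, scaffolds = scaff,
       clusters = clusters, queries = queries,
       hits_input = redisc_input$hits, hits_heldout = redisc_heldout$hits,
       heldout_library = gen2$library, metrics = metrics)
}

#' Run the fixture-driven retrieval pipeline
#'
#' Executes retrieval, standardization, labeling, scaffold clustering, query
#' generation and (when libraries are configured) substructure screening
#' from a fixture directory written by [generate_api_fixtures()], writing
#' per-stage TSVs, the query file and hit tables to `out_dir`.
#'
#' @param config A named list (or path to a JSON file) with elements
#'   `fixtures` (fixture directory), `out_dir`, and optionally `cutoff`
#'   (default 9), `threshold` (0.5), `linkage` ("average"),
#'   `min_query_size` (3), `libraries` (named character vector of library
#'   file paths), `page_size` (from the manifest when absent).
#' @return A list of stage tables plus `summary` (counts per stage), with
#'   the run configuration echoed in `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  stopifnot(is.list(config), !is.null(config$fixtures))
  fixtures <- config$fixtures
  out_dir <- config$out_dir %||% tempfile("scaffquery_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cutoff <- config$cutoff %||% 9
  threshold <- config$threshold %||% 0.5
  linkage <- config$linkage %||% "average"
  min_query_size <- config$min_query_size %||% 3

  manifest_path <- file.path(fixtures, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop_sq("validation", "fixture directory lacks manifest.json")
  }
  manifest <- jsonlite::fromJSON(manifest_path, simplifyVector = TRUE)
  page_size <- config$page_size %||% manifest$page_size

  # --- retrieval ----------------------------------------------------------
  assoc_body <- fetch_api(
    build_association_request(manifest$disease_id, 10000, 0.99), fixtures)
  targets_tbl <- parse_association_payload(assoc_body)

  act_rows <- list(); pdb_rows <- list()
  for (t in seq_along(manifest$targets)) {
    acc <- manifest$targets[t]; chembl <- manifest$chembl_ids[t]
    first <- fetch_api(build_activity_request(chembl, page_size, 0), fixtures)
    if (is.na(first)) next
    page1 <- parse_activity_page(first)
    plan <- plan_pagination(page1$total_count, page_size)
    recs <- list(page1$records)
    for (off in setdiff(plan$offsets, 0L)) {
      body <- fetch_api(build_activity_request(chembl, page_size, off), fixtures)
      if (is.na(body)) next
      recs[[length(recs) + 1L]] <- parse_activity_page(body)$records
    }
    acts <- dplyr::bind_rows(recs)
    acts$uniprot_id <- acc
    act_rows[[acc]] <- acts

    # structures: entry xrefs + best-structures, deduplicated per target
    entry <- fetch_api(build_uniprot_request(acc), fixtures)
    xref_ids <- if (is.na(entry)) character() else parse_uniprot_pdb_xrefs(entry)
    best_body <- fetch_api(new_api_request(
      sprintf(PDBE_BEST_STRUCTURES_TEMPLATE, acc), "json"), fixtures)
    best_ids <- if (is.na(best_body)) character()
                else parse_best_structures(best_body)$pdb_id
    pdb_ids <- unique(toupper(c(xref_ids, best_ids)))
    for (p in pdb_ids) {
      ebody <- fetch_api(new_api_request(sprintf(RCSB_ENTRY_TEMPLATE, p), "json"),
                         fixtures)
      if (is.na(ebody)) next
      comps <- parse_bound_ligands(ebody)
      for (cc in comps) {
        cbody <- fetch_api(new_api_request(sprintf(RCSB_CHEMCOMP_TEMPLATE, cc),
                                           "json"), fixtures)
        if (is.na(cbody)) next
        smi <- tryCatch(parse_chemcomp_smiles(cbody), sq_error = function(e) NA_character_)
        if (is.na(smi)) next
        pdb_rows[[length(pdb_rows) + 1L]] <- tibble::tibble(
          uniprot_id = acc, pdb_id = p, component = cc, smiles = smi,
          compound_id = paste0(p, "_", cc), source = "pdb")
      }
    }
  }
  activities <- dplyr::bind_rows(act_rows)
  pdb_ligands <- dplyr::bind_rows(pdb_rows)
  if (nrow(pdb_ligands)) {
    pdb_ligands <- dplyr::distinct(pdb_ligands, .data$uniprot_id, .data$pdb_id,
                                   .data$component, .keep_all = TRUE)
  }

  # --- standardization ----------------------------------------------------
  if (nrow(activities)) {
    activities$compound_id <- activities$molecule_chembl_id
  }
  all_compounds <- dplyr::bind_rows(
    if (nrow(activities)) dplyr::distinct(
      activities[c("compound_id", "smiles")]) else NULL,
    if (nrow(pdb_ligands)) dplyr::distinct(
      pdb_ligands[c("compound_id", "smiles")]) else NULL)
  std <- standardize_compounds(dplyr::distinct(all_compounds))
  split <- quarantined(std)

  # --- labeling + merge ---------------------------------------------------
  key_of <- function(ids) split$clean$inchikey[match(ids, split$clean$compound_id)]
  merged <- if (nrow(activities)) {
    activities$inchikey <- key_of(activities$compound_id)
    labeled <- label_activities(activities, cutoff = cutoff)
    agg <- aggregate_labels(labeled)
    pdb_tbl <- if (nrow(pdb_ligands)) {
      pdb_ligands$inchikey <- key_of(pdb_ligands$compound_id)
      dplyr::filter(pdb_ligands, !is.na(.data$inchikey))
    } else NULL
    merge_active_set(agg, pdb_tbl)
  } else tibble::tibble(uniprot_id = character(), inchikey = character())

  # --- scaffolds, queries -------------------------------------------------
  active_compounds <- split$clean |>
    dplyr::semi_join(merged, by = "inchikey") |>
    dplyr::inner_join(merged[c("uniprot_id", "inchikey")], by = "inchikey",
                      relationship = "many-to-many") |>
    dplyr::distinct(.data$uniprot_id, .data$inchikey, .keep_all = TRUE)
  scaff <- extract_scaffolds(active_compounds)
  scaff_kept <- filter_generic_scaffolds(scaff)
  clusters <- cluster_scaffold_table(scaff_kept, threshold = threshold,
                                     linkage = linkage)
  queries <- generate_queries(clusters, min_query_size = min_query_size)

  # --- screening ----------------------------------------------------------
  hits <- NULL; overlap <- NULL; redisc <- NULL
  lib_paths <- config$libraries
  if (!is.null(lib_paths) && length(lib_paths) && nrow(queries)) {
    libs <- purrr::imap(as.list(lib_paths), function(p, nm) {
      lib <- read_compound_library(p, library = if (nzchar(nm %||% "")) nm else NULL)
      stdl <- standardize_compounds(lib)
      quarantined(stdl)$clean
    })
    hits <- dplyr::bind_rows(purrr::map(libs, substructure_screen, queries = queries))
    rr <- flag_rediscoveries(hits, merged$inchikey)
    hits <- rr$hits; redisc <- rr$rediscovery_fraction
    if (length(libs) >= 2L) overlap <- cross_library_overlap(hits)
  } else if (is.null(lib_paths) || !length(lib_paths)) {
    warning("no screening libraries configured; pipeline stops after query generation")
  }

  # --- outputs ------------------------------------------------------------
  readr::write_tsv(targets_tbl, file.path(out_dir, "targets.tsv"))
  if (nrow(activities)) {
    readr::write_tsv(
      activities[setdiff(names(activities), "matched_atoms")],
      file.path(out_dir, "activities.tsv"))
  }
  write_identity_table(std, file.path(out_dir, "standardized.tsv"))
  readr::write_tsv(merged |> dplyr::mutate(
    provenance = vapply(.data$provenance, paste, character(1), collapse = ";")),
    file.path(out_dir, "actives.tsv"))
  readr::write_tsv(scaff_kept |> dplyr::mutate(
    parent_keys = vapply(.data$parent_keys, paste, character(1), collapse = ";")),
    file.path(out_dir, "scaffolds.tsv"))
  if (nrow(queries)) write_query_file(queries, file.path(out_dir, "queries.smarts"))
  if (!is.null(hits) && nrow(hits)) {
    readr::write_tsv(hits |> dplyr::mutate(
      matched_atoms = vapply(.data$matched_atoms, paste, character(1), collapse = ",")),
      file.path(out_dir, "hits.tsv"))
  }

  summary <- list(
    n_targets = nrow(targets_tbl),
    n_activity_records = nrow(activities),
    n_pdb_ligands = nrow(pdb_ligands),
    n_standardized = sum(is.na(std$rejected)),
    n_quarantined = sum(!is.na(std$rejected)),
    n_active_pairs = nrow(merged),
    n_scaffolds = nrow(scaff),
    n_scaffolds_after_generic_filter = nrow(scaff_kept),
    n_queries = nrow(queries),
    n_hits = if (is.null(hits)) 0L else nrow(hits),
    rediscovery_fraction = redisc)
  list(targets = targets_tbl, activities = activities,
       pdb_ligands = pdb_ligands, standardized = std, actives = merged,
       scaffolds = scaff_kept, clusters = clusters, queries = queries,
       hits = hits, overlap = overlap, summary = summary,
       config = config, out_dir = out_dir)
}
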