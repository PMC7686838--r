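# Synthetic study inputs: chemotype libraries with planted scaffold families
# and scaffold-free decoys, bioactivity tables with controlled pX
# distributions, and canned API payload fixtures - everything the pipeline
# needs to run and be validated offline, with ground truth known by
# construction.

# Default seed scaffolds: multi-ring (they survive the one-ring genericity
# filter), mutually distant chemotypes spanning aliphatic cages, biaryls,
# fused O-heterocycles, saturated N-heterocycles and a nucleoside-like
# purine - the chemotype families enriched screens typically surface.
DEFAULT_SEED_SCAFFOLDS <- c(
  adamantane = "C1C2CC3CC1CC(C2)C3",
  biphenyl = "c1ccc(-c2ccccc2)cc1",
  benzodioxole = "c1ccc2c(c1)OCO2",
  phenylpiperazine = "c1ccc(N2CCNCC2)cc1",
  purine_nucleoside = "c1ncc2ncn(C3CCCO3)c2n1"
)

# Substituent pool (attachment atom first); all within the element whitelist.
DEFAULT_SUBSTITUENTS <- c(
  methyl = "C", ethyl = "CC", hydroxyl = "O", amino = "N", fluoro = "F",
  methoxy = "OC", carboxyl = "C(=O)O"
)

#' Specification for a synthetic chemotype library
#'
#' @param seed_scaffolds Named character vector of family seed scaffolds
#'   (SMILES; must be valid, mutually non-matching frameworks).
#' @param analogs_per_family Analogs generated per family.
#' @param decoys Number of ring-free decoy compounds.
#' @param substituent_pool Named attachment fragments (SMILES, attachment
#'   atom first).
#' @param salt_rate,stereo_rate,charge_rate Fractions of records decorated
#'   with a counter-ion fragment, a chiral side chain, or a protonated amine,
#'   to exercise standardization.
#' @param rng_seed Integer seed; generation is a pure function of
#'   (spec, seed).
#' @return A `chemotype_spec` list.
#' @export
chemotype_spec <- function(seed_scaffolds = DEFAULT_SEED_SCAFFOLDS,
                           analogs_per_family = 8,
                           decoys = 50,
                           substituent_pool = DEFAULT_SUBSTITUENTS,
                           salt_rate = 0.2, stereo_rate = 0.2,
                           charge_rate = 0.1, rng_seed = 1L) {
  rates <- c(salt_rate, stereo_rate, charge_rate)
  if (any(rates < 0 | rates > 1)) stop_sq("validation", "rates must lie in [0, 1]")
  if (is.null(names(seed_scaffolds))) {
    names(seed_scaffolds) <- paste0("family_", seq_along(seed_scaffolds))
  }
  structure(list(seed_scaffolds = seed_scaffolds,
                 analogs_per_family = as.integer(analogs_per_family),
                 decoys = as.integer(decoys),
                 substituent_pool = substituent_pool,
                 salt_rate = salt_rate, stereo_rate = stereo_rate,
                 charge_rate = charge_rate, rng_seed = as.integer(rng_seed)),
            class = "chemotype_spec")
}

# Attach a substituent graph (attachment atom = its atom 1) to `mol` at
# `at_atom` with a single bond.
attach_fragment <- function(mol, at_atom, frag) {
  off <- n_atoms(mol)
  fb <- frag$bonds
  fb$i <- fb$i + off; fb$j <- fb$j + off
  joined <- new_mol(
    elem = c(mol$elem, frag$elem), arom = c(mol$arom, frag$arom),
    charge = c(mol$charge, frag$charge), hcount = c(mol$hcount, frag$hcount),
    hexp = c(mol$hexp, frag$hexp), stereo = c(mol$stereo, frag$stereo),
    iso = c(mol$iso, frag$iso),
    bonds = rbind(mol$bonds, fb,
                  data.frame(i = at_atom, j = off + 1L, order = 1L,
                             arom = FALSE, stereo = "", stringsAsFactors = FALSE))
  )
  resolve_hydrogens(joined)
}

# Ring atoms able to accept one more substituent (>= 1 implicit H).
open_ring_positions <- function(mol) {
  ra <- mol_ring_atoms(mol)
  ra[mol$hcount[ra] >= 1L & !mol$hexp[ra]]
}

# Chiral side chain -[C@H](C)O: a genuine stereocenter once ring-attached.
chiral_fragment <- function() {
  new_mol(
    elem = c("C", "C", "O"), arom = rep(FALSE, 3),
    charge = rep(0L, 3), hcount = c(1L, 3L, 1L),
    hexp = c(TRUE, FALSE, FALSE), stereo = c("@", "", ""),
    iso = rep(NA_integer_, 3),
    bonds = data.frame(i = c(1L, 1L), j = c(2L, 3L), order = 1L,
                       arom = FALSE, stereo = "", stringsAsFactors = FALSE))
}

# Protonated primary amine -[NH3+].
ammonium_fragment <- function() {
  new_mol(elem = "N", arom = FALSE, charge = 1L, hcount = 3L, hexp = TRUE,
          stereo = "", iso = NA_integer_, bonds = empty_bonds())
}

#' Generate a chemotype library with ground truth
#'
#' Family members are the seed scaffold plus 1-3 random substituents at open
#' ring positions, so their Murcko framework is the seed by construction;
#' decoys are ring-free chains that can match no ring-containing query. The
#' requested fractions of records carry stereo centers, salt fragments and
#' charges. Planted membership is verified at generation time by
#' substructure match.
#'
#' @param spec A [chemotype_spec()].
#' @return A list: `library` (tibble `compound_id`, `name`, `smiles`,
#'   `family`) and `truth` (tibble `compound_id`, `family`; decoys carry
#'   `"decoy"`).
#' @export
generate_chemotype_library <- function(spec = chemotype_spec()) {
  stopifnot(inherits(spec, "chemotype_spec"))
  withr::with_seed(spec$rng_seed, {
    seeds <- lapply(spec$seed_scaffolds, mol_from_smiles)
    seed_pats <- lapply(seeds, mol_to_pattern)
    subs <- lapply(spec$substituent_pool, function(s) parse_smiles(s))

    rows <- list()
    for (f in seq_along(seeds)) {
      fam <- names(spec$seed_scaffolds)[f]
      for (a in seq_len(spec$analogs_per_family)) {
        mol <- seeds[[f]]
        n_sub <- sample(1:3, 1)
        decorate_stereo <- stats::runif(1) < spec$stereo_rate
        decorate_charge <- stats::runif(1) < spec$charge_rate
        for (s in seq_len(n_sub)) {
          pos <- open_ring_positions(mol)
          if (!length(pos)) {
            stop_sq("validation",
                    sprintf("seed '%s' has no open attachment point", fam))
          }
          at <- if (length(pos) == 1L) pos else sample(pos, 1)
          frag <- if (s == 1L && decorate_stereo) chiral_fragment()
                  else if (s == 1L && decorate_charge) ammonium_fragment()
                  else subs[[sample(length(subs), 1)]]
          mol <- attach_fragment(mol, at, frag)
        }
        smi <- write_smiles(mol)
        if (stats::runif(1) < spec$salt_rate) {
          smi <- paste0(smi, ".", sample(c("Cl", "O"), 1))
        }
        # generation-time soundness: the analog must contain its seed scaffold
        if (!length(match_pattern(seed_pats[[f]], mol))) {
          stop_sq("validation",
                  sprintf("analog of '%s' lost its seed scaffold", fam))
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          compound_id = sprintf("SYN%s_%02d", toupper(substr(fam, 1, 3)), a),
          name = sprintf("%s analog %d", fam, a),
          smiles = smi, family = fam)
      }
    }
    for (d in seq_len(spec$decoys)) {
      smi <- random_acyclic_smiles()
      rows[[length(rows) + 1L]] <- tibble::tibble(
        compound_id = sprintf("DEC_%03d", d),
        name = sprintf("decoy %d", d), smiles = smi, family = "decoy")
    }
    library <- dplyr::bind_rows(rows)
    # unique ids by construction; make sure
    stopifnot(!anyDuplicated(library$compound_id))
    list(library = library,
         truth = library[c("compound_id", "family")])
  })
}

# Ring-free chains of C/N/O with occasional methyl branches: no framework at
# all, so they can never contain a ring query.
random_acyclic_smiles <- function() {
  len <- sample(4:9, 1)
  atoms <- sample(c("C", "C", "C", "N", "O"), len, replace = TRUE)
  # avoid O-O / N-O adjacencies that standardization might flag
  for (k in seq(2, len)) {
    if (atoms[k] != "C" && atoms[k - 1] != "C") atoms[k] <- "C"
  }
  branch_at <- which(atoms == "C" & seq_len(len) > 1 & seq_len(len) < len)
  out <- character(len)
  for (k in seq_len(len)) {
    out[k] <- atoms[k]
    if (length(branch_at) && k %in% branch_at && stats::runif(1) < 0.25) {
      out[k] <- paste0(out[k], "(C)")
    }
  }
  paste(out, collapse = "")
}

#' Generate a bioactivity table for a synthetic library
#'
#' Members of active families draw pX from the active distribution, all
#' other compounds from the inactive one; `replicates` measurements per
#' compound exercise median aggregation. Values are reported as IC50 in nM.
#'
#' @param truth Truth tibble from [generate_chemotype_library()].
#' @param active_families Character vector of family names treated as active
#'   (default: all non-decoy families).
#' @param px_active_mean,px_active_sd Active pX distribution (default 9.5,
#'   0.3: comfortably past the 1 nM cutoff).
#' @param px_inactive_mean,px_inactive_sd Inactive pX distribution (default
#'   5, 0.5).
#' @param replicates Measurements per compound.
#' @param uniprot_id Accession the synthetic target carries.
#' @param rng_seed Integer seed.
#' @return Tibble of bioactivity records (`uniprot_id`, `compound_id`,
#'   `endpoint`, `value`, `unit`, `relation`, `source`, `document_ref`).
#' @export
generate_bioactivity_table <- function(truth,
                                       active_families = NULL,
                                       px_active_mean = 9.5, px_active_sd = 0.3,
                                       px_inactive_mean = 5, px_inactive_sd = 0.5,
                                       replicates = 3,
                                       uniprot_id = "P99999",
                                       rng_seed = 1L) {
  if (!nrow(truth)) return(tibble::tibble(
    uniprot_id = character(), compound_id = character(), endpoint = character(),
    value = numeric(), unit = character(), relation = character(),
    source = character(), document_ref = character()))
  active_families <- active_families %||% setdiff(unique(truth$family), "decoy")
  withr::with_seed(rng_seed, {
    rows <- purrr::pmap(truth, function(compound_id, family) {
      active <- family %in% active_families
      px <- stats::rnorm(replicates,
                         if (active) px_active_mean else px_inactive_mean,
                         if (active) px_active_sd else px_inactive_sd)
      tibble::tibble(
        uniprot_id = uniprot_id, compound_id = compound_id,
        endpoint = "IC50", value = 10^(9 - px), unit = "nM", relation = "=",
        source = "synthetic_assay",
        document_ref = sprintf("DOC%05d", sample.int(99999L, 1)))
    })
    dplyr::bind_rows(rows)
  })
}

#' Write canned API payload fixtures
#'
#' Emits, per synthetic target: paginated bioactivity XML pages (constant
#' `total_count`, ragged last page), a disease-association JSON document, a
#' protein-entry XML with PDB cross-references, a best-structures JSON
#' mapping, and structure-entry / chemcomp JSON payloads - all shaped like
#' the live services' responses so every parser can be exercised offline.
#' File names follow [fetch_api()]'s URL-to-fixture mapping, plus a
#' `manifest.json` describing what was planted.
#'
#' @param dir Output fixture directory (created if missing).
#' @param targets Character vector of UniProt accessions.
#' @param records_per_target Bioactivity count per target (recycled).
#' @param page_size Records per page.
#' @param disease_id Disease identifier for the association payload.
#' @param rng_seed Integer seed.
#' @return The manifest, invisibly.
#' @export
generate_api_fixtures <- function(dir, targets = c("P99991", "P99992"),
                                  records_per_target = 25,
                                  page_size = 10,
                                  disease_id = "EFO_TEST01",
                                  rng_seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records_per_target <- rep_len(records_per_target, length(targets))
  chembl_ids <- sprintf("CHEMBL%d", 5000L + seq_along(targets))
  # mix of ring-free, single-ring and fused-ring chemotypes so downstream
  # scaffold stages see generic and non-generic frameworks alike
  pool <- c("CCO", "c1ccc2ncccc2c1", "CC(=O)O", "Cc1ccc2c(c1)OCO2",
            "c1ccncc1", "Cc1ccc2ncccc2c1")

  withr::with_seed(rng_seed, {
    for (t in seq_along(targets)) {
      total <- records_per_target[t]
      plan <- plan_pagination(total, page_size)
      made <- 0L
      offsets <- if (plan$n_pages == 0L) 0L else plan$offsets
      for (off in offsets) {
        n_here <- max(0L, min(page_size, total - off))
        acts <- character(n_here)
        for (r in seq_len(n_here)) {
          idx <- off + r
          acts[r] <- sprintf(paste0(
            "<activity><activity_comment/>",
            "<assay_description>Synthetic assay %d</assay_description>",
            "<molecule_chembl_id>CHEMBL%d</molecule_chembl_id>",
            "<molecule_pref_name>compound %d</molecule_pref_name>",
            "<canonical_smiles>%s</canonical_smiles>",
            "<standard_type>IC50</standard_type>",
            "<standard_units>nM</standard_units>",
            "<standard_value>%.3f</standard_value>",
            "<standard_relation>=</standard_relation>",
            "<parent_molecule_chembl_id>CHEMBL%d</parent_molecule_chembl_id>",
            "<document_chembl_id>CHEMBL_DOC%d</document_chembl_id>",
            "</activity>"),
            idx, 100000L + idx, idx, pool[(idx %% length(pool)) + 1L],
            10^stats::runif(1, -0.7, 2), 100000L + idx, 20000L + idx)
          made <- made + 1L
        }
        page <- paste0(
          "<response><page_meta><limit>", page_size, "</limit><offset>", off,
          "</offset><total_count>", total, "</total_count></page_meta>",
          "<activities>", paste(acts, collapse = ""), "</activities></response>")
        req <- build_activity_request(chembl_ids[t], page_size, off)
        writeLines(page, file.path(dir, fixture_name_for_url(req$url)))
      }
      stopifnot(made == total)

      # protein entry XML with PDB cross-references
      pdb_ids <- sprintf("%d%s%s%s", sample(1:9, 2, replace = TRUE)[1],
                         LETTERS[sample(26, 1)], LETTERS[sample(26, 1)],
                         sample(0:9, 1))
      pdb_ids <- unique(c(pdb_ids, sprintf("%dXY%d", sample(1:9, 1), t)))
      entry <- paste0(
        '<uniprot xmlns="http://uniprot.org/uniprot"><entry>',
        sprintf('<accession>%s</accession>', targets[t]),
        '<dbReference type="PubMed" id="12730500"/>',
        '<dbReference type="Pfam" id="PF06478"/>',
        paste(sprintf('<dbReference type="PDB" id="%s"/>', pdb_ids),
              collapse = ""),
        "</entry></uniprot>")
      ureq <- build_uniprot_request(targets[t])
      writeLines(entry, file.path(dir, fixture_name_for_url(ureq$url)))

      # best-structures mapping (mixed case on purpose; parser uppercases)
      best <- list()
      best[[targets[t]]] <- lapply(pdb_ids, function(p) {
        list(pdb_id = tolower(p), experimental_method = "X-ray diffraction",
             resolution = round(stats::runif(1, 1.2, 3.2), 2))
      })
      writeLines(jsonlite::toJSON(best, auto_unbox = TRUE),
                 file.path(dir, fixture_name_for_url(
                   sprintf(PDBE_BEST_STRUCTURES_TEMPLATE, targets[t]))))

      # structure entries with bound components + chemcomp descriptors
      for (p in pdb_ids) {
        comp <- sprintf("LG%d", t)
        entry_json <- list(rcsb_entry_info = list(
          nonpolymer_bound_components = c(comp, "GOL")))
        writeLines(jsonlite::toJSON(entry_json, auto_unbox = TRUE),
                   file.path(dir, fixture_name_for_url(
                     sprintf(RCSB_ENTRY_TEMPLATE, p))))
        cc <- list(rcsb_chem_comp_descriptor = list(
          smiles = pool[(t %% length(pool)) + 1L]))
        writeLines(jsonlite::toJSON(cc, auto_unbox = TRUE),
                   file.path(dir, fixture_name_for_url(
                     sprintf(RCSB_CHEMCOMP_TEMPLATE, comp))))
      }
    }

    assoc <- list(data = lapply(seq_along(targets), function(t) {
      list(disease = list(id = disease_id),
           target = list(id = sprintf("ENSG%011d", t),
                         gene_info = list(name = sprintf("synthetic gene %d", t),
                                          symbol = sprintf("SYN%d", t))),
           association_score = list(overall = round(stats::runif(1, 0.99, 1), 4)))
    }))
    areq <- build_association_request(disease_id, 10000, 0.99)
    writeLines(jsonlite::toJSON(assoc, auto_unbox = TRUE),
               file.path(dir, fixture_name_for_url(areq$url)))

    manifest <- list(disease_id = disease_id,
                     targets = targets, chembl_ids = chembl_ids,
                     records_per_target = records_per_target,
                     page_size = page_size, rng_seed = rng_seed)
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
               file.path(dir, "manifest.json"))
    invisible(manifest)
  })
}
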