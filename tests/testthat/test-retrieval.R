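# Request construction, status classification, pagination, and the payload
# parsers, all on canned fixtures.

test_that("association request carries the three query parameters", {
  req <- build_association_request("EFO_0001360", 10000, 0.99)
  expect_identical(
    req$url,
    paste0("https://platform-api.opentargets.io/v3/platform/public/",
           "association/filter?disease=EFO_0001360&size=10000&scorevalue_min=0.99"))
  expect_match(build_association_request("Orphanet_71277", 10000, 0.99)$url,
               "disease=Orphanet_71277", fixed = TRUE)
  req2 <- build_association_request("MONDO_0100096", 1, 0.0)
  expect_match(req2$url, "size=1&", fixed = TRUE)
  expect_match(req2$url, "scorevalue_min=0", fixed = TRUE)
  expect_error(build_association_request("", 10, 0.5), class = "sq_validation")
  expect_error(build_association_request("EFO_1", 10, 1.5), class = "sq_validation")
})

test_that("activity request substitutes id, limit, and offset", {
  expect_identical(
    build_activity_request("CHEMBL5118", 1000, 0)$url,
    paste0("https://www.ebi.ac.uk/chembl/api/data/activity",
           "?target_chembl_id=CHEMBL5118&limit=1000&offset=0"))
  expect_match(build_activity_request("CHEMBL5118", 1000, 2000)$url,
               "offset=2000$")
  expect_match(build_activity_request("CHEMBL1", 10, 0)$url,
               "^https://[^ ]+activity\\?target_chembl_id=CHEMBL1&")
  expect_error(build_activity_request("5118", 1000, 0), class = "sq_validation")
})

test_that("pharmacology request pair follows the printed target syntax", {
  reqs <- build_iuphar_requests(2421)
  expect_identical(reqs$url[1],
                   "http://www.guidetopharmacology.org/services/targets/2421/substrates")
  expect_identical(reqs$url[2],
                   "http://www.guidetopharmacology.org/services/targets/2421/interactions")
  expect_identical(nrow(build_iuphar_requests(1)), 2L)
  expect_error(build_iuphar_requests(0), class = "sq_validation")
})

test_that("request URLs round-trip their query parameters", {
  parse_query <- function(url) {
    q <- sub("^[^?]*\\?", "", url)
    kv <- strsplit(strsplit(q, "&", fixed = TRUE)[[1]], "=", fixed = TRUE)
    stats::setNames(vapply(kv, `[`, character(1), 2),
                    vapply(kv, `[`, character(1), 1))
  }
  for (case in list(list("EFO_0001360", 10000, 0.99),
                    list("Orphanet_71277", 500, 0.5),
                    list("MONDO_0100096", 1, 0))) {
    q <- parse_query(build_association_request(case[[1]], case[[2]], case[[3]])$url)
    expect_identical(unname(q["disease"]), case[[1]])
    expect_identical(as.numeric(q["size"]), as.numeric(case[[2]]))
    expect_identical(as.numeric(q["scorevalue_min"]), as.numeric(case[[3]]))
  }
  q <- parse_query(build_activity_request("CHEMBL5118", 1000, 2000)$url)
  expect_identical(unname(q[c("target_chembl_id", "limit", "offset")]),
                   c("CHEMBL5118", "1000", "2000"))
})

test_that("status classification partitions 100-599 into the five classes", {
  expect_identical(classify_status(200L), "success")
  expect_identical(classify_status(404L), "client_error")
  expect_identical(classify_status(599L), "server_error")
  all_codes <- classify_status(100:599)
  counts <- table(all_codes)
  expect_setequal(names(counts), c("informational", "success", "redirect",
                                   "client_error", "server_error"))
  expect_true(all(counts == 100L))
  expect_false(anyNA(all_codes))
  expect_error(classify_status(99), class = "sq_validation")
  expect_error(classify_status(600), class = "sq_validation")
})

test_that("pagination plans cover every record exactly once", {
  plan <- plan_pagination(2410, 1000)
  expect_identical(plan$offsets, c(0L, 1000L, 2000L))
  expect_identical(plan$n_pages, 3L)
  expect_identical(plan_pagination(1000, 1000)$offsets, 0L)
  expect_identical(plan_pagination(0, 1000)$offsets, integer())
  expect_error(plan_pagination(10, 0), class = "sq_validation")
  # exhaustive coverage for small sizes
  for (t in 0:50) {
    for (p in 1:7) {
      plan <- plan_pagination(t, p)
      expect_identical(length(plan$offsets), as.integer(ceiling(t / p)))
      got <- as.integer(unlist(lapply(plan$offsets, function(off) {
        seq_len(min(p, t - off)) + off
      })))
      expect_identical(sort(unique(got)), seq_len(t),
                       label = sprintf("t=%d p=%d", t, p))
      expect_identical(length(got), t)
    }
  }
})

test_that("association payload parsing follows the documented JSON paths", {
  doc <- jsonlite::toJSON(list(data = list(
    list(disease = list(id = "EFO_0001360"),
         target = list(id = "ENSG00000001",
                       gene_info = list(name = "gene one", symbol = "G1")),
         association_score = list(overall = 0.995)),
    list(disease = list(id = "EFO_0001360"),
         target = list(id = "ENSG00000002",
                       gene_info = list(name = "gene two", symbol = "G2")),
         association_score = list(overall = 1.0))
  )), auto_unbox = TRUE)
  tbl <- parse_association_payload(doc)
  expect_identical(nrow(tbl), 2L)
  expect_identical(tbl$target_id, c("ENSG00000001", "ENSG00000002"))
  expect_identical(tbl$gene_symbol, c("G1", "G2"))
  expect_true(all(tbl$association_score >= 0 & tbl$association_score <= 1))

  expect_identical(nrow(parse_association_payload('{"data": []}')), 0L)

  no_symbol <- '{"data": [{"target": {"id": "ENSG3", "gene_info": {"name": "g"}}}]}'
  tbl2 <- parse_association_payload(no_symbol)
  expect_identical(tbl2$target_id, "ENSG3")
  expect_true(is.na(tbl2$gene_symbol))

  expect_error(parse_association_payload('{"rows": []}'), class = "sq_parse")
})

test_that("PDB cross-references are picked out of the entry XML", {
  doc <- paste0(
    '<uniprot xmlns="http://uniprot.org/uniprot"><entry>',
    '<dbReference type="PubMed" id="12730500"/>',
    '<dbReference type="GO" id="GO:0039579"/>',
    '<dbReference type="InterPro" id="IPR036333"/>',
    '<dbReference type="Pfam" id="PF06478"/>',
    '<dbReference type="PDB" id="6NUR"/>',
    "</entry></uniprot>")
  expect_identical(parse_uniprot_pdb_xrefs(doc), "6NUR")
  pfam_only <- paste0(
    '<uniprot xmlns="http://uniprot.org/uniprot"><entry>',
    '<dbReference type="Pfam" id="PF06478"/></entry></uniprot>')
  expect_identical(parse_uniprot_pdb_xrefs(pfam_only), character())
  empty <- '<uniprot xmlns="http://uniprot.org/uniprot"><entry/></uniprot>'
  expect_identical(parse_uniprot_pdb_xrefs(empty), character())
  expect_error(parse_uniprot_pdb_xrefs("not xml"), class = "sq_parse")
})

test_that("best-structures payloads deduplicate and uppercase per accession", {
  doc <- paste0('{"Q9BYF1": [{"pdb_id": "6m17"}, {"pdb_id": "6M17"},',
                ' {"pdb_id": "1r42"}]}')
  tbl <- parse_best_structures(doc)
  expect_identical(tbl$pdb_id, c("6M17", "1R42"))
  expect_identical(unique(tbl$uniprot_id), "Q9BYF1")
  empty <- parse_best_structures("{}")
  expect_identical(nrow(empty), 0L)
  expect_warning(parse_best_structures('{"Q9BYF1": [{"resolution": 2.0}]}'),
                 "no pdb_id")
})

test_that("bound-ligand extraction honours the blocklist and absent keys", {
  doc <- '{"rcsb_entry_info": {"nonpolymer_bound_components": ["BME", "NAG", "XU3"]}}'
  expect_identical(parse_bound_ligands(doc, blocklist = character()),
                   c("BME", "NAG", "XU3"))
  # BME sits on the default buffer blocklist
  expect_identical(parse_bound_ligands(doc), c("NAG", "XU3"))
  expect_identical(parse_bound_ligands('{"rcsb_entry_info": {}}'), character())
  with_agent <- '{"rcsb_entry_info": {"nonpolymer_bound_components": ["XU3", "INI"]}}'
  expect_identical(parse_bound_ligands(with_agent, blocklist = "INI"), "XU3")
})

test_that("chemcomp descriptors yield a SMILES or a typed no-structure error", {
  expect_identical(
    parse_chemcomp_smiles('{"rcsb_chem_comp_descriptor": {"smiles": "CCO"}}'),
    "CCO")
  expect_error(parse_chemcomp_smiles('{"rcsb_chem_comp_descriptor": {}}'),
               class = "sq_no_structure")
  # synthetic stand-in for an N-acetylglucosamine component payload
  nag <- jsonlite::toJSON(list(rcsb_chem_comp_descriptor = list(
    smiles = "CC(=O)N[C@H]1[C@@H](O)[C@H](O)[C@@H](CO)O[C@@H]1O")),
    auto_unbox = TRUE)
  smi <- parse_chemcomp_smiles(nag)
  # the sugar parses and contains a pyranose-type oxygen heterocycle
  expect_true(smarts_matches("[#8]1-[#6]-[#6]-[#6]-[#6]-[#6]-1", smi))
})

test_that("activity pages surface records, the declared total, and value flags", {
  page <- paste0(
    "<response><page_meta><total_count>2410</total_count></page_meta>",
    "<activities>",
    "<activity><molecule_chembl_id>CHEMBL1</molecule_chembl_id>",
    "<standard_type>IC50</standard_type><standard_units>nM</standard_units>",
    "<standard_value>5</standard_value><standard_relation>=</standard_relation>",
    "<document_chembl_id>CHEMBL_DOC1</document_chembl_id></activity>",
    "<activity><molecule_chembl_id>CHEMBL2</molecule_chembl_id>",
    "<standard_type>Ki</standard_type></activity>",
    "</activities></response>")
  res <- parse_activity_page(page)
  expect_identical(res$total_count, 2410L)
  expect_identical(nrow(res$records), 2L)
  # the 5 nM row transforms to pX 8.301 downstream
  expect_equal(to_pscale(res$records$value[1], res$records$unit[1]), 8.301,
               tolerance = 1e-4)
  # the valueless row is kept but flagged
  expect_true(res$records$value_missing[2])
  empty <- parse_activity_page(
    "<response><page_meta><total_count>0</total_count></page_meta><activities/></response>")
  expect_identical(nrow(empty$records), 0L)
  expect_identical(empty$total_count, 0L)
  expect_error(parse_activity_page("<response><activities/></response>"),
               class = "sq_parse")
})

test_that("assay-chain mapping follows AID -> CID with secondary name lookup", {
  fx <- withr::local_tempdir()
  writeLines('["1001"]', file.path(fx, "pubchem_aids_P12345.json"))
  writeLines(paste0(
    '[{"cid": "501", "name": "compound A", "smiles": "CCO", "endpoint": "IC50",',
    ' "value": 12, "unit": "nM", "pmid": "999"},',
    ' {"cid": "502", "name": "CHEMBL25", "smiles": "CC(=O)Oc1ccccc1C(=O)O",',
    ' "endpoint": "Ki", "value": 3, "unit": "uM", "pmid": "998"}]'),
    file.path(fx, "pubchem_aid_1001.json"))
  writeLines('{"pref_name": "ASPIRIN"}', file.path(fx, "chembl_name_CHEMBL25.json"))
  recs <- map_pubchem_target("P12345", fx)
  expect_identical(nrow(recs), 2L)
  expect_identical(recs$molecule_name, c("compound A", "ASPIRIN"))
  expect_identical(recs$source, rep("pubchem", 2))
  # dangling assay id: skipped with a warning
  writeLines('["1001", "2002"]', file.path(fx, "pubchem_aids_P12345.json"))
  expect_warning(map_pubchem_target("P12345", fx), "2002")
  # no assays at all
  writeLines("[]", file.path(fx, "pubchem_aids_P00000.json"))
  expect_identical(nrow(map_pubchem_target("P00000", fx)), 0L)
})

test_that("PDB-format headers give method, resolution, and space group", {
  pdb_text <- paste(
    "HEADER    HYDROLASE                               01-JAN-20   1ABC",
    "TITLE     SYNTHETIC TEST STRUCTURE",
    "EXPDTA    X-RAY DIFFRACTION",
    "REMARK   2 RESOLUTION.    1.90 ANGSTROMS.",
    "REMARK   3   R VALUE            (WORKING SET) : 0.177",
    "CRYST1   50.000   60.000   70.000  90.00  90.00  90.00 P 21 21 21    4",
    sep = "\n")
  props <- read_pdb_properties(pdb_text)
  expect_identical(props$experimental_method, "X-RAY DIFFRACTION")
  expect_equal(props$resolution, 1.9)
  expect_equal(props$r_factor, 0.177)
  expect_match(props$space_group, "P 21 21 21")
  # unparseable header: fields stay NA, nothing raises
  junk <- read_pdb_properties("not a pdb file at all")
  expect_true(is.na(junk$experimental_method))
})

test_that("every generated fixture file parses with the matching parser", {
  fx <- withr::local_tempdir()
  generate_api_fixtures(fx, targets = c("P99991", "P99992"),
                        records_per_target = c(23, 7), page_size = 10,
                        rng_seed = 11)
  files <- list.files(fx, full.names = TRUE)
  expect_gt(length(files), 5)
  for (f in files) {
    body <- paste(readLines(f, warn = FALSE), collapse = "\n")
    nm <- basename(f)
    if (nm == "manifest.json") next
    if (grepl("^www_ebi_ac_uk_chembl", nm)) {
      expect_no_error(parse_activity_page(body))
    } else if (grepl("^www_uniprot_org", nm)) {
      expect_no_error(parse_uniprot_pdb_xrefs(body))
    } else if (grepl("best_structures", nm)) {
      expect_no_error(parse_best_structures(body))
    } else if (grepl("core_entry", nm)) {
      expect_no_error(parse_bound_ligands(body))
    } else if (grepl("core_chemcomp", nm)) {
      expect_no_error(parse_chemcomp_smiles(body))
    } else if (grepl("association_filter", nm)) {
      expect_no_error(parse_association_payload(body))
    }
  }
})

test_that("fixture transport maps URLs to files and drops missing rows", {
  fx <- withr::local_tempdir()
  req <- build_activity_request("CHEMBL99", 10, 0)
  writeLines("<response><page_meta><total_count>0</total_count></page_meta></response>",
             file.path(fx, scaffquery:::fixture_name_for_url(req$url)))
  body <- fetch_api(req, fixtures = fx)
  expect_match(body, "total_count")
  expect_warning(missing <- fetch_api(build_activity_request("CHEMBL98", 10, 0),
                                      fixtures = fx),
                 "row dropped")
  expect_true(is.na(missing))
})

test_that("bulk mapping reader splits multi-valued cross-references", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Entry\tCross-reference (OpenTargets)\tStatus",
               "P11166\tENSG00000117394;\treviewed",
               "Q9BYF1\tENSG00000130234\treviewed"), tsv)
  map <- read_uniprot_mapping(tsv)
  expect_identical(nrow(map), 2L)
  expect_identical(map$target_id[map$uniprot_id == "P11166"], "ENSG00000117394")
})
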