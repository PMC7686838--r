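# Substructure screening: the published query set, oracle agreement,
# overlap, rediscovery, and SVG highlights.

table2 <- read_smarts_file(system.file("extdata", "table2.smarts",
                                       package = "scaffquery"))

test_that("the shipped 18-query set parses and is distinct", {
  expect_identical(nrow(table2), 18L)
  expect_identical(length(unique(table2$smarts)), 18L)
  for (s in table2$smarts) expect_no_error(parse_smarts(s))
  # reported per-cluster hit totals carried with the fixture
  hits_by_cluster <- tapply(table2$hits, table2$cluster, sum)
  expect_identical(as.integer(hits_by_cluster[c("1", "2", "3", "4", "5")]),
                   c(59L, 53L, 22L, 3L, 3L))
})

test_that("published cage and diamine queries match their archetypes", {
  adamantane_q <- table2$smarts[table2$cluster == "5"]
  expect_true(smarts_matches(adamantane_q, "NC12CC3CC(CC(C3)C1)C2"))
  expect_true(oracle_match_smarts(adamantane_q, "NC12CC3CC(CC(C3)C1)C2"))

  piperazine_q <- "[#7]1-[#6]-[#6]-[#7]-[#6]-[#6]-1"
  expect_true(table2$smarts[9] == piperazine_q)
  expect_true(smarts_matches(piperazine_q, "C1CNCCN1"))
  expect_true(oracle_match_smarts(piperazine_q, "C1CNCCN1"))
  expect_true(smarts_matches(piperazine_q, "CCN1CCN(c2ccccc2)CC1"))
  # aromatic diazine does not satisfy the single-bonded ring query
  expect_false(smarts_matches(piperazine_q, "c1cnccn1"))
  expect_false(smarts_matches(piperazine_q, "C"))
})

test_that("screening a labeled library produces per-pair hit rows", {
  lib <- standardize_compounds(tibble::tibble(
    library = "demo",
    compound_id = c("D1", "D2", "D3"),
    name = c("amantadine", "phenylpiperazine", "butane"),
    smiles = c("NC12CC3CC(CC(C3)C1)C2", "CCN1CCN(c2ccccc2)CC1", "CCCC")))
  queries <- tibble::tibble(
    uniprot_id = "P1", cluster_id = c(5L, 3L),
    smarts = c(table2$smarts[table2$cluster == "5"],
               "[#7]1-[#6]-[#6]-[#7]-[#6]-[#6]-1"))
  hits <- substructure_screen(lib, queries)
  expect_identical(sort(hits$compound_id), c("D1", "D2"))
  expect_identical(nrow(hits), 2L)
  # matched atoms index into the compound and satisfy the pattern per oracle
  for (k in seq_len(nrow(hits))) {
    expect_true(all(hits$matched_atoms[[k]] >= 1))
    expect_true(oracle_match_smarts(hits$smarts[k], hits$smiles[k]))
  }
  expect_error(
    substructure_screen(lib, tibble::tibble(smarts = "[[bad")),
    class = "sq_validation")
})

test_that("screen results equal the brute-force oracle on a small library", {
  set.seed(31)
  gen <- generate_chemotype_library(chemotype_spec(
    analogs_per_family = 2, decoys = 15, salt_rate = 0, stereo_rate = 0,
    charge_rate = 0, rng_seed = 21))
  lib <- quarantined(standardize_compounds(gen$library))$clean
  lib$library <- "oracle_corpus"
  # small molecules only, so exhaustive matching stays cheap
  keep <- vapply(lib$std_smiles, function(s)
    scaffquery:::mol_heavy_atoms(scaffquery:::mol_from_smiles(s)) <= 12,
    logical(1))
  lib <- lib[keep, ]
  queries <- tibble::tibble(
    uniprot_id = "P1", cluster_id = seq_len(4),
    smarts = c("[#7]1-[#6]-[#6]-[#7]-[#6]-[#6]-1",
               "[#6]:1:[#6]:[#6]:[#6]:[#6]:[#6]:1",
               "[#6]-[#8]-[#6]",
               "[#6](=[#8])-[#8]"))
  hits <- substructure_screen(lib, queries)
  for (i in seq_len(nrow(lib))) {
    for (k in seq_len(nrow(queries))) {
      got <- any(hits$compound_id == lib$compound_id[i] &
                   hits$smarts == queries$smarts[k])
      want <- oracle_match_smarts(queries$smarts[k], lib$std_smiles[i])
      expect_identical(got, want,
                       label = sprintf("%s vs %s", lib$compound_id[i],
                                       queries$smarts[k]))
    }
  }
})

test_that("cross-library overlap intersects by InChIKey", {
  hits <- tibble::tibble(
    library = c("A", "A", "B", "B"),
    compound_id = c("a1", "a2", "b7", "b9"),
    inchikey = c("KEY1", "KEY2", "KEY2", "KEY3"),
    smarts = c("q1", "q1", "q2", "q1"))
  ov <- cross_library_overlap(hits)
  expect_identical(ov$inchikey, "KEY2")            # same compound, two ids
  expect_identical(ov$queries[[1]], c("q1", "q2"))
  disjoint <- dplyr::mutate(hits, inchikey = paste0(inchikey, library))
  expect_identical(nrow(cross_library_overlap(disjoint)), 0L)
  expect_warning(one <- cross_library_overlap(hits[hits$library == "A", ]),
                 "fewer than two")
  expect_identical(nrow(one), 0L)
})

test_that("rediscovery fractions count unique compounds", {
  hits <- tibble::tibble(inchikey = c("K1", "K1", "K2", "K3", "K4"))
  expect_equal(flag_rediscoveries(hits, "K1")$rediscovery_fraction, 0.25)
  expect_equal(flag_rediscoveries(hits, character())$rediscovery_fraction, 0)
  expect_equal(
    flag_rediscoveries(hits, c("K1", "K2", "K3", "K4"))$rediscovery_fraction, 1)
  expect_true(is.na(flag_rediscoveries(hits[0, ], "K1")$rediscovery_fraction))
})

test_that("highlight rendering writes well-formed SVG", {
  path <- withr::local_tempfile(fileext = ".svg")
  hit_atoms <- smarts_match("[#7]1-[#6]-[#6]-[#7]-[#6]-[#6]-1",
                            "CCN1CCN(c2ccccc2)CC1")[[1]]
  render_highlight("CCN1CCN(c2ccccc2)CC1", hit_atoms, path)
  doc <- xml2::read_xml(path)
  expect_identical(xml2::xml_name(doc), "svg")
  expect_gt(length(xml2::xml_find_all(doc, ".//*[local-name()='line']")), 10)
  # all-atom highlight is legal; a bad index is not
  render_highlight("C1CNCCN1", 1:6, path)
  expect_no_error(xml2::read_xml(path))
  expect_error(render_highlight("C1CNCCN1", c(1L, 99L), path),
               class = "sq_validation")
})
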