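# Standardization: stereo removal, salt stripping, charge neutralization,
# element filtering, and identity generation.

test_that("stereo removal is constitution-preserving", {
  cases <- list(c("C[C@H](N)C(=O)O", "CC(N)C(=O)O"),
                c("F/C=C/F", "FC=CF"),
                c("CCO", "CCO"))
  for (cs in cases) {
    expect_identical(canonical_smiles(remove_stereochemistry(cs[1])),
                     canonical_smiles(cs[2]), label = cs[1])
  }
  # no stereo glyphs survive
  expect_false(grepl("[@/\\\\]", remove_stereochemistry("C[C@@H](O)/C=C\\C")))
})

test_that("salt stripping keeps the organic parent and lists fragments", {
  res <- strip_salts("CCN.Cl")
  expect_identical(canonical_smiles(res$parent), canonical_smiles("CCN"))
  expect_identical(canonical_smiles(res$stripped), canonical_smiles("Cl"))

  res2 <- strip_salts("CC(=O)[O-].[Na+]")
  expect_identical(canonical_smiles(res2$parent), canonical_smiles("CC(=O)[O-]"))
  expect_identical(res2$stripped, "[Na+]")

  res3 <- strip_salts("c1ccccc1")
  expect_identical(res3$parent, "c1ccccc1")
  expect_length(res3$stripped, 0L)

  # two organic fragments: the larger is the parent
  res4 <- strip_salts("c1ccccc1CCCC.CCN")
  expect_identical(canonical_smiles(res4$parent), canonical_smiles("c1ccccc1CCCC"))

  expect_error(strip_salts("[Na+].[Cl-]"), class = "sq_normalization_failure")
})

test_that("charge neutralization adds/removes protons and flags quaternaries", {
  res <- neutralize_charges("CC(=O)[O-]")
  expect_identical(canonical_smiles(res$smiles), canonical_smiles("CC(=O)O"))
  expect_false(res$permanently_charged)

  res2 <- neutralize_charges("C[NH3+]")
  expect_identical(canonical_smiles(res2$smiles), canonical_smiles("CN"))

  res3 <- neutralize_charges("C[N+](C)(C)C")
  expect_identical(canonical_smiles(res3$smiles), canonical_smiles("C[N+](C)(C)C"))
  expect_true(res3$permanently_charged)
})

test_that("the element whitelist admits H,C,N,O,F,Br,I,Cl,P,S only", {
  expect_false(passes_element_filter("C[Se]C"))
  expect_true(passes_element_filter("CCO"))
  expect_false(passes_element_filter("OB(O)c1ccccc1"))
  expect_true(passes_element_filter("ClC(Br)(I)CP(=O)(O)OS"))
})

test_that("full standardization yields the expected identity for a known salt", {
  rec <- standardize_compound("CC(=O)[O-].[Na+]")
  expect_identical(rec$inchikey, "QTBSBXVTEAMEQO-UHFFFAOYSA-N")
  expect_identical(rec$std_smiles, canonical_smiles("CC(=O)O"))
  expect_identical(rec$salt_fragments[[1]], "[Na+]")
  expect_true(is.na(rec$rejected))
})

test_that("failures are flagged by stage, never dropped", {
  tbl <- standardize_compounds(tibble::tibble(
    smiles = c("C[Se]C", "not_a_smiles", "[Na+].[Cl-]", "CCO")))
  expect_identical(tbl$rejected,
                   c("element_filter", "unparseable", "normalization_failure", NA))
  expect_identical(nrow(tbl), 4L)
  split <- quarantined(tbl)
  expect_identical(nrow(split$clean), 1L)
  expect_identical(nrow(split$quarantine), 3L)
})

test_that("standardization is idempotent and stereo-free over the synthetic corpus", {
  gen <- generate_chemotype_library(chemotype_spec(
    analogs_per_family = 3, decoys = 10, salt_rate = 0.5, stereo_rate = 0.5,
    charge_rate = 0.3, rng_seed = 42))
  std1 <- standardize_compounds(gen$library)
  expect_true(all(is.na(std1$rejected)))
  # no stereo annotations anywhere in the standardized corpus
  expect_false(any(grepl("[@/\\\\]", std1$std_smiles)))
  # idempotence: standardizing the standardized structures changes nothing
  std2 <- standardize_compounds(
    tibble::tibble(smiles = std1$std_smiles))
  expect_identical(std2$std_smiles, std1$std_smiles)
  expect_identical(std2$inchikey, std1$inchikey)
  expect_true(all(lengths(std2$salt_fragments) == 0L))
})

test_that("standardization conserves parent heavy atoms and net charge", {
  gen <- generate_chemotype_library(chemotype_spec(
    analogs_per_family = 3, decoys = 5, salt_rate = 0.4, stereo_rate = 0.4,
    charge_rate = 0.5, rng_seed = 7))
  std <- standardize_compounds(gen$library)
  elem_counts <- function(s) {
    m <- scaffquery:::mol_from_smiles(s)
    as.list(table(m$elem[m$elem != "H"]))
  }
  for (k in seq_len(nrow(std))) {
    if (!is.na(std$rejected[k])) next
    raw <- elem_counts(std$smiles[k])
    out <- elem_counts(std$std_smiles[k])
    for (el in names(out)) {
      expect_lte(out[[el]], if (is.null(raw[[el]])) 0L else raw[[el]])
    }
    if (!std$permanently_charged[k]) {
      m <- scaffquery:::mol_from_smiles(std$std_smiles[k])
      expect_identical(sum(m$charge), 0L)
    }
  }
})

test_that("equal InChIKeys imply equal canonical SMILES within a run", {
  gen <- generate_chemotype_library(chemotype_spec(
    analogs_per_family = 5, decoys = 20, rng_seed = 3))
  std <- standardize_compounds(gen$library)
  clean <- quarantined(std)$clean
  by_key <- split(clean$std_smiles, clean$inchikey)
  for (grp in by_key) expect_identical(length(unique(grp)), 1L)
})
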