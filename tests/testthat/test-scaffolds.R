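# Murcko scaffolds, genericity, MCS distances, and clustering.

test_that("Murcko frameworks match independently computed references", {
  # expected values frozen from an independent scaffold implementation
  cases <- list(
    c("CCc1ccc(O)cc1", "c1ccccc1"),
    c("c1ccc(-c2ccccc2)cc1", "c1ccc(-c2ccccc2)cc1"),
    c("NC12CC3CC(CC(C3)C1)C2", "C1C2CC3CC1CC(C2)C3"),
    c("CC(=O)Nc1ccc(O)cc1", "c1ccccc1"),
    c("O=C(Nc1ccccc1)c1ccccc1", "O=C(Nc1ccccc1)c1ccccc1"),
    c("CCN1CCN(c2ccccc2)CC1", "c1ccc(N2CCNCC2)cc1"),
    c("Cc1ccc2ncccc2c1", "c1ccc2ncccc2c1"),
    c("OC(=O)c1ccc2c(c1)OCO2", "c1ccc2c(c1)OCO2"),
    c("CC1CC2CC1C2", "C1CC2CC1C2"),
    c("O=C1CCCCC1", "O=C1CCCCC1"),
    c("C1CCOC1n1cnc2cncnc21", "c1ncc2ncn(C3CCCO3)c2n1"))
  for (cs in cases) {
    expect_identical(murcko_scaffold(cs[1]), canonical_smiles(cs[2]),
                     label = cs[1])
  }
})

test_that("ring-free structures have no framework; frameworks are fixed points", {
  expect_true(is.na(murcko_scaffold("CCCC")))
  expect_true(is.na(murcko_scaffold("CC(C)CO")))
  for (s in c("c1ccccc1", "c1ccc2ncccc2c1", "C1C2CC3CC1CC(C2)C3")) {
    expect_identical(murcko_scaffold(murcko_scaffold(s)), canonical_smiles(s))
  }
})

test_that("single-ring frameworks are generic; fused systems are not", {
  expect_true(is_too_generic("c1ccccc1"))
  expect_true(is_too_generic("c1ccncc1"))
  expect_true(is_too_generic("C1CCNCC1"))
  expect_false(is_too_generic("c1ccc2ncccc2c1"))
  expect_false(is_too_generic("c1ccc(-c2ccccc2)cc1"))
})

test_that("pairwise MCS agrees with exhaustive enumeration on small systems", {
  corpus <- c("c1ccccc1", "c1ccncc1", "C1CCNCC1", "C1CC1", "C1CCC1",
              "c1cc[nH]c1", "C1CCOC1", "c1ccc2ccccc2c1", "c1ccc2ncccc2c1",
              "C1CC2CC1C2", "O=C1CCCC1", "C1CN1")
  pairs <- utils::combn(length(corpus), 2)
  for (k in seq_len(ncol(pairs))) {
    a <- corpus[pairs[1, k]]; b <- corpus[pairs[2, k]]
    got <- mcs_common_atoms(a, b)$size
    expect_identical(got, oracle_mcs_size(a, b),
                     label = sprintf("%s vs %s", a, b))
  }
})

test_that("MCS anchors: self, single atom, fused-ring pair", {
  expect_identical(mcs_common_atoms("c1ccccc1", "c1ccccc1")$size, 6L)
  expect_identical(mcs_common_atoms("CC", "C")$size, 1L)
  res <- mcs_common_atoms("c1ccc2ccccc2c1", "c1ccc2ncccc2c1")
  expect_identical(res$size, 9L)
  # the emitted pattern matches both inputs
  expect_true(smarts_matches(res$smarts, "c1ccc2ccccc2c1"))
  expect_true(smarts_matches(res$smarts, "c1ccc2ncccc2c1"))
})

test_that("distances: formula anchors and metric sanity", {
  expect_identical(scaffold_distance("c1ccccc1", "c1ccccc1"), 0)
  expect_identical(scaffold_distance("CC", "O"), 1)
  expect_equal(scaffold_distance("c1ccc2ccccc2c1", "c1ccc2ncccc2c1"),
               1 - 9 / 11, tolerance = 1e-12)
  expect_equal(scaffold_distance("c1ccc2ccccc2c1", "c1ccc2ncccc2c1",
                                 formula = "max"),
               1 - 9 / 10, tolerance = 1e-12)
  # m never exceeds the smaller structure
  a <- "C1CC2CC1C2"; b <- "c1ccc2ncccc2c1"
  m <- mcs_common_atoms(a, b)$size
  expect_lte(m, 6L)
})

test_that("distance matrices are symmetric, zero-diagonal, in [0,1], order-stable", {
  scaffs <- c("c1ccc2ccccc2c1", "C1C2CC3CC1CC(C2)C3", "c1ccc(-c2ccccc2)cc1",
              "c1ccc2c(c1)OCO2")
  d <- scaffold_distance_matrix(scaffs)
  expect_identical(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  d2 <- scaffold_distance_matrix(rev(scaffs))
  expect_identical(d, d2)
})

test_that("cluster assignment respects the threshold and degenerate inputs", {
  # identical scaffolds co-cluster at any threshold
  cl <- cluster_scaffolds(c("c1ccc2ccccc2c1", "c1ccc2ccccc2c1"), threshold = 0.05)
  expect_identical(unique(cl$cluster_id), 1L)
  # distance-1 pairs split at 0.5
  cl2 <- cluster_scaffolds(c("C1C2CC3CC1CC(C2)C3", "c1ccc2c(c1)OCO2"),
                           threshold = 0.5)
  expect_identical(sort(cl2$cluster_id), c(1L, 2L))
  # singleton: one cluster, no matrix computation
  cl3 <- cluster_scaffolds("c1ccc2ccccc2c1")
  expect_identical(cl3$cluster_id, 1L)
  expect_error(cluster_scaffolds("c1ccccc1", threshold = 0), class = "sq_validation")
})

test_that("clustering is invariant to row order and to duplicated input", {
  scaffs <- c("c1ccc2ccccc2c1", "c1ccc2ncccc2c1", "C1C2CC3CC1CC(C2)C3",
              "c1ccc(-c2ccccc2)cc1")
  base <- cluster_scaffolds(scaffs, threshold = 0.5)
  expect_identical(cluster_scaffolds(rev(scaffs), threshold = 0.5), base)
  expect_identical(cluster_scaffolds(c(scaffs, scaffs), threshold = 0.5), base)
  # naphthalene and quinoline (d ~ 0.18) join; the cage stays apart
  joined <- base$cluster_id[base$scaffold %in%
    c("c1ccc2ccccc2c1", "c1ccc2ncccc2c1")]
  expect_identical(length(unique(joined)), 1L)
})

test_that("per-target clustering runs independently and tidies cleanly", {
  tbl <- tibble::tibble(
    uniprot_id = c("P1", "P1", "P2"),
    inchikey = c("K1", "K2", "K3"),
    std_smiles = c("CCc1ccc2ccccc2c1", "Cc1ccc2ncccc2c1", "NC12CC3CC(CC(C3)C1)C2"))
  scaff <- extract_scaffolds(tbl)
  expect_identical(nrow(scaff), 3L)
  fit <- cluster_scaffold_table(scaff, threshold = 0.5)
  expect_s3_class(fit, "sq_clustering")
  # P1's two fused azine/arene scaffolds co-cluster; P2 is its own singleton
  expect_identical(dplyr::n_distinct(fit$cluster_id[fit$uniprot_id == "P1"]), 1L)
  td <- tidy(fit)
  expect_identical(nrow(td), 3L)
  gl <- glance(fit)
  expect_identical(gl$n_targets, 2L)
  expect_identical(gl$threshold, 0.5)
})
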