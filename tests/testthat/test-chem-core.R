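# Molecular representation and stereochemistry primitives.

test_that("parsing validates, canonicalizes and counts heavy atoms", {
  p <- mol_parse(data.frame(smiles = "c1ccccc1"))
  expect_equal(p$n_heavy_atoms, 6L)
  expect_equal(canonical_smiles(p$smiles), p$smiles) # idempotent

  # canonicalization is idempotent on a varied sample
  smis <- c("OCC", "C[C@H](N)C(=O)O", "COc1ccc(cc1)C1CCNCC1", "O=S1(=O)CCCCC1")
  can <- canonical_smiles(smis)
  expect_equal(canonical_smiles(can), can)
})

test_that("salt stripping keeps the largest organic component", {
  p <- mol_parse(data.frame(smiles = "OC(=O)C1CCNCC1.Cl"), strip_salts = TRUE)
  expect_equal(p$smiles, canonical_smiles("OC(=O)C1CCNCC1"))
  expect_true(p$stripped)

  # stripping that leaves nothing organic is a degenerate input
  expect_error(mol_parse(data.frame(smiles = "[Na+].[Cl-]")),
               class = "fragmatrix_degenerate_input")
})

test_that("malformed SMILES raise parse errors naming the position", {
  expect_error(mol_parse(data.frame(smiles = "C1CC")),
               class = "fragmatrix_parse_error")
  err <- tryCatch(canonical_smiles("CC(C"), error = identity)
  expect_s3_class(err, "fragmatrix_parse_error")
  expect_match(conditionMessage(err), "position")
  expect_error(canonical_smiles(""), class = "fragmatrix_parse_error")
})

test_that("stereocentre inversion flips descriptors and is an involution", {
  expect_equal(invert_stereocenters("C[C@H](N)C(=O)O"),
               canonical_smiles("C[C@@H](N)C(=O)O"))
  # achiral input unchanged
  expect_equal(invert_stereocenters("c1ccccc1"), canonical_smiles("c1ccccc1"))

  # involution on a property-based sample of chiral SMILES
  smis <- c(random_chiral_smiles(40, seed = 101),
            design_library_fixture()$smiles[c(1, 10, 25, 40, 51)])
  can <- canonical_smiles(smis)
  expect_equal(invert_stereocenters(invert_stereocenters(can)), can)
})

test_that("enantiomers differ in canonical SMILES but share a racemate key", {
  smis <- random_chiral_smiles(40, seed = 202)
  can <- canonical_smiles(smis)
  inv <- invert_stereocenters(can)
  expect_true(all(can != inv))
  expect_equal(racemate_key(can), racemate_key(inv))

  # achiral molecules are their own key
  expect_equal(racemate_key("CCO"), canonical_smiles("CCO"))
})

test_that("cis and trans diastereomers have different racemate keys", {
  # brute force over all four stereoisomers of one vicinal pattern
  iso <- c(
    stereo_template_smiles("pyrrolidine_23", "@", "@@"),
    stereo_template_smiles("pyrrolidine_23", "@@", "@"),
    stereo_template_smiles("pyrrolidine_23", "@", "@"),
    stereo_template_smiles("pyrrolidine_23", "@@", "@@")
  )
  keys <- racemate_key(iso)
  expect_equal(keys[1], keys[2]) # enantiomeric cis pair
  expect_equal(keys[3], keys[4]) # enantiomeric trans pair
  expect_false(keys[1] == keys[3]) # diastereomers differ
})

test_that("relative-configuration classification matches the frozen 3D oracle", {
  # 8 stereoisomers: 2 patterns x cis/trans x both enantiomers. Expected
  # labels frozen from an independent 3D conformer same-face oracle.
  cases <- tidyr::expand_grid(
    pattern = c("pyrrolidine_23", "piperidine_43"),
    descr = list(c("@", "@"), c("@", "@@"), c("@@", "@"), c("@@", "@@"))
  )
  cases$expected <- vapply(cases$descr, function(d) {
    if (d[1] == d[2]) "trans" else "cis"
  }, character(1))
  smis <- vapply(seq_len(nrow(cases)), function(i) {
    stereo_template_smiles(cases$pattern[i], cases$descr[[i]][1], cases$descr[[i]][2])
  }, character(1))
  got <- classify_relative_config(smis)
  expect_equal(got$relative_config, cases$expected)
  expect_equal(got$n_defined_centers, rep(2L, 8))

  # classification is invariant under enantiomer inversion
  got_inv <- classify_relative_config(invert_stereocenters(smis))
  expect_equal(got_inv$relative_config, got$relative_config)
})

test_that("classification preconditions fall back to not_applicable", {
  res <- classify_relative_config(c("c1ccccc1", "C[C@H](N)C(=O)O"))
  expect_equal(res$relative_config, rep("not_applicable", 2))
  expect_equal(res$n_defined_centers, c(0L, 1L))
})

test_that("stereo_summary appends columns to a molecule table", {
  df <- data.frame(id = "x", smiles = stereo_template_smiles("pyrrolidine_23", "@", "@@"))
  out <- stereo_summary(df)
  expect_named(out, c("id", "smiles", "n_defined_centers",
                      "n_undefined_centers", "relative_config"))
  expect_equal(out$relative_config, "cis")
})
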