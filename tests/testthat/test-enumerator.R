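# Design-matrix enumeration and bookkeeping.

test_that("the packaged configuration has seven series and validates", {
  cfg <- load_design_config(default_design_config())
  expect_length(cfg$series, 7)
  scafs <- vapply(cfg$series, `[[`, character(1), "scaffold")
  expect_setequal(unique(scafs),
                  c("pyrrolidine", "piperidine", "cyclic_sulfone_6",
                    "gem_difluorocyclohexane"))
})

test_that("config validation rejects broken inputs", {
  empty <- tempfile(fileext = ".yaml"); file.create(empty)
  expect_error(load_design_config(empty), "no 'series'")

  bad <- tempfile(fileext = ".yaml")
  writeLines(c(
    "series:",
    "  - scaffold: piperidine",
    "    head_position: 3",
    "    aryl_position: 3", # violates the vicinal rule
    "    aryls: [4-methoxyphenyl]",
    "    heads: [carboxylic_acid]",
    "    configs: [cis]",
    "    fragments:",
    "      - {frag_id: F1}"), bad)
  expect_error(load_design_config(bad), "vicinal")
})

test_that("packaged enumeration reproduces the collection bookkeeping", {
  lib <- design_library_fixture()
  s <- tally_designs(lib)$summary
  expect_equal(nrow(lib), 51L)
  expect_equal(length(unique(lib$racemate_key)), 51L)
  expect_equal(s$n_synthesized, 44L)
  expect_equal(s$n_synthesized_n_heterocycle, 38L)
  expect_equal(s$n_synthesized_other, 6L)
  expect_equal(s$n_commercial, 2L)
  expect_setequal(lib$frag_id[lib$status == "commercial"], c("FRAG29", "FRAG31"))
  # tallies are conserved
  expect_equal(sum(tally_designs(lib)$by_status$n), nrow(lib))
  expect_equal(sum(tally_designs(lib)$by_scaffold$n), nrow(lib))
  # nitrile heads occur only in the 4,3-piperidine series
  nit <- lib[lib$polar_head == "nitrile", ]
  expect_true(all(nit$scaffold == "piperidine" & nit$head_position == 4))
})

test_that("a toy series expands to the full option product", {
  toy <- tempfile(fileext = ".yaml")
  writeLines(c(
    "series:",
    "  - scaffold: pyrrolidine",
    "    head_position: 2",
    "    aryl_position: 3",
    "    aryls: [4-methoxyphenyl, 4-fluorophenyl]",
    "    heads: [carboxylic_acid, primary_amide]",
    "    configs: [cis, trans]",
    "    fragments:",
    paste0("      - {frag_id: T", 1:8, "}")), toy)
  lib <- enumerate_designs(toy)
  expect_equal(nrow(lib), 8L)
  expect_equal(length(unique(lib$racemate_key)), 8L)
})

test_that("duplicate designs across fragment IDs raise an integrity error", {
  dup <- tempfile(fileext = ".yaml")
  writeLines(c(
    "series:",
    "  - scaffold: pyrrolidine",
    "    head_position: 2",
    "    aryl_position: 3",
    "    aryls: [4-methoxyphenyl]",
    "    heads: [carboxylic_acid]",
    "    configs: [cis]",
    "    fragments:",
    "      - {frag_id: A1}",
    "  - scaffold: pyrrolidine",
    "    head_position: 2",
    "    aryl_position: 3",
    "    aryls: [4-methoxyphenyl]",
    "    heads: [carboxylic_acid]",
    "    configs: [cis]",
    "    fragments:",
    "      - {frag_id: A2}"), dup)
  expect_error(enumerate_designs(dup), "integrity")
})

test_that("built structures have the designed formulae", {
  lib <- design_library_fixture()
  # hand atom counts: 2,3-pyrrolidine acid + 4-methoxyphenyl, cis
  expect_equal(mol_formula(lib$smiles[lib$frag_id == "FRAG1"]), "C12H15NO3")
  # cyclic sulfone C(4) acid + 4-methoxyphenyl, cis
  expect_equal(mol_formula(lib$smiles[lib$frag_id == "FRAG46"]), "C13H16O5S")
  # ring N-H is free on every N-heterocycle (no protecting groups)
  nhet <- lib[lib$scaffold %in% c("pyrrolidine", "piperidine"), ]
  flt <- scaffold_filter(nhet, keep_all = TRUE)
  expect_true(all(flt$matches_pyrrolidine | flt$matches_piperidine))
})

test_that("cis and trans designs of one series are distinct diastereomers", {
  d <- tibble::tibble(scaffold = "pyrrolidine", head_position = 2L,
                      aryl_position = 3L, relative_config = c("cis", "trans"),
                      aryl = "4-methoxyphenyl", polar_head = "carboxylic_acid")
  built <- build_structure(d)
  expect_false(built$smiles[1] == built$smiles[2])
  expect_false(racemate_key(built$smiles[1]) == racemate_key(built$smiles[2]))
})

test_that("every synthesized design round-trips its declared configuration", {
  syn <- synthesized_fixture()
  got <- classify_relative_config(syn$smiles)
  expect_equal(got$relative_config, syn$relative_config)
})

test_that("impossible build requests error", {
  d <- tibble::tibble(scaffold = "pyrrolidine", head_position = 2L,
                      aryl_position = 4L, relative_config = "cis",
                      aryl = "4-methoxyphenyl", polar_head = "carboxylic_acid")
  expect_error(build_structure(d), "vicinal")
})
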