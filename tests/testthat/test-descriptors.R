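# Descriptor correctness against the frozen reference panel and
# descriptor-level invariants.

test_that("the reference panel matches the independent oracle", {
  panel <- descriptor_panel()
  got <- compute_properties(panel[, c("id", "smiles")])
  expect_equal(got$mw, panel$mw, tolerance = 0.01)
  expect_equal(got$clogp, panel$clogp, tolerance = 0.01)
  expect_equal(got$tpsa, panel$tpsa, tolerance = 0.01)
  expect_identical(got$hbd, panel$hbd)
  expect_identical(got$hba, panel$hba)
  expect_identical(got$rotb, panel$rotb)
})

test_that("the plain N+O acceptor convention is available and documented", {
  got <- compute_properties(data.frame(smiles = "OC(=O)C1CCNCC1"),
                            hba_rule = "n_o_count")
  expect_equal(got$hba, 3L) # ring N + both acid oxygens
})

test_that("all six descriptors are blind to chirality", {
  smis <- canonical_smiles(random_chiral_smiles(100, seed = 303))
  a <- compute_properties(data.frame(smiles = smis))
  b <- compute_properties(data.frame(smiles = invert_stereocenters(smis)))
  for (p in c("mw", "clogp", "hbd", "hba", "tpsa", "rotb")) {
    expect_identical(a[[p]], b[[p]])
  }
})

test_that("profiler rejects charged and multi-component input", {
  expect_error(compute_properties(data.frame(smiles = "[NH4+]")), "charged")
  expect_error(compute_properties(data.frame(smiles = "CCO.CCO")),
               "multi-component")
})

test_that("racemate-aware properties equal single-enantiomer properties", {
  df <- data.frame(id = "a", smiles = "C[C@H](N)C(=O)O")
  rac <- racemate_properties(df)
  one <- compute_properties(df)
  expect_equal(rac[, c("mw", "clogp", "hbd", "hba", "tpsa", "rotb")],
               one[, c("mw", "clogp", "hbd", "hba", "tpsa", "rotb")])

  # feeding both enantiomers as two records changes no mean
  both <- data.frame(id = c("a", "b"),
                     smiles = c("C[C@H](N)C(=O)O", "C[C@@H](N)C(=O)O"))
  st <- library_statistics(both)
  expect_equal(st$mean[st$property == "mw"], one$mw)
  expect_equal(st$sd[st$property == "mw"], 0)
})

test_that("library statistics follow the sample convention and flag n = 1", {
  two <- compute_properties(data.frame(smiles = c("CCO", "CCCO")))
  st <- library_statistics(two)
  expect_true(attr(st, "sd_defined"))
  mwrow <- st[st$property == "mw", ]
  expect_equal(mwrow$mean, mean(two$mw))
  expect_equal(mwrow$sd, sd(two$mw)) # n - 1 convention
  expect_true(mwrow$min <= mwrow$mean && mwrow$mean <= mwrow$max)

  one <- library_statistics(data.frame(smiles = "CCO"))
  expect_false(attr(one, "sd_defined"))
  expect_equal(unique(one$sd), 0)
  expect_error(library_statistics(data.frame(smiles = character())), "empty")
})

test_that("adding a molecule above the max raises max and weakly raises mean", {
  base <- compute_properties(data.frame(smiles = c("CCO", "CCC", "CCN")))
  bigger <- compute_properties(data.frame(smiles = "COc1ccc(CCCC)cc1"))
  expect_gt(bigger$mw, max(base$mw))
  st0 <- library_statistics(base)
  st1 <- library_statistics(dplyr::bind_rows(base, bigger))
  expect_gt(st1$max[st1$property == "mw"], st0$max[st0$property == "mw"])
  expect_gte(st1$mean[st1$property == "mw"], st0$mean[st0$property == "mw"])
})
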