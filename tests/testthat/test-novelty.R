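# Scaffold filtering, embeddings and separation diagnostics.

test_that("scaffold queries hit exactly their own parent scaffolds", {
  parents <- data.frame(
    id = c("pyrrolidine", "piperidine", "cyclic_sulfone_6",
           "gem_difluorocyclohexane"),
    smiles = c("C1CCNC1", "C1CCNCC1", "O=S1(=O)CCCCC1", "FC1(F)CCCCC1"))
  flt <- scaffold_filter(parents, keep_all = TRUE)
  m <- as.matrix(flt[, paste0("matches_", parents$id)])
  expect_equal(unname(m), diag(4) == 1) # diagonal match matrix
})

test_that("motif filtering keeps matches with flags and drops the rest", {
  df <- data.frame(id = c("pip", "benzene"),
                   smiles = c("C1CCNCC1", "c1ccccc1"))
  flt <- scaffold_filter(df)
  expect_equal(flt$id, "pip")
  expect_equal(flt$motifs, "piperidine")
  expect_error(scaffold_filter(df, queries = c(bad = "[")), "invalid SMARTS")
})

test_that("every synthesized N-heterocycle matches pyrrolidine or piperidine", {
  syn <- synthesized_fixture()
  nhet <- syn[syn$scaffold %in% c("pyrrolidine", "piperidine"), ]
  expect_equal(nrow(nhet), 38L)
  flt <- scaffold_filter(nhet, keep_all = TRUE)
  expect_true(all(flt$matches_pyrrolidine | flt$matches_piperidine))
})

test_that("pca embedding is deterministic and respects symmetries", {
  # three mutually equidistant fingerprints: pairwise 2D distances equal
  fp <- rbind(a = c(1L, 0L, 0L, 0L), b = c(0L, 1L, 0L, 0L), c = c(0L, 0L, 1L, 0L))
  emb <- embed_2d(fp, method = "pca")
  d <- as.numeric(dist(as.matrix(emb$coords[, c("x", "y")])))
  expect_equal(max(d) - min(d), 0, tolerance = 1e-8)

  # duplicated fingerprints map onto identical coordinates
  fp2 <- rbind(fp, a2 = c(1L, 0L, 0L, 0L))
  emb2 <- embed_2d(fp2, method = "pca")
  expect_equal(unlist(emb2$coords[1, c("x", "y")]),
               unlist(emb2$coords[4, c("x", "y")]))

  # bit-identical reproduction across runs
  expect_identical(embed_2d(fp, method = "pca")$coords, emb$coords)
  expect_error(embed_2d(fp[1:2, ], method = "pca"), "at least 3")
})

test_that("umap embedding is reproducible for a fixed seed", {
  set.seed(99)
  fp <- matrix(rbinom(40 * 64, 1, 0.2), 40, 64)
  e1 <- embed_2d(fp, method = "umap", seed = 7, n_neighbors = 8)
  e2 <- embed_2d(fp, method = "umap", seed = 7, n_neighbors = 8)
  expect_equal(e1$coords, e2$coords, tolerance = 1e-6)
  expect_equal(e1$method, "umap")
  expect_equal(e1$seed, 7)
  expect_error(embed_2d(fp[1:5, ], method = "umap", n_neighbors = 8),
               "n_neighbors")
})

test_that("separation score behaves at its limit cases", {
  # two groups collapsed onto two distinct points: score -> 1
  coords <- tibble::tibble(x = c(0, 0, 10, 10), y = c(0, 0, 0, 0))
  expect_gt(separation_score(coords, c("a", "a", "b", "b")), 0.95)

  # one group an exact copy of the other: score <= 0
  coords2 <- tibble::tibble(x = c(0, 1, 0, 1), y = c(0, 0, 0, 0))
  expect_lte(separation_score(coords2, c("a", "a", "b", "b")), 0)

  expect_error(separation_score(coords, c("a", "a", "a", "b")), "degenerate")
})

test_that("random label permutations score near zero on average", {
  set.seed(606)
  coords <- tibble::tibble(x = runif(40), y = runif(40))
  scores <- vapply(seq_len(100), function(i) {
    separation_score(coords, sample(rep(c("a", "b"), each = 20)))
  }, numeric(1))
  expect_lt(abs(mean(scores)), 0.05)
})

test_that("well-separated fingerprint families split in the embedding", {
  # two disjoint-scaffold decoy families (seeded)
  fam1 <- generate_decoys(25, c(piperidine = 1), seed = 11)
  fam2 <- generate_decoys(25, c(gem_difluorocyclohexane = 1), seed = 12)
  fps <- morgan_fp_matrix(dplyr::bind_rows(fam1, fam2))
  rownames(fps) <- sprintf("d%d", 1:50)
  labels <- rep(c("pip", "dfc"), each = 25)
  emb_pca <- embed_2d(fps, method = "pca")
  expect_gt(separation_score(emb_pca, labels), 0)
  emb_umap <- embed_2d(fps, method = "umap", seed = 42, n_neighbors = 10)
  expect_gt(separation_score(emb_umap, labels), 0)
})
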