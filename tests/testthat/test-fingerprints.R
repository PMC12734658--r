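# Morgan fingerprints and Tanimoto similarity.

test_that("fingerprints are deterministic and canonicalization-invariant", {
  f1 <- morgan_fingerprint("OC(=O)C1CCNCC1")
  f2 <- morgan_fingerprint("C1CC(CCN1)C(O)=O") # same molecule, different writing
  expect_identical(as.integer(f1), as.integer(f2))
  expect_equal(length(f1), 2048L)
  expect_equal(attr(f1, "n_set"), sum(f1))
})

test_that("methane at radius 0 sets exactly one bit", {
  fp <- morgan_fingerprint("C", radius = 0)
  expect_equal(attr(fp, "n_set"), 1L)
})

test_that("enantiomer pairs share fingerprints unless chirality is folded in", {
  smis <- random_chiral_smiles(20, seed = 404)
  a <- morgan_fp_matrix(data.frame(smiles = smis))
  b <- morgan_fp_matrix(data.frame(smiles = invert_stereocenters(smis)))
  expect_identical(unname(a), unname(b))

  ac <- morgan_fp_matrix(data.frame(smiles = smis), use_chirality = TRUE)
  bc <- morgan_fp_matrix(data.frame(smiles = invert_stereocenters(smis)),
                         use_chirality = TRUE)
  expect_false(identical(unname(ac), unname(bc)))
})

test_that("invalid fingerprint parameters error", {
  expect_error(morgan_fp_matrix(data.frame(smiles = "C"), n_bits = 0), "n_bits")
  expect_error(tanimoto(c(1L, 0L), c(1L, 0L, 1L)), "mismatch")
})

test_that("tanimoto reproduces the set-overlap arithmetic", {
  a <- c(1L, 1L, 1L, 0L); b <- c(1L, 1L, 0L, 1L)
  expect_equal(tanimoto(a, b), 0.5) # |A^B| = 2, |AvB| = 4
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(c(1L, 0L), c(0L, 1L)), 0)
  expect_equal(tanimoto(integer(4), integer(4)), 1) # empty-empty convention
})

test_that("tanimoto invariants hold on 10,000 random fingerprint pairs", {
  set.seed(505)
  n <- 10000L; len <- 64L
  A <- matrix(rbinom(n * len, 1, 0.2), n, len)
  B <- matrix(rbinom(n * len, 1, 0.2), n, len)
  sim_ab <- vapply(seq_len(n), function(i) tanimoto(A[i, ], B[i, ]), numeric(1))
  sim_ba <- vapply(seq_len(n), function(i) tanimoto(B[i, ], A[i, ]), numeric(1))
  expect_equal(sim_ab, sim_ba)                    # symmetry
  expect_true(all(sim_ab >= 0 & sim_ab <= 1))     # bounds
  ident <- rowSums(A != B) == 0
  expect_equal(sim_ab == 1, ident)                # identity iff equal sets
})

test_that("nearest-neighbour report finds exact maxima", {
  q <- morgan_fp_matrix(data.frame(id = "q1", smiles = "OC(=O)C1CCNCC1"))
  refs <- morgan_fp_matrix(data.frame(
    id = c("r1", "r2", "r3"),
    smiles = c("OC(=O)C1CCNCC1", "c1ccccc1", "CCO")))
  rep <- nearest_neighbor_report(q, refs)
  expect_equal(rep$nearest_id, "r1")   # query present in references
  expect_equal(rep$max_tanimoto, 1)
  expect_equal(rep$novelty, 0)

  # single fully disjoint reference (constructed bit patterns)
  q2 <- matrix(c(1L, 1L, 0L, 0L), 1, dimnames = list("q", NULL))
  r2 <- matrix(c(0L, 0L, 1L, 1L), 1, dimnames = list("r", NULL))
  rep2 <- nearest_neighbor_report(q2, r2)
  expect_equal(rep2$novelty, 1)

  expect_error(nearest_neighbor_report(q, q[0, , drop = FALSE]), "empty")
})
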