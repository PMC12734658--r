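# Shared fixtures: all generated in code, nothing stored on disk.

# memoized design library (enumeration is deterministic; avoid re-running
# OpenBabel for every test file)
.fixture_env <- new.env(parent = emptyenv())

design_library_fixture <- function() {
  if (is.null(.fixture_env$lib)) {
    .fixture_env$lib <- enumerate_designs(default_design_config())
  }
  .fixture_env$lib
}

synthesized_fixture <- function() {
  lib <- design_library_fixture()
  out <- lib[lib$status == "synthesized", ]
  out$id <- out$frag_id
  out
}

# Random chiral SMILES: one tetrahedral centre bearing three distinct heavy
# substituents plus H, so every draw is a genuine stereocentre.
random_chiral_smiles <- function(n, seed) {
  pool <- c("F", "Cl", "C", "CC", "O", "N", "OC", "CO",
            "C(=O)O", "C(N)=O", "C#N", "c1ccccc1", "C1CCCC1")
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    subs <- sample(pool, 3)
    descr <- sample(c("@", "@@"), 1)
    sprintf("[C%sH](%s)(%s)%s", descr, subs[1], subs[2], subs[3])
  }, character(1))
}

# Two-substituent saturated-ring templates used for stereochemistry tests:
# ring walk starts at the head-bearing carbon, aryl-bearing carbon second.
stereo_template_smiles <- function(pattern, a, b,
                                   head = "C(=O)O", aryl = "c2ccc(OC)cc2") {
  rest <- switch(pattern,
    "pyrrolidine_23" = "CCN1",
    "piperidine_43" = "CNCC1",
    stop("unknown pattern"))
  sprintf("[C%sH]1(%s)[C%sH](%s)%s", a, head, b, aryl, rest)
}

# 10-molecule descriptor reference panel with frozen oracle values.
# Expected numbers were computed once with an independent descriptor
# implementation (RDKit 2024.09: MolWt, Crippen MolLogP, Lipinski donor/
# acceptor counts, Ertl TPSA with S/P terms, strict rotatable-bond count)
# and hand-checked for the count descriptors; they are frozen here and the
# package implementation is required to reproduce them.
descriptor_panel <- function() {
  tibble::tribble(
    ~id, ~smiles, ~mw, ~clogp, ~hbd, ~hba, ~tpsa, ~rotb,
    "ethanol", "CCO", 46.069, -0.0014, 1L, 1L, 20.23, 0L,
    "benzene", "c1ccccc1", 78.114, 1.6866, 0L, 0L, 0.00, 0L,
    "piperidine-4-carboxylic acid", "OC(=O)C1CCNCC1", 129.159, 0.0706, 2L, 2L, 49.33, 1L,
    "paracetamol", "CC(=O)Nc1ccc(O)cc1", 151.165, 1.3506, 2L, 2L, 49.33, 1L,
    "PMP piperidine acid", "COc1ccc(cc1)C1CCNCC1C(=O)O", 235.283, 1.4729, 2L, 3L, 58.56, 3L,
    "prolinamide", "NC(=O)C1CCCN1", 114.148, -0.7763, 2L, 2L, 55.12, 1L,
    "3-piperidinylmethanol", "OCC1CCCNC1", 115.176, -0.0217, 2L, 2L, 32.26, 1L,
    "piperidine-4-carbonitrile", "N#CC1CCNCC1", 110.160, 0.5096, 1L, 2L, 35.82, 0L,
    "thiane 1,1-dioxide", "O=S1(=O)CCCCC1", 134.200, 0.5851, 0L, 2L, 42.52, 0L,
    "1,1-difluorocyclohexane", "FC1(F)CCCCC1", 120.142, 2.5858, 0L, 0L, 0.00, 0L
  )
}

write_temp_smi <- function(data, ...) {
  tf <- tempfile(fileext = ".smi")
  write_smiles_table(data, tf)
  tf
}
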