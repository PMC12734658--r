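#' Canonicalize SMILES strings
#'
#' Converts SMILES to canonical isomeric SMILES (OpenBabel dialect). Canonical
#' strings are dialect-dependent; [toolkit_metadata()] records the back end so
#' that stored canonical SMILES can be interpreted later.
#'
#' @param smiles character vector of SMILES.
#' @param strict if `TRUE` (default) unparseable SMILES raise an error naming
#'   the offending position where the lexer can locate it; if `FALSE` they
#'   yield `NA`.
#' @return character vector of canonical isomeric SMILES.
#' @examples
#' canonical_smiles("OCC")
#' @export
canonical_smiles <- function(smiles, strict = TRUE) {
  if (length(smiles) == 0L) return(character())
  if (strict) {
    for (s in smiles) lex_smiles(s) # syntactic validation with positions
  }
  out <- ob_canonical(smiles)
  if (strict && anyNA(out)) {
    bad <- smiles[which(is.na(out))[1]]
    abort(sprintf("SMILES could not be parsed by the chemistry back end: '%s'", bad),
          class = "fragmatrix_parse_error")
  }
  trimws(out)
}

#' Parse a table of SMILES into validated molecules
#'
#' The entry point of the molecule layer: takes a data frame with a SMILES
#' column, validates and canonicalizes every structure, and (optionally)
#' strips salt/counterion components, keeping the largest covalently connected
#' organic component. Fragments are typically isolated as HCl/HI salts but
#' profiled as neutral parents, so stripping is on by default.
#'
#' @param data data frame with at least a `smiles` column; an `id` column is
#'   carried through (one is generated when absent).
#' @param smiles,id tidy-select columns holding SMILES and identifiers.
#' @param strip_salts drop all but the largest organic component.
#' @return tibble with columns `id`, `smiles_input`, `smiles` (canonical
#'   isomeric SMILES of the parent), `n_heavy_atoms`, `stripped` (logical).
#' @examples
#' mol_parse(data.frame(smiles = "OC(=O)C1CCNCC1.Cl"))
#' @export
mol_parse <- function(data, smiles = "smiles", id = "id", strip_salts = TRUE) {
  stopifnot(is.data.frame(data))
  if (!smiles %in% names(data)) {
    abort(sprintf("column '%s' not found in `data`", smiles))
  }
  smi <- as.character(data[[smiles]])
  ids <- if (id %in% names(data)) as.character(data[[id]]) else sprintf("mol%d", seq_along(smi))
  parsed <- vapply(smi, parse_one_structure, character(1), strip_salts = strip_salts,
                   USE.NAMES = FALSE)
  stripped <- vapply(smi, function(s) length(smiles_components(s)) > 1L, logical(1),
                     USE.NAMES = FALSE) & strip_salts
  tibble(
    id = ids,
    smiles_input = smi,
    smiles = parsed,
    n_heavy_atoms = vapply(parsed, count_heavy_atoms, integer(1), USE.NAMES = FALSE),
    stripped = stripped
  )
}

# Parse one SMILES, optionally keeping only the largest organic component.
parse_one_structure <- function(smiles, strip_salts = TRUE) {
  lex_smiles(smiles) # lexical validation (reports token position)
  comps <- smiles_components(smiles)
  if (length(comps) > 1L && strip_salts) {
    has_c <- vapply(comps, function(s) {
      any(toupper(lex_smiles(s)$symbol) == "C")
    }, logical(1))
    pool <- if (any(has_c)) comps[has_c] else comps
    if (!any(has_c)) {
      abort(sprintf("no organic component left after salt stripping: '%s'", smiles),
            class = "fragmatrix_degenerate_input")
    }
    sizes <- vapply(pool, count_heavy_atoms, integer(1))
    smiles <- pool[which.max(sizes)]
  } else if (length(comps) > 1L) {
    abort(sprintf("multi-component SMILES '%s' (set strip_salts = TRUE to keep the parent)",
                  smiles))
  }
  canonical_smiles(smiles)
}

#' Invert all defined tetrahedral stereocentres
#'
#' Returns the enantiomer of each input: every explicit tetrahedral
#' stereodescriptor is flipped (`@` to `@@` and vice versa); double-bond
#' geometry and the molecular graph are untouched, as reflection preserves
#' them. Achiral inputs are returned unchanged (up to canonicalization);
#' undefined stereocentres are left undefined. Applying the function twice
#' recovers the starting canonical SMILES.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical isomeric SMILES of the enantiomers.
#' @examples
#' invert_stereocenters("C[C@H](N)C(=O)O")
#' @export
invert_stereocenters <- function(smiles) {
  can <- canonical_smiles(smiles)
  canonical_smiles(vapply(can, swap_tetrahedral_descriptors, character(1),
                          USE.NAMES = FALSE))
}

#' Racemate-level identity key
#'
#' A racemic sample of a chiral molecule is one chemical entity but has two
#' enantiomeric SMILES. The racemate key is the lexicographically smaller of
#' the canonical SMILES of the molecule and of its enantiomer, so both members
#' of an enantiomeric pair map to the same key, while diastereomers keep
#' distinct keys. Achiral molecules map to their own canonical SMILES.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of racemate keys.
#' @export
racemate_key <- function(smiles) {
  can <- canonical_smiles(smiles)
  inv <- invert_stereocenters(can)
  pmin(can, inv)
}

#' Classify the relative configuration of vicinal ring substituents
#'
#' For molecules carrying exactly two defined tetrahedral stereocentres on
#' adjacent atoms of one saturated ring, each bearing exactly one non-ring,
#' non-hydrogen substituent, classifies the pair as `cis` (substituents on the
#' same ring face) or `trans`. Any molecule violating those preconditions is
#' reported as `not_applicable` together with its stereocentre counts.
#'
#' The classification embeds a 3D conformer (OpenBabel) and applies a
#' local-normal same-face test: at each stereocentre the two adjacent ring
#' bonds define a local ring normal (their cross product, oriented by a common
#' ring traversal), and the sign of the projection of the exocyclic substituent
#' onto that normal gives the face. Equal signs mean `cis`. The local normal
#' follows ring puckering, which makes the test robust on chair conformers
#' where a global ring-plane fit is not.
#'
#' @param smiles character vector of SMILES.
#' @return tibble with one row per input: `smiles`, `n_defined_centers`,
#'   `n_undefined_centers`, `relative_config` (`"cis"`, `"trans"` or
#'   `"not_applicable"`).
#' @examples
#' classify_relative_config("[C@H]1(C(=O)O)[C@@H](c2ccccc2)CCN1")
#' @export
classify_relative_config <- function(smiles) {
  can <- canonical_smiles(smiles)
  res <- lapply(can, classify_one_relative_config)
  dplyr::bind_rows(res)
}

#' Stereochemistry summary columns for a molecule table
#'
#' Data-frame-first wrapper around [classify_relative_config()]: appends
#' `n_defined_centers`, `n_undefined_centers` and `relative_config` columns.
#'
#' @inheritParams mol_parse
#' @return the input tibble with three stereochemistry columns appended.
#' @export
stereo_summary <- function(data, smiles = "smiles") {
  stopifnot(is.data.frame(data), smiles %in% names(data))
  cls <- classify_relative_config(data[[smiles]])
  bind_cols(as_tibble(data), cls[, c("n_defined_centers", "n_undefined_centers",
                                     "relative_config")])
}

classify_one_relative_config <- function(can) {
  g0 <- mol_graph(can, gen3d = FALSE)
  defined <- which(nzchar(g0$atoms$stereo))
  n_def <- length(defined)
  pot <- potential_stereocenters(g0)
  n_undef <- length(setdiff(pot, defined))
  nope <- function() tibble(smiles = can, n_defined_centers = n_def,
                            n_undefined_centers = n_undef,
                            relative_config = "not_applicable")
  if (n_def != 2L) return(nope())
  a <- defined[1]; b <- defined[2]
  bonds <- g0$bonds
  k <- which((bonds$a == a & bonds$b == b) | (bonds$a == b & bonds$b == a))
  if (length(k) == 0L || !bonds$in_ring[k[1]] || bonds$aromatic[k[1]]) return(nope())
  ring <- ring_through_bond(g0, a, b)
  if (is.null(ring)) return(nope())
  adj <- molgraph_adjacency(g0)
  subs <- lapply(c(a, b), function(ctr) setdiff(adj[[ctr]]$nbr, ring))
  if (any(lengths(subs) != 1L)) return(nope())

  g3 <- mol_graph(can, gen3d = TRUE)
  coords <- as.matrix(g3$atoms[, c("x", "y", "z")])
  m <- length(ring)
  face_sign <- vapply(seq_along(c(a, b)), function(j) {
    ctr <- c(a, b)[j]
    k0 <- match(ctr, ring)
    prv <- ring[((k0 - 2) %% m) + 1]
    nxt <- ring[(k0 %% m) + 1]
    nrm <- cross3(coords[nxt, ] - coords[ctr, ], coords[prv, ] - coords[ctr, ])
    sign(sum(nrm * (coords[subs[[j]], ] - coords[ctr, ])))
  }, numeric(1))
  if (any(face_sign == 0)) return(nope())
  tibble(smiles = can, n_defined_centers = n_def, n_undefined_centers = n_undef,
         relative_config = if (face_sign[1] == face_sign[2]) "cis" else "trans")
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Back-end metadata for reproducibility records
#'
#' Canonical SMILES strings and aromaticity perception are toolkit-dependent;
#' every serialized result should carry this record.
#'
#' @return named list with the package and chemistry back-end versions.
#' @export
toolkit_metadata <- function() {
  list(
    package = sprintf("fragmatrix %s", as.character(utils::packageVersion("fragmatrix"))),
    chemistry_backend = toolkit_version()
  )
}
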