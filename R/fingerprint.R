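# Morgan (circular/ECFP-style) fingerprints.
#
# Implemented directly on the molecular graph: each atom starts from a tuple
# of constitutional invariants, identifiers are iteratively rehashed over
# sorted (bond order, neighbour identifier) lists for `radius` rounds, and
# every identifier generated at every round is folded into a fixed-length bit
# vector. Chirality is excluded from the invariants by default so that the
# two enantiomers of a racemate share a fingerprint (racemate screening);
# an optional flag folds tetrahedral parity in.

# deterministic 31-bit string/integer hash (polynomial, exact in doubles)
MORGAN_MOD <- 2147483647
hash_ints <- function(ints) {
  h <- 17
  for (x in ints) h <- (h * 31 + (x %% MORGAN_MOD)) %% MORGAN_MOD
  h
}

#' Morgan fingerprint of a single molecule
#'
#' @param smiles one SMILES string.
#' @param radius circular environment radius (2 is the ECFP4-equivalent
#'   community default).
#' @param n_bits folded fingerprint length (2048 by default).
#' @param use_chirality include tetrahedral parity in the atom invariants;
#'   `FALSE` by default so enantiomers coincide.
#' @return integer vector of 0/1 of length `n_bits`, with attributes `radius`,
#'   `n_bits` and `n_set` (population count).
#' @examples
#' fp <- morgan_fingerprint("c1ccccc1")
#' attr(fp, "n_set")
#' @export
morgan_fingerprint <- function(smiles, radius = 2L, n_bits = 2048L,
                               use_chirality = FALSE) {
  m <- morgan_fp_matrix(tibble(id = "x", smiles = smiles),
                        radius = radius, n_bits = n_bits,
                        use_chirality = use_chirality)
  fp <- as.integer(m[1, ])
  attr(fp, "radius") <- radius
  attr(fp, "n_bits") <- n_bits
  attr(fp, "n_set") <- sum(fp)
  fp
}

#' Morgan fingerprint matrix for a molecule table
#'
#' @param data data frame with SMILES (and optionally id) columns.
#' @param smiles,id column names.
#' @inheritParams morgan_fingerprint
#' @return integer 0/1 matrix, one row per molecule (rownames = ids), with
#'   attributes `radius` and `use_chirality`.
#' @export
morgan_fp_matrix <- function(data, smiles = "smiles", id = "id",
                             radius = 2L, n_bits = 2048L,
                             use_chirality = FALSE) {
  stopifnot(is.data.frame(data), smiles %in% names(data))
  if (n_bits <= 0L) abort("n_bits must be positive")
  if (radius < 0L) abort("radius must be non-negative")
  smi <- as.character(data[[smiles]])
  ids <- if (id %in% names(data)) as.character(data[[id]]) else sprintf("m%d", seq_along(smi))
  can <- canonical_smiles(smi)
  graphs <- mol_graphs(can)
  out <- matrix(0L, nrow = length(smi), ncol = n_bits,
                dimnames = list(ids, NULL))
  for (i in seq_along(graphs)) {
    bits <- morgan_bits(graphs[[i]], radius = radius, n_bits = n_bits,
                        use_chirality = use_chirality)
    out[i, bits + 1L] <- 1L
  }
  attr(out, "radius") <- radius
  attr(out, "use_chirality") <- use_chirality
  out
}

ELEMENT_Z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
               S = 16, Cl = 17, As = 33, Se = 34, Br = 35, Te = 52, I = 53)

morgan_bits <- function(graph, radius, n_bits, use_chirality = FALSE) {
  atoms <- graph$atoms
  adj <- molgraph_adjacency(graph)
  n <- nrow(atoms)
  z <- ELEMENT_Z[atoms$elem]
  z[is.na(z)] <- 0
  parity <- if (use_chirality) match(atoms$stereo, c("", "@", "@@")) else rep(1L, n)
  ids <- vapply(seq_len(n), function(i) {
    hash_ints(c(z[i], atoms$degree[i], atoms$nh[i], atoms$charge[i] + 10,
                as.integer(atoms$aromatic[i]), as.integer(atoms$in_ring[i]),
                parity[i]))
  }, numeric(1))
  all_ids <- ids
  if (radius > 0L) {
    for (r in seq_len(radius)) {
      new_ids <- vapply(seq_len(n), function(i) {
        nb <- adj[[i]]
        if (length(nb$nbr) == 0L) return(hash_ints(c(r, ids[i])))
        pairs <- cbind(nb$order, ids[nb$nbr])
        ord <- order(pairs[, 1], pairs[, 2])
        hash_ints(c(r, ids[i], t(pairs[ord, , drop = FALSE])))
      }, numeric(1))
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  unique(as.integer(all_ids %% n_bits))
}

#' Tanimoto similarity between two bit fingerprints
#'
#' `|A intersect B| / |A union B|`; defined as 1 when both fingerprints are
#' empty (documented convention: two featureless molecules are treated as
#' maximally similar rather than undefined).
#'
#' @param a,b equal-length 0/1 integer vectors.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    abort(sprintf("fingerprint length mismatch: %d vs %d", length(a), length(b)))
  }
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(1)
  inter / uni
}

# all-pairs Tanimoto between the rows of two fingerprint matrices
tanimoto_cross <- function(A, B) {
  if (ncol(A) != ncol(B)) abort("fingerprint length mismatch between sets")
  An <- rowSums(A)
  Bn <- rowSums(B)
  inter <- A %*% t(B)
  uni <- outer(An, Bn, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / uni)
  sim
}

#' Nearest-neighbour novelty report
#'
#' For every query fingerprint, the exact maximum Tanimoto similarity over a
#' reference set (brute force -- exact at these library sizes), the identity
#' of the nearest reference, and novelty = 1 - max similarity.
#'
#' @param queries,references fingerprint matrices from [morgan_fp_matrix()]
#'   (rownames are molecule ids).
#' @return tibble with `id`, `nearest_id`, `max_tanimoto`, `novelty`.
#' @export
nearest_neighbor_report <- function(queries, references) {
  if (is.null(dim(queries)) || nrow(queries) == 0L) abort("empty query set")
  if (is.null(dim(references)) || nrow(references) == 0L) abort("empty reference set")
  sim <- tanimoto_cross(queries, references)
  best <- max.col(sim, ties.method = "first")
  tibble(
    id = rownames(queries) %||% sprintf("q%d", seq_len(nrow(queries))),
    nearest_id = (rownames(references) %||% sprintf("r%d", seq_len(nrow(references))))[best],
    max_tanimoto = sim[cbind(seq_len(nrow(sim)), best)],
    novelty = 1 - sim[cbind(seq_len(nrow(sim)), best)]
  )
}
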