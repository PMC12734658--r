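# Seeded decoy-library generator.
#
# Stands in for commercial fragment collections in tests and benchmarks:
# drug-like small decorated ring systems, a configurable fraction of which
# contain each of the four central motifs of the collection. Generation is
# template-based (scaffold + substituent grafting onto CH ring positions), so
# every output is valence-valid by construction -- no rejection loop.

# scaffold templates: ring SMILES written with substitution sites as "%s"
# (each site replaces one ring H). Sites sit on carbons only.
DECOY_MOTIF_TEMPLATES <- list(
  pyrrolidine = "C1%sCC%sCN1",
  piperidine = "C1%sCC%sCCN1",
  cyclic_sulfone_6 = "C1%sCC%sCS(=O)(=O)C1",
  gem_difluorocyclohexane = "C1%sCC%sCC(F)(F)C1"
)
DECOY_NEUTRAL_TEMPLATES <- list(
  cyclohexane = "C1%sCC%sCCC1",
  cyclopentane = "C1%sCC%sCC1",
  tetrahydrofuran = "C1%sCC%sCO1",
  tetrahydropyran = "C1%sCC%sCCO1",
  morpholine = "C1%sC%sNCCO1",
  benzene = "c1%scc%sccc1",
  pyridine = "c1%scc%scnc1"
)

DECOY_SUBSTITUENTS <- c(
  none = "", fluoro = "(F)", chloro = "(Cl)", methyl = "(C)",
  methoxy = "(OC)", hydroxyl = "(O)", amide = "(C(N)=O)",
  nitrile = "(C#N)", phenyl = "(c2ccccc2)"
)
# aromatic sites cannot carry two substituents on one atom; templates above
# always place sites on distinct ring atoms, so any pool entry is graftable.

#' Generate a seeded decoy fragment library
#'
#' Draws `n` small decorated ring systems. Each decoy receives a scaffold --
#' one of the four central motifs with the configured probability, otherwise a
#' neutral ring from a drug-like pool -- and 0-2 substituents drawn from a
#' pool of common groups grafted onto ring carbons. Motif assignment is
#' exclusive (one motif per decoy), so the motif fractions must sum to at
#' most 1. Identical spec + seed reproduce the identical SMILES list.
#'
#' @param n number of decoys.
#' @param motif_fractions named fractions for
#'   `pyrrolidine`, `piperidine`, `cyclic_sulfone_6`,
#'   `gem_difluorocyclohexane` (missing names default to 0).
#' @param substituents named SMILES branch pool (defaults to halogen, methyl,
#'   methoxy, hydroxyl, amide, nitrile, phenyl, or no substituent).
#' @param seed integer seed; generation is deterministic given (spec, seed).
#' @return tibble with `id`, `smiles` (canonical), `scaffold` (the planted
#'   scaffold label).
#' @examples
#' generate_decoys(5, c(piperidine = 0.5), seed = 1)
#' @export
generate_decoys <- function(n, motif_fractions = c(),
                            substituents = DECOY_SUBSTITUENTS, seed = 42L) {
  stopifnot(is.numeric(n), n >= 0)
  fr <- setNames(rep(0, length(DECOY_MOTIF_TEMPLATES)), names(DECOY_MOTIF_TEMPLATES))
  if (length(motif_fractions)) {
    unknown <- setdiff(names(motif_fractions), names(fr))
    if (length(unknown)) {
      abort(sprintf("unknown motif name(s): %s", paste(unknown, collapse = ", ")))
    }
    fr[names(motif_fractions)] <- motif_fractions
  }
  if (any(fr < 0) || any(fr > 1)) abort("motif fractions must lie in [0, 1]")
  if (sum(fr) > 1) {
    abort(sprintf("infeasible spec: exclusive motif fractions sum to %.3f > 1", sum(fr)))
  }
  if (n == 0) {
    return(tibble(id = character(), smiles = character(), scaffold = character()))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  probs <- c(fr, other = 1 - sum(fr))
  scaffold <- sample(names(probs), n, replace = TRUE, prob = probs)
  neutral <- sample(names(DECOY_NEUTRAL_TEMPLATES), n, replace = TRUE)
  smi <- vapply(seq_len(n), function(i) {
    tmpl <- if (scaffold[i] == "other") DECOY_NEUTRAL_TEMPLATES[[neutral[i]]]
            else DECOY_MOTIF_TEMPLATES[[scaffold[i]]]
    subs <- sample(substituents, 2, replace = TRUE)
    # bias towards light decoration: drop each substituent with prob 1/3
    subs[stats::runif(2) < 1/3] <- ""
    sprintf(tmpl, subs[1], subs[2])
  }, character(1))
  tibble(
    id = sprintf("DECOY%d", seq_len(n)),
    smiles = canonical_smiles(smi),
    scaffold = ifelse(scaffold == "other", paste0("other_", neutral), scaffold)
  )
}
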