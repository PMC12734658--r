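---
title: "Designing and analysing stereodefined heterocyclic fragment collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing stereodefined heterocyclic fragment collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragmatrix)
```

## The problem this package addresses

Fragment-based drug discovery screens very small molecules (typically under
300 Da) and grows the best binders into leads. The quality of that process
depends on the screening library: fragments should sit inside the Rule-of-3
physicochemical envelope (MW < 300 g/mol, cLogP < 3, hydrogen-bond donors and
acceptors < 3, with the customary extensions TPSA ≤ 60 Å² and ≤ 3 rotatable
bonds), and they should populate three-dimensional chemical space with
well-defined exit vectors — the bond directions along which a bound fragment
can later be elaborated.

Saturated nitrogen heterocycles are a particularly attractive chassis:
pyrrolidines and piperidines are ubiquitous in approved drugs, a free ring
N–H is a reliable binding element, and placing an aryl group *vicinal* to a
polar head group on the ring creates pairs of exit vectors whose geometry is
switched by the relative configuration (*cis* or *trans*) of the two
substituents and by the substitution pattern (2,3-, 3,4- or
4,3-disubstitution, counted from the ring heteroatom).

`fragmatrix` implements the computational side of building and analysing such
a collection:

1. **Enumeration** — expand a declarative design matrix (scaffold ×
   substitution pattern × relative configuration × aryl group × polar head
   group) into stereochemically explicit structures with synthesis-status
   bookkeeping.
2. **Profiling** — racemate-aware computation of the six fragment
   descriptors, library statistics, and normalization against Rule-of-3
   limits (the radar-plot profile).
3. **Novelty analysis** — motif-based extraction of comparator libraries,
   2048-bit Morgan fingerprints, exact Tanimoto nearest-neighbour novelty,
   seeded 2D embedding (UMAP or PCA) and silhouette separation scores.

The packaged configuration (`default_design_config()`) transcribes a
51-member design matrix over four scaffold families — pyrrolidine,
piperidine, six-membered cyclic sulfone and *gem*-difluorocyclohexane — of
which 44 designs were synthesized, 38 of them N-heterocycles, plus 2
commercially available designs and 5 that resisted preparation.

## The design matrix and its expansion

Each series block in the YAML configuration fixes a scaffold and a
substitution pattern, and lists the allowed aryl groups (4-methoxyphenyl,
4-fluorophenyl), polar head groups (carboxylic acid, primary amide, primary
alcohol, nitrile) and relative configurations. The expansion order is
head → configuration → aryl, and the configured fragment IDs are assigned to
that order; the numbering is editorial input, not derived, so the enumerator
validates counts rather than inventing an ordering. Per-head restrictions
(`head_configs`) express irregular corners of the matrix, such as nitriles
existing only as *cis* diastereomers in the 4,3-piperidine series.

```{r enumerate, eval = FALSE}
lib <- enumerate_designs(default_design_config())
tally_designs(lib)$summary
```

Ring position 1 is the anchor atom (N, sulfonyl S, or the CF2 carbon);
every template writes the ring walk starting from the head-bearing carbon
with the aryl-bearing carbon second, so the two stereocentres appear
adjacently in the SMILES: `[CaH]1(head)[CbH](aryl)…1`. Under that writing
convention, *opposite* tetrahedral descriptors (`@`/`@@`) produce the *cis*
diastereomer and *equal* descriptors the *trans*, uniformly across all seven
ring templates. This was established against an independent
three-dimensional conformer oracle and is re-verified by the test suite,
which round-trips every enumerated design through the package's own
classifier.

## Stereochemistry model

**Racemates.** The collection is prepared racemic, so a racemic design is one
chemical entity with two enantiomeric SMILES. `racemate_key()` maps both
enantiomers to the lexicographically smaller of the two canonical SMILES;
enumeration materializes that key-minimal enantiomer and deduplicates on the
key. Diastereomers keep distinct keys.

**Enantiomer generation.** `invert_stereocenters()` flips every explicit
tetrahedral descriptor (`@` ↔ `@@`) and re-canonicalizes. Reflection
preserves double-bond geometry, so *cis*/*trans* alkene markers are left
untouched. Undefined stereocentres are left undefined and reported in
`stereo_summary()` — the package never guesses intent for molecules with
one or three defined centres; it inverts whatever is defined and flags the
counts.

**Relative configuration.** `classify_relative_config()` applies a 3D
same-face test: embed one conformer (OpenBabel `gen3d`), locate the smallest
ring through the bond joining the two defined stereocentres, and compute at
each centre a *local* ring normal as the cross product of its two adjacent
ring bonds, oriented by a common ring traversal. The sign of the projection
of the exocyclic substituent onto that normal gives the face; equal signs
mean *cis*. The local normal follows ring puckering, which matters: a global
best-fit ring plane misclassifies chair conformers whose substituents sit
equatorially (nearly in-plane), while the local test is stable across
conformers and seeds. Preconditions (exactly two defined centres, adjacent
on one non-aromatic ring, one exocyclic heavy substituent each) are checked
on the molecular graph; violations return `not_applicable` with the centre
counts rather than an arbitrary label.

Potential-but-undefined stereocentres are detected by symmetry-class
refinement (Weisfeiler–Lehman colouring of the heavy-atom graph): an sp³
carbon with at most one hydrogen whose neighbour branches carry pairwise
distinct colours. Dependent ("para") stereocentres and ring-stereo edge
cases are outside this definition and documented as such; they do not occur
in the chemical space this package targets.

## Descriptors and their conventions

The six descriptors are deliberately pinned to explicit conventions, since
"HBD/HBA/rotatable bonds" mean different things to different tools:

* **MW** — sum of standard atomic weights (implicit hydrogens included).
* **cLogP** — Wildman–Crippen atom-contribution logP, implemented in the
  package from the published atom-type table. Atom typing is first-match-wins
  over ~70 published types; the implementation reproduces an independent
  reference implementation to better than 0.01 log units across the
  reference panel, the full 51-design matrix and generated decoy sets.
* **HBD** — N or O atoms bearing at least one hydrogen.
* **HBA** — two selectable conventions. The default (`"pattern"`) mirrors
  the acceptor definition of common fragment tooling: N and O acceptors
  excluding amide/sulfonamide nitrogens and acidic hydroxyls. The plain
  Lipinski count of all N + O atoms is available as `hba_rule = "n_o_count"`.
  The distinction is not cosmetic: under the plain N+O count the mean
  acceptor count of the synthesized set is 3.16 (normalized 1.05, outside
  the Ro3 envelope), while the pattern-based count gives 2.55 (normalized
  0.85, inside). The radar-profile claim that the library sits wholly inside
  the Ro3 polygon is reproducible only under the pattern convention, which
  is what the tool chain that produced that claim uses — hence the default.
* **TPSA** — Ertl fragment-contribution topological polar surface area,
  including the sulfur/phosphorus terms of the original parameterization
  (the cyclic sulfones would otherwise lose their SO2 contribution).
* **RotB** — non-ring single bonds between non-terminal heavy atoms,
  excluding amide C–N bonds and bonds involving triple-bonded atoms.

**Racemate-aware profiling.** `racemate_properties()` computes each
descriptor for the molecule and its generated enantiomer and averages the
two. All six descriptors are constitutional, so the average equals the
single-enantiomer value exactly; the function asserts that equality at run
time as a self-check rather than silently assuming it. Whether the
averaging happens at the molecule level or the library level is
mathematically immaterial for these descriptors; the self-check records
the fact.

**Compliance semantics.** Rule-of-3 compliance uses the strict `<` of the
rule's definition; a value exactly at a limit is non-compliant and reported
separately (`*_at_limit` flags). Normalization divides library means by the
limits, so the unit polygon is the Ro3 boundary. Note that the library
*mean* sitting inside the envelope does not imply every member complies:
in the packaged collection the per-molecule all-six compliance fraction is
about 0.41, driven mostly by TPSA and rotatable-bond values at or above the
extension limits.

Profiling operates on neutral single-component parents only; the fragments
are isolated as HCl/HI salts, so `mol_parse(strip_salts = TRUE)` keeps the
largest organic component before profiling, and charged or multi-component
input to the profiler is an error rather than a silent normalization.

## Fingerprints, novelty and embeddings

**Morgan fingerprints** are implemented on the package's molecular graph:
atom identifiers start from constitutional invariants (element, heavy
degree, hydrogen count, charge, aromaticity, ring membership), are
iteratively rehashed over sorted (bond order, neighbour identifier) lists
for `radius` rounds (default 2, the ECFP4-equivalent community default),
and every identifier from every round is folded into `n_bits` (default
2048). Chirality is excluded from the invariants by default so enantiomer
pairs coincide — consistent with racemate screening — and can be folded in
with `use_chirality = TRUE`. The fingerprint radius is a convention choice;
it is recorded on the fingerprint matrix and in embedding metadata.

**Tanimoto / novelty.** `nearest_neighbor_report()` computes the exact
maximum Tanimoto similarity of each query against a reference set by brute
force (a single matrix product at these library sizes; no approximate
index) and reports novelty = 1 − max similarity. Tanimoto of two empty
fingerprints is defined as 1, a documented convention for featureless
inputs.

**Embedding.** `embed_2d()` offers UMAP (on the pairwise Jaccard distances
of the bit vectors, single-threaded, seeded; defaults n_neighbors = 15,
min_dist = 0.1, seed = 42) and PCA (centred bit matrix, first two
components, sign fixed by the largest-magnitude loading, bit-reproducible).
UMAP coordinates are reproducible for a fixed seed and environment up to the
method's rotation/reflection freedom; PCA is the deterministic method the
test suite relies on. Exact embedding geometry is explicitly *not* a
reproduction target — the upstream hyperparameters behind any particular
published map are unknowable — so all embedding claims are property-based:
`separation_score()` (mean silhouette over the 2D coordinates) must be
positive for the synthesized-vs-comparator labelling, and is near zero under
random label permutations.

## The decoy generator

`generate_decoys()` emulates the *statistical shape* of a commercial
fragment collection for benchmarking: small decorated ring systems in which
a configured fraction contains each of the four central motifs (assigned
exclusively, so fractions must sum to ≤ 1), with the remainder drawn from a
drug-like neutral-ring pool (cyclohexane, cyclopentane, THF, THP,
morpholine, benzene, pyridine). Decoration grafts 0–2 substituents from a
pool of common groups (halogen, methyl, methoxy, hydroxyl, amide, nitrile,
phenyl) onto distinct ring carbons. Template-based assembly guarantees
valence validity without a rejection loop, and generation is deterministic
for a given (spec, seed) without disturbing the caller's RNG stream.

What the decoys do **not** emulate: the size and functional-group
distributions of real vendor catalogues, sp³ richness, synthetic
accessibility, or salt forms. Consequently, a positive separation score
against decoys demonstrates that the pipeline detects genuine substructural
separation where it exists; it does not by itself prove novelty against any
particular commercial collection — for that, feed the real SMILES exports
through the same `scaffold_filter()` → fingerprints → novelty path.

The acceptance benchmark uses 1,000 decoys with motif fractions 0.4
(piperidine), 0.3 (pyrrolidine), 0.05 (cyclic sulfone) and 0.05
(*gem*-difluorocyclohexane), roughly mirroring the dominance of N-heterocycles
in motif-matched commercial extractions; SMARTS recovery of the planted
motifs is checked against central 99% binomial intervals.

## Numerical and design choices

* Canonical SMILES are dialect-dependent; all stored canonical strings are
  OpenBabel-canonical, and every serialized result carries
  `toolkit_metadata()` naming the back end.
* Batch SMILES conversion aborts at the first invalid entry in the back
  end, so the I/O layer pre-validates with the package's SMILES lexer
  (reporting character positions) and retries per-row to collect rejects;
  rejected rows are reported, never dropped.
* Library statistics use the sample (n − 1) standard deviation; for n = 1
  the sd is reported as 0 with `sd_defined = FALSE`.
* Silhouette scores use Euclidean distance in the embedding plane;
  labellings with fewer than two groups of two are rejected as degenerate.
* Tie-break in nearest-neighbour reports: first reference in input order.
* Test-suite problem sizes: 100 random chiral molecules for the
  enantiomer-invariance property, 40 for involution, 1,000 decoys for the
  pipeline benchmark, 10,000 random bit-vector pairs for Tanimoto
  invariants. These sizes give stable properties while keeping the suite
  fast enough to run routinely.

## Known limitations

* No CIP R/S assignment, tautomer canonicalization or pKa/charge-state
  enumeration; profiling is defined on the drawn neutral parent.
* Potential-stereocentre detection ignores dependent (para) stereocentres.
* The conformer used by the same-face test is a single generated 3D
  structure; for the vicinal disubstituted monocycles in scope the face
  assignment is conformer-independent, but macrocycles or fused systems are
  untested territory.
* OpenBabel and other toolkits can disagree on aromaticity perception for
  exotic heteroaromatics; the chemical space covered here (benzene,
  pyridine-like rings) is uncontroversial.
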