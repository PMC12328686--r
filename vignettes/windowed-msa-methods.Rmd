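---
title: "Windowed MSAs for chimeric proteins: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed MSAs for chimeric proteins: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeraMSA)
```

## The problem and the method

MSA-conditioned structure predictors derive spatial-contact signal from
columns of co-varying residues in an alignment of homologs. A chimeric
protein — a well-characterised scaffold (SUMO, GST, GFP, MBP are the
classic carriers) with a short structured peptide tag fused to its N- or
C-terminus through a flexible Gly-Ser linker — has no natural homologs as
a whole sequence. A single search over the fused query therefore tends to
recover scaffold homologs only: the peptide window of the alignment is
left nearly empty, and the predictor loses exactly the coevolutionary
evidence it needs to fold the tag, even though it folds the same peptide
accurately in isolation.

The windowed MSA construction repairs this at the alignment level rather
than the model level. Alignments are generated independently for the
scaffold (carrying the linker on its peptide-facing side) and for the
peptide, and are then merged into one alignment over the chimeric query:

* the chimeric query row is the full fusion sequence;
* every scaffold-derived homolog keeps its aligned residues across the
  scaffold and linker columns and carries `-` across the entire peptide
  window;
* every peptide-derived homolog carries `-` across the scaffold and
  linker columns and keeps its aligned residues across the peptide
  window.

No columns are created or destroyed, so the merged alignment has exactly
`len(scaffold) + len(linker) + len(peptide)` columns and depth
`1 + hits(scaffold) + hits(peptide)`. Because each homolog row has
residues in only one block, no alignment column ever pairs a scaffold
residue with a peptide residue: the merge cannot fabricate cross-segment
coevolution, it can only restore per-segment coverage. This conservation
is checkable, and `validate_windowed()` checks it before any file is
exported; `coverage_profile()` of the merged alignment restricted to the
peptide window reproduces the peptide alignment's own profile exactly.

The package prepares predictor inputs and evaluates predictor outputs;
running AlphaFold-2/3 or ESMFold themselves, and any molecular-dynamics
follow-up, are out of scope by design.

## Data model

`alignment()` objects hold a gapless query plus homolog rows expressed in
query-column space (A3M dialect: uppercase/`-` are match columns,
lowercase letters are insertions relative to the query). All merging
operates after insertion stripping, because "same length" is only
well-defined in match-column space; stripping is idempotent and the
A3M writer/reader pair is byte-exact on match columns. The first record
of an A3M file must be the query — a gapped first record is rejected
rather than silently reordered, since reordering would mask upstream
errors. Duplicate row ids (which MMseqs2 output can produce) are kept and
suffixed.

`make_fusion()` records the three part windows as 0-based half-open
intervals into the fused sequence, so window extraction is an exact
inverse of assembly and the evaluation code can address the peptide
region without re-deriving coordinates from sequence.

## Tunable parameters

* **Linker** (`linker`, default `"GS"`): one Gly-Ser unit. The linker is
  deliberately configurable because reported usage varies in length but
  linker length does not materially change tag prediction accuracy; the
  default is the smallest flexible spacer. The linker belongs to the
  *scaffold* sub-alignment: `incorporate_linker()` extends the scaffold
  query on the peptide-facing side and gap-fills homolog rows at the new
  columns — offline, no natural homolog covers residues that exist only
  in the engineered construct. A scaffold alignment whose query already
  carries the linker (e.g. produced by a live server search over
  scaffold+linker) is accepted as-is.
* **Clustering thresholds** (`identity_threshold = 0.5`,
  `coverage_threshold = 0.8`): the canonical redundancy-removal setting.
  "Similarity" is implemented as sequence identity over aligned pairs of
  a global Needleman-Wunsch alignment (match +1, mismatch 0, affine gap
  open 2 / extend 0.5, Biostrings' convention of charging
  `open + extend * length` per gap run). Coverage is aligned pairs over
  the *shorter* sequence, which makes the 80 % requirement bidirectional
  by construction. Greedy centroid clustering processes sequences in
  descending length order (ties broken by id) and assigns each sequence
  to the first qualifying representative, so results are deterministic
  and the cluster count is monotone non-decreasing in the identity
  threshold.
* **MSA-depth filter** (`min_hits = 2`): peptides whose alignment has
  fewer than two homolog hits are dropped — below that depth there is no
  usable coevolution signal, and such targets only add noise to any
  benchmark.
* **RMSD atom set** (`atoms = "CA"`, option `"backbone"`): CA-only RMSD
  is the conventional fold-level metric for short peptides; an N/CA/C/O
  backbone mode is available behind the flag. The atom set is reported
  with the metric because the choice is not universal.
* **Evaluation reference** (`model_index = 0`): for NMR ensembles the
  first deposited model is the reference, matching common benchmarking
  convention for peptides with NMR-only structures.

## Numerical choices

`kabsch_superpose()` is the closed-form SVD solution for the
least-RMSD rigid superposition, with the reflection corrected by flipping
the sign of the smallest singular direction whenever
`det(V U') < 0`, so the returned matrix is always a proper rotation
(determinant +1 to 1e-9) even for mirror-image point sets. Degenerate
inputs whose second singular value vanishes (collinear points) leave one
rotation axis unconstrained; the result is still the minimum RMSD but is
flagged `ill_conditioned`. The superposition of a peptide window is
*local*: the window's CA atoms are fitted directly onto the reference
peptide, independent of the scaffold frame, which matches per-part
accuracy reporting and makes the peptide metric provably insensitive to
scaffold coordinates. Residue correspondence is positional within the
window (i-th window residue to i-th reference residue, with a sequence
cross-check that warns on mismatch) rather than by residue number,
because fusion constructs renumber residues.

The test suite cross-checks the analytic RMSD against an independent
brute-force minimizer that searches rotation space from a dense set of
random axis-angle starts refined by Nelder-Mead; the two agree to better
than 1e-4 Å on every random instance, and congruent inputs give RMSD
below 1e-9 Å.

Ratios of in-context to isolated RMSD are reported per construct;
a zero isolated RMSD makes the ratio undefined and the row is excluded
from grouped summaries rather than reported as infinite.

## What the synthetic generators emulate

All fixtures are generated in code, from explicit seeds, with no hidden
RNG state (each generator restores the caller's RNG).

* `synth_msa()` draws a uniform random query and derives homologs by
  i.i.d. per-column substitution and gap conversion. This reproduces the
  *structural* properties the merge depends on — row lengths, gap
  placement, identity and coverage statistics (mean identity converges
  to `1 - substitution_rate` binomially) — but has no phylogeny, no
  conserved columns and no realistic gap blocks. Tests built on it
  therefore validate the merge/bookkeeping machinery, not biological
  alignment quality.
* `synth_coords()` builds ideal α-helix CA traces (rise 1.5 Å, 100° turn,
  radius 2.3 Å) or extended chains (3.8 Å CA-CA), with optional isotropic
  Gaussian noise — enough geometry to exercise superposition, region
  extraction and PDB round-trips, with no side chains and no full
  backbone beyond CA.
* `planted_families()` plants mutually unrelated progenitors (~5 %
  background identity) with point-mutated members at a configured
  within-family identity, giving clustering tests a known ground-truth
  partition whose separability is itself verified by an all-vs-all
  identity matrix before any recovery assertion.

Consequently, a green test suite shows the algorithms are implemented
correctly and conservatively; it does not certify prediction accuracy on
real chimeras, which depends on live MSA searches and external
predictors.

## Problem sizes used in the automated checks

The randomized suites run 500 merge instances (queries up to ~45 and ~20
residues for scaffold and peptide, depths up to 8), 100 superposition
instances of 5–20 points against the brute-force oracle, 3×5 planted
families of length 60 for clustering recovery, and 40 alignment
round-trips. These sizes were chosen to exercise every code path and
give stable statistics while keeping the whole suite fast enough to run
on every change.

## Design decisions that were genuinely open

* **Sub-query consumption.** The scaffold and peptide queries are merged
  into the single chimeric query row instead of being kept as two padded
  homolog rows. Predictors require the first A3M record to equal the
  input sequence; duplicating the sub-queries would inflate depth by two
  rows that carry no information the query row does not.
* **Row order and deduplication.** Merged rows are query, then scaffold
  homologs in their original order, then peptide homologs. No
  deduplication is attempted across blocks — cross-block duplicates are
  impossible by construction since the blocks occupy disjoint windows —
  and none within blocks, preserving whatever redundancy the upstream
  search chose to report.
* **No pairing heuristics.** No attempt is made to join scaffold and
  peptide homologs from the same organism into one row. The construction
  is explicitly unpaired; pairing would reintroduce the cross-segment
  coupling the method exists to avoid.
* **Unpaired single block.** Every input A3M is treated as one unpaired
  block; no paired/unpaired distinction is modelled.
* **Clustering algorithm.** The redundancy thresholds are phrased over
  whole-sequence identity and bidirectional coverage, so a greedy
  centroid pass over a global-alignment identity matrix is the natural
  fit. Other tools' internal heuristics (k-mer prefilters, similarity
  matrices) are not replicated, so cluster *counts* on external datasets
  will not match other software exactly; the recovery guarantees here
  are stated for separable inputs.
* **pLDDT as a window mean.** Per-residue confidence is summarized as
  the arithmetic mean over the window, and labelled as such; the
  per-residue vector remains available on the `structure_model` for
  callers who want distributions.

## Known limitations

* Offline linker incorporation gap-fills linker columns in homolog rows;
  a live scaffold+linker server search could in principle align homolog
  residues across those columns. This is a documented difference from
  server-generated inputs.
* Whether merged alignments should be depth-capped or deduplicated
  before prediction is left to the caller; the package preserves
  everything it is given.
* Automatic window discovery for arbitrary multidomain proteins is not
  attempted — windows are taken from the construct definition.
* mmCIF reading relies on bio3d's parser; exotic mmCIF dialects may need
  conversion to PDB first.
* The CLI chain has a documented gap where the external predictor runs:
  `window-msa` writes the predictor input, `evaluate` consumes the
  predictor output, and no network-dependent MSA fetching is included.
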