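---
title: "Methods: hydrophobin sequence profiling and structure assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrophobin sequence profiling and structure assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrophobinr)
```

This vignette explains the models and procedures behind `hydrophobinr`,
the parameters that matter, and the choices made where the design was
genuinely open. Everything stated here is computed by the package's test
suite or by `scripts/acceptance.R`; nothing rests on results the code does
not itself produce.

## The cysteine-motif model

Hydrophobins are recognised by their eight-cysteine scaffold
`C–Xa–CC–Xb–C–Xc–C–Xd–CC–Xe–C`: ordinals 2–3 and 6–7 are adjacent
doublets, and the five `X` segments are the intercysteine loops named
`C1-C2` through `C7-C8`. `scan_cys_motif()` walks the cysteine positions
of a sequence left to right and greedily emits every non-overlapping
window of eight consecutive cysteines whose gap vector fits the pattern.
Greedy non-overlapping matching was chosen because it is deterministic
and segments multi-domain chains (polyhydrophobins) naturally: each
matched window consumes its eight cysteines and scanning resumes after
it.

The loop-length bounds default to 1–75 residues for the five non-doublet
segments (doublet gaps are fixed at exactly 0). The literature states no
numeric spacing ranges, so the bounds are a package decision: 75 residues
accommodates the longest loops seen in solved hydrophobin structures
while preventing a single window from straddling two domains of a
polyhydrophobin, whose linkers are longer. Both bounds are arguments, not
constants.

A ten-cysteine (decet) mode supports the five-disulfide variants: a
window of ten consecutive cysteines where every gap is either 0 or within
bounds and at least two doublets are present. Ordinals remain positional
(C1…C10 in sequence order); whether a given bond of such a variant
corresponds to a canonical bond is a spatial question answered by the
disulfide-topology mapping, not by the naming.

## Class I / class II assignment

Curated databases assign hydrophobin classes through family annotation,
not through a published algorithm, so any sequence-only classifier is
necessarily a heuristic and `classify_hydrophobin()` is explicit about
being one. It uses a nearest-centroid rule on the 7-component
intercysteine spacing vector — the feature the two classes are described
as differing in — with the margin between the two centroid distances as
the confidence. Exact ties fall back to the mean Kyte–Doolittle
hydropathy of the C7-C8 loop (more hydrophobic favours class I, whose
C7-C8 loop carries the aggregation segment, e.g. FLIIN in EAS). Default
centroids match the synthetic generator's class spacing means and can be
regenerated from any labelled set with `spacing_centroids()`; they are
configuration data, not code.

## Physicochemical profile

*GRAVY* is the arithmetic mean of the 1982 Kyte–Doolittle hydropathy
values, hard-coded so the scale cannot drift with an external dependency.
Ambiguity codes (X/B/Z) and selenocysteine carry no scale value and are
excluded from the mean rather than imputed — exclusion is conservative
and keeps the score within the scale's bounds of ±4.5.

*Isoelectric point* follows the Bjellqvist pK set, including its
residue-specific N- and C-terminal pK values, with every cysteine treated
as a titratable free thiol (sequence-only prediction; the disulfide state
is unknown at this stage). The pH of zero Henderson–Hasselbalch net
charge is found by bisection on [0, 14] to a net-charge magnitude below
10⁻³, which the tests verify against a brute-force pH grid of step 10⁻⁴.
Because the terminal pKs depend on the identity of the first and last
residue, pI is invariant to permutations of the *interior* residues only;
the property tests respect that.

*Mining thresholds.* The non-canonical filters are exact thresholds:
ten cysteines with length below 250 residues flags a five-disulfide
candidate; at least 70 residues before the first cysteine flags an
extended N-terminal tail; more than one motif in a chain longer than 250
residues flags a polyhydrophobin, with domain counts labelled mono- to
penta-hydrophobin.

## Structure model assessment

All three comparison metrics operate on a residue correspondence:
index pairing when the two sequences are identical, otherwise a global
alignment (match +1, mismatch −1, linear gap −2) keeping aligned non-gap
pairs. A deterministic pairing rule is required because interactive
assessment servers hide theirs.

*Cα RMSD* uses the Kabsch algorithm — SVD of the covariance matrix with
the determinant correction enforcing a proper rotation. Degenerate
(collinear) point sets are rejected since the rotation is
underdetermined. The tests bound the result by a brute-force Euler-angle
grid search, which the SVD optimum can never exceed.

*TM-score* is `TM = (1/L_ref) Σ 1/(1 + (d_i/d0)²)` maximised over rigid
superpositions, normalised by the reference (experimental) chain length
— the convention when models are judged *relative to* experiment — with
`d0 = 1.24 (L_ref − 15)^{1/3} − 1.8` floored at 0.5 Å. The floor matters
here: hydrophobins are short (~70–120 residues) and the unfloored formula
degenerates below ~20 residues. The maximisation seeds superpositions
from the full aligned chain and from contiguous fragments of half and
quarter length at sliding offsets (step = half the fragment), refining
each seed by re-superposing on the residues within `max(d0, 4.5 Å)` until
the inlier set stabilises (capped at 30 iterations), and reports the best
score seen. Fragment seeding lets a well-predicted core dominate a
flexible terminus.

*lDDT-Cα* is superposition-free: over all residue pairs whose reference
Cα–Cα distance is below the 15 Å inclusion radius, it averages, across
tolerances 0.5/1/2/4 Å, the fraction of pairs preserved within the
tolerance. It is computed Cα-only, with no stereochemistry penalty.

*Ensemble rule and gates.* Against an NMR ensemble, all metrics are
computed per member and the member with the lowest Cα RMSD is reported.
Quality gates follow the standard cut-offs: RMSD < 2.5 Å, lDDT-Cα > 0.6,
TM-score > 0.6. Batch runs aggregate mean ± SD per class.

The widely used per-class benchmark means for hydrophobin model quality
(on the order of 2 Å RMSD, 0.7–0.85 lDDT-Cα, 0.8–0.9 TM-score) require
the deposited experimental structures and matching predicted models,
which cannot be redistributed with the package; the corresponding
acceptance test documents the expected file layout and fails loudly until
those inputs are supplied. The package's own verification therefore rests
on synthetic pairs with known noise levels.

## Disulfide topology and surface area

Sγ atoms are paired by greedy minimum-distance matching under a 2.5 Å
cutoff: a covalent S–S bond is ≈ 2.05 Å, and 2.5 Å excludes non-bonded
sulfur contacts while tolerating strained geometry. Ties break by
ascending (distance, lower ordinal), making the matching deterministic
and independent of atom order. Unpaired cysteines are reported as free,
not as errors. The canonical flag tests set equality with
{C1–C6, C2–C5, C3–C4, C7–C8}; for non-canonical sets a reference
structure can be supplied, and each bond is mapped to the spatially
nearest canonical bond after superposition — the appropriate comparison
when sequence numbering of cysteines differs between variants.

Solvent-accessible surface area uses Shrake–Rupley quadrature with Bondi
van der Waals radii, a 1.4 Å probe and 960 points per atom on a
deterministic Fibonacci lattice. 960 points keep the error on an isolated
sphere well under 1% and halving the density changes fixture totals by
under 2%. Exactly coincident duplicate atom records are collapsed before
quadrature. Note that absolute SASA values depend on the coordinate
preparation (energy-minimised versus as-deposited structures), so the
package treats SASA as a relative, not an absolute, quantity.

## Structure-based clades

Pairwise distance is `1 − mean bidirectional TM-score` — symmetric,
bounded in [0, 1] and length-aware. Trees are UPGMA (average linkage via
`stats::hclust`, serialised with `ape`): unlike neighbour joining, the
ultrametric tree admits a well-defined cut into exactly *k* clades, which
is how a dendrogram with "k main clades" is read in practice. Labels are
sorted lexicographically before clustering so topology is invariant to
input order, and clades are numbered by their lexicographically first
leaf. The pipeline default is k = 6, the headline clade count for the
hydrophobin structural universe; k is a user parameter because clade
delimitation on a dendrogram is ultimately a reading, not a discovered
quantity.

## The synthetic-data generator

`synth_sequences()` emulates a curated hydrophobin corpus: sequences
assembled as `[N-tail][octet core][C-tail]` with class-specific Gaussian
intercysteine spacing (class I mean spacing 8, 0, 16, 9, 6, 0, 17;
class II 9, 0, 11, 15, 8, 0, 6; both anchored on well-studied exemplars
of each class and documented as package parameters, not literature
values), loop residues from a small/polar-rich composition that excludes
cysteine, and a per-sequence planting of a few charged residues with a
small acidic excess. The charge planting is deliberate: real hydrophobin
isoelectric points cluster between pH 4 and 6, which reflects a
consistent per-sequence charge balance that independent per-residue
frequency draws do not produce. Planted non-canonical features occupy
disjoint records, and the ground-truth table is returned alongside the
sequences. The default corpus — n = 100 with 10 ten-cysteine, 10
extended-tail and 5 trihydrophobin records — is the condition under which
the recovery tests (precision = recall = 1) run.

`synth_structure_pair()` perturbs a template Cα trace (a helical curve
with ≈ 3.8 Å consecutive spacing) by isotropic Gaussian noise and a
uniformly random rigid motion; `synth_structure_families()` builds
distinct templates per family for clustering tests;
`synth_canonical_structure()` adds Sγ pairs at covalent distance in the
canonical connectivity and is labelled synthetic throughout — it stands
in for a deposited structure without reproducing anyone's coordinates.
All generators route every draw through a single integer seed and restore
the caller's RNG state.

What the generator does *not* emulate: real secondary structure and
side-chain packing, homology between families, sequence–structure
coupling (generated structures are not folded from generated sequences),
database redundancy, or signal peptides. Passing the recovery tests
therefore demonstrates the correctness of the detection and clustering
machinery under controlled conditions, not its performance on noisy
curated data.

## Problem sizes, determinism, degenerate inputs

The shipped tests use n = 100 sequence corpora, 40–80-residue templates,
20 replicates per noise level and 12-structure family sets — sizes chosen
so the full suite completes in about a minute while leaving the recovery
margins far from their thresholds. Degenerate inputs are contracts, not
afterthoughts: empty FASTA streams yield empty tibbles, duplicate ids and
invalid residue characters are parse errors naming the line, sequences
without cysteine are flagged and excluded from motif work rather than
erroring, unpaired Sγ atoms are free cysteines, and fewer than three
paired residues is an error for any superposition-based metric. The
pipeline aborts with a stage-named error and leaves a `FAILED` marker
while retaining partial outputs.

## Known limitations

* The class I/II classifier is a spacing heuristic; sequences with
  atypical spacing will be assigned with low confidence and should be
  checked against family annotation.
* TM-score seeding is a heuristic maximisation; scores are lower bounds,
  though the identity and noise-response tests show the bound is tight on
  the cases exercised.
* The decet motif definition is permissive (any arrangement of the two
  extra cysteines consistent with the bounds); true five-disulfide
  topology assessment requires coordinates.
* Absolute SASA values are preparation-dependent, as noted above.
* `run_pipeline()` is the package's orchestration surface; there is no
  shell executable, since the intended use is scripted R sessions.
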