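---
title: "Binding-site mapping by pose placement and clash screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-site mapping by pose placement and clash screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribosite)
```

## The problem and the model

Rigid-body docking of a ligand against one isolated subunit produces a
score-ranked ensemble of poses, but the subunit belongs to a much larger
assembly, and a pose that is plausible in the binary complex can be
impossible in context. `ribosite` formalizes the screening procedure
commonly used to resolve this:

* the docking-frame receptor is superposed onto its *anchor chain* inside
  the assembly (Kabsch least squares on CA atoms matched by author
  residue number), giving a rigid transform $T_a$;
* each pose transform $T_p$ is transplanted as $T_a \circ T_p$ applied to
  the ligand;
* a *clash* is a backbone–backbone atom pair at distance $d < 2.0$ Å
  between the placed ligand and the assembly minus the anchor chain;
* the **selected model is the first pose in docking-score order with zero
  clashes**.

The interface of the selected model is then characterized: a residue pair
is a *contact* when any pair of their heavy (non-hydrogen) atoms satisfies
$d < 4.6$ Å; candidate binding-epitope residues are those that are both
highly conserved and surface-exposed toward the partner-subunit interface;
a partner assembly placed in the same frame yields a steric verdict on
whether partner joining is blocked by the bound ligand.

Assumptions worth stating explicitly: rigidity everywhere (no relaxation
of clashing poses, no flexible side chains); the binary docking is trusted
for ligand–anchor geometry, which is why the anchor chain is excluded from
the clash context by default; and the backbone-only 2 Å clash rule is
deliberately permissive so that modest, unmodelled conformational
rearrangement of context components does not veto genuine poses.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `clash_cutoff` | 2.0 | Å | backbone–backbone clash rule (strict `<`) |
| `contact_cutoff` | 4.6 | Å | heavy-atom residue contact rule (strict `<`) |
| conservation tiers | 0.8 / 0.5 | — | high / moderate category edges (lower edge inclusive) |
| `rel_sasa_min` | 0.25 | — | relative SASA for "surface exposed" |
| `partner_dist_max` | 10 | Å | proximity for "exposed *toward* the partner" |
| SASA probe | 1.4 | Å | water-sized probe |
| SASA points | 960 | — | golden-spiral samples per atom |
| `clash_weight` | 10 | — | sampler score: one clash outweighs typical toy contact counts |

Every threshold is a strict inequality: a pair at exactly 2.0 Å is not a
clash and a pair at exactly 4.6 Å is not a contact. The boundary semantics
are tested at machine-representable values; they matter because assemblies
contain enormous numbers of near-cutoff pairs and an inclusive rule would
silently change counts between implementations.

Backbone definitions are polymer-type aware: `N, CA, C, O` for protein
(`OXT` excluded), and the sugar-phosphate trace `P, OP1, OP2, O5', C5',
C4', C3', O3'` for nucleic acids, mirroring the protein main-chain notion
for rRNA chains, which the clash rule never defines on its own.

## Conservation scoring

ConSurf-style Bayesian, phylogeny-aware scoring is *not* re-implemented.
The package's documented substitute is the normalized Jensen–Shannon
divergence: for each alignment column with amino-acid frequency vector
$p$ (gaps excluded) and uniform background $u$,

$$s = \frac{\mathrm{JSD}(p \,\|\, u)}{\mathrm{JSD}(\delta \,\|\, u)}
      \cdot (1 - g),$$

where $\delta$ is a point mass (the most conserved possible column) and
$g$ the column's gap fraction. This puts scores in $[0,1]$ with an
invariant gap-free column scoring exactly 1 and a column uniform over all
20 residues scoring 0. Categories (`high`/`moderate`/`low`) bin the score
at configurable tier edges; the lower edge is inclusive, so $s = 0.5$ is
`moderate` and $s = 0.8$ is `high`. Ties in `top_conserved()` break by
ascending column index.

One subtlety discovered while testing: "adding a duplicate row never
decreases a column score" holds only when the duplicated letter is the
column's consensus letter. Duplicating a minority letter moves the column
distribution *toward* uniform and can lower the normalized JSD slightly
(numerically, never by more than ~0.02), and duplicating a row that is
gapped at a column raises the gap penalty. The test suite therefore
asserts the corrected invariant (consensus duplication is monotone) plus
a small-perturbation bound for arbitrary rows.

## Solvent accessibility and exposure

Shrake–Rupley SASA places quasi-uniform points on each heavy atom's
probe-expanded sphere using the deterministic golden-spiral construction
(no seed is involved anywhere in SASA). A point is occluded only if it is
*strictly inside* a neighbor's expanded sphere, with a relative guard of
1e-10 on the squared radius so that points lying exactly on a neighbor's
surface stay exposed — the degenerate case of exactly coincident spheres
therefore yields the full isolated-atom area for both atoms rather than
an arbitrary split. Radii default to C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80 Å; relative SASA normalizes residue sums by the Tien et al.
theoretical maxima (any published table of the same shape can be
substituted).

"Exposed toward the partner interface" is operationalized as two
conditions: relative SASA ≥ 0.25 in the isolated receptor assembly, and
minimum heavy-atom distance to the partner < 10 Å in a reference complex.
A hemisphere/direction criterion was considered and rejected as less
reproducible (it requires choosing an interface normal). With no partner
supplied the criterion degrades to SASA-only and the output is flagged.

## The pose sampler is a surrogate

`enumerate_poses()` exists to produce contacting, clash-diverse pose
ensembles for exercising the downstream machinery — it is not a docking
engine and no attempt is made to reproduce any external engine's
ensemble. Orientations are drawn uniformly over SO(3) (quaternion
method), approach directions uniformly over the sphere, and the ligand is
slid along the center-to-center axis to first touch (bisection to 0.01 Å
on a 1 Å bracketing walk, which handles hollow receptors). Its surrogate
score is `contacts − 10 × clashes` over heavy-atom pairs; higher is
better. Imported pose tables are assumed ordered best-first, with a
`reverse` flag for engines that write worst-first; rotations are
validated on import (orthonormal within 1e-4, determinant +1) and ranking
is a stable sort, so score ties keep import order.

## Numerical choices and degenerate inputs

* **Altloc collapse**: highest occupancy wins; ties break to the
  lexicographically smallest altloc id. Deterministic by construction.
* **Waters** are dropped at parse; other HETATM records are kept and
  participate in clash/contact sets (a "rest of the assembly" reading
  that includes ions and modified residues), excludable by flag.
* **First MODEL only** for multi-model files; author residue numbering is
  authoritative throughout.
* **Kabsch** uses base `svd()` with the determinant-sign correction, so
  reflections are impossible; fewer than 3 matched points, or length
  mismatches, are errors. Collinear anchors leave the rotation
  under-determined, which is why fixtures always use non-collinear CA
  sets.
* **Neighbor search** is a cell-list spatial hash (compiled): pair
  enumeration under a cutoff costs O(atoms + pairs); the global minimum
  distance brackets itself with a strided-scan upper bound before one
  grid pass, so it is sub-quadratic in practice.
* **Selection** short-circuits at the first clash-free pose; the
  exhaustive mode exists for reporting. An all-clash ensemble returns an
  explicit "none admissible" result rather than an error.
* **PDB writing** rejects chain ids longer than one character and
  coordinates with |v| ≥ 10000 Å (the fixed-width field), rather than
  silently truncating.

## What the synthetic generator emulates — and what it does not

`make_toy_assembly()` builds poly-alanine-like chains (N, CA, C, O, CB)
on parametric helices: chemically meaningless, geometrically realistic.
It plants a true pose that touches the anchor chain at 4.0 Å (inside the
contact cutoff) on the face opposite the other chains (hence clash-free),
and decoy poses translated toward context chains until the planned number
of backbone violations falls under 2 Å (bisection to 0.01 Å). Scores are
assigned so decoys occupy the top ranks. Every fixture is self-certified
before being returned: the generator re-runs the package's own clash
screen and contact mapper and aborts if the ground truth does not hold.
`make_toy_msa()` plants invariant, gap-free columns in background noise.

Passing the planted-truth suites shows the *logic* is right — placement
composes transforms correctly, screening counts exactly what an
exhaustive scan counts, selection picks the documented pose, conserved
columns are recovered. It does not show robustness to the things real
data add: atom-naming irregularities, missing residues and insertion
codes, modified nucleotides, alignment uncertainty, or docking ensembles
whose near-native poses are only approximately rigid. The deposited-model
checker (`deposited_model_check()`) exists for exactly that hand-off: it
runs the same contact and clash machinery on an externally produced
complex, identifying the ligand chain by elimination when it is not
annotated.

## Problem sizes

The shipped tests run the oracle-equivalence suites on random fixtures up
to ~500 atoms per side (20 replicates), the selection scenario on a
100-pose ensemble with 16 planted decoys, SASA cross-validation on
10-atom clusters at 4000 sample points against a 20000-point
Monte-Carlo integration, and conservation recovery across 20 seeded
alignments of 10 × 50. These sizes exercise every code path while keeping
the whole suite fast enough to run on every change; all scale linearly or
near-linearly, and the compiled neighbor search is the only piece whose
constant factor matters on full-size ribosomal assemblies.

## Known limitations

* No energetics: selection is purely steric, and the surrogate docking
  score is not comparable across systems.
* No flexibility: clashing poses are discarded, never relaxed.
* Conservation is alignment-quality-bound and phylogeny-blind; tier
  boundaries are conventions, not calibrated probabilities.
* mmCIF, symmetry expansion, anisotropic records, and SEQRES-derived
  sequences are out of scope; inputs are single-model PDB text.
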