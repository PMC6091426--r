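---
title: "Predicting ligand binding sites from surface point ligandability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ligand binding sites from surface point ligandability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketrank)
```

## The model

pocketrank treats ligand binding site prediction as a point classification
problem. The unit of classification is a *SAS point*: a sample on the
protein's solvent accessible surface — the surface traced by the center of
a 1.4 Å probe sphere rolled over the van der Waals surface. Each point
stands for the local spherical chemical neighbourhood centered on it, and
equivalently for a potential location of a contact atom of a potential
ligand. A trainable Random Forest assigns every point a *ligandability
score* in [0, 1]; high-scoring points are clustered into ranked pocket
predictions.

This pocket-centric formulation — a ranked list of localized sites,
evaluated by identification success at rank cutoffs — is deliberately
different from residue-centric binding-residue classification: the target
quantity is "where are the most promising sites and in what order", not a
per-residue confusion matrix.

### Surface sampling

Candidate points are placed on each atom's expanded sphere (van der Waals
radius + probe radius) with a deterministic Fibonacci golden-angle
lattice, and candidates falling strictly inside any other atom's expanded
sphere are discarded. The survivors are regularly spaced, lie exactly on
the SAS, and are produced without any random number: the surface of a
given structure is always the same point set.

One subtlety is worth recording. A sampling lattice fixed in world
coordinates would make the point cloud depend on the structure's
orientation on file. We instead orient the lattice in the structure's own
principal-axes frame (eigenvectors of the coordinate covariance, with each
axis' sign fixed by the third moment of coordinates along it), so rigidly
moving a structure rigidly moves its point cloud. For degenerate spectra —
single atoms, perfectly symmetric clouds — the frame falls back to the
identity, which preserves determinism even where equivariance is
ill-defined.

Van der Waals radii come from a small per-element table (C 1.70, N 1.55,
O 1.52, S 1.80, P 1.80 Å, …); unknown elements fall back to the carbon
value with a warning. All boundary comparisons in the package are
inclusive (≤).

### Features

Two kinds of features describe a point, assembled in a configurable
ordered *schema*:

* **Projected atom properties.** For each physico-chemical property $p$
  and point $x$, the projection is
  $\sum_{a:\,d(x,a) \le 6} (1 - d(x,a)/6)\, p(a)$ over protein atoms
  within the 6 Å neighbourhood — the linear weight $w(d) = 1 - d/6$ is 1
  at the point and 0 at the edge. Properties are residue-level
  (Kyte–Doolittle hydrophobicity, aromaticity, formal charge, polarity)
  and element-level (H-bond donor/acceptor capability), plus the atomic
  B-factor passed through from the file. Distances are measured to atom
  centers, matching the plain reading of the geometric descriptors below.
* **Direct geometric descriptors.** Chief among them *protrusion*: the
  number of protein atoms within 10 Å of the point. Buried, concave
  locations see many atoms; exposed convex ones see few, so this single
  count is a strong concavity proxy. Atom counts at 6 Å and 4 Å complete
  the default schema.

The default schema has ten features. It is explicitly configurable, and
the single-feature schema `"protrusion"` reproduces a purely geometric
reduced predictor that is a useful baseline and ablation: the acceptance
checks confirm it still recovers synthetic pockets far better than random
ranking. Whether properties should be projected from all protein atoms or
only solvent-exposed ones is genuinely open; we project from all atoms,
which is simpler and parameter-free (a buried atom 6 Å from a surface
point still shapes its electrostatic environment).

Projection defaults to the distance-weighted **sum**, which deliberately
mixes composition with local atom density. A weighted-**mean** option
(`aggregation = "mean"`) isolates composition where that coupling is
unwanted.

### Scoring and training

The classifier is a probability Random Forest: 200 trees, grown to purity
with no depth limit, 6 candidate features per split (capped at the schema
length). Training supervision comes from bound ligands: a point is
positive iff it lies within 2.5 Å of a heavy atom of a *relevant* ligand.
The 2.5 Å default reflects the reading of SAS points as potential ligand
contact-atom locations — a near-contact distance, between a van der Waals
contact and the probe offset. Negatives vastly outnumber positives on any
surface, so they are randomly subsampled to 10 per positive (seeded, and
recorded in the model's training summary). Training is single-threaded
and fully seeded: the same data, schema and seed give a byte-identical
model archive.

Relevant ligands are decided by an auditable filter: residue name not on
an exclusion list (waters, isolated ions, common buffer and
cryoprotectant molecules), at least 5 heavy atoms, and closest approach to
the protein within 4 Å. All three rules are parameters of
`relevance_rules()` and are logged per group; they are this package's
declared defaults, not a claim about any other implementation's unpublished
filter.

### From points to pockets

Points with score ≥ 0.35 are clustered by single-linkage at a 3 Å cutoff —
computed as the connected components of the ≤3 Å distance graph, via the
single-linkage dendrogram cut at that height, so the partition is unique
and order-independent. Clusters smaller than 3 points are discarded as
noise. Each surviving cluster becomes a pocket:

* **score** = $\sum_i s_i^2$ over member points — squaring favours a few
  confident points over many lukewarm ones, and adding any positive-score
  point strictly increases the score;
* **center** = score-weighted centroid of member points (plain centroid if
  all scores are zero). Weighting is declared and switchable; it pulls the
  center toward the most ligandable part of the cluster, which is also the
  part the DCC evaluation cares about;
* **surface atoms / residues** = protein atoms within 3.5 Å of any member
  point and their distinct residues, as `<chain>_<resno>` tokens — pockets
  at chain interfaces legitimately span chains.

Pockets are sorted by score descending; exact ties break by larger point
count, then by lexicographic center coordinates. The tie-break chain
exists purely for determinism. The 0.35 threshold and minimum size 3 are
tunable defaults (the corresponding knobs of the original method were
tuned on a development set without published values); both are exposed in
`default_run_params()` and re-tunable with the train/eval loop.

### Evaluation protocol

Predictions are evaluated ligand-centrically with **DCC**: the distance
from a pocket's center to the closest heavy atom of a known relevant
ligand, with a 4 Å identification threshold. Only pockets ranked within
the cutoff are considered — Top-*n* or Top-(*n*+2), with *n* the number
of relevant ligands in that structure (so single-ligand proteins get the
usual Top-1/Top-3 cutoffs). Every relevant ligand counts equally in the
dataset success rate; a structure with no relevant ligand is excluded.
When fewer pockets were predicted than the cutoff allows, all of them are
considered. One pocket may identify several ligands and each ligand needs
only one identifying pocket — the inclusive reading; it is declared here
rather than inherited. DCA (ligand-to-nearest-point) is available as a
secondary criterion but headline reports use DCC only.

## The synthetic generator, and what passing tests mean

`generate_fixture()` emulates just enough of a protein for the pipeline
to be exercised end to end: a quasi-uniform shell of pseudo-atoms over a
jittered interior lattice (~500 atoms, seconds-scale end to end), with
each pocket carved as a concave bite (atom removal plus slight inward
wall displacement) and a compact pseudo-ligand placed in contact with the
lining. Two independent signal channels make learnability controllable:

* **geometry** — carving makes protrusion genuinely higher at pocket
  points than on the open shell;
* **properties** — lining atoms' B-factors are shifted by
  `property_contrast`, which propagates through the projected-B-factor
  feature.

The *null condition* sets both `pocket_depth = 0` and
`property_contrast = 0`. This is deliberate: concavity is genuine signal,
not leakage — a model that learns "concave ⇒ ligandable" from geometric
pockets generalizes correctly — so a meaningful no-signal control must
remove both channels. Under the null, held-out point-level AUC sits at
chance (≈ 0.49–0.53 across seeds in the acceptance runs), while the
default generator yields AUC > 0.99 and Top-(*n*+2) identification at or
near 100% on held-out fixtures. That establishes the pipeline learns
transferable surface signal rather than memorizing artifacts.

What fixtures do **not** show: performance on real proteins. They have no
side-chain chemistry, no realistic packing or secondary structure, one
atom type, and pockets far cleaner than crystallographic reality — where,
additionally, many true sites carry no bound ligand in the deposited
entry, making real training labels noisy in a way the generator does not
emulate. Results on fixtures validate the machinery and its contracts,
not benchmark-level accuracy; training on real complexes is done by
pointing `run_train()` at a dataset of real PDB files.

## Numerical choices and degenerate inputs

* Occlusion and surface tests use a 1e-6 Å tolerance; candidate points are
  kept when not *strictly* inside another expanded sphere.
* Alternate locations resolve to the highest-occupancy conformer, ties to
  file order; hydrogens and waters are dropped; HETATM records of common
  modified amino acids (MSE, SEP, TPO, …) count as protein atoms since
  they are part of the described surface. Only the first MODEL of
  multi-model files is used unless `model_index` says otherwise.
* A structure with zero relevant ligands trains as all-negative (with a
  warning) and is excluded from evaluation (with a note); an empty
  candidate set yields zero pockets and a header-only CSV, which is a
  legal prediction.
* Clustering of 0 or 1 points short-circuits; `hclust` handles the rest.
* Dataset prediction parallelises over structures
  (`parallel::mclapply`); within-structure computation is single-threaded,
  so outputs are identical for any thread count.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data: 30 training / 20 held-out structures of ~500 atoms for parameter
recovery, 5 × (6 + 4) structures for the null condition, 100 random point
sets for the clustering cross-check, and 30 random clouds for the
feature-oracle cross-check. These sizes were chosen so a full run
completes in minutes on one core while keeping every success criterion
statistically meaningful at its stated bound.

## Known limitations

* No volumetric pocket shapes or volumes — pockets are point sets with
  centers, not closed surfaces.
* No sequence-conservation or energetic-probe features; the schema is
  geometric and physico-chemical only.
* The relevance filter is a documented stand-in, not a reconstruction of
  any published filter's exact list.
* mmCIF input, PDB fetching, and biological-assembly generation are out of
  scope; input is PDB-format files as provided.
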