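---
title: "Hybrid ligand/structure-based target fishing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid ligand/structure-based target fishing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`targetfish` predicts the protein targets of a small molecule by combining
two complementary signals: chemical similarity of the query to ligands
with known targets, and geometric similarity of its predicted binding mode
to the experimentally observed one. This vignette documents the models,
the tunable parameters and their defaults, the synthetic test harness, and
the design decisions a maintainer should know about.

## The scoring model

**Ligand similarity (T~L~).** For each fingerprint algorithm *a* in the
active preset, the Tanimoto coefficient
$T_a = N_{ab} / (N_a + N_b - N_{ab})$ is computed between query and
co-crystal ligand; T~L~ is the unweighted mean over algorithms. Averaging
several fingerprints damps the idiosyncrasies of any single hashing
scheme. Two presets are provided: `MMD` (Morgan radius 2, MACCS keys,
Daylight-style path fingerprint) for all-class searches and `MM` (without
Daylight) for class-restricted searches, where the narrower preset is the
more precise choice. The shortlist cutoff on T~L~ defaults to 0.4:
empirically, lower cutoffs mostly add false positives that must then be
docked, while higher cutoffs discard true targets before the structural
stage can rescue them.

**Binding similarity (T~B~).** Each shortlisted candidate is docked and
the pose is summarized as a per-residue interaction fingerprint: 8 bits
per residue, in file order, with slots *hydrophobic*, *aromatic face*,
*aromatic edge*, *protein-H-bond-acceptor*, *protein-H-bond-donor*,
*salt bridge (protein positive)*, *salt bridge (protein negative)*,
*metal contact*. T~B~ is the Tanimoto coefficient between this fingerprint
and the one of the co-crystallized ligand on the same receptor.
Fingerprints from different receptors are never compared — the residue
index is part of the object and a mismatch is a contract error.

**Combined score.** Candidates are ranked by
$w_L \, T_L + w_B \, T_B$ with default weights (0.7, 0.3). The ligand
term dominates deliberately: fingerprint similarity is robust, while a
single docked pose is noisy; the binding term acts as a structural
tie-breaker that can promote a moderately similar ligand whose pose
reproduces the native interaction pattern. Ranks are assigned
deterministically (combined score descending, then T~L~ descending, then
PDB id ascending) so results are reproducible to the byte.

## Geometric criteria (interaction scheme "v1")

The contact typing rules are explicit and versioned; all distances in
Å, angles in degrees:

| interaction | criterion |
|---|---|
| hydrophobic | non-aromatic ligand C/S to non-aromatic side-chain C ≤ 4.5 |
| H-bond | donor-heavy–acceptor ≤ 3.5 and D–H···A ≥ 120° when the donor H is present; distance-only otherwise |
| salt bridge | opposite formal charges ≤ 4.0 |
| aromatic face | ring-centroid distance ≤ 4.5 and interplanar angle ≤ 30° |
| aromatic edge | centroid distance ≤ 6.0 and angle in (30°, 90°] |
| metal contact | ligand O/N/S ≤ 2.8 from a metal ion |

Hydrophobic contacts are restricted to non-aromatic carbons on both sides
so that an aromatic stacking geometry registers as exactly one interaction
type; ring atoms of Phe/Tyr/Trp/His count only toward the aromatic slots.
Ring planes are fitted by SVD and the interplanar angle uses the absolute
cosine, so ring normal orientation is immaterial and the fingerprint is
invariant under rigid motion of the complex. Hydrogens are associated with
their donor heavy atom by distance (≤ 1.3 Å) when connectivity is absent.

Degenerate inputs have defined outcomes: two all-zero fingerprints compare
to T~B~ = 0 with a warning (never NaN, never 1 — featureless poses must
not look like perfect matches), and the same convention applies to
all-zero 2D fingerprints in T~L~.

## Activity models

Binding activity is regressed from 512-bit Avalon fingerprints with a
random forest (the `ranger` backend, single-threaded for determinism),
one model per target class. Avalon is used *only* as the regression
descriptor, not in the similarity search — the two roles are kept
separate because the similarity presets were selected for retrieval,
whereas Avalon's dense structural hashing suits descriptor use.

Training uses repeated nested cross-validation: an outer 5-fold split
estimates generalization; inside each outer training fold an inner 3-fold
loop selects hyperparameters from a grid of {100, 300, 500} trees ×
mtry ∈ {√p, p/3, p}. Outer test folds never influence selection; the
package exposes the per-fold selections (`details`) so this no-leak
property is directly testable — scrambling one outer fold's held-out
labels provably cannot move that fold's inner choice. Performance is the
mean ± SD of outer-fold Pearson R and RMSE across repeats (default 10
repeats; the test suite and acceptance script use 1 repeat, which is
sufficient for their pass/fail bounds). Zero-variance folds are excluded
from the R average with a warning. The final model is refit on all rows
with the most frequently selected grid point.

## Docking adapter

The engine interface speaks the AutoDock Vina contract: PDBQT in,
multi-model PDBQT out with `REMARK VINA RESULT` energies; the lowest
energy model is the binding mode. Any conformant binary can be plugged
in (`vina_engine()`); defaults are padding 8 Å around the co-crystal
ligand's bounding box, exhaustiveness 8, and a fixed seed. The search box
is centered on the co-crystal ligand centroid — the library's reference
pose defines the binding site, so no cavity detection is needed.

The bundled `mock_engine()` returns planted poses verbatim and
`library_mock_engine()` redocks every entry's own co-crystal pose. This
makes the pipeline exactly deterministic end-to-end, which the test suite
exploits; it also means mock T~B~ values are upper bounds relative to a
real engine. Poses re-typed from engine PDBQT output carry element,
aromaticity and H-bond capability from AutoDock atom types, but PDBQT
stores partial rather than formal charges, so salt-bridge bits are not
recoverable on the real-engine path — a documented limitation.

## Synthetic fixtures: what they do and do not show

`generate_complex()` writes short (10–30 residue) ideal-geometry peptides
directly in PDB format and places ligand fragments so that exactly the
requested interaction bits are realized: residues sit 12 Å apart on a
line, far beyond every criterion cutoff, and each planted geometry is
chosen to satisfy one criterion while provably missing the others (e.g.
salt-bridge partners sit at 3.8 Å — inside the 4.0 Å charge cutoff,
outside the 3.5 Å H-bond cutoff). These receptors are geometric test
articles, not physical proteins: no force field, no realistic side-chain
packing. Passing the round-trip tests demonstrates that the extraction
logic implements the stated criteria exactly; it does not demonstrate
that scheme "v1" captures the interactions a crystallographer would
annotate in a real complex.

`generate_library()` builds toy libraries whose ligand families are
chemically disjoint homologue series; the generator verifies (and fails
otherwise) that the first two ligands of each class have Morgan Tanimoto
≥ 0.7 and that all cross-class pairs stay ≤ 0.3. Close homologues can
have *identical* hashed fingerprints (e.g. long-chain fatty acids differ
only by repeated interior environments), so within-class ties are
expected and exercise the deterministic tie-break. Activities are drawn
around typical −log M values (mean 6.5, SD 1.2). `generate_decoys()`
draws from a fixed combinatorial pool under two constraints: Morgan
Tanimoto < 0.4 to every ligand of the intended target (so decoys cannot
clear the shortlist for that target by construction) and ≥ 100 Da
molecular-weight spread across the set. `generate_activity_dataset()`
plants a linear signal on moderate-frequency (0.2–0.8) Avalon bits with
Gaussian noise, recording the ground truth for recovery tests.

All generators are pure functions of their arguments and seed; the
acceptance script runs the full study at n = 300 molecules for the
activity models, 8 queries and 15 decoys for retrieval — sizes chosen so
the whole study re-runs in a few minutes on one core while keeping every
statistical bound comfortably testable.

## Design decisions and open points

- **Fingerprint lengths** (Morgan 2048, MACCS 166, Daylight 2048, Avalon
  512, others 2048) follow the reference toolkit's community defaults and
  are recorded in library metadata; libraries reject entries whose
  lengths disagree.
- **Pharmacophore fingerprints**: a single 2D pharmacophore algorithm
  (Gobbi scheme, folded to 2048 bits) is exposed. Whether a 3D variant
  would behave differently is left open; the 2D variant is the one
  comparable with the other hashed fingerprints.
- **Per-entry ranking**: one output row per PDB complex, not per target
  name — the complex is the unit that was docked and scored. Correctness
  checks compare target *names* (case-insensitive, whitespace
  normalized), and duplicate entries of one name count once toward TP.
- **Precision denominator** at rank *N* is min(*N*, records returned), so
  short result lists keep precision ≤ 1. F1 is defined as 0 when
  precision + recall = 0, and is bounded by 1 by construction.
- **Every shortlisted entry is docked** — no secondary T~B~ cutoff and no
  cap on candidates. Capping would couple retrieval quality to shortlist
  ordering; the cutoff already bounds the work.
- **Missing class models degrade gracefully**: target identification
  proceeds with a null activity and an explanatory status, rather than
  aborting.
- **Library serialization is plain JSON text** (manifest + sparse
  fingerprint sidecars + structure files). At library scale the
  human-inspectable, diff-able representation outweighs the compactness
  of a binary sidecar, and byte-identical round-trips make rebuild
  determinism trivially checkable. For the same reason metadata carries
  no build timestamp.
- **Split constraint**: every validation entry's target name must occur
  in training (a query can only be retrieved if its protein is
  searchable); singleton target names are forced into training with a
  warning.

## Known limitations

- The interaction scheme omits water-mediated and halogen bonds and works
  per residue, not per atom.
- Kinase-like classes with many diverse proteins are poorly served by a
  single class-wide activity model; subclass models would need more data.
- The mock engine validates orchestration and scoring arithmetic, not
  docking accuracy; conclusions about real-world retrieval require a real
  engine and a curated structural library.
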