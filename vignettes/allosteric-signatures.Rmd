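---
title: "Detecting allosteric signatures in two-condition trajectory ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allosteric signatures in two-condition trajectory ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopath)
```

## The problem

A positive allosteric modulator (PAM) bound at the periphery of a G-protein
coupled receptor — for instance a compound like LY3154207 at the second
intracellular loop (IL2) of the dopamine D1 receptor — typically produces no
large conformational change.  Its signature in molecular-dynamics ensembles
is statistical: residues form slightly more or slightly fewer contacts, a
loop holds its helical turn a little more often, the receptor–Gα interface
rewires by tenths of a contact frequency.  `allopath` implements the
comparison machinery for such ensembles: given trajectory frames for two
simulated conditions (e.g. PAM-bound and PAM-free), it quantifies

* residue–residue **contact frequencies** with bootstrap uncertainty,
* **eigenvector centrality** on the weighted residue-interaction network,
* per-residue **helicity fractions** from a Kabsch–Sander
  secondary-structure assignment,
* ligand **RMSD** in the evolution and pairwise schemes,
* **COM–COM distances** between transmembrane subsegments, and
* receptor/Gα **interface contact difference maps**,

and reports the between-condition differences with the display thresholds
used in that literature (0.005 for absolute centrality differences, 0.10
for contact-frequency differences).

## Contact frequencies and their bootstrap

Two residues are in contact in a frame when their closest heavy-atom
distance is at most 4.5 Å (inclusive).  Frames from all trajectories of a
condition are pooled with equal weight; a `bootstrap_plan()` then draws
`n_samples` sets of `frames_per_sample` frames with replacement (default
10 × 2000 = 20,000 drawn frames, the convention of the analyses this
package reproduces).  The per-pair frequency within each sample is the
fraction of drawn frames in contact; the reported frequency is the mean
over samples and the reported uncertainty their standard deviation.  A
plan with a single sample covering every frame without replacement reduces
exactly to the plain per-frame frequency, which the tests exploit as an
oracle.

The naive frame bootstrap treats frames as exchangeable.  Real MD frames
are autocorrelated, so the bootstrap spread underestimates the true
sampling error on correlated data; it remains a useful *relative* measure,
which is how it is used here.  In `run_comparison()` both conditions of a
stage share the bootstrap sample indices (common random numbers), so a
comparison of a condition with itself is identically zero.

## The residue-interaction network

The averaged contact-frequency matrix becomes a weighted graph: an edge
joins any residue pair with non-zero frequency separated by at least two
positions in sequence (`|i - j| >= 2`; immediate neighbors are excluded,
inter-chain pairs are always eligible), with the frequency as edge weight.
Eigenvector centrality is the Perron eigenvector of the weighted adjacency
matrix.  Numerical choices:

* **Solver** — shifted power iteration on `W + I`.  The shift leaves the
  eigenvector unchanged while making the leading eigenvalue strictly
  dominant in magnitude, so the iteration also converges on bipartite
  graphs (a star graph, whose unshifted spectrum is symmetric, is one of
  the closed-form tests).  Convergence is declared at an eigen-residual of
  1e-10; an unconverged small graph falls back to a dense symmetric
  eigendecomposition.
* **Normalization** — unit Euclidean norm, recorded in the result's
  metadata.  The published score tables this package mirrors (maxima near
  0.22 across hundreds of residues) are consistent with L2 scaling and not
  with max-1 scaling.
* **Disconnected graphs** — scores are computed on the largest connected
  component; all other nodes score zero.
* **Sign** — the Perron vector is taken non-negative; a negative entry
  after convergence is a test failure, not a convention.

Centrality is computed on the sample-averaged matrix (the published
procedure); per-sample centralities are available as a diagnostic spread
only.  `compare_conditions()` reports the signed difference
`condition 1 - condition 2` and highlights absolute differences *strictly
exceeding* the threshold (default 0.005, following the "exceeding"
wording of the source convention), optionally filtered to residues scoring
at least 0.10 in either condition.

## Secondary structure

Backbone hydrogen bonds are scored with the Kabsch–Sander electrostatic
energy

$$E = 27.888 \left( \frac{1}{r_{ON}} + \frac{1}{r_{CH}} -
      \frac{1}{r_{OH}} - \frac{1}{r_{CN}} \right) \ \mathrm{kcal/mol},$$

with a bond declared below −0.5 kcal/mol.  Amide hydrogens are
reconstructed 1.01 Å from N opposite the preceding carbonyl (standard
practice for heavy-atom trajectories); chain starts and prolines never
donate.  N-turns (n = 3, 4, 5) and parallel/antiparallel bridge patterns
are evaluated and collapsed to the three broad categories: H/G/I → helix,
bridge → sheet, else coil.  Because both isolated bridges and extended
ladders collapse to "sheet", ladder bookkeeping cannot change the 3-state
output and is folded.  Consecutive residues whose Cα–Cα distance exceeds
4.5 Å terminate turn patterns (chain break), which keeps artificial
constructs with spatially separated segments from forming spurious turns.
A chain shorter than five residues cannot host a 4-turn and is entirely
coil.

`helicity_fractions()` labels every pooled frame once and then applies the
bootstrap plan to the per-frame helix indicators, retaining the full label
track for evolution-style plots.

## Geometry

`kabsch_superpose()` is the SVD solution of the weighted orthogonal
Procrustes problem constrained to proper rotations (det = +1); collinear
alignment sets are rejected.  The **evolution RMSD** aligns each frame to
the *first frame of its own trajectory* on the alignment selection
(conventionally Cα atoms of the binding-pocket or TM3/TM4/IL2 residues)
and then measures the target heavy atoms without re-fitting.  The
**pairwise RMSD** draws frame samples (plain random samples, without
replacement, per its source convention), computes all within-sample frame
pairs with the lower-index frame as reference, and reports the mean of the
per-sample averages with their standard deviation.

The subsegment analysis (`pia_distances()`) tracks the mass-weighted
center of mass of each named residue range over heavy atoms — hydrogens
are excluded for robustness to stripped trajectories, and the weighting
choice is recorded in the output.  The 21 published transmembrane
subsegments of the D1 receptor construct ship as `d1r_subsegments()`.

## The synthetic-data generator

No trajectories are publicly deposited for the study conditions this
package is designed around, so validation rests on
`synthetic_spec()`/`generate_condition()`: a statistical mimic of a
two-condition ensemble with planted, parameterized effects.

The geometry is a seven-helix bundle (12 residues per helix, ideal
α-helical backbone built from internal coordinates: φ = −57°, ψ = −47°,
rise ≈ 1.5 Å, ≈100°/residue) on a 15 Å circle, a 16-residue "Gα" helix
outside the bundle, and an 8-atom rigid ligand at the bundle periphery.
Every residue carries one sidechain pseudo-atom (CB).  Planted effects:

* **Helicity window** — three consecutive residues of helix 3 (the IL2
  analogue) switch between helix and coil as *one* two-state Markov chain;
  coil frames displace the window backbone 8 Å radially outward, breaking
  every hydrogen bond through the window.  The default per-frame rates
  give stationary helix occupancies of 0.25 (condition A) and 0.85 (B)
  with mean dwell times of a few to ~17 frames, so evolution plots show
  contiguous runs rather than per-frame noise.  The window switches
  cooperatively rather than per-residue because helix labels are defined
  by i→i+4 bond patterns spanning four residues: displacing a single
  residue leaves its own label covered by neighboring turns, so only a
  cooperative window can realize a target per-residue occupancy — which
  also matches how short loop segments fold and unfold in practice.
* **Contacts** — each planted pair realizes a per-frame Bernoulli draw at
  its condition's target frequency by moving one partner's CB to 4.0 Å
  from the other's CB (contact) or leaving it at its canonical position
  (no contact).  Defaults: one "hub" edge strengthening 0.30 → 0.80
  between helices 1–2, an independent gain pair (helices 5–6, 0.30 →
  0.80), a loss pair (helices 4–5, 0.60 → 0.35), and seven static 0.70
  background pairs that keep the inter-helix network connected.  Residue
  pairs are chosen deterministically and pose-aware: candidates are tried
  in order of increasing CB–CB distance and accepted only when the contact
  pose clears every other residue, the ligand, the displaced window and
  all previously accepted poses — an impossible plant is an error naming
  the pair.  Baseline inter-helix separations exceed the 4.5 Å cutoff by
  ≥ 0.5 Å (≈3.5 standard deviations of the pair-distance noise), so
  thermal jitter cannot create or destroy planted contacts at a rate that
  matters at the 0.10 display threshold.
* **Interface** — the same mechanism across chains: two receptor–Gα pairs
  at 0.30 → 0.45 and one static pair at 0.60.
* **Ligand** — isotropic Gaussian jitter (σ = 0.5 Å) about a fixed pose,
  giving an evolution-RMSD plateau near √6·σ ≈ 1.2 Å; all protein atoms
  carry σ = 0.1 Å thermal jitter.
* Optionally a rigid **segment shift** of a residue set in one condition,
  for COM-distance validation.

Everything is deterministic given the spec seed (per-trajectory sub-seeds
are derived by a label hash), and conditions share the topology exactly.

What the mimic does *not* emulate: force-field energetics, correlated
collective motions, side-chain rotamers, solvent and membrane, and
realistic contact-frequency distributions.  Passing the planted-recovery
tests therefore demonstrates that the *analysis machinery* is correct and
sensitive at realistic effect sizes, not that any biological conclusion
transfers.

## Problem sizes used in the shipped validation

The test-suite and the acceptance script run desk-scale versions of the
study design, chosen so every planted margin sits several standard errors
from its threshold: two trajectories of 1500 frames per condition with a
10 × 1000 bootstrap for the end-to-end replicates (at 3000 pooled frames
the planted 0.15 interface change is ≈3σ above the 0.10 threshold); 20
seeded replicates for the recovery-rate estimate; 10,000 pooled frames
with the canonical 10 × 2000 plan for the planted-0.5 frequency check; and
100 random graphs of up to 50 nodes against a dense eigensolver for the
centrality core.

## Known limitations

* XTC trajectories are not read; convert to DCD or multi-model PDB.
* The frame bootstrap ignores autocorrelation (see above).
* Periodic boundaries are not unwrapped: distances are computed in plain
  Cartesian coordinates, which assumes pre-imaged trajectories in which
  the complex is whole — the standard situation for exported GPCR
  trajectories, and the reason receptor-internal contacts never span the
  box.
* The 3-state collapse discards 3₁₀/π distinctions and bends; helicity
  here means "any DSSP helix class".
* No formal hypothesis test is attached to helicity or contact
  differences; fractions are reported with bootstrap spreads and the
  published display thresholds, and formal testing is left to the user.

## A worked example

```{r example, eval = FALSE}
library(allopath)

spec <- synthetic_spec(n_trajectories = 2, frames_per_trajectory = 1500)
cfg <- analysis_config(spec, spec,          # condition A vs condition B
                       plan = bootstrap_plan(10, 1000),
                       stages = c("contacts", "network", "helicity",
                                  "interface"),
                       seed = 42)
report <- run_comparison(cfg)
report$centrality[report$centrality$highlighted, ]
subset(report$interface_difference$pairs, flagged)
write_report(report, "allopath_out")
```
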