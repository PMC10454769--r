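# allopath

Detecting positive-allosteric-modulation signatures in GPCR trajectory
ensembles.

## What this is for

When a positive allosteric modulator (PAM) binds a G-protein coupled
receptor — the motivating case is a THIQ-scaffold PAM like LY3154207 at the
second intracellular loop of the dopamine D1 receptor — the structural
response is subtle and statistical rather than a visible conformational
change.  The differences between PAM-bound and PAM-free simulation
ensembles live in contact frequencies, loop helicity and network topology.
`allopath` is an R package for computational structural biologists who have
such two-condition ensembles (topology as PDB, frames as DCD or multi-model
PDB) and want the standard comparison battery with reproducible bootstrap
statistics:

* **Contact frequencies** — a residue pair is in contact when its closest
  heavy-atom distance is ≤ 4.5 Å; frequencies are estimated from bootstrap
  frame samples (default 10 × 2000 frames drawn with replacement from the
  pooled trajectories of a condition) with the across-sample standard
  deviation as uncertainty.
* **Residue-interaction network** — non-zero frequencies between residues
  with sequence separation |i − j| ≥ 2 become weighted edges; node
  importance is eigenvector centrality, the Perron vector of the weighted
  adjacency *W* (*W x = λ₁ x*), normalized to unit Euclidean norm.
  Between-condition tables report signed and absolute score differences
  and highlight |Δ| > 0.005.
* **Secondary structure** — three-state (helix/sheet/coil) assignment from
  the Kabsch–Sander backbone hydrogen-bond energy
  *E* = 27.888·(1/r₍ON₎ + 1/r₍CH₎ − 1/r₍OH₎ − 1/r₍CN₎) kcal/mol with the
  −0.5 kcal/mol bond threshold and reconstructed amide hydrogens, plus
  bootstrap helicity fractions and per-frame evolution tracks.
* **Ligand RMSD** — evolution RMSD (each frame vs. the first frame of its
  trajectory, Kabsch-aligned on a pocket/Cα selection) and sampled average
  pairwise RMSD.
* **Subsegment COM distances** — mass-weighted heavy-atom center-of-mass
  distances between named transmembrane subsegments (the 21 published D1R
  ranges ship as `d1r_subsegments()`), with between-condition difference
  tables.
* **Receptor–Gα interface maps** — the same contact machinery across
  chains, with differences ≥ 0.10 flagged.

Because the motivating study's raw trajectories are not deposited, the
package also ships a first-class synthetic generator
(`synthetic_spec()` / `generate_condition()`): a seven-helix bundle with a
Gα chain and a jittering ligand, in which helicity shifts, contact
rewiring and interface changes are *planted* with known parameters, so
every stage can be validated against ground truth.  The methods vignette
(`vignettes/allosteric-signatures.Rmd`) documents the models, numerical
choices and the generator's limits.

## Worked example

Compare the two conditions of a synthetic ensemble (condition B differs by
a planted helicity shift 0.25 → 0.85 on three loop residues, a hub contact
strengthening 0.30 → 0.80, and two interface contacts 0.30 → 0.45):

```r
library(allopath)

spec <- synthetic_spec(n_trajectories = 2, frames_per_trajectory = 1500)
cfg <- analysis_config(spec, spec,     # generated as conditions A and B
                       plan = bootstrap_plan(10, 1000),
                       stages = c("contacts", "network", "helicity",
                                  "interface"),
                       seed = 42)
report <- run_comparison(cfg)

head(report$centrality[order(-report$centrality$abs_diff), ], 5)
#>    chain resid score_1 score_2 signed_diff abs_diff highlighted
#> 43     R    43   0.181   0.124      0.0569   0.0569        TRUE
#> 41     R    41   0.173   0.117      0.0566   0.0566        TRUE
#> 42     R    42   0.181   0.125      0.0564   0.0564        TRUE
#> 39     R    39   0.155   0.100      0.0546   0.0546        TRUE
#> 64     R    64   0.151   0.205     -0.0540   0.0540        TRUE

subset(report$interface_difference$pairs, flagged)
#>     res_i res_j chain_i chain_j freq_1 freq_2 delta flagged both_conditions
#> 305    53   188       R       G  0.308  0.464 0.155    TRUE            TRUE
#> 561    57   191       R       G  0.297  0.444 0.147    TRUE            TRUE

subset(report$helicity, resid %in% 29:31)[, c("resid", "fraction_1",
                                              "fraction_2", "delta")]
#>    resid fraction_1 fraction_2 delta
#> 29    29      0.252      0.846 0.594
#> 30    30      0.252      0.846 0.594
#> 31    31      0.252      0.846 0.594
```

Reading the output: residues 39–46 sit around the planted *loss* pair, so
their centrality drops in condition B (positive signed difference, since
the sign convention is condition 1 − condition 2); residue 64 is an
endpoint of the planted *gain* pair and rises.  The two flagged interface
pairs are exactly the planted ones, with Δ ≈ 0.15, and the loop window
recovers its planted helix occupancies (0.25 vs 0.85).  `write_report()`
emits every table as CSV plus a JSON manifest; reruns with the same
configuration are byte-identical.

A thin command-line wrapper for the simulate/compare round trip lives at
`inst/cli/allopath.R`.

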