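# channelgauge

Structural analysis of ion-channel molecular-dynamics ensembles in R.

Trafficking-deficient mutants of tetrameric potassium channels such as
hERG/Kv11.1 are retained in the endoplasmic reticulum, and their
simulations show a characteristic structural phenotype: the conduction
pore collapses just beneath the selectivity filter, the intracellular
PAS and CNBD domains reorient relative to the transmembrane domain, a
linker α-helix unfolds, and linear internalization signals become
solvent-exposed. channelgauge provides the measurements needed to
quantify each of those observations on any channel ensemble, plus a
synthetic-trajectory generator with known ground truth so every
estimator is testable without microsecond simulations.

## What it computes

* **Pore-radius profile** — largest-inscribed-sphere radius ρ(z) along
  the channel axis, per frame and as mean ± SD over a trajectory, via a
  deterministic HOLE-style search (coarse grid seeded at the axis,
  hill-climb, Nelder–Mead). Negative radii report occlusion depth, so
  a collapse is visible rather than clamped to zero.
* **Superposition / RMSD / RMSF** — Kabsch fits (reflections excluded,
  mass-weighted by default), per-domain RMSD averaged over monomers,
  ligand RMSD against a docked pose (fit on protein, no ligand re-fit),
  per-residue monomer-averaged RMSF and low-RMSF anchor segments.
* **Conformational clustering** — average-linkage (UPGMA) on pairwise
  superposed RMSD of a selection (e.g. the S6 backbone), with the
  medoid Davies–Bouldin index
  DBI = (1/k) Σᵢ maxⱼ (Sᵢ+Sⱼ)/Mᵢⱼ and the explained-variance fraction
  SSR/SST; the cluster count is the smallest k that is a local DBI
  minimum where the SSR/SST gain falls below its plateau threshold.
* **Secondary structure** — simplified 3-state DSSP (Kabsch–Sander
  hydrogen-bond energies, E < −0.5 kcal/mol, amide H rebuilt when
  absent) and per-residue helix propensity with condition deltas.
* **Domain angles** — the COM–hingeCOM–COM angle of an intracellular
  domain against the TMD, per monomer and monomer-averaged, with an
  end-window drift estimator and a replica-consistency summary.
* **Motif exposure** — Shrake–Rupley SASA (golden-spiral quadrature,
  1.4 Å probe) of linear motifs, normalised by their extended-state
  SASA; the four hERG internalization signals (K21-Q25, Y54-A57,
  Y827-L830, Y845-F848) are built in.
* **Accelerated-MD dual boost** — ΔV = (E−V)²/(α+(E−V)), the modified
  potential V* = V + ΔV, the dual-boost parameterisation from
  equilibration energy means, and exponential reweighting with an
  effective-sample-size diagnostic.
* **Synthetic fixtures** — a 4-fold pseudo-atom channel realising a
  prescribed pore profile, programmable hinge drifts, helix unfolding
  and energy series, all seeded and manifest-tracked.

I/O: PDB and multi-model PDB (via bio3d), CHARMM 32-bit DCD (bio3d
reader, in-package writer), CSV energy tables, YAML pipeline configs.

## Worked example

The pipeline compares conditions end to end. Here the built-in
`collapse+hinge+unfold` preset plays the role of a trafficking-mutant
ensemble against its wildtype control (24 frames per condition):

```r
library(channelgauge)
rep <- run_pipeline(list(
  preset = "collapse+hinge+unfold", seed = 13, n_frames = 24,
  output_dir = "cg_demo",
  parameters = list(dz = 2, z_range = c(-8, 8), search_radius = 6,
                    stride = 4L, k_scan_max = 5L)))
print(rep)
#> cg_report: 2 condition(s); outputs in cg_demo
#>   condition rmsd_tmd_mean  rmsf_mean chosen_k pore_min_mean
#> 1  wildtype     0.1180818 0.08448077        5      3.391441
#> 2    mutant     0.6067183 0.78104687        5      2.140388
#>   helix_propensity_mean pas_angle_drift cnbd_angle_drift
#> 1                 0.875     -0.01723512      -0.01228598
#> 2                 0.525    -21.04589056       9.17497209
#>   interface_exposed_fraction amd_E_total
#> 1                  0.0000000   -119725.3
#> 2                  0.4583333   -118726.6
#> deltas vs wildtype :
#>   rmsd_tmd_mean rmsf_mean chosen_k pore_min_mean helix_propensity_mean
#> 1     0.4886365 0.6965661        0     -1.251053                 -0.35
#>   pas_angle_drift cnbd_angle_drift interface_exposed_fraction amd_E_total
#> 1       -21.02866         9.187258                  0.4583333    998.7407
```

Reading the deltas: the mutant's minimum pore radius is 1.25 Å
narrower than wildtype (the programmed collapse below the filter), its
PAS domain angle drifts by −21° and the CNBD angle by +9° over the run
(programmed −20°/+10° under 2° angle noise), mean helix propensity in
the linker peptide drops by 35 percentage points, and the interface
motif — buried in every wildtype frame — is exposed in 46 % of mutant
frames. Every CSV written to `output_dir` carries a provenance header
(package version, config hash, seed), and a rerun with the same config
is byte-identical.

Individual stages are plain functions (`pore_timeseries()`,
`cluster_trajectory()`, `helix_propensity()`, `angle_timeseries()`,
`motif_exposure()`, `parameterize_dual_boost()`, …); see the package
vignette for the underlying models and conventions. A thin CLI wrapper
lives at `inst/cli/channelgauge.R`.

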