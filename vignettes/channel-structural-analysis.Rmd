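---
title: "Structural analysis of channel simulation ensembles with channelgauge"
author: "channelgauge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural analysis of channel simulation ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(channelgauge)
```

## Scope and model

channelgauge analyses molecular-dynamics ensembles of tetrameric ion
channels such as hERG/Kv11.1 — a homotetramer whose monomer carries a
transmembrane domain (TMD, with the pore-lining S6 helices and the
selectivity filter) and two intracellular domains, the N-terminal PAS
domain and the C-terminal CNBD, joined to the TMD by linker hinges.
Trafficking-deficient mutants of such channels are retained in the ER,
and the structural correlates of that phenotype — pore collapse beneath
the selectivity filter, reorientation of the intracellular domains,
loss of a linker helix, and solvent exposure of internalization motifs
— are exactly the quantities this package measures.

The package deliberately stops at geometry: it quantifies pore radii,
domain angles, helicity and motif accessibility, and never claims a
causal link between those changes and ER retention.

## The analyses

### Pore-radius profile

The pore radius at height $z$ along the channel axis is the radius of
the largest sphere whose center lies in the plane normal to the axis at
$z$:
$$\rho(z) \;=\; \max_{c \,\in\, \text{plane}(z)} \; \min_i \left( \lVert c - a_i \rVert - r_i \right),$$
with $a_i, r_i$ the atom centers and van der Waals radii.  The search
is deterministic: a coarse lateral grid (0.25 Å), a hill-climb on that
grid **seeded at the axis**, then Nelder–Mead refinement.  Seeding at
the axis matters: the global maximum over a 10 Å window around a finite
channel wall almost always lies *outside* the wall, so the sphere must
be grown inside the lumen's own basin, as the classic pore-tracing
programs do.  Three outcomes are distinguished:

* `ok` — an interior optimum; the reported radius may be *negative*
  (occlusion depth) when the lumen is collapsed, which preserves the
  collapse signal instead of clamping it to zero;
* `open` — no wall within reach; the radius is capped at the lateral
  search radius (default 10 Å);
* `escaped` — the optimum ran to the window boundary, i.e. the wall
  does not enclose this height; the on-axis occlusion value is
  reported.

Per-trajectory output is the per-frame radius stack with its mean and
standard deviation over frames at each $z$, plus the per-frame minimum
radius (optionally restricted to a window, e.g. just beneath the
selectivity filter).

A geometric point worth stating explicitly: the inscribed-sphere
profile of a ring stack with radii $R(z_k)$ is the *erosion*
$\min_k \sqrt{R(z_k)^2 + (z_k - z)^2} - r$, not $R(z) - r$.  For a
cylinder the two coincide; near a narrow waist they cannot — a sphere
whose radius exceeds the waist curvature radius spans the waist
shoulders.  The test suite therefore validates the profiler against
the exact erosion of its fixtures, with the naive target asserted only
where the wall is locally flat.

### Superposition, RMSD, RMSF

Rigid-body fits use the Kabsch SVD solution with reflections excluded
and mass weighting by default (a flag switches to uniform weights).
Per-frame RMSD separates the *fit* selection from the *measure*
selection, which directly supports the ligand-drift measurement: fit
on the protein, measure on the ligand with no re-fit, so a ligand
riding rigidly with the protein scores zero.  Per-domain RMSD is run
chain-by-chain and averaged over the four monomers.

RMSF is computed against the time-average structure (one alignment
pass to frame 1, then one refinement pass against the mean), per
residue as the RMS deviation of the residue's backbone centroid, and
averaged across monomers on their shared residue numbering.
Low-RMSF anchor segments — used to superpose representative
conformations without letting mobile loops dominate — are the lowest
quantile of residues (ties broken by residue order) filtered to
contiguous runs of at least 5 residues.

### Conformational clustering

Frames are clustered on the pairwise superposed-RMSD matrix of a
selection (for a channel, the S6 backbone: Cα, C, N, O) with
unweighted average linkage (UPGMA), ties broken by the
lexicographically smallest pair of cluster labels so results are
bit-reproducible.  RMSD space has no coordinates, so cluster quality
uses medoid formulations: the Davies–Bouldin index
$\mathrm{DBI} = \tfrac1k \sum_i \max_{j \ne i} (S_i + S_j)/M_{ij}$
with $S_i$ the mean member–medoid distance and $M_{ij}$ the
medoid–medoid distance, and the explained-variance fraction
SSR/SST computed from pairwise distances
($\mathrm{SST} = \sum_{\text{pairs}} d^2/n$, SSE its within-cluster
analogue with per-cluster normalisation).

The cluster count is chosen in two stages, mirroring common practice
with MD ensembles: a scan (default 2 to min(100, n−1)) records DBI and
SSR/SST per k, and the chosen k is the smallest that is simultaneously
a local DBI minimum and at which the SSR/SST gain to the next k falls
below a plateau threshold (0.01 absolute, a documented convention —
the elbow is visual in most published work).  The full trace is
returned so a custom k can be imposed per system.  A frame stride
(default 10) keeps the O(n²) matrix tractable; the stride is recorded
in the output.

### Secondary structure and helix propensity

A simplified 3-state DSSP: backbone amide hydrogens are rebuilt
(1.01 Å from N, anti to the C(prev)–N/Cα–N bisector, none on prolines
or chain starts), hydrogen bonds scored with the Kabsch–Sander
electrostatic model
$E = 0.084 \cdot 332 \, (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol, bond if $E < -0.5$, clashes clamped to −9.9.  A residue is
helical when $i{-}1 \to i{+}3$ and $i \to i{+}4$ turns both exist (two
consecutive α-turns, the minimal helix); isolated bridge patterns give
`E`; everything else, including 3₁₀/π geometries, folds into `C` since
only α-helix propensity is reported.  Helix propensity is the fraction
of frames a residue is assigned `H`; condition differences are taken
per residue and as domain means.  Note a practical consequence of the
$i \to i{+}4$ context: unfolding a segment suppresses helicity up to 4
residues beyond the segment boundary, so localization tests allow that
halo.

### Domain angles

The descriptor for intracellular-domain orientation is the angle at
the hinge center of mass between the vectors to the domain COM and to
the TMD COM, in degrees, clamped arccos.  By default each monomer's
angle uses that monomer's own TMD atoms (a flag switches to the
tetramer TMD COM); the monomer-averaged series is reported alongside.
Drift is the mean over the last 10 % of frames minus the mean over the
first 10 % — windows are configurable.  A replica-consistency helper
reports per-replica drifts and their maximum pairwise deviation.

### Motif exposure

Shrake–Rupley SASA with a deterministic golden-spiral quadrature
(default 92 points; quadrature error is about 1 % per atom and mostly
cancels in sums) and a 1.4 Å water probe.  A linear motif's exposure
is its residues' summed SASA normalised by the same residues' SASA in
a generated extended conformation — this keeps sequence context, which
a Gly-X-Gly normalisation would discard — and a frame counts as
exposed above a 0.25 relative threshold, a documented convention since
no quantitative criterion is established for these signals.  The four
hERG internalization signals (K21-Q25 KFERQ-related; Y54-A57,
Y827-L830, Y845-F848 tyrosine-based) ship as built-in definitions.

### Accelerated-MD dual boost

The boost potential is
$\Delta V = (E - V)^2 / (\alpha + (E - V))$ for $V < E$, else 0, so
$0 \le \Delta V \le E - V$, $V^* = V + \Delta V$ is continuous and
non-decreasing and approaches $E$ from below as $\alpha \to 0$.  Dual
boost parameters come from equilibration energy means:
$E_{dih} = \langle V_{dih}\rangle + a\,n_{res}$,
$\alpha_{dih} = a\,n_{res}/5$,
$E_{tot} = \langle V_{tot}\rangle + b\,n_{atoms}$,
$\alpha_{tot} = b\,n_{atoms}$, with $a = 3.5$ kcal/mol/residue and
$b = 0.16$ kcal/mol/atom as explicit, logged recipe constants — the
standard dual-boost choices, configurable because published studies
frequently defer their exact values to supplements.  Exponential
reweighting with $w \propto e^{\Delta V / k_B T}$ (max-subtracted) and
an effective-sample-size diagnostic is provided; reweighted ensembles
are a companion tool, not a default, since boosted ensembles are often
reported unreweighted.

## The synthetic-data generator

Every stage is validated against generated fixtures whose ground truth
is recorded in a manifest, because no deposited trajectories exist for
this kind of study and microsecond ensembles cannot be regenerated at
desk scale.  The generator emulates the *statistical and geometric
structure* each estimator assumes, not the physics:

* a 4-fold symmetric pseudo-atom channel whose pore rings realise a
  prescribed radius profile (atom centers on rings of radius $R(z)$,
  uniform vdW 1.5 Å), with PAS-like, CNBD-like and hinge blobs at
  prescribed centers of mass, and three planted 5-residue motifs per
  monomer: surface, buried (inside the PAS shell), and interface
  (facing a static occluder plate it slides off when the hinge
  swings);
* motion schedules with exact realisation: pore constriction below a
  marked z (ring radii rescaled), hinge-angle drift (each blob rotated
  in its hinge's rotation plane so the programmed angle is realised
  exactly, with optional Gaussian angle noise), helix unfolding (a
  real-backbone peptide whose segment torsions are randomised in
  flagged frames), plus i.i.d. isotropic Gaussian coordinate noise;
* Gaussian energy series for the dual-boost recipe.

Drift schedules use a smoothstep ramp that plateaus over the first and
last 20 % of frames.  This is a deliberate choice: the drift estimator
compares 10 % end windows, and a ramp still moving inside those
windows would make "the programmed drift" ill-defined (a linear ramp
yields 0.9 of the programmed value).  The plateau mimics a system that
has settled into its start and end states, which is also how such
angle changes present in converged simulations.  The step ramp
(switch at half time) exists for exposure-fraction tests where the
crossing frame must be exact.

Default condition parameters mirror the trafficking-mutant phenotype
structurally: −20° PAS drift, +10° CNBD drift with 2° angle noise,
pore constriction to half radius below z = 8, a 25-residue linker
segment unfolded in half the frames, 0.05 Å thermal noise, 0.01 ns
frame interval.  What passing these tests shows is that the estimators
recover known geometry and known mixtures at the stated tolerances; it
does not show force-field realism, solvent effects, correlated
dynamics, or that real channels move this way.

## Numerical choices and degenerate inputs

* Coordinates are Å throughout; residue ranges are 1-based inclusive.
  vdW radii are the Bondi set (C 1.70, N 1.55, O 1.52, S 1.80,
  H 1.20 Å) from a packaged, replaceable table; the element is taken
  from the PDB element column or inferred from the atom name, and an
  unknown element is an error naming the atom.
* Alternate locations collapse to the highest-occupancy copy; duplicate
  (chain, residue, name) identities are an error.
* Collinear point sets make the Kabsch rotation non-unique and are
  rejected; fits need at least 3 points.
* The pore search is seed-free (grid + simplex, no annealing); slices
  are independent, continuity is not enforced.
* UPGMA ties break on the smallest label pair; medoid ties on the
  lowest frame index; coincident medoids are a "degenerate clusters"
  error rather than an Inf ratio.
* Angle vertices closer than 1e-6 Å are a "degenerate angle" error.
* DCD is written in the CHARMM 32-bit dialect; coordinates quantise to
  float32 on the first write and are bit-stable thereafter.  Multi-model
  PDB is the canonical text dialect (MODEL/ENDMDL per frame, 1e-3 Å
  precision).
* All generator randomness flows from one integer seed, and the
  generators restore the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script run on sizes chosen to
exercise every code path while staying desk-sized: channels of ~1,600
pseudo-atoms, trajectories of 24–1,000 frames (1,000 for drift
recovery, where the estimator variance at 2° noise requires it),
20-seed repetition for recovery-rate claims, pairwise-RMSD matrices up
to ~60 frames, and 92–960 SASA points.  The full two-condition
pipeline on the combined preset runs in about half a minute per
condition pair.

## Known limitations

* The 3-state SS assignment matches full DSSP at the level of helix
  trends, not per-residue codes; π- and 3₁₀-helices are reported as
  coil.
* The per-slice pore search constrains the sphere center to the slice
  plane (no 3-D relaxation) and reports basin-local optima by design;
  a pore whose lumen wanders more than the search radius off-axis
  needs an explicit axis definition from COM anchors.
* Monomer averaging assumes the chains share residue numbering;
  mismatches fall back to the residue-id intersection.
* Domain, hinge and motif residue ranges are configuration, not
  constants: published channel studies rarely print their exact
  boundaries, so defaults exist only for the synthetic system.
* The pipeline's comparison report subtracts summary scalars between
  conditions; it performs no statistical testing across replicas —
  replica_consistency() is a descriptive helper, not an inference
  tool.
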