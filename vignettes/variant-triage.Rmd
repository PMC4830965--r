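---
title: "Structural triage of membrane receptor variants: models and methods"
author: "gpcrTriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural triage of membrane receptor variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrTriage)
```

## The problem

Non-synonymous variants of membrane receptors such as the β2-adrenergic
receptor (β2AR, a class-A GPCR with seven transmembrane helices) can shift
receptor behaviour anywhere from constitutive activation to loss of ligand
binding. Molecular-dynamics trajectories of a wildtype receptor, a panel of
variants and a negative control carry the structural signatures of those
shifts, but the signatures live in very different observables: backbone
stability of the transmembrane (TM) bundle, a single side-chain torsion, the
shape of the surrounding lipid bilayer, the open volume of the ligand
pocket, and the water content around the mutated site. `gpcrTriage`
computes each of those observables from a trajectory and combines them into
an explicit, reproducible triage label per variant.

All internal units are nm, ns and degrees. PDB input/output converts
Angstrom at the boundary; the baseline trajectory format is multi-model PDB
so the whole pipeline is testable without any binary-format dependency.
Orthorhombic periodic boxes only; triclinic input is rejected with a clear
error. Residue numbers are preserved verbatim from the input — the pipeline
speaks receptor numbering (286, 290, 320, ...) throughout.

## The observables

### TM backbone RMSD

Per frame, the TM backbone (N, CA, C, O of the annotated helix ranges; a
CA-only option exists) is superposed onto a reference structure by the
Kabsch algorithm — SVD of the covariance matrix with the determinant
correction that excludes reflections — and the post-fit RMSD is reported.
The helix ranges are configuration inputs: crystal-structure helix
annotations differ slightly between depositions, so the package does not
hard-code them; the synthetic systems carry their own annotation.

### The chi1 rotamer toggle switch

The chi1 torsion of the conserved TM6 tryptophan (residue 6.48 in
Ballesteros–Weinstein numbering) is defined by the atoms N–CA–CB–CG, IUPAC
sign convention, range (−180, 180]. Rotamer states use the standard
three-state windows: `trans` for |chi1| ≥ 120°, `gauche−` for (−120, 0),
`gauche+` for [0, 120). The literature never states window bounds for this
switch, so the conventional ±120° bounds are adopted and are overridable;
ties at exactly ±120° go to `trans`, a documented tie-break chosen for
reproducibility. A *flip event* is a state change that persists for at
least `minDwell` frames (default 5): the dwell criterion operationalises
"transient flip" against single-frame jitter, and event counts are
monotone non-increasing in `minDwell` (a tested invariant).

### Ballesteros–Weinstein numbering

Label `h.nn` where the most conserved residue of helix `h` is `h.50` and
other residues are numbered by sequence offset from the anchor. With the
canonical class-A anchors (helix-6 anchor 288, helix-7 anchor 323) residues
286, 290 and 326 map to 6.48, 6.52 and 7.53.

### Bilayer thickness maps

Thickness is measured between the phosphorus atoms of the two leaflets'
headgroups: per frame, phosphates are wrapped into the primary box and
binned on an xy grid (default spacing 0.2 nm); a cell's thickness that
frame is the mean upper-phosphate z minus the mean lower-phosphate z,
counted only when both leaflets contribute; the map is the frame average.
Cells that never see both leaflets are reported as undefined (`NA`), never
zero-filled or interpolated — interpolation would silently manufacture
thickness under the protein footprint where no lipid sits. Leaflet
assignment is per frame (midplane = mean phosphate z, ties to upper), so
pathological flip-flop is representable. Map differencing is cellwise and
propagates undefined cells.

### Headgroup perturbation profiles

Every lipid whose phosphate comes within a cutoff (default 0.6 nm) of any
atom of a target residue in at least one frame is tracked; the profile
reports its time-averaged phosphate position and its mean signed
z-displacement from its leaflet's mean phosphate plane, with negative
meaning pulled toward the membrane core for either leaflet. This is the
readout for a polar or charged side chain dragging a phosphate inward.

One bias is worth knowing: the displaced lipid itself contributes to its
leaflet's mean plane, so a programmed displacement `d` on one of `n`
leaflet lipids is estimated as `d·(1 − 1/n)` (−0.48 nm for −0.5 nm at
n = 32). The recovery tolerance in the tests (±0.05 nm) accounts for this;
at realistic leaflet sizes the bias is negligible.

### Binding-pocket volume

Pocket residues are defined once, on a reference structure containing a
bound ligand, as all protein residues with a heavy atom within 0.7 nm of a
ligand heavy atom (minimum image). Volume tracking is grid-void detection
rather than Voronoi/alpha-sphere machinery — an equivalent-purpose method
whose correctness is pinned by an analytic fixture. Per frame: the frame is
superposed onto the reference on pocket heavy atoms; a shared voxel grid
(default 0.08 nm, probe 0.14 nm) covers the reference pocket bounding box;
voxels within vdW + probe of any heavy atom are occluded (Bondi radii,
user-overridable); free voxels outside the convex hull of the pocket atom
centres are discarded; and only the 6-connected component containing the
pocket seed (pocket CA centroid, or the nearest free voxel within 0.3 nm)
is counted. An occluded seed yields volume 0 with a warning, not an error.

Hull membership is computed with a supporting-halfspace test over a fixed
set of 162 quasi-uniform sphere directions. This is an outer approximation
of the true hull — a point passing every halfspace test can lie slightly
outside the hull near a vertex — but the error is bounded by the support
gaps between adjacent directions and is far below the voxel discretisation
error; the hollow-shell test (analytic sphere volume, 2% observed error at
0.05 nm voxels, 5% tolerance) bounds the combined effect. The grid is
shared across frames after superposition, so the volume series is invariant
under rigid motion of the input frames (tested explicitly).

### Hydration

Waters are counted by their oxygen atom within 0.8 nm of the residue's CA
under the minimum image — counting by oxygen rather than any-atom is a
documented choice; with single-site water models they coincide. The count
is integer-exact against a 27-image brute force (tested on every frame of
a wrapped fixture).

## The synthetic generator

There is no public benchmark trajectory for this pipeline, so the package
ships a deterministic generator whose every signal is known exactly:

* **Protein** — seven ideal α-helices (rise 0.15 nm/residue, 100°/residue
  twist, radius 0.23 nm: textbook helix geometry, giving realistic CA
  spacing for RMSD and dihedral work) arranged as a bundle, 50 residues per
  helix so that receptor numbering puts residue 286 (and 290) in helix 6
  and 323/326 in helix 7. The probe residue carries CB/CG placed by
  internal-coordinate construction so its chi1 equals the scheduled value
  exactly.
* **Bilayer** — two leaflet lattices of 3-bead lipid pseudo-molecules
  (choline bead, phosphate `P`, tail bead) at ±1.9 nm. Only the phosphate
  position enters any analysis, so richer lipid models would add nothing
  testable.
* **Waters** — single `OW` atoms in two slabs, placed from the config seed.
* **Programmable signals** — per-frame chi1 schedule; cumulative
  random-walk backbone drift; a static Gaussian thickness modulation split
  half-and-half between the leaflets; a single-lipid z-pull after an onset
  frame; per-helix radial displacement (to enlarge the pocket on one side);
  isotropic i.i.d. Gaussian positional noise per atom per frame. The noise
  model is deliberately memory-free: under it the analytic RMSD expectation
  (σ√3 for the fitted backbone) is exact, which the tests exploit.
* **Determinism** — a single RNG stream seeded from the config, consumed in
  documented order (per frame: drift, then noise, atom-major). Identical
  (seed, config) pairs give bit-identical trajectories, and byte-identical
  TSVs after format rounding.

What the generator does *not* emulate: correlated thermal motion, lipid
diffusion and exchange, water structure, side chains beyond the probe, or
force-field energetics. Passing the closure tests therefore demonstrates
that the *estimators* are correct and unbiased at known signal-to-noise,
not that any particular biological variant behaves as programmed. Problem
sizes in the test suite (16–128 lipids per leaflet, 20–150 frames, 20-seed
repetitions) were chosen as the smallest systems in which every programmed
signal is comfortably above the noise floor of its estimator.

## Triage

Per system (wildtype, negative control, variants), replicate trajectories
are pooled: means, per-frame SDs, and between-replicate SDs (undefined for
a single replicate, by contract). Five flags compare a variant with the
wildtype:

* `flip_observed` — flips in a majority of variant replicates and none in
  any wildtype replicate;
* `elevated_rmsd` — variant mean RMSD above wildtype mean + max(k·SD,
  floor);
* `pocket_enlarged`, `hydration_changed` — analogous mean comparisons with
  their own floors;
* `membrane_perturbed` — max |thickness difference| vs the wildtype map or
  max |headgroup displacement| above absolute thresholds.

`k` defaults to 2; the absolute floors (0.02 nm RMSD, 0.05 nm³ volume,
2 waters, 0.1 nm thickness, 0.2 nm headgroup) keep a zero-variance
wildtype from flagging on numerical noise. The label is a pure function of
the flags: *activating-candidate* when the toggle-switch flip is seen
without pocket/hydration/membrane damage; *neutral-like* when nothing is
flagged (the negative-control contract — a supplied control is itself
triaged and a warning is raised if it fails it); *damaging-candidate*
otherwise. Raising any threshold can only clear flags, never set them, so
neutral-like is stable under threshold increases (a tested invariant).
The published judgements this mirrors are narrative, not formulaic; the
flag definitions above are this package's explicit operationalisation, with
every threshold exposed in configuration, and are not claimed to reproduce
any particular narrative call. The report schema reserves fields for
externally computed binding free energies so they can be merged and clearly
marked as external inputs.

## Worked example

```{r example, eval = FALSE}
library(gpcrTriage)

wtCfg <- generatorConfig(seed = 1, n_frames = 100, noise_sigma = 0.01)
vCfg  <- generatorConfig(seed = 2, n_frames = 100, noise_sigma = 0.01,
                         chi1_schedule = list(
                           list(frames = c(1, 50),  angle = -60),
                           list(frames = c(51, 100), angle = 180)))

wt <- buildSystem(wtCfg)
trWT <- generateTrajectory(wt, wtCfg)$trajectory
trV  <- generateTrajectory(buildSystem(vCfg), vCfg)$trajectory

summWT <- summarizeMetrics("wildtype",
                           list(analyzeTrajectory(trWT, hydrationResid = 326)))
summV  <- summarizeMetrics("F290S-like",
                           list(analyzeTrajectory(trV, hydrationResid = 326)))
triageVariant(summV, summWT)
```

## Numerical choices and degenerate inputs

* Kabsch refuses fewer than 3 points or collinear clouds (singular
  covariance) with a geometry error.
* `detectFlips` treats a sub-dwell excursion as noise even when it visits a
  third state; events carry the last old-state frame and first new-state
  frame.
* Thickness cells falling outside the grid after wrapping are clamped to
  the edge cell (can only occur through floating-point edge cases).
* PDB serials above 99,999 wrap modulo 100,000 on output — the documented
  dialect rule for oversized systems.
* The chi1 value at exactly ±180° is reported as the (−180, 180] member;
  angle comparisons in the tests are circular.
* Empty atom selections are legal everywhere and yield empty results, not
  errors; an empty *pocket definition* is an error, because a volume with
  no enclosing residues is meaningless.

## Known limitations

Triclinic boxes, chi2+ dihedrals, secondary-structure assignment, lipid
order parameters/area-per-lipid/curvature, pocket druggability scoring and
binding free energies are out of scope. Binary trajectory formats are not
read; convert to multi-model PDB upstream. The thickness estimator averages
per trajectory; averaging maps across replicates is a separate explicit
step (`thicknessDifference` on per-replicate maps, or pooling upstream), so
whether replicate averaging happens before or after gridding is the user's
choice and is documented per analysis.
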