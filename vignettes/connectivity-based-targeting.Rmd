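---
title: "Connectivity-based thalamic targeting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based thalamic targeting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalatrack)
```

## The problem

Stereotactic neurosurgery for tremor targets small thalamic nuclei — the
posteroventral ventro-lateral nucleus (VLpv, the Vim target) and, as a
"no-go" region, the posterior ventral-posterolateral nucleus (VPLp) — that
are nearly invisible on structural MRI. Probabilistic diffusion
tractography offers an indirect route: seed the whole thalamus, count for
every seed voxel how many stochastic streamlines reach a remote cortical
territory, and threshold the resulting connectivity map to obtain a
*connectivity-based target* (CBT). The same machinery, with ordered
way-point filtering, reconstructs the cerebello-thalamic tract (CTT) from
the contralateral dentate nucleus through the superior cerebellar peduncle
and past the red nucleus into the thalamus.

Two questions decide whether such targets are clinically usable: how well
they agree with histology-derived atlas volumes, and how reproducible they
are — across subjects, and across MRI scanners of different vendors. This
package implements the full evaluation pipeline and exercises it on
synthetic multi-subject, multi-scanner phantoms, so every property of the
pipeline can be tested against analytic ground truth without any real MRI
data.

## Pipeline overview

1. **Phantom** (`generate_phantom_set()`): a mirror-symmetric label volume
   (thalami with VLpv/VPLp-like nuclei, cortical target slabs, cerebellum
   with dentate, SCP, red nucleus) plus per-voxel fiber orientation fields
   realizing thalamocortical bundles and a decussating cerebello-thalamic
   arc. Subjects differ by a smooth random warp, scanners by added
   orientation dispersion and a systematic direction tilt.
2. **Orientation model** (`fit_tensor()`, `compute_fa()`,
   `sample_orientation()`): log-linear tensor fits, fractional anisotropy,
   and a Watson-type parametric sampler standing in for a Bayesian
   multi-fiber posterior.
3. **Tracking** (`track_seed_mask()`, `track_waypoint_tract()`):
   probabilistic streamline propagation with loop, curvature and mask
   termination rules; back-projected per-seed-voxel counters; waytotal
   normalization; ordered way-point filtering for the CTT.
4. **Evaluation** (`percentile_threshold()`, `dice()`, `cog_distance()`,
   `sweep_thresholds()`): CBTs at percentile thresholds of the non-zero
   map values, swept over the 50th–100th percentiles against atlas
   targets.
5. **Threshold optimization** (`optimize_all()`): the optimal percentile
   per target and hemisphere maximizes the product of the median
   inter-subject overlap and the median atlas overlap.
6. **Reproducibility** (`pairwise_dice()`, `decompose_variability()`,
   `ctt_reproducibility()`): pairwise Dice between all (subject, scanner)
   units, tagged within-subject/inter-scanner versus
   inter-subject/within-scanner, group means compared by a Welch test
   (permutation alternative available); the CTT is analysed inside a 40 mm
   slab around the AC-PC plane at a fixed 90th-percentile cut.

## Models and assumptions

**Orientation sampling.** Each voxel carries up to two fiber populations
with mean axes, volume fractions, and a shared Watson concentration
$\kappa$; a tracking step samples an axis from the axial density
$p(x) \propto \exp(\kappa\,(\mu^\top x)^2)$ and sign-aligns it with the
previous step (on the first step, with the stored field polarity). This
parametric stand-in preserves the stochastic-orientation contract of
Bayesian multi-fiber trackers at a tiny fraction of their cost; it does
not model fanning asymmetry or more than two populations. The sampler uses
a rejection scheme (exponential proposal in $t=\mu^\top x$, acceptance
$\exp(\kappa(t^2-t))$) whose acceptance rate never falls below about one
half; $\kappa = \infty$ short-circuits to the mean axis, giving
deterministic limit fields for oracle tests. When a field is derived from
a tensor fit rather than the phantom, $\kappa$ is taken proportional to
the tensor linearity, $\kappa = 50\,(\lambda_1-\lambda_2)/\lambda_1$ — a
tuning choice exposed as `kappa_scale`.

**Signal model.** Simulated DWI follows the monoexponential
Stejskal–Tanner form $S = S_0 \exp(-b\,g^\top D g)$ with a prolate tensor
($\lambda_\parallel = 1.7\times10^{-3}$,
$\lambda_\perp = 3\times10^{-4}\,\mathrm{mm^2/s}$) inside bundles and an
isotropic $8\times10^{-4}\,\mathrm{mm^2/s}$ elsewhere; 1 unweighted plus
32 weighted volumes at $b = 1000\,\mathrm{s/mm^2}$ by default, matching a
clinical 32-direction protocol. The tensor fit is exact on noise-free
data, which the acceptance suite verifies to $10^{-6}$ relative error.

**Tracking rules.** A sample is credited to the *first* target mask it
enters and then terminated, so a multi-target run (precentral + SMA +
cerebellum for the VLpv intent) never double-counts. Loops are forbidden
literally: re-entering any voxel already visited by the same streamline
terminates it (consecutive steps inside one voxel are not a revisit).
Because the orientation model is axial, a literal 180° reversal is
indistinguishable from no turn after sign alignment; the curvature rule
therefore acts on the post-alignment angle, and any turn sharper than the
limit (default 80°) terminates the sample. Orientation lookup is
nearest-neighbour in voxel space, avoiding interpolation across the
antipodal ambiguity. Tracking runs in the phantom's native space; all
spaces coincide by construction.

**Waytotal.** One global waytotal per run (the total number of samples
that reached any target) divides the counters. Whether the original
protocol used a global or per-target count is not documented; the global
choice is used and, because percentile thresholds are scale-free, CBTs
are provably identical either way — a property the acceptance suite
asserts on random maps.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `samples_per_seed_voxel` | 5000 | – | study protocol; `run_study()` uses 200 for phantom-scale experiments |
| `step_mm` | half the smallest voxel | mm | standard probabilistic-tracker default |
| `curvature_limit_deg` | 80 | deg | permissive cortical-tracking default |
| `max_steps` | 2000 | – | several brain lengths at default step |
| `subject_displacement_mm` | 2 | mm RMS | residual anatomical variability after nonlinear normalization |
| `scanner_dispersion_delta` | 20 per step | – | reduces bundle $\kappa$ 60→20 on scanner 3; with the tilt, a strong plausible vendor effect |
| `tilt_base` | 2000 | – | tilt amplitude $\sqrt{\delta/\mathrm{tilt\_base}}$: ~6–8° at default deltas |
| `kappa_bundle` / `kappa_background` | 60 / 4 | – | tight bundles over a diffuse background |
| percentile grid | 50–100, step 1 | percentile | the full evaluated threshold range |
| CTT percentile / slab | 90 / ±20 | percentile / mm | fixed tract cut inside the 40 mm AC-PC slab |

## What the phantom emulates — and what it does not

The phantom reproduces the *statistical design* of a multi-vendor
test–retest study: four subjects by three scanners by default, co-registered
in one space. Subject warps are sums of three low-frequency transverse
(divergence-free) sinusoidal displacement fields with subject-specific
phases and orientations, scaled to a requested RMS; being
volume-preserving in the continuum, and with regions re-painted at
constant voxel count, label volumes are conserved across subjects.
Scanner effects combine a dispersion increase (lower $\kappa$) with a
systematic per-scanner direction tilt shared by all subjects scanned on
that scanner — a vendor bias — plus multiplicative signal noise in
simulated DWI. Left and right hemispheres are built mirror-symmetric; the
hemispheric asymmetries seen in vivo are deliberately not emulated.

Passing tests on this phantom demonstrate that the *pipeline* is correct
(metrics match brute-force oracles, the tracker follows analytic
centerlines, the optimizer recovers constructed optima, the decomposition
recovers a known generative asymmetry and stays calibrated under
exchangeable noise). They do not certify performance on real data: the
phantom has no susceptibility distortion, eddy currents, registration
error, partial-volume crossing anatomy, or realistic Rician noise. Two
visible consequences: the phantom's connectivity falls off less gradually
than in vivo maps, so consensus optima land near the lower end of the
percentile grid rather than the 76th–90th percentiles seen on real data;
and the default scanner effect, though strong, still produces somewhat
less CBT variability than the subject warp, whereas real multi-vendor
data showed the two comparable.

## Numerical choices and degenerate inputs

- Percentile cutoffs use the type-7 (linear-interpolation) quantile of
  the *strictly positive* values, retention rule `value >= cutoff`. The
  definition makes thresholds exactly invariant under positive scaling.
- Consensus ties resolve toward the *lowest* percentile — the more
  inclusive, safer-to-review volume.
- CBT centres of gravity are intensity-weighted over surviving voxels
  (the source-map values are retained at thresholding time); atlas
  centroids are binary. Both switchable via `weighted`.
- Degenerate (empty) CBTs are flagged, excluded pair-wise, and counted —
  never silently dropped; an all-zero map is an error at thresholding and
  a warning at waytotal normalization.
- The slab restriction for the CTT is applied *before* thresholding;
  the reverse order would let high connectivity outside the slab set the
  cutoff, and a dedicated test pins the order.
- All tracking randomness comes from a counter-based splitmix64 stream
  keyed by (master seed, seed voxel, sample, draw), so runs are
  bit-reproducible across platforms and independent of R's RNG state.
  Phantom-level randomness uses hierarchical sub-seeds (subject streams,
  scanner streams) so adding a scanner never changes existing subjects.

## Statistical design choices

Group means are compared with a two-sided Welch two-sample t-test on the
pairwise Dice values, the natural reading of a reported group-difference
p-value. Pairwise Dice values sharing a unit are not independent, which
the t-test ignores; `decompose_variability(test = "permutation")`
therefore offers a permutation test that permutes *unit* labels (10,000
permutations by default in spirit, 2000 by default here for speed, both
seeded) and so preserves the dependence structure. Calibration
experiments use `simulate_cbt_units()`, a light-weight generator of
spherical CBTs displaced by subject effects, scanner effects and
independent scan noise; with both systematic effects at zero the units
are exchangeable, giving an honest null. Under that null the Welch test's
empirical type-I rate sits near (slightly below) the nominal 5% in the
acceptance experiment. "Crossed" pairs (different subject *and* different
scanner) enter only the overall mean, matching the three-column
reproducibility table structure. Pairwise overlaps are pooled across
scanner replicates before taking medians in the inter-subject curve; the
alternative (per-scanner curves, then medians) was not chosen because the
pooled version uses all replicates symmetrically.

## Problem sizes used by the test and acceptance suites

Chosen as the package's own scaling of the experiments: metric oracles
run on 1000 random volumes at up to $16^3$ voxels; tracker-limit checks
use deterministic tube and 60°-arc fields at 1 mm resolution (the Euler
drift over a 60° arc stays comfortably under one step); the
reproducibility recovery experiment uses 20 replicate phantoms of
6 subjects × 3 scanners at $32\times36\times32$ voxels with 100 samples
per seed voxel; type-I calibration uses 200 replicates of the
exchangeable unit simulator; and the end-to-end determinism check runs
the full default study twice at 200 samples per seed voxel.

## Known limitations

- The Watson single-$\kappa$ model cannot represent fanning or three-way
  crossings; crossing voxels carry at most two populations at fixed 0.5
  fractions.
- The consensus optimum is only meaningful when at least two subjects per
  intent and side are present; groups below that are skipped with a
  warning.
- The phantom's scanner effect acts on orientations only (plus DWI
  noise); real inter-scanner variability also includes distortion and
  fat-suppression differences that are out of scope here.
- p-values from the Welch test inherit the pair-dependence caveat above;
  for small designs prefer the permutation variant.
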