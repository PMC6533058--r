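---
title: "Methods and design choices in kinlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in kinlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinlink)
```

kinlink bundles four analyses used to dissect how the kinesin-1 neck linker
couples nucleotide state to force generation and transport: masked ensemble
difference distance matrices (eDDM), invariant-core principal component
analysis of C-alpha coordinates, single-molecule motility/trap statistics,
and radial quantification of cargo dispersion in cells. This vignette
documents the models behind each, the parameters that matter, the numerical
conventions, and what the synthetic-data generators do and do not emulate.

## Masked ensemble difference distance matrices

**Model.** For each conformation, the residue-pair distance is the minimum
Euclidean distance over all heavy-atom pairs (hydrogens excluded). Raw
distances `x` are transformed with a smooth saturating mask with break
points `c1` and `c2` (defaults 4 Å and 8 Å):

- `x` itself for `x ≤ c1`,
- `c1 + (2(c2−c1)/π)·cos((π/2)(c2−x)/(c2−c1))` for `c1 < x ≤ c2`,
- the cap `c1 + 2(c2−c1)/π ≈ 6.546` Å beyond `c2`.

The mask is continuous with a continuous first derivative at both break
points (the ramp's slope is 1 at `c1` and 0 at `c2`), monotone, and
1-Lipschitz. Its purpose is statistical: residue pairs that are far apart in
both states fluctuate by many Å without any change in contact, and the mask
collapses those fluctuations onto the cap so that only contact-range
rearrangements — pairs crossing the 4–8 Å band — can produce a large mean
difference.

**Test.** Per pair, the masked samples of the two states are compared with a
two-sided two-sample Wilcoxon rank-sum test with normal approximation and
tie correction. The frames of the two states are unpaired ensembles (there
is no frame-to-frame correspondence between, say, apo and ATP-bound
replicates), so the rank-sum form is the defensible reading of "Wilcoxon"
here; a signed-rank test would require a pairing that does not exist. Pairs
whose masked values are fully tied across both states (both saturated at the
cap, a common case) carry no evidence and are assigned p = 1.

**Significance rule.** A pair is flagged when `p < alpha` (default 0.05)
**and** the absolute masked mean difference exceeds `min_diff` (default
1 Å). The masked difference is the difference of per-state masked means —
the only well-defined "average difference" for unpaired ensembles. No
multiple-testing correction is applied by default, matching the raw-p
convention of eDDM practice; `p_adjust = "BH"` is available. All `i < j`
pairs are tested, sequence neighbours included; callers who want to drop
short-range pairs can filter the pair table before or after.

**Caveats.** Frames are treated as independent observations. MD frames are
autocorrelated, so nominal p-values on real trajectories are optimistic;
the 1 Å effect-size gate is what keeps the flagged set meaningful. Handling
autocorrelation (e.g. effective sample sizes) is out of scope and should be
kept in mind when interpreting borderline pairs.

## Frame subsampling

Ensembles are reduced to `n_frames` per replicate (default 100) taken at
equal time spacing over the trailing `window_ns` (default 20 ns) of each
replicate: target times `t_end − window + k·window/(n−1)` are each mapped
to the nearest stored frame. Nearest-time mapping (rather than a fixed
stride or interpolation) was chosen because it is deterministic, exact when
frames are evenly saved, and well-defined when they are not; two targets
resolving to the same stored frame is treated as an error rather than
silently duplicating frames. The span precondition tolerates half a target
spacing so that subsampling is idempotent. With four replicates the pooled
per-state ensemble holds 400 conformations, the scale at which the default
thresholds were calibrated.

## Invariant-core PCA

Conformations are rigidly superposed (Kabsch/SVD, rotation determinant
forced to +1 so reflections can never occur) onto the C-alpha atoms of an
invariant core — for kinesin motor domains, the structurally stable
elements β1, β2, β3, P-loop, α2, β6, β7 and α6. The core and the analysis
selection (the equivalent, non-gap positions across a structure set) are
supplied explicitly as residue ordinals and a per-structure mapping, not
computed by internal alignment: that keeps the module deterministic, and
the exact residue ranges depend on the structure set, so the defaults are
provisional and must be reviewed per application. Superposition is single
pass onto the supplied core; an iteratively re-weighted core refinement is
deliberately not implemented.

The covariance of the selected 3N C-alpha coordinates is normalized by `n`
(the ensemble-average form), not `n − 1`; consequently the variance of the
fitting-set scores along each eigenvector equals its eigenvalue exactly,
which the tests assert to 1e−9. Eigenvector signs are fixed by making the
largest-magnitude coordinate positive, so results are order-invariant and
reproducible. Projections subtract the fitting mean and dot with the
eigenvectors; the 2-D score density (`density_map()`) is a normalized
histogram with optional Gaussian smoothing (off by default) for topographic
contouring of the conformational space sampled by different simulations.

## Motility and trap statistics

Events shorter than three frames are discarded before fitting. All
distribution fits minimize the squared distance between the model CDF and
the empirical CDF at the Hazen plotting positions `(i − 0.5)/n`; the 0.5
offset avoids the 0 and 1 endpoints that otherwise dominate least-squares
CDF fits. Fits are invariant to input order and (up to optimizer
tolerance) to duplication of the full sample.

- **Velocities**: Gaussian CDF, free mean and sd; SEM reported as sd/√n.
- **Run lengths, single population**: shifted-exponential CDF
  `1 − exp(−(x − offset)/λ)`; the offset accommodates a minimum detectable
  run and defaults to 0 (whether the original analyses used one is not
  stated; the parameter makes the choice explicit). Derived mean =
  offset + λ.
- **Run lengths, interrupted runs**: gamma CDF with the scale θ fixed at
  each candidate in `{1, 2}` µm and the shape k as the only free parameter;
  the candidate with the smaller CDF residual is selected, and the expected
  mean run length is k·θ. "Fixed rate of 1 or 2" is read as the *scale*
  being 1 or 2 µm because the mean is computed as shape × scale; readers
  who prefer the rate-parameter reading can pass `fixed_scales = 1/rates`.
- **Landing rate**: events/(µm·nM·s), with the Poisson standard error.
- **Gaps**: per gap, deficit = velocity × gap duration − observed
  displacement, also expressed in pixels (default 0.16 µm/px).
- **Group tests**: one-way ANOVA for velocities, tie-corrected
  Kruskal-Wallis for run lengths, and two-tailed unpaired Student's t tests
  (pooled variance by default, Welch by flag) for detachment forces against
  a reference construct.

Events that end because the motor reached the microtubule end are retained
(flagged in the table), so run-length estimates for highly processive
constructs are underestimates; a censoring-aware fit is out of scope.
Kymograph tracing itself is also out of scope — the module consumes event
tables.

## Cargo dispersion

Each in-mask pixel of a cell image receives a normalized distance: its
distance from the center divided by the center-to-boundary distance along
the same ray. The center is the nucleus-mask centroid when provided,
otherwise an explicit point or the cell-mask centroid. Rays are marched in
0.25-px steps and the boundary is the farthest in-mask sample along the
ray, which tolerates mild concavity (re-entrant rays); pixels whose ray
normalization still fails fall back to distance divided by the maximum
in-mask distance, and their count is reported as an attribute. Intensity is
summed into `n_bins` equal-width bins over [0, 1] (default 25) and divided
by total in-mask intensity, so profiles sum to 1 and are invariant to
global intensity scaling.

Profiles are averaged per condition with SEM across cells; conditions are
compared per bin with two-tailed unpaired t tests (no correction by
default, Benjamini-Hochberg by flag). Peripheral and perinuclear intensity
fractions integrate the profile beyond/below a normalized-radius threshold,
splitting straddling bins proportionally so the two regions partition the
total exactly at any threshold. The defaults — 25 bins, peripheral
threshold 0.8, perinuclear 0.2 — are explicitly provisional conventions:
published "periphery" and "adjacent to the nucleus" cutoffs are not
standardized, so these percentages should be compared only within one
choice of threshold.

## Synthetic-data generators

Every generator is a pure function of its spec: a root seed expands into
per-component child seeds through a counter-based scheme, so regenerating
one input never perturbs another, and the global RNG state is restored
afterwards. Each generator returns a machine-readable truth table of its
generating parameters.

- **Two-state ensembles** emulate replicated MD of two conformational
  states at the analysis scale (4 replicates × 100 frames by default): a
  toy helical chain shared by both states, residue pairs placed at
  specified separations per state in isolated remote sites (so each
  injected change perturbs exactly one pair), and per-frame noise applied
  as a rigid Gaussian displacement of each residue (per-axis sd
  `noise_sd`, default 0.3 Å). The rigid-residue noise model keeps the
  minimum-over-atom-pairs statistic unbiased; the realized pair-distance sd
  is √2·`noise_sd`, and for a pair at nominal distance d the mean distance
  carries a small transverse bias of order `noise_sd²/d`. What these
  ensembles do **not** emulate: frame autocorrelation, force-field
  energetics, correlated domain motions, or solvent — passing recovery
  tests shows the statistics behave as designed, not that any particular
  biological system does.
- **Mode ensembles** add known orthonormal 3N-direction displacements with
  Gaussian amplitudes plus isotropic coordinate noise; the truth table
  records both the population variances and the realized (sample, n-
  normalized) amplitude variances, which are the exact spectrum injected
  into a finite ensemble and therefore the right target for eigenvalue
  recovery at tight tolerances.
- **Motility events** draw Gaussian velocities and exponential or gamma run
  lengths (defaults follow typical wild-type kinesin-1 populations:
  0.617 ± 0.08 µm/s, exponential mean 0.99 µm, 250 events); the pause model
  inserts a gap of fixed duration with a stationary fraction, so the
  expected gap deficit is exactly pause fraction × expected displacement.
  Photophysics (blinking) and load dependence are not modelled.
- **Cell images** place photons at Beta-distributed normalized radii and
  uniform angles inside a disk mask, plus optional Poisson background
  (default 0). Beta(2, 8) gives perinuclear clustering, Beta(8, 2)
  peripheral dispersion, Beta(1, 1) uniformity over radius. Real cells are
  not disks and real backgrounds are structured; the generator validates
  the profile machinery, not segmentation.

## Problem sizes and runtimes

The test suite and the acceptance script run the eDDM calibration at 12–20
residues × 400 frames per state over a handful of seeds, PCA recovery at
n = 500 frames, fit recovery at n = 2000 events, type-I calibration at
3000–5000 null replicates, and dispersion checks at 10⁴–10⁵ photons per
image over up to 50 seeds — sizes chosen so each property is measured with
comfortable statistical margin while the whole suite completes in a few
minutes on one CPU.

## Known limitations

- eDDM p-values assume independent frames (see above).
- The invariant core and analysis selection are user inputs; no automated
  multi-structure alignment is provided, so cross-structure studies need an
  external equivalence mapping.
- CDF-fit standard errors are asymptotic conveniences (sd/√n-type), not
  profile-likelihood intervals.
- The ray-based radial normalization degrades on strongly concave cell
  masks (the fallback count should be checked).
- Binary trajectory formats (DCD/XTC) are not read; ensembles arrive as
  multi-model PDB or the plain TSV trajectory dialect.
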