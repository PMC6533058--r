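# kinlink

Statistical analysis of kinesin-1 neck-linker mechanics: conformational
ensembles, single-molecule motility, and cargo transport in cells.

## What this package is for

The kinesin-1 neck linker (NL) docks along the motor core upon ATP binding,
via cover-neck-bundle (CNB) and asparagine-latch (N-latch) formation, and
thereby couples the catalytic cycle to force generation. Dissecting that
coupling requires four quite different quantitative analyses, which this
package implements as one tested, reusable toolkit for structural
biophysicists and single-molecule labs:

1. **Masked ensemble difference distance matrices (eDDM).** For two
   conformational ensembles (e.g. apo vs ATP-bound MD replicates), per-frame
   residue-pair minimum heavy-atom distances `x` are transformed with a
   smooth saturating mask

   ```
   f(x) = x                                              x ≤ c1
   f(x) = c1 + (2(c2−c1)/π)·cos((π/2)·(c2−x)/(c2−c1))    c1 < x ≤ c2
   f(x) = c1 + 2(c2−c1)/π                                x > c2
   ```

   with c1 = 4 Å and c2 = 8 Å by default, so contact-range changes are kept
   intact while differences between long distances are suppressed. Masked
   samples are compared per pair with a two-sided Wilcoxon rank-sum test;
   pairs with p < 0.05 and |masked mean difference| > 1 Å are flagged as
   significant contact changes.

2. **Invariant-core PCA.** C-alpha coordinates of equivalent, non-gap
   positions are analyzed after rigid superposition onto an invariant core;
   the covariance matrix `C_ij = ⟨(r_i−⟨r_i⟩)(r_j−⟨r_j⟩)⟩` is diagonalized
   and structures or trajectory frames are projected onto the leading
   eigenvectors to map, e.g., ADP-like vs ATP-like motor-domain
   conformations.

3. **Motility and trap statistics.** Kymograph event tables are filtered
   (≥ 3 frames), velocity distributions are fit with a Gaussian CDF, run
   lengths with an exponential or a fixed-scale gamma CDF (mean run length
   = shape × scale), landing rates are normalized per µm·nM·s, gap
   displacement deficits are scored against constant motility, and groups
   are compared with one-way ANOVA, Kruskal-Wallis, or two-tailed unpaired
   t tests (detachment forces).

4. **Cargo-dispersion quantification.** Per-cell radial profiles of cargo
   intensity over normalized center-to-edge distance, averaged per
   condition with SEM, compared per distance bin with t tests, and reduced
   to peripheral/perinuclear intensity fractions.

Seeded generators (`make_two_state_ensembles()`, `make_mode_ensemble()`,
`simulate_motility_events()`, `simulate_cell_image()`) produce synthetic
inputs with recorded ground truth for every stage, so each analysis can be
validated against known answers.

## Worked example

Detect an injected contact change (3 Å → 9 Å across states) in a pair of
synthetic 400-frame ensembles, then fit a gamma run-length distribution:

```r
library(kinlink)
library(dplyr)

sp <- two_state_spec(
  n_residues = 20, atoms_per_residue = 4,
  shifted_pairs = tibble::tibble(i = 3, j = 11, dist_a = 3, dist_b = 9),
  seed = 7
)
sim <- make_two_state_ensembles(sp)
apo <- distance_tensor(sim$state_a)
atp <- distance_tensor(sim$state_b)
changes <- eddm_compare(apo, atp, c1 = 4, c2 = 8, alpha = 0.05, min_diff = 1)
glance(changes)
#> # A tibble: 1 × 4
#>   n_pairs n_significant alpha min_diff
#>     <int>         <int> <dbl>    <dbl>
#> 1     190             1  0.05        1
head(tidy(changes) |>
  select(res_i, res_j, mean_masked_A, mean_masked_B,
         masked_diff, p_value, closer_in), 3)
#> # A tibble: 3 × 7
#>   res_i res_j mean_masked_A mean_masked_B masked_diff   p_value closer_in
#>   <int> <int>         <dbl>         <dbl>       <dbl>     <dbl> <chr>
#> 1     3    11          3.01          6.55      3.53   1.75e-150 A
#> 2    13    14          3.39          3.34     -0.0420 3.63e-  1 none
#> 3    14    15          2.97          3.00      0.0351 1.20e-  1 none
```

The one injected pair (3, 11) is recovered: its masked mean rises from
3.01 Å to the mask's saturation value ≈ 6.55 Å (= 4 + 8/π), a masked
difference of +3.53 Å flagged as significantly closer in state A; all 189
unshifted pairs stay below both thresholds. `autoplot(changes)` draws the
signed contact-change map.

```r
runs <- simulate_motility_events(
  motility_sim_spec(n_events = 2000, runlength_family = "gamma",
                    gamma_shape = 4, gamma_scale = 1, seed = 11)
)
fit <- fit_runlength_gamma(runs$events)
fit
#> <cdf_fit> gamma (n = 2000)
#>   shape = 4.012, scale = 1
#>   derived mean = 4.012, CDF residual (SS) = 0.122
```

The fixed-scale gamma CDF fit selects the generating scale θ = 1 µm and
recovers the shape k ≈ 4, giving the expected mean run length
k·θ ≈ 4.0 µm.

## Layout

- `R/ensembles.R` — conformations, ensembles, PDB/TSV input, subsampling
- `R/eddm.R` — distance tensors, smooth mask, two-state comparison
- `R/structure-pca.R` — invariant-core superposition, PCA, projections
- `R/motility.R` — event filtering, CDF fits, landing rates, group tests
- `R/dispersion.R` — radial profiles, condition comparison, fractions
- `R/synthetic.R` — seeded generators with recorded ground truth
- `vignettes/kinlink-methods.Rmd` — models, assumptions, design choices
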