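# strainmap

Whole-brain biomechanical vulnerability mapping from magnetic resonance
elastography (MRE), with validation against diffusion-derived tissue injury.

## The problem

Mild traumatic brain injury concentrates damage in a stereotyped set of
structures (midbrain, cerebellum, mesial temporal lobe, sulcal depths)
regardless of where the skull was struck. One candidate explanation is
biomechanical: some regions concentrate shear strain under any skull loading,
either because more shear-wave energy arrives there or because they cannot
dissipate the energy that does. `strainmap` implements the full analysis
chain needed to test that idea on voxel data:

1. **Rheology.** From a complex harmonic displacement field `u` measured
   under skull actuation, the strain tensor is
   `eps = (grad u + grad u')/2` (finite differences on the voxel grid,
   one-sided at mask edges). Its scalar summary is the octahedral shear
   strain, maximised over the oscillation phase:

   `OSS = max_phi (2/3) * sqrt((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2)`

   with `e_i` the principal strains of `Re(eps * exp(i*phi))`. Shear
   stiffness comes from the complex modulus `G = G' + iG''` as
   `mu = 2|G|^2 / (G' + |G|)`, strain energy density as `U = mu * eps^2 / 2`
   (J/m^3), and the dispersion of the storage and loss moduli across
   actuation frequencies is summarised by voxelwise OLS slopes
   `dG'/df`, `dG''/df` and their ratio (the dispersion index; values above 1
   mean energy is absorbed faster than it is dissipated).

2. **Vulnerability map.** OSS is z-scored within subject, tested voxelwise
   against zero across subjects (one-sample t, two-tailed p), and
   high-strain (HS) regions are the voxels with `t >= 4.0` surviving
   Benjamini–Hochberg FDR at `q < .05`; all other in-mask voxels are
   low-strain (LS). Maps from occipital and lateral actuation are
   intersected to isolate actuation-invariant vulnerability, and the region
   definition is cross-validated leave-one-out.

3. **Injury validation.** Apparent fiber density (AFD) from control and
   mTBI cohorts is averaged over HS and LS, normalised as `AFD_HS / AFD_LS`
   per subject, and tested with a 2 (region, within) x 2 (group, between)
   mixed ANOVA, a directed one-tailed contrast, paired HS-vs-LS contrasts
   for strain energy and the dispersion index, and a threshold-agnostic
   analysis binning the voxelwise control-minus-mTBI AFD difference into
   0.25-z-wide OSS bins.

A seeded voxel-phantom simulator (`make_phantom()` and the
`simulate_*_cohort()` functions) generates displacement, moduli and AFD
cohorts with configurable ground truth, so the entire pipeline is testable
without any imaging data.

## Worked example

```r
library(strainmap)

spec   <- make_phantom(c(32, 32, 32), seed = 42)   # 2 mm voxels, amplification 2
cohort <- simulate_displacement_cohort(spec, "occipital", frequency = 50,
                                       n_subjects = 20, seed = 42)
zmaps  <- lapply(cohort, function(u) {
  eps <- strain_from_displacement(u, voxel_size = spec$voxel_size,
                                  mask = spec$brain_mask)
  oss <- octahedral_shear_strain(eps, phase_samples = 16)
  znormalize(oss, spec$brain_mask)
})
regions <- define_regions(group_tmap(zmaps, spec$brain_mask),
                          t_threshold = 4.0, q = 0.05)
regions
#> <region_mask> HS 857 voxels, LS 10799 voxels (t >= 4, FDR q = 0.05)
dice_coefficient(regions$hs, spec$hs_occipital)
#> [1] 0.8521127
```

857 voxels exceed the HS criterion; they overlap the phantom's true
high-strain blob at Dice 0.85. Leave-one-out cross-validation shows every
left-out subject carries more strain in the training-set HS region:

```r
glance(loo_crossvalidate(zmaps, spec$brain_mask))
#> # A tibble: 1 x 9
#>   n_folds n_excluded frac_hs_gt_ls t_threshold fdr_q paired_t  p_t_two wilcoxon_W  p_w_two
#> 1      20          0             1           4  0.05     20.5 2.02e-14        210 1.91e-6
```

Validating against a simulated injury cohort (10% AFD deficit inside the
true high-strain region):

```r
afd <- simulate_afd_cohort(spec, n_control = 20, n_mtbi = 20, seed = 43)
tab <- cohort_afd_table(afd, regions)
interaction_anova(tab)
#> <strain_anova> region x group interaction: F(1, 38) = 4210.647, p = 1.55e-40
#>             hs     ls
#> control 0.4944 0.4944
#> mtbi    0.4733 0.4933
directed_contrast(tab)
#> # A tibble: 1 x 3
#>       t    df p_one_tailed
#> 1  64.9    38     7.75e-41
```

The cell means show the construction directly: mTBI AFD is reduced only in
the high-strain region (0.473 vs 0.494), so the interaction and the directed
contrast are both large. `run_pipeline(pipeline_config(seed = 7))` chains
all of the above (both actuations, intersection, LOO, energy and dispersion
contrasts, binned analysis) and `autoplot()` methods visualise each result
type.

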