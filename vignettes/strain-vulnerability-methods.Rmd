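---
title: "Methods: strain-concentration mapping, dispersion, and injury validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-concentration mapping, dispersion, and injury validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainmap)
```

## The model

`strainmap` operationalises a biomechanical account of why brain injury
concentrates in particular structures. The measurement model has three
layers.

**Voxel mechanics.** Under harmonic skull actuation at frequency $f$, tissue
displacement is a complex field $u(r)\,e^{i\omega t}$. The infinitesimal
strain tensor is $\varepsilon = \tfrac12(\nabla u + \nabla u^\top)$, computed
by finite differences on the voxel grid with only in-mask voxels entering any
stencil. Its octahedral shear strain,
$$\mathrm{OSS} = \max_{\varphi\in[0,\pi)}
\tfrac{2}{3}\sqrt{(e_1-e_2)^2+(e_2-e_3)^2+(e_3-e_1)^2},$$
with $e_i$ the eigenvalues of $\mathrm{Re}(\varepsilon e^{i\varphi})$, is the
rotation-invariant "maximum shear regardless of direction" at that voxel.
Internally we evaluate the algebraically identical deviatoric form
$(2/\sqrt3)\sqrt{\operatorname{tr}(\operatorname{dev}E^2)}$, which
vectorises over voxels; the eigenvalue route is kept in the test suite as an
independent oracle. Shear stiffness uses the nonlinear-inversion convention
$\mu = 2|G|^2/(G'+|G|)$ (with $|G| = \sqrt{G'^2+G''^2}$; it reduces to $G'$
for a lossless material), exposed alongside the simpler $\mu=|G|$ as a
strategy option because the underlying convention is a community choice, not
a law. Strain energy density is $U = \tfrac12 \mu\,\varepsilon^2$, reported
in J/m^3 with stiffness converted from kPa to Pa. Frequency dispersion is
summarised by voxelwise ordinary-least-squares slopes of $G'(f)$ and
$G''(f)$; their ratio (storage slope over loss slope) indexes whether a
voxel absorbs energy faster than it dissipates it. A log-frequency fit is
available behind a flag, but with three frequencies a straight line is all
the data support.

**Group map.** OSS is z-scored across voxels within each subject (sample
standard deviation, $n-1$), which removes global amplitude differences
between subjects — exactly the quantity a between-subject amplitude scalar
would otherwise dominate. The group statistic at each voxel is a one-sample
t of the z-values against zero ($n-1$ df, two-tailed p). After z-scoring,
zero is the only available null; no other contrast exists. High-strain (HS)
regions are voxels with $t \ge 4$ that also survive Benjamini–Hochberg FDR
at $q<.05$ pooled over the whole analysis mask; the HS rule uses the
positive tail only while the FDR input stays two-tailed, a literal reading
of thresholding "at or above" a positive t within a two-tailed correction.
Low-strain (LS) is simply every other in-mask voxel, not a matched control
region. Zero-variance voxels are flagged and excluded from the FDR pool
(assigning them p = 1 would dilute the step-up threshold for everyone else)
and fall into LS.

**Injury validation.** Per subject, AFD is averaged over HS and LS and
normalised as the ratio $\mathrm{AFD}_{HS}/\mathrm{AFD}_{LS}$; the ratio is
what removes lognormal between-subject AFD scaling, and the test suite
checks that rescaling one subject's whole volume leaves every ratio-scale
statistic unchanged. The interaction of a 2 (region, within-subject) x 2
(group, between-subject) mixed ANOVA is the headline test. It is computed
twice — through `aov()` with an `Error(subject/region)` stratum and as the
square of the pooled two-sample t on per-subject HS$-$LS differences — and
the two routes are asserted to agree to 1e-8; the ANOVA is run on region
means, with the same contrasts reported on the ratio scale, since the two
scales answer slightly different questions and the field plots the ratio.
The directed contrast is the one-tailed version of the same two-sample t,
signed so that a positive statistic means the injured group's deficit is
differentially larger in high-strain tissue. The threshold-agnostic analysis
bins voxels by group-mean z-OSS into half-open $[lo, lo+w)$ intervals of
width 0.25 z (spanning the observed range, empty bins retained with missing
medians, voxel counts conserved by construction) and rank-correlates the
per-bin median control-minus-mTBI AFD difference against the bin centre,
with average ranks for ties. Paired HS-vs-LS contrasts (used for z-OSS,
energy and dispersion index) report both a paired t and a Wilcoxon
signed-rank test — exact when $n \le 25$ and $|d|$ has no ties, a normal
approximation with continuity correction otherwise, zero differences
dropped with their count reported — because the analysis tradition in this
literature quotes both.

## The phantom generator

The simulators exist so that every stage above can be exercised, at
desk scale, on data whose ground truth is known. `make_phantom()` builds an
ellipsoidal brain mask with two overlapping ellipsoidal high-strain blobs —
one matched to occipital actuation, one to lateral, overlapping by roughly
half of the smaller blob — whose intersection is the actuation-invariant
vulnerable region used by the moduli and AFD simulators.

* **Displacement** (`simulate_displacement_cohort()`): a complex shear plane
  wave (amplitude 0.02 mm, wavelength 12 voxels at the 50 Hz reference,
  scaled inversely with frequency and floored at 6 voxels) whose amplitude
  is multiplied by `oss_amplification` (default 2) on the actuation-matched
  blob. Because strain is linear in displacement, the in-blob OSS ratio is
  analytically the amplification factor, which the tests check to 5%. The
  blob edge is smoothed over ~0.5 voxel; an optional counter-propagating
  reflection (default off) adds standing-wave structure. Between-subject
  variability comes from a random propagation-direction jitter (sd 10
  degrees), a random global phase, and a smooth lognormal amplitude field
  (sd 0.25, correlation length 3 voxels). The amplitude field is the load-
  bearing realism choice: a purely global amplitude factor would be erased
  by within-subject z-scoring, leaving essentially no between-subject
  variance and making the group t-map wildly anticonservative. Random
  fields are generated on a padded grid and cropped so their statistics are
  stationary up to the mask boundary.
* **Moduli** (`simulate_moduli_cohort()`): $G'(f), G''(f)$ linear in $f$
  around a 2.2/1.0 kPa baseline at 50 Hz, with storage slope 0.02 kPa/Hz
  inside the true vulnerable region versus 0.01 outside and loss slope 0.01
  everywhere — dispersion index 2 inside, 1 outside — plus lognormal subject
  scaling (sd 0.05) and voxel noise (sd 0.05 kPa, clamped to keep $G'>0$,
  $G''\ge 0$).
* **AFD** (`simulate_afd_cohort()`): baseline 0.5, lognormal subject
  multipliers (sd 0.05, deliberately larger than the injury effect so that
  ratio normalisation matters), voxel noise sd 0.02, and a multiplicative
  deficit (default 10%) applied to injured subjects inside the true
  vulnerable region only.

The amplification and deficit defaults are plausible placeholders exposed as
parameters, not quantitative claims: no physical effect-size estimates exist
for either, so the defaults were chosen once to produce a clearly detectable
but not degenerate effect at cohort sizes of 20.

What the phantom does *not* emulate: heterogeneous wave propagation,
reflection and mode conversion at real tissue interfaces (the wave is a
plane wave with an amplitude envelope); skull, CSF or registration effects
(all subjects are born aligned on a common grid); spatially correlated or
tissue-dependent AFD structure; realistic inversion noise in the moduli.
Passing tests therefore demonstrate that the analysis recovers the
structure it assumes, with correct error control — not that the assumptions
hold in real MRE or dMRI data.

## Numerical choices

* **Finite differences.** Interior voxels use 4th-order central stencils,
  falling back to 3rd-order biased, 2nd-order central, 2nd-order one-sided,
  and 1st-order one-sided stencils as mask support shrinks, and 0 where a
  voxel has no in-mask neighbour along an axis. The graded scheme matters
  twice: plain 2nd-order central differences carry a ~2.5% sinc bias at a
  16-voxel wavelength (the analytic plane-wave test demands 1%), and a
  sharp accuracy step between interior and edge stencils imprints a
  systematic OSS pattern near the mask boundary strong enough to bias
  null-phantom HS-vs-LS contrasts.
* **Phase maximisation.** OSS maximises over 16 uniformly spaced phases in
  $[0,\pi)$ (configurable, minimum 8). $\pi$ suffices because
  $E(\varphi+\pi) = -E(\varphi)$ leaves the invariant unchanged. Whether the
  original analyses phase-maximised, used a fixed phase, or used the strain
  amplitude is not documented anywhere we could verify; phase maximisation
  is the default because it is the only choice that realises "maximum shear
  strain regardless of direction" for a complex harmonic field.
* **Degenerate inputs.** Constant volumes cannot be z-scored (error);
  all-zero paired differences cannot be rank-tested (error); a voxel with
  non-positive loss slope gets a missing dispersion index rather than an
  infinite one; an empty HS region is recorded as a provenance warning where
  a downstream consumer can still proceed, but is a hard error where a
  ratio would be undefined. LOO folds whose training HS set is empty are
  flagged and excluded with a reported count.
* **Determinism.** Every simulator derives per-stage, per-subject seeds from
  a single integer (kept below $2^{31}$), so cohorts are reproducible
  element-wise and the full pipeline's stats are bit-identical across
  reruns with the same configuration.

## Test and replicate scales

Unit tests run on 16–20 voxel grids. The deeper recovery checks use the
default study conditions (32^3 grid at 2 mm, 20 subjects per actuation, 20
controls and 20 mTBI). Calibration properties (null HS fraction, null
rejection rates of the interaction, directed, and paired contrasts; power of
the interaction under a 10% deficit) are measured over 100 seeded replicates
on 24^3 grids with 8–20 subjects, the package's chosen replicate scale; the
binomial uncertainty of a rate estimated from 100 replicates is what the
acceptance tests account for.

## Known limitations

* The group test assumes approximate normality of z-OSS across subjects at
  each voxel; OSS is a non-negative maximum statistic and is mildly skewed,
  which matters most at very small $n$.
* The strain boundary layer at a sharp amplification edge is physical —
  strain genuinely concentrates at amplitude interfaces — so recovered HS
  regions include a thin shell around the true blob, and Dice against the
  idealised truth saturates below 1.
* FDR pooling is whole-mask; restricted or anatomically stratified pooling
  is not implemented.
* No cluster-extent or permutation thresholding, no surface-based (sulcal)
  analysis, no covariate adjustment in the cohort models, and no inversion
  from displacement to moduli: moduli are inputs, simulated or measured
  elsewhere.
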