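---
title: "Building and validating subcortical gray-matter tissue priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating subcortical gray-matter tissue priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Automated tissue classification of brain MRI assigns each voxel a
probability of being gray matter (GM), white matter (WM), cerebrospinal
fluid (CSF) or non-brain tissue by combining two sources of evidence: the
voxel's intensity under a per-class mixture model, and a spatial prior — a
tissue probability map (TPM) giving the probability of each class at each
template location. Deep gray-matter nuclei (pallidum, substantia nigra,
red nucleus, subthalamic nucleus, …) defeat this scheme on T1-weighted
images: their high iron content raises the effective transverse relaxation
rate R2\*, which drives their T1w intensity toward that of white matter.
Conventional T1w-derived priors consequently carry little GM probability
there, and the classifier hands the nuclei to WM. Worse, iron accumulates
with age, so the misclassification is *age-dependent*: a naive morphometry
study reads progressive contrast loss as progressive atrophy.

`subprior` implements the remedy and the machinery to test it:

1. **Prior construction** (`warp_and_binarize`, `average_raters`,
   `build_mbp`, `merge_into_tpm`): binary structure masks from several
   human raters are warped to template space (trilinear, then
   re-binarized at 0.5), averaged across raters, smoothed with a 4 mm
   FWHM Gaussian into a nucleus probability map (MBP), and merged into an
   existing TPM set at single-voxel level:
   every class is scaled by $(1-\mathrm{MBP})$ and the MBP is added to
   GM. The merge provably conserves the voxel-wise sum at one, never
   decreases GM and never increases any other class.
2. **Inter-rater agreement** (`dice`, `cohen_kappa`, `icc`,
   `disagreement_pct`, `pairwise_summary`): the reliability statistics of
   the manual labels.
3. **A prior-weighted Gaussian-mixture EM classifier** (`segment`) to
   exercise the priors, with a leave-one-out validation harness
   (`loo_validate`).
4. **R2\* relaxometry** (`fit_r2star`): per-voxel ordinary least squares
   of the log multi-echo signal against echo time; the negated slope is
   R2\*.
5. **Morphometry statistics** (`modulate`, `weighted_smooth`, `glm_fit`,
   `paired_t_map`, `regress_delta_r2s`, `permutation_fwe`): Jacobian
   modulation, probability-weighted smoothing, voxel-wise GLM and paired
   tests, the regression of prior-induced GM volume differences
   ($\Delta\mathrm{GM} = \beta R2^* + \varepsilon$), and
   permutation/sign-flip maxT family-wise error control.
6. **A deterministic phantom generator** (`make_phantom`,
   `make_age_cohort`, …) providing the synthetic study conditions under
   which every claim above is tested end to end.

## The classifier model

`segment()` fits, per voxel $v$ with intensity $y_v$,

$$p(y_v) \;=\; \sum_{c} \pi_c(v) \sum_{g=1}^{G_c} w_{cg}\,
\mathcal N(y_v;\, \mu_{cg}, \sigma^2_{cg}),$$

where the mixing weights $\pi_c(v)$ are the spatial priors (optionally
rescaled by fixed global class weights) and each class $c$ owns $G_c$
Gaussians. The posteriors are the EM responsibilities. There is no
bias-field model and no embedded registration: images must already live on
the priors' grid (the phantoms are generated bias-free and pre-aligned, so
neither omission is exercised falsely).

Three design choices deserve explanation, because each was forced by an
observed failure mode:

* **Within-class weights are fixed at $1/G_c$** (`update_weights = FALSE`
  by default). A maximum-likelihood weight is a *global* quantity; for a
  nucleus holding ~1 % of the GM mass it converges to ~0.01 and multiplies
  into the prior, so a WM Gaussian with weight 1 beats a GM prior of 0.95
  at equal likelihoods — the weight update defeats precisely the rescue the
  priors exist to provide. With all mixing weights fixed, EM monotonicity
  is retained exactly (the E-step is exact and the M-step ascends the
  usual minorant).
* **Multi-Gaussian classes are seeded deterministically.** Prior-weighted
  moment initialisation places every component of a multi-modal class on
  the dominant mode. The default seeding draws a prior-weighted intensity
  sample (restricted to voxels with class prior > 0.01, so a probability
  floor spread over the whole volume cannot dominate) and applies
  farthest-point seeding plus Lloyd iterations. Pipelines that know more
  can say more: `init_means` accepts explicit anchors, and the validation
  harnesses anchor GM at the prior-weighted mean intensities under the
  CSF, GM and WM priors plus (for the merged priors) under the MBP — the
  four intensity populations the GM prior's support actually overlaps.
  Initial component variances are capped at half the gap to the nearest
  neighbouring anchor, so a dominant mode cannot capture components
  anchored elsewhere during early iterations.
* **Duplicate initial means are spread over intensity quantiles.** Flat
  priors give identical moments for every class — a symmetric EM fixed
  point; the spread breaks it deterministically.

Degenerate components have their variance floored at $10^{-6}$ times the
image variance. Convergence is declared when the relative log-likelihood
increase falls below `tol` (default $10^{-6}$).

## The phantom and what it does (not) emulate

The default phantom (`default_phantom_spec()`) is a 64×64×64 grid at 1 mm:
a CSF shell (radius 28 mm), a cortical GM shell (20–26 mm), a WM core, and
four GM-class nuclei embedded in the WM — caudate-, putamen-, pallidum-
and thalamus-like ellipsoids. Nucleus sizes are realistic (the
pallidum-like nucleus is a 6.5 mm-radius ball, ≈1150 mm³, the scale of a
human GP): with the prescribed 4 mm MBP smoothing, structures much below
500 mm³ retain almost no interior probability after smoothing, so the size
of the modelled structure is itself a study condition, not a free dial.

Two channels are generated with Gaussian class noise (SD 3):

* `mt` — MT-saturation-like, good subcortical contrast (nuclei ≈ cortex),
  except the pallidum-like nucleus at 62 against WM 70 — WM-like, as real
  GP appears even on MT;
* `t1w` — T1w-like (CSF 15, GM 60, WM 90); the pallidum-like nucleus
  starts at 75 at the reference age (40 y) and drifts toward (capped at)
  the WM mean by `contrast_loss_coeff` (0.8 intensity units per s⁻¹) times
  the R2\* elevation, while its R2\* rises linearly with age
  (base 40 s⁻¹, slope 0.4 s⁻¹/year). True nucleus geometry never changes
  with age: any fitted age slope of nucleus GM volume is bias by
  construction.

Raters are simulated by flipping boundary-layer voxels (surface ± 1)
independently with probability `flip_prob` (default 0.1), concentrating
disagreement at borders as in real manual labels; the expected pairwise
Dice has a closed form (`expected_pairwise_dice`) used to calibrate the
agreement tests. Deformations are Gaussian-filtered white-noise
displacement fields rescaled to a maximum amplitude (default 0.7 mm) and
checked for positive Jacobians. Cohort ages are evenly spaced over 21–88
years — a regular sample of the design range that maximises contrast for
age regressions at small n. The recorded TIV carries ±3 % spread so it can
serve as a non-degenerate covariate despite the shared geometry.

What the phantom does **not** emulate: partial-volume mixing, bias fields,
anatomical variability of structure shape, Rician intensity statistics
(optional in the relaxometry tests only), registration error beyond the
small simulated warps. Passing tests therefore demonstrate the *mechanism*
— that nucleus-aware priors rescue iron-rich nuclei and suppress
age-dependent classification bias — not performance on real cohorts.

## Conventional ("old") priors for the phantom

`make_base_tpm()` emulates T1w-derived priors that miss the iron-rich
nucleus: one-hot class maps with the pallidum-like structure assigned to
WM (its T1w appearance) and the remaining nuclei to GM, smoothed at 6 mm
and normalized with a $10^{-3}$ probability floor. The floor keeps every
prior strictly positive, so likelihood evidence can override the prior
anywhere — without it the old priors would pin the nucleus's GM posterior
to exactly zero at every age and no age *slope* could exist at all.

## Numerical choices

* FWHM→σ uses $2\sqrt{2\ln 2}$; smoothing is separable discrete-Gaussian
  convolution with zero padding and kernel radius $\lceil 4\sigma\rceil$;
  the unit-sum kernel conserves interior sums exactly.
* Threshold comparisons are `>=` throughout (a warped mask value of
  exactly 0.5 is kept; GM probability exactly 0.2 counts).
* Deformations are voxel-unit displacement maps in pull-back convention
  (`out(x) = in(x + disp(x))`); out-of-domain samples fill with 0;
  Jacobians use central differences (one-sided at faces).
* Leave-one-out Dice restricts the thresholded GM map to consensus-labeled
  voxels before comparing with the consensus mask — the reading of the
  validation protocol under which the reported overlap scales are
  reproducible; `overlap_dice()` itself is generic.
* `weighted_smooth` masks voxels where the smoothed weight is below 0.05;
  it equals plain smoothing under unit weights wherever the kernel support
  avoids the zero-padded faces (at the faces the ratio deliberately
  renormalizes).
* Family-wise error is controlled by permutation/sign-flip maxT rather
  than random-field theory: exact at desk scale, no smoothness estimation;
  `exhaustive = TRUE` enumerates all $2^n$ sign patterns for small paired
  designs.
* The ΔGM–R2\* regression defaults to fitting an intercept (zero-mean
  residual convention); `intercept = FALSE` fits the bare proportional
  model. Both are tested.
* Paired tests with zero-variance differences report t = 0 with a
  degeneracy flag instead of failing batch harnesses.
* Config files are YAML; tabular outputs CSV; run sidecars JSON recording
  the full configuration, its MD5, the seed and the package version.

## Problem sizes

The shipped tests and the acceptance script run on 64³ phantoms with
cohorts of 5 (leave-one-out validation) and 12 subjects (age-bias
analysis), 1000 permutations × 200 repetitions for the FWE calibration,
and 1000-voxel Monte-Carlo panels for the relaxometry and null-t
calibrations — sizes chosen so the full battery completes in minutes on a
single core while keeping every statistical check at conventional power.

## Known limitations

* The classifier is a deliberate simplification of full unified
  segmentation: no bias field, no embedded registration, no MRF
  regularization, no partial-volume model.
* Anchored GM initialisation assumes the channel orders tissue intensities
  the way the anchors do; pathological contrasts would need explicit
  `init_means`.
* The ICC is fixed to ICC(2,1) (two-way random effects, absolute
  agreement, single rater); the kappa chance term uses a recorded domain
  (default: union bounding box dilated by 5 voxels) because whole-volume
  domains inflate observed agreement for small structures.
* Deformation fields are consumed, never estimated; registration quality
  is outside the package's scope.
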