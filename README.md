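# subprior

Probabilistic tissue priors for subcortical gray-matter nuclei, and the
statistics to prove they work.

## The problem

Automated brain-MRI tissue classification combines an intensity mixture
model with spatial tissue probability maps (TPMs). Iron-rich deep
gray-matter nuclei — the globus pallidus above all — have T1w intensities
close to white matter (iron raises R2\* = 1/T2\*, which destroys
gray–white contrast), and conventional T1w-derived priors carry almost no
GM probability there, so classifiers hand these nuclei to WM. Because
iron accumulates with age, the error grows with age and masquerades as
atrophy in morphometry studies.

`subprior` builds nucleus-aware priors from multi-rater manual labels and
validates them end to end:

* **Prior construction** — warp rater masks to template space, re-binarize
  at 0.5, average across raters, smooth at 4 mm FWHM into a nucleus
  probability map (MBP), and merge into an existing TPM set at voxel level:
  `newTPM_c = TPM_c × (1 − MBP)` for every class, then `MBP` is added to
  GM. The merge conserves the voxel-wise sum at one.
* **Inter-rater agreement** — Dice, Cohen's kappa, ICC(2,1), and the
  disagreement percentage `100·(|∪| − |∩|)/|∪|`.
* **Prior-weighted GMM-EM classifier** (`segment`) with a leave-one-out
  validation harness (`loo_validate`).
* **R2\* relaxometry** — per-voxel OLS of log signal on echo time across a
  multi-echo series (`fit_r2star`).
* **Morphometry statistics** — Jacobian modulation, probability-weighted
  smoothing, voxel-wise GLM, paired t-maps,
  `ΔGM = β·R2* + ε` regression, and permutation/sign-flip maxT
  family-wise error control.
* **Deterministic phantoms** (`make_phantom`, `make_age_cohort`) with
  simulated raters, deformations, multi-echo decay, and an aging cohort in
  which nucleus R2\* rises linearly with age and T1w contrast falls
  accordingly while true nucleus volume stays constant.

## Worked example

Five phantom subjects, leave-one-out: rebuild the priors without each
subject, segment its MT-like image with conventional and rebuilt priors,
and compare against the rater consensus of the pallidum-like nucleus.

```r
library(subprior)

cohort  <- make_age_cohort(n_subjects = 5, seed = 1)
base    <- make_base_tpm(cohort$spec)          # nucleus-blind priors
val     <- loo_validate(cohort, base, channel = "mt", seed = 1)

pal <- subset(val$records, structure == "pallidum")
pal[, c("subject", "volume_old", "volume_new", "dice_old_02", "dice_new_02")]
```

```
  subject volume_old volume_new dice_old_02 dice_new_02
1   sub01          7        927       0.015       0.991
2   sub02          2        951       0.004       0.992
3   sub03          3        940       0.006       0.991
4   sub04          1        930       0.002       0.994
5   sub05          0        958       0.000       0.992
```

Columns: consensus-region GM volume (mm³, probability ≥ 0.2) and Dice
overlap with the rater consensus at threshold 0.2, under the conventional
(`old`) and rater-derived (`new`) priors.

With the conventional priors the WM-like nucleus is all but lost (only a
handful of consensus voxels reach GM probability 0.2); the rater-derived
priors recover it almost perfectly. On real data the same mechanism is
attenuated by anatomy and noise; the phantom's shared geometry shows it
in its clean extreme. On a 12-subject age cohort,
`age_bias_analysis()` shows the complementary result: the
conventional-prior pipeline fits a strongly negative age slope for nucleus
GM volume although true volume is age-constant, the new-prior slope is
smaller in magnitude, and the volume disagreement between the two
pipelines tracks the nucleus's (independently re-estimated) R2\*.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/subprior all --n 5 --seed 1 --out runs/demo
```

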