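# atlasseg

Multi-atlas segmentation of small-animal brain MRI and atlas-driven
regional PET quantification, in R.

Regional analysis of rodent PET needs anatomical volumes of interest, and
manual delineation of a full rat-brain nomenclature takes tens of hours per
animal. `atlasseg` automates it with a multi-atlas pipeline:

* **Registration** — rigid / affine (9 DOF, no shear) registration by
  Nelder–Mead simplex on partial-volume mutual information, and
  hierarchical non-linear registration (control-point deformation fields,
  cross-correlation with analytic gradients, blur schedule 1.0/0.5/0.4/0.3
  mm FWHM with control spacing 1.6/0.8/0.4/0.3 mm). Transforms compose,
  invert (fixed-point field inversion with fold detection) and serialize.
* **Atlas construction** — population MRI template by
  register-normalize-average (default grid 256 x 256 x 225 at 0.1 mm), and
  a maximum-probability atlas by majority-vote fusion of co-registered
  label volumes (`0` competes as background; deterministic tie policy).
* **Segmentation** — the three automated strategies: single atlas (SA),
  maximum-probability atlas via template space (MP), and direct
  propagation-fusion in subject space (PF).
* **Evaluation** — exact-count morphometrics: signed relative volume
  difference `100 (N_auto − N_manual) / N_manual`, its magnitude, Dice
  `2|A∩B| / (|A|+|B|)`; paired t-tests with Bonferroni correction and
  F-tests across methods.
* **PET** — SUV conversion (`SUV = C·BW/dose`, 1 g/mL), regional means
  through four label-reslicing pathways (SA, MP with MRI, MP without MRI,
  PF), and OLS agreement regressions.
* **Phantoms** — a seeded synthetic generator (labelled 3-D brain
  phantoms, smooth fold-free inter-individual deformations, pose/scale
  jitter, matched low-resolution PET with 1.4 mm PSF) so the whole pipeline
  is testable without licensed animal data.

All volumes are NIfTI-1 (`RNifti`); label lookup tables are 2-column TSV;
a 27-region rat-brain nomenclature ships with the package.

## Worked example

```r
library(atlasseg)

cfg <- experiment_config(
  n_atlas = 3L, n_test = 2L, seed = 1L,
  phantom = phantom_spec(dim = c(32L, 32L, 32L), spacing = 0.5,
                         n_regions = 5L, pet_dim = c(16L, 16L, 16L),
                         pet_spacing = 1),
  schedule = nl_schedule(fwhm = c(1, 0.5), spacing = c(2.5, 1.5),
                         iters = c(20L, 15L), stride = c(2L, 2L)),
  template_iterations = 1L)
res <- run_experiment(cfg)
res$dice_summary
#>   method      dice
#> 1     MP 0.8632220
#> 2     PF 0.8705159
#> 3     SA 0.8639721
round(sapply(res$regressions, function(r)
  c(slope = r$slope, r2 = r$r_squared)), 3)
#>       mp_with_mri mp_without_mri    pf    sa
#> slope       0.940          0.803 0.853 0.925
#> r2          0.959          0.916 0.974 0.963
```

The Dice summary is the mean regional overlap between each automated
segmentation and the ground-truth labels of the held-out test phantoms;
the regression table compares automated regional SUV means against
extraction with the true labels — slopes near 1 and high R² mean the
automated VOIs recover the same regional PET signal as perfect
delineation. At this toy scale (3 atlases, 32³) the methods are nearly
tied; the method separation needs the full design. With the
`experiment_config()` defaults (7 atlas + 5 test phantoms at 64³, seed 0,
about 6 minutes on one CPU) the same run prints mean Dice SA 0.894,
MP 0.923, PF 0.948 — the PF ≥ MP > SA ordering with multi-atlas Dice
above 0.8 — and PET agreement slope 0.993 / R² 0.998 for PF; the test
suite asserts exactly these orderings.

A command-line front end for the individual stages
(`make-phantom`, `build-template`, `build-atlas`, `segment`, `evaluate`,
`extract-pet`, `run-experiment`) is installed at `inst/cli/atlasseg`.

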