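# spineqmr

Quantitative-MRI biomarkers of the lumbar disc-endplate complex, and the
statistics that relate them.

The nucleus pulposus (NP) of an intervertebral disc is avascular: its cells
live on nutrients that diffuse from the vertebral capillaries, across the
cartilage endplate (CEP), into the disc. Two imaging biomarkers probe that
supply route — **CEP T2\*** from multi-echo ultra-short echo-time MRI (a
surrogate for endplate composition and permeability) and **vertebral bone
marrow fat fraction (BMFF)** from water-fat MRI (a surrogate for marrow
vascularity) — while **NP T1ρ** from spin-lock MRI grades disc degeneration
on a continuum. `spineqmr` is for imaging scientists and biostatisticians
who need this pipeline end to end:

* voxelwise mono-exponential relaxometry, `S(t) = S0·exp(−t/τ)`, for both
  T2\* and T1ρ, with fit-quality maps and validity masking;
* BMFF maps `100·F/(F+W)` from co-registered fat/water images;
* principal-axis standardisation of segmented tissues and extraction of
  the central CEP (kidney-bean template), hemi-vertebral, and central-40%
  NP regions; CEP orientation against B0 with the magic-angle filter
  (include only endplates within ±15° of `arccos(1/√3) = 54.7°`);
* per-endplate observation units with auditable exclusion bookkeeping and
  intra-rater ICC;
* the association analyses: univariate OLS, Pearson correlation matrix,
  proportional-odds regression of Pfirrmann grade on NP T1ρ, and two
  multivariable mixed-effects models with a random intercept per subject
  (effect-coded level ±1, REML, Wald or Satterthwaite inference);
* synthetic phantoms and cohorts with known ground truth — the basis of
  the whole validation suite and of the parameter-recovery studies.

The statistical heart is the random-intercept model for endplate `k` of
subject `i`,

    NP T1ρ_ik = β0 + β1·CEP T2*_ik + β2·level_ik + β3·(CEP T2*×level)_ik
                + β4·age_i + β5·BMFF_ik + β6·sex_i + β7·BMI_i + b_i + ε_ik,

with `b_i ~ N(0, σ_b²)`, `ε ~ N(0, σ²)`, level effect-coded (+1 = L4/5,
−1 = L5/S1) and continuous predictors centred at their sample means.

## Worked example

Fit a noiseless phantom's CEP, check its orientation, then simulate a
study-sized cohort, apply the exclusion rules and fit the first
multivariable model:

```r
library(spineqmr)

ph <- generate_phantom(phantom_spec(cep_angle_deg = 54.7))
t2map <- fit_decay(decay_series(ph$echo_series, ph$te_ms, mask = ph$masks$cep))
central <- central_cep_template(ph$masks$cep)
cep_angle(ph$masks$cep)                 # 54.4 deg -> inside the window
map_region_mean(t2map, central)$mean    # 20 (the ground-truth CEP T2*, ms)

coh <- generate_cohort(cohort_spec(n_subjects = 80, seed = 20260505))
cov_tab <- unique(coh[c("subject_id", "age", "sex", "bmi")])
units <- assemble_units(coh[setdiff(names(coh), c("age", "sex", "bmi"))], cov_tab)
res <- apply_exclusions(units, n_enrolled = 84, n_complete_mri = 80)
res$ledger
#> <exclusion_ledger>
#>   enrolled: 84 | complete MRI: 80
#>   excluded: damage 21 subjects; orientation 99 endplates; other 0 endplates
#>   final: 56 subjects, 137 endplates
mixed_model(res$included, "model1")
#> <model_fit_result> model1 | n = 137 obs, 56 subjects | converged
#>             term estimate ci_lower ci_upper  p_value
#>      (Intercept)   59.906   57.044   62.769 0.00e+00
#>          CEP T2*    0.849    0.349    1.349 8.70e-04
#>            Level    4.860    3.053    6.667 1.35e-07
#>  CEP T2* x Level    0.867    0.373    1.361 5.86e-04
#>              Age   -0.492   -0.786   -0.198 1.04e-03
#>   Vertebral BMFF    0.115   -0.146    0.376 3.89e-01
#>              Sex    3.316    0.409    6.223 2.54e-02
#>              BMI    0.160   -0.494    0.815 6.31e-01
#>   random intercept var 70.131 | residual var 104.636
```

Read it as the science: in this simulated cohort, NP T1ρ rises ~0.85 ms per
ms of CEP T2\* after adjustment (healthier endplates, healthier discs),
discs at L4/5 sit ~2×4.86 ≈ 9.7 ms above L5/S1, and BMFF carries no
independent association — the pattern the generative coefficients encode.

The numbered scripts under `analysis/` run the full narrative — phantom
validation, cohort simulation and descriptives, association models,
parameter recovery/type-I error, and composition ranges — writing their
tables under `results/`:

```sh
Rscript analysis/01_phantom_validation.R
Rscript analysis/02_cohort_simulation.R
# ...
```

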