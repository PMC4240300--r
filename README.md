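# crowding

Simulation and analysis of visual crowding in flanked letter
identification.

## What this package is for

Visual crowding — the collapse of target identification when flankers
fall within a critical spacing — is ordinarily a peripheral-vision
phenomenon, but in posterior cortical atrophy (PCA) it can invade central
vision and make ordinary text unreadable. The standard assay asks a
participant to name a target letter flanked on both sides, while the
edge-to-edge spacing (condensed 0.1° vs. spaced 1.0°), flanker category
(letters, triangles, digits 2–9) and flanker contrast polarity are
manipulated. This package provides, for researchers studying crowding in
neurodegenerative or healthy populations:

* deterministic stimulus construction at exact visual-angle geometry
  (10.5 mm letters = 1.20° at 50 cm), with PGM/PNG export;
* the Type A/B/C error taxonomy (no response / flanker named / letter
  absent from the array), latency trimming (2 SD per participant after
  removal of erroneous, prompted and distracted trials), inverse latency
  transformation, 0–100 score standardization and raw-difference
  crowding indices;
* pixel-overlap (fuzzy Jaccard) similarity between images, with
  centre-of-mass alignment:
  `S(a,b) = Σ min(|a|,|b|) / Σ max(|a|,|b|)`;
* the three-model comparison of *compulsory averaging* vs. *flanker
  substitution* accounts of crowding errors: logistic mixed models with
  crossed random intercepts (participant, error-response letter) whose
  fixed effects are similarity of each candidate letter to the averaged
  target/flanker composite (Model 1), to the individual flankers
  (Model 2), or to flankers plus target (Model 3);
* cluster-robust (CR0 sandwich) group contrasts of accuracy and inverse
  latency, Wilcoxon utilities and covariate-adjustment reports;
* a seeded synthetic cohort generator (26 PCA-like / 17 tAD-like / 14
  controls, Tasks 1–6) with planted masking, substitution and averaging
  mechanisms, so the entire pipeline is testable without patient data.

## Worked example

Simulate the default cohort, classify errors, and ask whether the
averaging or the substitution account explains the PCA-like group's
errors:

```r
library(crowding)

cfg    <- cohort_config(seed = 1)
trials <- simulate_cohort(cfg)

pca <- classify_trials(subset(trials, group == "PCA" & task != 1))
error_summary(pca)[c("error_rate", "proportions")]
#> $error_rate
#> [1] 0.1769231
#> $proportions
#>         A         B         C
#> 0.3278986 0.2409420 0.4311594

err <- subset(pca, error_class %in% c("B", "C"))
f1 <- fit_logistic_mixed(build_design(err, 1))
f2 <- fit_logistic_mixed(build_design(err, 2))
f3 <- fit_logistic_mixed(build_design(err, 3))
compare_models(list(model1 = f1, model2 = f2, model3 = f3))
#> Averaging vs. substitution model comparison (alpha = 0.05 )
#>    model       term estimate     se      z         p
#> 1 model1    sim_avg   5.1361 0.5050 10.171 2.668e-24
#> 2 model2   sim_left   3.2285 0.2210 14.611 2.404e-48
#> 3 model2  sim_right   2.8830 0.2215 13.016 9.932e-39
#> 4 model3   sim_left   3.2256 0.2205 14.626 1.906e-48
#> 5 model3  sim_right   2.8844 0.2215 13.024 8.890e-39
#> 6 model3 sim_target  -0.3865 0.3849 -1.004 3.153e-01
#> Supported account: both
```

The default cohort plants a *mixture* of mechanisms (masking,
substitution and averaging all active), and the report says so: the
composite-similarity coefficient of Model 1 is large and highly
significant (z ≈ 10.2), and the individual-flanker terms of Model 2 are
significant as well, so the comparison flags both accounts. Fitting the
same models on cohorts generated with a single pure mechanism separates
the accounts (see the mechanism-recovery study in
`tests/testthat/test-acceptance.R`).

Stimuli themselves are ordinary matrices:

```r
geom <- viewing_geometry(distance_mm = 500, pixel_pitch_mm = 0.25)
arr  <- build_array(render_glyph("G", geometry = geom),
                    render_glyph("T", role = "flanker", geometry = geom),
                    render_glyph("X", role = "flanker", geometry = geom),
                    spacing_condition = "condensed", geometry = geom)
arr
#> <stimulus_array T-G-X, condensed/same, gap 0.10 deg, canvas 101 x 224 px>
write_pgm(arr, "TGX_condensed.pgm")
```

A thin command-line wrapper over the same functions is installed as
`exec/crowding`; `crowding simulate --seed 1 --out out/` writes a trial
table plus planted-truth JSON, and `classify`, `score`, `fit`, `indices`,
`render` and `report` cover the rest of the pipeline.

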