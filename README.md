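# leukdyn

Feedback-regulated ODE models of acute myeloid leukemia (AML) competing
with healthy hematopoiesis, for asking a clinical question from blast
kinetics: **do a patient's leukemic cells depend on endogenous cytokines
to expand, or do they grow autonomously?**

The package implements two four-compartment models. Each lineage
(healthy, leukemic) has a mitotic marrow pool and a post-mitotic pool; a
mitotic pool with self-renewal fraction *a*, proliferation rate *p* and
cytokine signal *s* grows at the effective growth rate

```
egr = (2·a·s − 1)·p        s = 1/(1 + k·C)
```

where *C* is the density of mature cells consuming the cytokine. In the
**cytokine-dependent** model (`"model1"`) both lineages share the signal
and compete for it (`C = c2 + l2`); in the **cytokine-independent**
model (`"model2"`) leukemic cells have `s ≡ 1` and are limited only by
crowding death `dbar·(c1 + l1)` in the marrow. The consequences:

* a cytokine-dependent clone invades iff its self-renewal exceeds the
  healthy one (`a_l > a_c`), and its expansion is throttled by feedback —
  from one leukemic stem cell per kg it needs **≥ ~200 days** to reach a
  10% marrow blast fraction;
* an autonomous clone invades iff `(2·a_l − 1)·p_l > 0` and can reach
  10% blasts within **~3 weeks**.

Fast relapses therefore point to autonomous growth. The package fits
both models to a patient's marrow blast time course (bounded multistart
least squares; interval records such as "<5% blasts" enter through their
distance to the interval), applies a 5% relative-RMSE selection rule,
groups patients by compatibility, and compares overall survival between
the groups with Kaplan–Meier curves and a log-rank test. A synthetic
cohort generator with realistic sparse sampling, reporting thresholds
and censoring makes the whole pipeline testable end to end. Cytokine
priming is also simulated: a 30-day signal clamp whose outcome
(beneficial / harmful / neutral) is classified by the blast share and
predicted analytically from the ordering of effective growth rates.

## Worked example

```r
library(leukdyn)

## expansion speed of the two feedback modes at equal cell parameters
p2 <- model_params(lineage_params(a = 0.97, p = 1, d = 2.3), variant = "model2")
p1 <- model_params(lineage_params(a = 0.97, p = 1, d = 2.3), variant = "model1")
time_to_blast_threshold(p2)   # 20.87 days to 10% marrow blasts
time_to_blast_threshold(p1)   # 442.14 days

## classify a synthetic patient by fitting both models
coh <- generate_cohort(cohort_config(n_patients = 6, seed = 3))
r <- coh[[1]]
r$observations
#>          t     kind     value lower upper
#> 1  0.00000 interval        NA     0  0.05
#> 2 37.12521    exact 0.2506025    NA    NA
f1 <- fit_model("model1", r$observations, n_starts = 8, seed = 1)
f2 <- fit_model("model2", r$observations, n_starts = 8, seed = 1)
f1$rmse                       # 0.173  -- cannot reach 25% blasts in 37 days
f2$rmse                       # ~1e-15 -- autonomous model fits exactly
select_model(f1, f2)$group    # "group2" (true generating variant: model2)

## cytokine priming of a slow autonomous leukemia
ex <- stimulation_experiment(model_params(lineage_params(0.75, 0.6, 2.3),
                                          variant = "model2"))
ex
#> stimulation experiment (model2): triggered at day 93.5
#>   blast-share change vs control: -98.6% (burden -97.2%) -> beneficial
```

The first patient relapses to 25% marrow blasts 37 days after remission:
the cytokine-dependent model misses by an RMSE of 0.173 blast-fraction
units while the autonomous model passes through both observations, so
the patient is assigned to group 2 (cytokine-independent). In the
priming run, stimulated healthy cells out-compete a leukemia whose
effective growth rate (0.25/day) is below the stimulated healthy rate
(0.60/day), clearing 98.6% of the blast share — transiently: the blasts
regrow after the protocol ends, as `plot(ex)` shows.

The full cohort pipeline (generate → fit/classify → survival
comparison) runs from one configuration:

```r
cfg <- as_leukdyn_config(list(seed = 1, out_dir = "out",
                              cohort = list(n_patients = 41),
                              fit = list(n_starts = 12)))
run_pipeline(cfg)   # writes cohort CSVs, per-patient fits/groups, KM + log-rank
```

or from the shell via `Rscript inst/cli/leukdyn.R pipeline --config cfg.yaml`.

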