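# cnvsizer

How much of a chromosome arm must be gained or lost before the alteration
predicts outcome? Tumor risk models that use arm-level copy-number variants
(CNVs) — meningioma grading schemes most prominently — apply size thresholds
anywhere from 5% to 80% of the arm, and the choice changes the model.
`cnvsizer` treats the threshold as a measurable quantity and builds the full
analysis around it, for statisticians and computational biologists working
with segmented copy-number profiles and censored survival endpoints.

## What it computes

Starting from a SEG-format segment table (sample, chromosome, start, end,
mean log-ratio intensity), clinical outcomes (time, event, endpoint label)
and a chromosome-arm table:

1. **Arm-level altered fractions.** Each arm is sampled every 30 kb; a grid
   point is *lost* when its covering segment mean is below −0.1 and *gained*
   above 0.15 (strict inequalities); the altered fraction of an arm is the
   altered share of covered grid points, summing non-consecutive events.
   Sex chromosomes and acrocentric p arms are excluded.
2. **The threshold sweep.** For every feature (arm × direction) and every
   threshold t ∈ {0.05, …, 0.95}, the binary call `fraction ≥ t` is scored
   by its cumulative/dynamic time-dependent AUC at 60 months,

   AUC(t) = P(marker_i > marker_j | T_i ≤ 60, T_j > 60),

   estimated with Kaplan–Meier case/control weights under censoring. A
   feature is **size-dependent** when max AUC ≥ 0.60 and some threshold
   falls below 95% of that maximum; the **optimal threshold** is the argmax.
3. **Penalized Cox models** on calls at optimal thresholds: elastic-net
   paths, event-stratified 10-fold CV scored by Harrell's c-index, the 1-SE
   rule for predictor selection, an alpha grid search over 0.05–0.95, and
   cross-validated AUC of pooled out-of-fold risk scores.
4. **Co-occurrence models**: conjunction pair features, Jaccard/odds-ratio
   edge lists, four-group Kaplan–Meier comparisons with log-rank contrasts,
   and burden-adjusted Cox fits.
5. **Acquisition order**: CNV burden, burden-binned prevalence profiles,
   Ward clustering into (by default) 3 clusters, and rule-based
   early/late/uncommon labels with leave-one-out burden binning.
6. **Focal regions**: per-position loss/gain pileups and a
   peak-over-flanking-background detector, with optional BED gene
   annotation.

The survival layer (Kaplan–Meier, log-rank, Efron-tie Cox, concordance,
time-dependent ROC) is implemented in the package and cross-checked against
independent references in the test suite. A seeded synthetic-cohort
generator (`simulate_cohort()`, `standard_scenarios()`) plants known
thresholds, hazard ratios, co-occurring pairs, early/late schedules and
focal spikes so that every stage can be validated against ground truth.

## A worked example

```r
library(cnvsizer)

sim    <- simulate_cohort(standard_scenarios()$single_threshold, seed = 7)
cohort <- as_cohort(sim)
#> <cnv_cohort> 500 samples, 9330 segments, 12 arms, endpoints: OS

fractions <- arm_fractions(cohort)
sweep     <- sweep_auc(fractions, cohort$survival, endpoint = "OS")
subset(sweep_summary(sweep), feature == "1p_loss")
#> # A tibble: 1 × 6
#>   feature opt_threshold max_auc min_auc n_thresholds size_dependent
#>   <chr>           <dbl>   <dbl>   <dbl>        <int> <lgl>
#> 1 1p_loss           0.4   0.667   0.499           19 TRUE
```

The scenario plants a loss of arm 1p with hazard ratio 3 for tumors whose
altered fraction reaches 40% of the arm. The sweep recovers exactly that:
the AUC profile of the 1p-loss call peaks at threshold 0.40 (5-year AUC
0.667), drops toward 0.5 at badly chosen thresholds (minimum 0.499), and the
feature is flagged size-dependent because the profile both exceeds 0.60 and
varies by more than 5% of its maximum. Downstream,
`binarize(fractions, optimal_thresholds(sweep))` turns the optimized
thresholds into the call matrix used by `cv_select()` (penalized Cox with
1-SE selection), `pair_features()` / `four_group_km()` (co-occurrence),
`cnv_burden()` / `early_late_from_calls()` (acquisition order) and
`pileup()` / `detect_focal()` (focal regions). `run_pipeline()` chains all
stages and writes TSV/JSON reports; each result has `autoplot()`, and model
objects have `tidy()`/`glance()` methods.

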