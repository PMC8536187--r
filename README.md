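# repleteaudit

Audit of electrolyte repletion practice in ICU event streams.

Electrolyte repletion — ordering potassium, magnesium or phosphate to raise
a serum level — is one of the most frequent interventions in critical care.
Observed practice is often driven by hospital routine rather than the lab
value: most orders are placed while the level is already within its nominal
range, draws cluster at the morning round, and the post-repletion change in
serum level can be modest. `repleteaudit` is for intensivists, clinical
informaticists and health-services researchers who want to quantify that
pattern reproducibly over MIMIC-shaped event tables (LABEVENTS-like labs,
INPUTEVENTS-like orders, ICUSTAYS-like stays, DIAGNOSES_ICD-like
diagnoses), or to validate such an audit end-to-end on synthetic data when
access to protected records is unavailable.

## What it computes

The unit of analysis is the **episode**: within each (stay, electrolyte)
stream, every repletion order *R* is anchored to the latest lab *L* of the
same electrolyte with

```
charttime(L) <= ordertime(R)  and  ordertime(R) − charttime(L) <= 24 h,
```

the closest qualifying lab being the *index* ("pre") value and any other
qualifying labs *ignored*; orders consume labs greedily in time order. Labs
with no order in the following 24 h are no-repletion episodes. This yields
the three scenarios `NR`, `1L→1R` and `ML→1R`. The first same-electrolyte
lab strictly after the order (≤ 24 h) is the follow-up ("post") value.

On top of the episodes the package builds:

* a cohort exclusion cascade (age, first-listed ICD-9 diagnosis,
  physiologic error bounds) with a conservative attrition log;
* below/within/above interpretation tables of pre-order values against
  nominal reference ranges, repletion fractions and near-miss rates
  (orders placed above range);
* repletion effectiveness: pooled-variance Student *t* and Cohen's
  *d* = (x̄₁ − x̄₂)/s_p, s_p² = ((n₁−1)s₁² + (n₂−1)s₂²)/(n₁+n₂−2),
  over pre vs post values;
* decision-factor OLS regression and one-way threshold ANOVA across ICU
  units or medication groups;
* circadian hour-of-day histograms, lab→order and order→follow-up latency
  summaries, and threshold-by-hour curves;
* a synthetic event-stream generator (`generate_cohort()`) with planted,
  analytically known truth (`planted_truth()`) for validation.

## Worked example

Generate a synthetic cohort at the default study conditions (5275 stays)
and run the full audit:

```r
library(repleteaudit)

g <- generate_cohort(generator_params(seed = 1), dir = "data")
cfg <- pipeline_config(
  paths = list(labs = "data/labs.csv", repletions = "data/repletions.csv",
               stays = "data/stays.csv", diagnoses = "data/diagnoses.csv"),
  output_dir = "audit_out", seed = 1)
report <- run_pipeline(cfg)

report$repletion_fraction
#>   electrolyte n_repletion n_total percent
#> 1   potassium        1126   33048    3.41
#> 2   magnesium        1726   16703   10.33
#> 3   phosphate        1417    8716   16.26

report$effects_table[, c("electrolyte", "n", "d_cohen", "p_value")]
#>   electrolyte    n   d_cohen       p_value
#> 1   potassium 1126 0.3235462  2.410910e-14
#> 2   magnesium 1726 1.0632452 7.845767e-189
#> 3   phosphate 1417 0.8462518 1.722423e-103

report$latency[report$latency$kind == "lab_to_order", ]
#>   electrolyte         kind    n mean_minutes sd_minutes median_minutes
#> 1   potassium lab_to_order 1126     217.5835   140.8645          180.5
#> 2   magnesium lab_to_order 1726     317.5823   190.9439          270.5
#> 3   phosphate lab_to_order 1417     337.7855   204.8801          288.0

modal_hour(report$hour_histograms$lab)    # 6  (morning-round draw peak)
modal_hour(report$hour_histograms$order)  # 9  (orders follow ~3 h later)
```

Reading: only 3.4% of potassium lab-order episodes ended in a repletion,
yet repletion produced only a small standardized change in serum potassium
(d ≈ 0.32) versus large changes for magnesium and phosphate (d ≈ 1.06 and
0.85); orders lag the triggering draw by ~3.6 h for potassium, and the
draw/order clock peaks sit at 06:00 and 09:00 — hospital routine, not
physiology. These are the planted study conditions recovered by the
pipeline; `g$truth` holds the corresponding closed-form expectations.

The package also ships the interpretation-cell counts of a published
MIMIC-III repletion audit as a worked example
(`inst/extdata/mimic3_audit_interpretation_counts.csv`); feeding them
through the same arithmetic reproduces the printed percentages:

```r
counts <- read.csv(system.file("extdata",
  "mimic3_audit_interpretation_counts.csv", package = "repleteaudit"))
repletion_fraction(counts)
#>   electrolyte n_repletion n_total percent
#> 1   magnesium        3743   36107   10.37
#> 2   phosphate         295    1775   16.62
#> 3   potassium        7166  221032    3.24
```

For real MIMIC-III extracts, `mimic3_schema_map()` and `default_item_map()`
translate raw column headers and ITEMID codes into the canonical schema.

## Documentation

The methods vignette (`vignettes/repletion-audit-methods.Rmd`) documents
the episode model and its tie-breaks, the exclusion cascade, the reference
ranges and their known inconsistency for magnesium, the generator's design
and what its planted-truth tests do and do not demonstrate about real data.
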