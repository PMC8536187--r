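---
title: "Auditing ICU electrolyte repletion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing ICU electrolyte repletion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repleteaudit)
```

## The question and the unit of analysis

Serum electrolyte repletion — giving potassium, magnesium or phosphate to
raise a serum level — is ordered constantly in intensive care, yet the lab
value that triggers an order is often already inside the nominal reference
range, and the post-repletion change is frequently small. An audit of this
practice needs three ingredients: a clean cohort, a way to say *which* lab
value a given order was reacting to, and summary statistics of the
resulting decision pattern.

The package's unit of analysis is the **episode**. Within each
(stay, electrolyte) event stream, every repletion order is anchored to the
latest lab of the same electrolyte charted at or before the order and at
most 24 h earlier. When several labs precede the order inside that window,
the closest one becomes the *index* lab and the rest are recorded as
*ignored* — orders are consumed greedily in time order, so a lab is used or
ignored by at most one order. Labs that never anchor an order, and have no
order in the 24 h after them, are *no-repletion* (NR) episodes. That yields
three scenarios: `NR`, `ONE_L_ONE_R` (one lab, one order) and
`MULTI_L_ONE_R` (several labs, one order). The first lab of the same
electrolyte *strictly after* the order, within 24 h, is the episode's
follow-up ("post") value; a single draw may simultaneously close one
episode as its follow-up and open the next as its index — routine morning
labs genuinely play both roles.

Tie-breaking is deliberate and deterministic: among equally close preceding
labs the later charttime wins, then the larger input row number; the
follow-up search is strictly-after so the anchoring draw can never be its
own follow-up; a lab charted at exactly the order minute counts as
preceding (charting granularity makes exact ties common). Timestamps are
timezone-naive at minute resolution and all arithmetic is in minutes:
de-identified ICU data is date-shifted, so only differences and the clock
hour are meaningful.

## Cohort construction

The exclusion cascade runs in a fixed order: stays with neither a lab nor a
repletion; stays under a minimum age (18 y by default; "under" is strict,
so exactly 18 is retained); stays whose *first-listed* (most relevant,
`seq_num == 1`) ICD-9 diagnosis falls in a configured exclusion set
(conditions that independently derange electrolytes: kidney disease,
rhabdomyolysis, parathyroid disease, transfusion, heart failure, and so
on); and finally, at the event level, lab values outside physiologic error
bounds (potassium outside [2, 7] mEq/L, magnesium outside [1, 5] mg/dL,
phosphate outside [0.5, 5] mg/dL — strictly outside, a value exactly at a
bound is kept). Every step appends to an attrition log; because diagnoses
remove whole stays while error bounds remove single events, the log keeps a
`level` column and the conservation invariant (final = initial − removed,
non-increasing) holds within each level.

The ICD-9 code sets ship as editable configuration
(`default_exclusion_rules()`), not as a fixed claim: published audits of
this kind do not always print their exact code lists, and real deployments
must review them. Dialysis exclusion is applied at the stay level — whether
it should instead void only a time window around the procedure is genuinely
ambiguous; stay-level is the conservative reading and is flagged here.

## Classification and statistics

Every index value is labelled below / within / above its electrolyte's
nominal reference range (inclusive bounds by default). Ranges are a
**mandatory argument** wherever they matter. The shipped defaults are the
MIMIC-III nominal ranges (potassium 3.7–5.7 mEq/L, magnesium and phosphate
2.5–4.5 mg/dL), but note a documented inconsistency in that source: its
printed magnesium range (2.5–4.5) sits *above* the magnesium levels its own
summary tables report as "within" (about 2.0 mg/dL). The range that system
actually applied is not recoverable, so the package refuses to guess — it
exposes the default and lets the analyst set ranges explicitly.

Statistics follow the field's plain conventions: groups as mean ± sample
SD; pooled-variance two-sample Student *t* with two-sided *p*; effect sizes
as Cohen's *d* on the pooled SD; one-way fixed-effects ANOVA for thresholds
across ICU units or medication groups; ordinary least squares for the
decision-factor screen, reported with coefficient, SE, star thresholds
(0.1/0.05/0.01), R², adjusted R², residual SE and the overall *F* with
(k, n−k−1) degrees of freedom. No multiplicity correction is applied — the
audit works at a flat two-sided 0.05, and the tables are descriptive, not
confirmatory.

Two places were genuinely open and are exposed as options rather than
decided silently:

* **Pairing of the pre/post comparison.** `pre_post_effect()` defaults to
  the *unpaired* pooled-SD form (the two marginal distributions, which is
  what group-summary tables print); `paired = TRUE` computes *d* on
  within-episode differences. With strongly correlated pre/post pairs the
  paired *d* is much larger, so the choice matters and is the caller's.
* **The regression outcome.** The decision-factor table can be read as a
  model of the post-repletion level or of the decision itself;
  `regression_outcome = "post_value"` (default) fits the follow-up serum
  value, `"decision"` fits a 0/1 linear probability model. ICU unit enters
  as a single numeric code by default (matching the one-row-per-factor
  table layout) with a categorical option available. A forward/backward
  stepwise screening mode exists, clearly labelled non-canonical (AIC-based
  via `stats::step()`).

## The synthetic generator and its planted truth

Protected ICU data cannot ship with a package, so validation runs on a
synthetic generator whose data-generating process is exactly known:

* **Decision windows.** Each stay carries Poisson-many windows per
  electrolyte (defaults 4/2/1 for K/Mg/Phos — a several-day ICU stay with
  potassium checked most often). A window holds one index lab; with
  probability `scenario_mix` (default 0.489, the multi-lab share observed
  in repletion practice) one or two extra labs precede it inside the
  window.
* **Values.** Serum values are normal, truncated at the physiologic error
  bounds: K ~ N(3.9, 0.45²) mEq/L, Mg ~ N(2.0, 0.28²), Phos ~ N(2.5, 0.6²)
  mg/dL — centred on the group means that large ICU audits report.
  Truncation guarantees no genuine value trips the error filter, so the
  attrition log's error count equals the planted count exactly.
* **Decisions.** Repletion fires with probability
  `base · plogis((θ − v)/s)` — a deliberately fuzzy threshold, since
  observed practice shows a linear-ish, overlapping relation rather than a
  sharp cut-off. θ sits near each electrolyte's action level (3.5 / 1.8 /
  2.3) with shallow slopes (0.30 / 0.20 / 0.30).
* **Timing.** Index draws follow a two-component wrapped-normal clock-hour
  mixture (major peak hour 6, minor peak hour 18, weights 0.7/0.3,
  SD 1.5 h — the hospital-routine pattern). Order latency and
  order-to-follow-up delay are lognormal, truncated at the 24-h window.
* **Effect.** The follow-up value is `pre + δ + ε`, with ε normal and
  truncated into the physiologic bounds.

Where the audited literature states the *downstream* quantity rather than
the primitive parameter, the generator plants the stated quantity: the
logistic `base` is solved (closed form plus quadrature over the value
distribution) so the per-episode repletion fraction is exactly the stated
3.24% / 10.37% / 16.62%; δ is solved so the expected unpaired pooled-SD *d*
is 0.32 / 1.08 / 0.87; the lognormal meanlogs are solved so the truncated
latency means are 217.20 / 323.29 / 339.83 min (orders) and 443.45 /
643.10 / 567.13 min (follow-ups). These are the study conditions, fixed
once in `generator_params()` — not tuning knobs.

`planted_truth()` returns every expectation in closed form (quadrature over
the truncated value density; analytic truncated-lognormal means; tilted
moments for the pre-repletion distribution), never by simulation, so
recovery tests compare a Monte-Carlo pipeline against an independent
analytic oracle.

One geometric simplification keeps the truth closed-form: windows within a
(stay, electrolyte) stream are spaced ≥ 3 days apart (first window ≥ 2 days
after admission, then 4–5-day gaps), so no window's labs, order or
follow-up can interact with a neighbour's. Real ICU streams overlap
heavily; the matcher's behaviour under overlap is validated separately
against an exhaustive O(n²) brute-force matcher on dense random streams.
Consequently the synthetic stays are longer than real ICU stays, and
passing recovery tests demonstrate correctness of the *pipeline*, not
realism of inter-variable physiology (creatinine–potassium coupling,
unit-specific case mix and medication effects are deliberately absent).

Planted integer counts — minors (default 19 of 5275 stays), excluded first
diagnoses (10%), out-of-bounds error values (0.1% of labs) — are inserted
exactly and disjointly, with every excluded stay guaranteed at least one
event so the cascade, not the no-event filter, removes it.

## Numerical choices and degenerate inputs

* Percentages print at 2 decimals with half-up rounding (base `round()` is
  half-even and would disagree with conventional table arithmetic).
* Zero pooled SD: *d* is 0 for equal means, signed `Inf` otherwise; the
  *t* result carries a `degenerate` flag. Identical data across ANOVA
  groups returns F = 0 exactly rather than 0/0 noise. A constant regression
  outcome reports R² = 0. Rank-deficient designs are a hard error naming
  the collinear columns.
* Empty groups and zero-episode denominators are reported as `NA`
  (undefined), never as 0/0.
* Truncated draws use inverse-CDF sampling, so they are exact and cost one
  uniform each; all randomness flows from the single generator seed, and
  the pipeline itself is deterministic (byte-identical bundles on rerun).

## Problem sizes used by the test-suite

Recovery tests run 50 replicates of 5000-stay cohorts (≈ 60 000 labs each)
and require each planted quantity to land within 3 standard errors in at
least 95% of replicates, with attrition counts exact in every replicate;
matcher equivalence runs on 1000 random dense instances of up to 300
events. These sizes give comfortable Monte-Carlo resolution for every
planted quantity while keeping a full test run to a couple of minutes.

## Known limitations

* The package audits *ordering behaviour*, not outcomes: no adverse-event,
  mortality or cost modelling.
* Repeated orders inside one window collapse to a single "1R" — the rarer
  multi-repletion bursts are not modelled as separate scenarios.
* Combination products (e.g. potassium phosphate) map to a single
  electrolyte under the default item map; cross-electrolyte linkage exists
  behind a configuration flag but is off by default.
* Lab timestamps are draw times, not result-availability times; true
  decision latency is therefore underestimated by the assay turnaround.
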