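---
title: "Constructing representative cancer sample cohorts by stratified sampling with an FPC representativeness guarantee"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing representative cancer sample cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratcohort)
```

## The problem

National cancer registries linked to claims and death data are too
sensitive to release in full. A practical compromise is a *sample cohort*:
a roughly 20% subsample, released under de-identification constraints,
that researchers can treat as representative of the registry population.
`stratcohort` implements the construction recipe behind the Korean
K-CURE cancer sample cohorts (stomach, breast, colorectal, liver;
diagnoses 2012–2019) and its validation suite, against a synthetic
registry population standing in for the access-restricted linked data.

The pipeline is: eligibility exclusions → privacy suppression →
stratification → proportional-allocation sampling with a
representativeness guarantee → survival validation → descriptive
reporting. The `analysis/` scripts run these stages in order; every
computation lives in the package and is unit-tested.

## Stratification and privacy rules

Records flagged as secondary cancers, records missing any of age, sex,
region, diagnosis year, cancer type or stage, and male breast-cancer
records are excluded (the breast target population is female only).
Strata are the cross of cancer type × diagnosis year × sex × age group ×
region (17 first-level divisions) × SEER summary stage. Age is collapsed
to six groups — 0–39, four 10-year bands, ≥80 — because the extreme ages
are sparse. Two conventions needed fixing where the published account is
ambiguous:

* **Age boundary.** The text description ("<39") and the table labels
  ("0-39") disagree at age 39; we follow the table labels (ages ≤39 in
  the first group) so the recoding is total.
* **Region collapse.** The 17→3 recoding (metropolitan / city / rural)
  used for released tables is administrative and not published at the
  17-level resolution; it is a mandatory configuration table here, with
  `example_region3_mapping()` provided for tests and demonstrations, and
  stratification always uses the 17-level region.

Strata with fewer than five members are *suppressed*: their patients are
removed from the target population entirely, the size-5 rule limiting
re-identification risk from rare covariate combinations. Note that at
simulated scales well below the real registry (about 826,000 patients)
suppression removes a visibly larger share of patients; the partition
accounting (kept + suppressed = eligible) is asserted in the tests.

## The sampler

Within each stratum of size $N_h$, the allocation is proportional:
$n_h = \min(N_h, \lceil 0.2\,N_h \rceil)$ (ceiling, so tiny strata still
contribute at least one patient). A candidate is a simple random sample
without replacement, and it is *representative* when the stratum
population mean of annual medical cost lies inside the closed interval

$$\bar y_h \pm z \sqrt{\frac{N_h - n_h}{N_h - 1}}\; \frac{\sigma_h}{\sqrt{n_h}},$$

with $z = 1.96$ and $\sigma_h$ the *population* standard deviation of the
stratum (divide-by-$N_h$ convention — it is treated as known, not
estimated). If the first draw is representative it is kept; otherwise up
to 50 candidates are drawn at this $n_h$ and, among the representative
ones, the candidate whose mean is closest to the population mean wins
(ties to the earliest draw). If none is representative, $n_h$ grows by
one (configurable) and the process repeats; a census is always
representative, so termination is guaranteed, and the per-stratum
guarantee — population mean inside the accepted candidate's interval —
is asserted on every run.

Design choices that were genuinely open:

* **First-draw acceptance.** The published wording implies resampling
  only on failure; that is the default. `always_best_of_k = TRUE`
  switches to always drawing the full candidate set and keeping the
  closest representative mean.
* **Allocation rounding** (ceiling) and **augmentation step** (+1) are
  unstated in the source; ceiling guarantees nonempty samples, +1 is the
  smallest perturbation of the allocation. Ceiling is also why realised
  fractions sit above 20% (about 22.9% at the simulated scale, against
  20.5–22.0% published at full scale): a stratum of 6 contributes 2 of 6.
* **RNG discipline.** One master seed; each stratum draws on an
  independent substream keyed by a hash of its stratum key, so adding or
  removing a stratum never perturbs another stratum's draws. Everything
  downstream of a config (which includes its seed) is reproducible
  byte-for-byte.

The 1%-margin-of-error sizes ($n_0 = (z\sigma_h/d)^2$ with
$d = 0.01\,\bar Y_h$, FPC-deflated to $N_h n_0 / (n_0 + N_h - 1)$,
rounded up, capped at $N_h$) are reported per stratum. At full registry
scale a 20% allocation dwarfs these sizes; in small or high-variance
strata the closed form can exceed 20%, and the report flags such strata
rather than resolving which aggregation level the published claim refers
to.

## Survival validation

Per stratum, the sample is compared with the stratum population by a
one-sample log-rank test: with $\Lambda$ the population's Nelson–Aalen
cumulative hazard, $O$ the sample's observed deaths and
$E = \sum_i \Lambda(T_i)$ over the sample's follow-up times,
$Z = (O - E)/\sqrt{E}$ is referred to a standard normal, two-sided. The
classic variance-$E$ form is used; an exact self-consistency follows
from the estimator algebra — a sample equal to its reference population
gives $O = E$ and $p = 1$ — which the census-rate pipeline test
exercises end to end. Ties are handled events-first; $E = 0$ with
$O = 0$ passes with $p = 1$, and $E = 0$ with $O > 0$ is reported as an
undefined-test failure.

One subtlety matters for interpreting pass rates: the sample *is* a 20%
subset of its reference population, so $O$ and the estimated $\Lambda$
are positively correlated and the test is conservative — pass
proportions land above the nominal 95% (96–99% on synthetic cohorts,
against 91.1–97.9% published). The Monte-Carlo size check therefore
draws each replicate sample independently of a fresh, much larger
reference population (equivalently SRSWOR at a negligible fraction),
under which the empirical size at $\alpha = 0.05$ falls in the binomial
band [0.035, 0.065] at 2,000 replicates, and power against a doubled
hazard exceeds 0.8 by a wide margin at roughly 200 events. Pass
proportions are reported both over all strata and over strata above a
configurable event-count floor, since the published aggregation level is
unstated.

Cohort-level checks compare Kaplan–Meier curves of population and sample
per cancer type (sup-distance below 0.05 on cohorts of several thousand;
observed ≈ 0.017 at the simulated scale) and follow-up summaries
(median/min/max of follow-up time regardless of event status — the
convention under which a minimum of 0 years is reportable).

## The synthetic registry

The generator draws, per cancer type, independent categorical marginals
for diagnosis year, sex, age group, 17-level region and SEER stage, with
age/sex/stage/year weights set to the published population tables
(embedded in `published_cohort_counts()`); liver assigns no "in situ"
stage, breast is all-female. Region weights approximate national
population shares, as the published tables only report the 3-level
collapse. Annual cost is lognormal per cancer × age cell, matched to the
published cell means and SDs (7,900–14,000 USD, SDs of the same order —
SD ≈ mean indicates strong right skew, hence lognormal). Within-cell age
is uniform; patient ids are sequential.

Survival is piecewise-exponential: a per-cancer baseline rate times
stage and age multipliers (ordered in situ < localized < regional <
distant) times a time-profile with a higher first-year rate. The source
publishes only curve shapes and follow-up summaries, so these rates are
the package's own calibration; the stage ordering of the resulting KM
curves is property-tested. Administrative censoring occurs at December
31 of `censor_cutoff_year` (default 2021), with uniform within-year
diagnosis timing; both are parameters because the published follow-up
medians (≈0.5 years for 2019 diagnoses, ≈7.5 for 2012) cannot be
reproduced by any single cutoff convention we could identify, and
follow-up summaries are deliberately not used as numeric targets.
Secondary-cancer flags and missing required fields are injected at 2%
each so the eligibility filter has real work.

What the generator does *not* emulate: correlations between
stratification variables (marginals are independent given cancer type),
claims-level utilization, screening and checkup variables, geographic
incidence gradients, or cost–survival dependence. Passing tests
therefore demonstrate the construction machinery and its guarantees, not
fidelity of any particular synthetic cohort to Korean registry reality.

## Numerical conventions and problem sizes

Display percentages and ratios use round-half-up at one decimal
(matching the published style, where 25.04 must print as 25.0 and 2.05
as 2.1); base R's round-half-to-even is not used for display. Cost SDs
use $n-1$ for reporting cells but the population convention inside the
sampler. Allocation ceilings subtract a $10^{-9}$ guard before
`ceiling()` so that binary float noise (e.g. $0.2 \times 15$) cannot
inflate a sample size. The analysis scripts and acceptance checks run at
25,000 patients per cancer (100,000 rows), where the full pipeline
completes in about a minute; unit tests use populations of 1,200–6,000
per cancer, and exhaustive subset enumeration cross-checks every stratum
with $N_h \le 12$.

## Limitations

The construction assumes cost representativeness (the FPC criterion) is
the binding constraint and lets survival representativeness follow from
sample size; the one-sample log-rank stage checks, but does not enforce,
survival agreement. Published stratum counts, pass proportions, cost
means and follow-up medians depend on the restricted registry data and
are not reproducible at synthetic scale; only the printed-table
arithmetic (sampling fractions, age proportions, sex ratios) is exactly
recomputable, and the pass-proportion range is retained as a
plausibility band only.
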