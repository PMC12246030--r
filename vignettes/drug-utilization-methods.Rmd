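---
title: "Methods: episode construction, utilization metrics and competing-risks estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: episode construction, utilization metrics and competing-risks estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxpersist)
```

`rxpersist` reconstructs treatment exposure from dispensation records and
estimates discontinuation, reinitiation, switching, adherence and their
covariate associations under the competing risk of death. This vignette is
the package's account of the underlying methods: the conventions it adopts,
the parameters that matter, the synthetic data it validates itself on, and
what that validation does and does not demonstrate.

## Time and interval conventions

All computations run on integer day indices (`as_day()` converts ISO dates
against a configurable epoch, default 2017-01-01) and half-open intervals
`[start, end)`. A fill on day `d` with `s` days of supply covers days
`d, ..., d + s - 1`. Events on the index day are assigned time 0.5
("end of day"), keeping all survival times strictly positive.

## New-user cohorts

A person enters the cohort of a drug class when their first-ever fill of
that class — over the entire available fill history, i.e. a full-history
washout rather than a fixed window — falls inside the inclusion window.
That fill's day is the index day. Follow-up runs to the earliest of death,
emigration and the administrative study end; at ties, death takes
precedence over emigration over administrative censoring (configurable). A
person who dies on the index day is retained and censored at the end of
that day. Cohorts for different classes are assembled independently, so
the same person can appear in several, and initiating another class never
censors follow-up.

## Coverage, stockpiling and grace-period episodes

With stockpiling (the default), a refill made before the pooled supply of
earlier fills is exhausted is queued behind it: coverage for fill *k* ends
at `end_k = max(fill_k, end_{k-1}) + s_k`. Total covered time then equals
total dispensed days — an invariant the tests check on random fill streams.
Same-day fills pool their supply. Supplies pool across *drug codes within
the class*, because exposure is defined at class level; a switch therefore
never interrupts an episode. Without stockpiling, fill intervals are
unioned and overlapping days count once.

Episodes are built from the resulting disjoint coverage segments with a
grace period `g`: consecutive segments separated by at most `g` uncovered
days belong to one episode; a larger gap closes the episode with
**discontinuation day = supply end + g**, and the next segment's start is
the reinitiation day. An episode whose supply end plus grace reaches past
the end of follow-up is `ongoing_at_censor`: its discontinuation cannot be
observed inside the study. Coverage that starts after the end of follow-up
(e.g. fills recorded after death — data noise) is dropped with a logged
count.

Two event-time conventions exist in the literature: the grace-inclusive
discontinuation day, and the end of supply. The package uses the former as
the default event time in time-to-event analyses (it is the natural
reading of "no refill within the grace period"), with
`event_time = "supply_end"` available; the *definition* of which episodes
are discontinued is unaffected by this flag. When a discontinuation day
coincides with death, discontinuation is taken to occur first.

Only the first discontinuation per person enters the headline
discontinuation and reinitiation analyses; all cycles are retained for the
proportion of patients covered. Whether later cycles should also feed the
reinitiation analysis is genuinely open; first-cycle-only is the default
because repeated events within person would otherwise require robust
variances downstream.

## Trajectories and switching

For every cohort member with full potential follow-up
(`index + horizon <= study end`; horizon default 1095 days), the package
records a time-ordered path of at most `max_events = 5` events: first
within-class switch, discontinuation(s), reinitiation(s), death or
emigration, and continued treatment at the horizon. Later events are
truncated rather than re-coded. Only the first switch is a path event;
*all* switches contribute to the switch matrix, whose percentages are
relative to the number of initiators of the origin category. Code changes
inside an aggregate "other" category count as switches but are not further
categorised. Among persons in the discontinued state at the horizon,
"later reinitiated" means any reinitiation after their first
discontinuation during the full follow-up, which may fall beyond the
horizon — this is the reading under which the three terminal-state shares
and the reinitiated share are simultaneously well-defined.

## Adherence (PDC) and proportion of patients covered (PPC)

PDC is the number of days covered by raw supply (no grace extension)
within `[index, index + 365)` divided by 365, for persons alive at one
year; emigration does not exclude, since dispensations remain observable
up to emigration. Threshold shares at ≥80%, ≥90% and exactly 100% are
reported along with mean, SD, median and IQR on the percent scale. When
fills never overlap, PDC is invariant to the stockpiling flag (tested).

PPC at time *t* since initiation is the share of patients with ongoing
grace-extended treatment — counting any number of
discontinuation/reinitiation cycles — among those alive, not emigrated,
and (by default) enrolled early enough that `index + t` does not exceed
the study end. That administrative-coverage exclusion is a deliberate
design choice: without it, late initiators mechanically deflate late-time
PPC; `admin_exclude = FALSE` restores the naive denominator. The default
evaluation grid is every 30 days to five years.

## Aalen–Johansen estimator

For records (time, event ∈ {0 censored, 1 interest, 2 competing}), the
cause-*k* cumulative incidence is
`CIF_k(t) = Σ_{t_i ≤ t} S(t_i−) d_k(t_i)/n(t_i)` with `S` the all-cause
Kaplan–Meier. The implementation guarantees
`CIF_1 + CIF_2 + S = 1` at every jump to numerical tolerance (the update
telescopes exactly), reduces to `1 − KM` when no competing events are
present, and matches the multistate machinery of `survival::survfit` to
machine precision in the tests. Pointwise variance uses the standard
counting-process (Marubini–Valsecchi) estimator; 95% intervals are
computed on the complementary log-log scale,
`CIF^{exp(±z·se/(CIF·log CIF))}`, and clipped to [0, 1] — the transform is
chosen because it respects the range of a probability; the source studies
rarely state theirs. Step evaluation is right-continuous: at a jump time
the post-jump value is returned. All-censored input yields a zero CIF
with a warning rather than an error.

## Fine–Gray sub-distribution hazard model

The fit maximizes the IPCW-weighted Breslow partial likelihood: at each
cause-1 event time, the risk set contains subjects still event-free plus
subjects with a *prior competing event*, the latter weighted
`w_i(t) = G(t−)/G(T_i−)` where `G` is the Kaplan–Meier estimate of the
censoring distribution with failures preceding censorings at ties.
Optimization is Newton–Raphson with step-halving from β = 0; convergence
is declared when the relative log-likelihood change falls below `tol`
(default 1e-9), and a fit that exhausts `max_iter` is returned flagged,
not thrown. Risk-set sums are computed with suffix/prefix cumulative sums
over time-sorted subjects, so each iteration is O(n log n) rather than
O(n·events). Breslow tie handling was chosen for its simplicity and
because it makes the no-censoring/no-competing limit *exactly* the Cox
partial likelihood — an identity the tests verify against both
`survival::coxph` and a brute-force one-dimensional likelihood maximizer.
Coefficients also agree with `cmprsk::crr` on competing-risks data.

The reported covariance is the inverse observed information. This is the
correct asymptotic variance when censoring is administrative
(censoring-complete), where all weights are exactly 1; with heavy random
censoring it omits the correction for estimating `G` and is mildly
approximate — `cmprsk::crr`'s robust variance is the reference there, and
the tests document the difference. The CI-coverage validation therefore
simulates from a sub-distribution model (unit-exponential mixture CIF,
`simulate_fine_gray()`) with fixed administrative censoring, under which
nominal coverage of the model-based interval is the theoretically correct
expectation. Age enters adjusted models as bands rather than a continuous
term, matching common register practice; per-covariate fits adjusted for
sex and age (rather than one joint model) mirror how such association
tables are usually reported, via `fg_extra` in `run_study()`.

## The synthetic register generator

`simulate_registry()` emulates the structure of a national prescription
register for one drug class: patients initiate uniformly over a five-year
entry window (days 0–1824) with follow-up to day 2190 (one further year);
a configurable fraction (default 5%) initiates *before* the window and
must be excluded by the cohort stage. While a latent, covariate-scaled
exponential discontinuation clock runs, refills are emitted with pooled
supply (default 30 days w.p. 0.7 / 90 days w.p. 0.3) and gaps drawn from
a mixture — early refills (−10..−1 days, 15%), short (0–20, 70.5%),
medium (21–60, 14%) and occasional long gaps (61–365, 0.5%). Latent
discontinuation stops refilling; a Bernoulli(0.58) share of discontinuers
reinitiates after an Exp(1/250 per day) delay. A single exponential
reinitiation hazard cannot produce the plateauing reinitiation incidence
seen in register studies (roughly 40% at one year but under 60% at three),
which is why the generator uses this cure-fraction mixture. Death
(4e-5/day) and emigration (6e-6/day) censor everything; switching flips
the drug code at refills with probability 0.015 under a category
transition matrix. Covariate effects on the discontinuation hazard
default to directions reported in register studies of glucose-lowering
drugs (male ≈ 0.95; obesity protective, down to ≈ 0.64; age-band effects
0.70–0.80 vs <50).

These defaults were fixed once, by calibration to published register
quantities *before* any estimator was run on the output, and are treated
as study conditions, not tuning knobs. The generator deliberately
reproduces the field's central measurement problem: the observable
discontinuation day (last supply end + grace) is a lagged, granular proxy
for the latent decision time, so observed incidence depends materially on
the grace period while PPC does not — the property the acceptance tests
formalise as "largest PPC gap across graces below half the 3-year CIF
spread, with CIFs strictly decreasing in grace".

What the generator does **not** emulate: dose titration and
package-size/duration correlation, seasonal or calendar effects,
prescriber-level clustering, informative censoring (death correlated with
recent discontinuation), comorbidity registries, and missing-data
mechanisms. Tests passing on this generator therefore validate the
*algorithms* — episode logic, metric definitions, estimator correctness
and parameter recovery — not the clinical realism of any particular
number.

Ground truth is logged per patient (latent discontinuation times, last
supply end per cycle, reinitiation days, death/emigration times), which
enables two exact checks: with grace exceeding every possible refill gap,
the derived discontinuations equal ground-truth last-supply-end + grace
*exactly*; and on the latent timescale the Aalen–Johansen estimate
converges to the closed form
`CIF_d(t) = λ_d/(λ_d+λ_m)·(1 − e^{−(λ_d+λ_m)t})` (`ground_truth_cif()`).
The closed form holds for latent times, not the grace-shifted observable
ones, so the estimator check runs on `ground_truth_records()` while the
shift itself is covered by the exact pipeline-recovery test.

## Problem sizes and numerical tolerances

The validation suite uses sizes chosen to make Monte-Carlo error small
relative to each check: 1,000 random fill streams × 5 grace periods
against a day-by-day scanner; probability conservation to 1e-10 and the
Kaplan–Meier reduction to 1e-12; the Cox limit to 1e-6 against a
brute-force maximizer at n = 30; Fine–Gray recovery at n = 2,000 (single
replicate, CI must cover sdHR = 2) and 200 replicates at n = 500
(coverage inside the central 99% binomial region around 0.95, bias below
two Monte-Carlo standard errors); Aalen–Johansen versus the closed form
at n = 5,000 within three estimated standard errors at one and three
years; and the grace-sensitivity contrast at n = 2,000. The acceptance
script reproduces the headline pipeline on a 4,000-patient register.

## Known limitations

- The Fine–Gray variance is model-based (see above); under heavy random
  censoring, prefer the robust variance of `cmprsk::crr` for inference.
- Supplies are taken at face value; dose-level exposure (DDD) modelling,
  cross-class switching and reasons for discontinuation are out of scope.
- Missing covariates are labelled `"missing"`; multiple imputation is
  intentionally not implemented.
- Trajectory classification requires full potential follow-up, so late
  initiators are excluded from trajectory summaries by design.
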