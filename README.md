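# rxpersist

Treatment persistence, adherence and competing-risks analysis of
prescription-fill registers.

## The problem

Pharmacy-claims and prescription registers record *dispensations*, not drug
intake. Whether a patient is "still on treatment" must be reconstructed from
the stream of fill dates and days of supply, and every choice in that
reconstruction — how overlapping supplies are handled, how long a refill may
be late before treatment counts as stopped — changes the answer. `rxpersist`
implements the standard reconstruction used in drug-utilization
pharmacoepidemiology for new-user cohorts:

- **Stockpiling.** If a refill arrives before the previous supply is used
  up, the patient is assumed to finish the old supply first, so coverage is
  pooled: total covered time equals total dispensed days of supply.
- **Grace periods.** Treatment is considered discontinued when no refill
  occurs within *g* days (default 90; sensitivity values 30/60/180/365)
  after the estimated end of supply. The discontinuation day is
  `supply end + g`.
- **Reinitiation and switching.** A fill after a discontinuation starts a
  new treatment episode (followed from the discontinuation day); a fill of
  a different drug code within the same class is a switch.
- **Competing risk of death.** Time to discontinuation and time to
  reinitiation are analysed with the Aalen–Johansen estimator of the
  cumulative incidence function,
  `CIF_k(t) = Σ_{t_i ≤ t} S(t_i−) d_k(t_i)/n(t_i)`,
  and covariate associations with the Fine–Gray sub-distribution hazard
  model, fitted by the IPCW-weighted partial likelihood in which subjects
  with a prior competing event stay in risk sets with weight
  `w_i(t) = G(t−)/G(T_i−)` (`G` = Kaplan–Meier of the censoring
  distribution). Both estimators are implemented in the package and are
  cross-checked against `survival` and `cmprsk` in the test suite.
- **Utilization metrics.** One-year adherence as proportion of days covered
  (PDC, raw supply, grace excluded) with threshold shares (≥80/≥90/100%),
  and the proportion of patients covered (PPC) over time — the share of
  alive, non-emigrated initiators with ongoing grace-extended treatment,
  counting reinitiated patients — which is far less sensitive to the grace
  period than time-to-event discontinuation.
- **Trajectories.** Per-patient event paths over a 3-year horizon (first
  switch, discontinuations, reinitiations, death/emigration, continued
  treatment; at most five events) with cohort-level percentage summaries
  and a within-class switch matrix.

Because real prescription registers cannot be redistributed, the package
ships a synthetic register generator (`simulate_registry()`): a multistate
prescription-behaviour model with latent discontinuation/reinitiation
clocks, mixture-distributed refill gaps, switching, death and emigration,
plus a ground-truth event log, so the whole pipeline and both estimators
are testable end to end.

## Who it is for

Pharmacoepidemiologists and biostatisticians running new-user
drug-utilization studies on tabular fill/person data (any register with
patient id, drug code, fill date, days of supply), and methodologists who
need a transparent, oracle-tested reference implementation of
grace-period episode construction and IPCW competing-risks estimation.

## Worked example

```r
library(rxpersist)

cfg <- sim_config(n_patients = 500, seed = 11)   # synthetic register
sim <- simulate_registry(cfg)

cohort <- assemble_new_users(sim$fills, sim$persons, "GLP1",
                             inclusion_window = cfg$entry_window,
                             study_end_day = cfg$study_end_day)
coverage <- build_coverage(sim$fills[sim$fills$person_id %in% cohort$person_id, ])
episodes <- derive_episodes(coverage, grace_days = 90, cohort)

cif <- aalen_johansen(discontinuation_records(episodes, cohort))
cif_at(cif, c(365, 1095))
#>   time        cif      lower     upper         se
#> 1  365 0.08532169 0.06252425 0.1124425 0.01274420
#> 2 1095 0.23237178 0.19195730 0.2751416 0.02128767
```

8.5% (95% CI 6.3, 11.2) of this synthetic cohort has discontinued one year
after initiation and 23.2% (95% CI 19.2, 27.5) after three years, death
treated as a competing risk. The same bundle of outputs — CIF per grace
period, reinitiation CIF, PPC curves, PDC summary, trajectory summary and
Fine–Gray fits — comes from a single call:

```r
res <- run_study(list(fills = sim$fills, persons = sim$persons,
                      drug_class = "GLP1",
                      inclusion_window = cfg$entry_window,
                      study_end_day = cfg$study_end_day,
                      fg_extra = "bmi_category",
                      out_dir = "study_out"))
res$pdc_summary$mean      # mean 1-year proportion of days covered (%)
res$trajectory_summary$shares
res$fg_fits$bmi_category  # sdHRs adjusted for sex and age
```

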