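test_that("PDC counts raw supply days inside the 1-year window, capped", {
  persons <- data.frame(person_id = c("full", "six", "over", "dead"),
                        death_day = c(NA, NA, NA, 200L))
  f <- function(id, d, s) data.frame(person_id = id, fill_day = d, days_supply = s)
  fills <- rbind(f("full", 0, 400), f("six", seq(0, 150, 30), 30),
                 f("over", c(0, 10), c(360, 360)), f("dead", 0, 365))
  coh <- toy_cohort(c("full", "six", "over", "dead"), index = 0L, fu_end = 2190L)
  coh$end_reason[4] <- "death"; coh$follow_up_end_day[4] <- 200L
  pdc <- proportion_days_covered(build_coverage(fills), coh, persons)
  # continuous supply beyond a year -> 1.0
  expect_equal(pdc$pdc[pdc$person_id == "full"], 1.0)
  # six 30-day fills back-to-back -> 180/365
  expect_equal(pdc$pdc[pdc$person_id == "six"], 180 / 365)
  # stockpiled overlap extending past day 365 is capped at the window
  expect_equal(pdc$days_covered[pdc$person_id == "over"], 365L)
  # dead before index + window: excluded, not zero
  expect_false("dead" %in% pdc$person_id)
})

test_that("PDC is invariant to stockpiling when fills never overlap", {
  set.seed(77)
  for (i in 1:20) {
    k <- sample(1:6, 1)
    d <- cumsum(c(0, sample(31:80, k - 1, replace = TRUE)))
    fills <- data.frame(person_id = "X", fill_day = d,
                        days_supply = sample(5:30, k, replace = TRUE))
    coh <- toy_cohort("X", 0L, 2190L)
    persons <- data.frame(person_id = "X", death_day = NA_integer_)
    p1 <- proportion_days_covered(build_coverage(fills, TRUE), coh, persons)
    p2 <- proportion_days_covered(build_coverage(fills, FALSE), coh, persons)
    expect_equal(p1$pdc, p2$pdc)
  }
})

test_that("pdc_summary reports threshold shares and moments on the percent scale", {
  res <- data.frame(person_id = c("a", "b"), days_covered = c(365L, 183L),
                    window_days = 365L, pdc = c(1.0, 0.5))
  s <- pdc_summary(res)
  expect_equal(s$pct_ge80, 50)
  expect_equal(s$pct_ge90, 50)
  expect_equal(s$pct_100, 50)
  expect_equal(s$mean, 75)
  res2 <- res; res2$pdc <- 1.0; res2$days_covered <- 365L
  s2 <- pdc_summary(res2)
  expect_equal(c(s2$pct_ge80, s2$pct_ge90, s2$pct_100), c(100, 100, 100))
  expect_error(pdc_summary(res[0, ]), "no PDC results")
})

test_that("simulated mean PDC matches the renewal closed form of the generator", {
  # deterministic supply 30 and gap 10: cycle 40 days; in 365 days every
  # patient covers 9 * 30 + 5 = 275 days -> PDC = 275/365 for everyone
  cfg <- sim_config(n_patients = 150,
                    supply_days = list(values = 30, probs = 1),
                    gap_mix = list(probs = c(short = 1), short = c(10, 10)),
                    lambda_disc = 0, lambda_death = 0, lambda_emig = 0,
                    p_switch = 0, prevalent_frac = 0, seed = 88)
  sim <- simulate_registry(cfg)
  coh <- assemble_new_users(sim$fills, sim$persons, cfg$drug_class,
                            cfg$entry_window, cfg$study_end_day)
  pdc <- proportion_days_covered(build_coverage(sim$fills), coh, sim$persons)
  expect_true(all(pdc$pdc == 275 / 365))
})

test_that("PPC is covered/at-risk with grace-consistency checking", {
  f <- function(id, d, s) data.frame(person_id = id, fill_day = d, days_supply = s)
  fills <- rbind(f("a", 0, 400), f("b", 0, 60))
  coh <- toy_cohort(c("a", "b"), index = 0L, fu_end = 2190L)
  ep <- derive_episodes(build_coverage(fills), 90, coh)
  ppc <- proportion_patients_covered(ep, coh, 90, eval_days = c(0, 200, 365),
                                     study_end_day = 2190)
  # at t = 200: a covered (supply to 400), b's grace ended at 150 -> 1/2
  expect_equal(ppc$ppc, c(1, 0.5, 0.5))
  expect_equal(ppc$at_risk, c(2L, 2L, 2L))
  # requesting a different grace than the episodes were built with errors
  expect_error(proportion_patients_covered(ep, coh, 60, study_end_day = 2190),
               "grace")
  # everyone continuously treated -> ppc identically 1
  ep1 <- derive_episodes(build_coverage(f("a", 0, 400)), 90, coh[1, ])
  ppc1 <- proportion_patients_covered(ep1, coh[1, ], 90,
                                      eval_days = seq(0, 360, 120),
                                      study_end_day = 2190)
  expect_true(all(ppc1$ppc == 1))
})

test_that("denominators shrink only via death/emigration/administrative end", {
  f <- data.frame(person_id = c("a", "b", "late"),
                  fill_day = c(0L, 0L, 2000L), days_supply = 30L)
  coh <- toy_cohort(c("a", "b", "late"), index = c(0L, 0L, 2000L),
                    fu_end = c(2190L, 300L, 2190L),
                    reason = c("admin_censor", "death", "admin_censor"))
  ep <- derive_episodes(build_coverage(f), 90, coh)
  ppc <- proportion_patients_covered(ep, coh, 90, eval_days = c(0, 365),
                                     study_end_day = 2190)
  # t=0: all three enrolled; t=365: b dead, late's index+365 > study end
  expect_equal(ppc$at_risk, c(3L, 1L))
  ppc2 <- proportion_patients_covered(ep, coh, 90, eval_days = c(0, 365),
                                      study_end_day = 2190,
                                      admin_exclude = FALSE)
  expect_equal(ppc2$at_risk, c(3L, 2L))
})

test_that("PPC dominates the never-discontinued fraction in uncensored data", {
  cfg <- sim_config(n_patients = 250, lambda_death = 0, lambda_emig = 0,
                    prevalent_frac = 0, seed = 99)
  sim <- simulate_registry(cfg)
  coh <- assemble_new_users(sim$fills, sim$persons, cfg$drug_class,
                            cfg$entry_window, cfg$study_end_day)
  ep <- derive_episodes(build_coverage(sim$fills), 90, coh)
  grid <- seq(0, 1095, by = 90)
  ppc <- proportion_patients_covered(ep, coh, 90, eval_days = grid,
                                     study_end_day = cfg$study_end_day)
  # brute-force per-patient enumeration of first observed discontinuation
  first_disc <- vapply(coh$person_id, function(id) {
    dd <- ep$discontinuation_day[ep$person_id == id & ep$status == "discontinued"]
    if (length(dd) == 0) Inf else min(dd)
  }, numeric(1))
  idx <- coh$index_day
  for (k in seq_along(grid)) {
    t <- grid[k]
    in_denom <- idx + t <= cfg$study_end_day
    frac_never <- sum(first_disc[in_denom] > idx[in_denom] + t) / sum(in_denom)
    expect_gte(ppc$ppc[k] + 1e-12, frac_never)
  }
})
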