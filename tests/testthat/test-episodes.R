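test_that("days-of-supply lookup multiplies packages and rejects unknown codes", {
  rec <- data.frame(drug_code = c("A", "A", "B", "Z"),
                    n_packages = c(2, 1, 3, 1))
  tab <- c(A = 30, B = 10)
  expect_message(out <- resolve_days_supply(rec, tab), "1 record")
  expect_equal(out$days_supply, c(60L, 30L, 30L))
  expect_equal(attr(out, "n_rejected"), 1L)
  out2 <- resolve_days_supply(rec, tab, default = 30)
  expect_equal(out2$days_supply[4], 30L)
  rec$n_packages[1] <- -1
  expect_error(resolve_days_supply(rec, tab), "positive")
})

test_that("stockpiling pools overlapping supply; gaps are preserved", {
  f <- function(d, s) data.frame(person_id = "X", fill_day = d, days_supply = s)
  # overlap: second fill starts when first supply ends
  expect_equal(build_coverage(f(c(0, 20), c(30, 30)))[, c("start_day", "end_day")],
               data.frame(start_day = 0L, end_day = 60L))
  # single fill
  expect_equal(build_coverage(f(0, 90))$end_day, 90L)
  # gap preserved
  seg <- build_coverage(f(c(0, 100), c(30, 30)))
  expect_equal(seg$start_day, c(0L, 100L))
  expect_equal(seg$end_day, c(30L, 130L))
  # same-day fills pool their supply
  expect_equal(build_coverage(f(c(5, 5), c(10, 20)))$end_day, 35L)
  # without stockpiling, overlaps are unioned (days counted once)
  seg2 <- build_coverage(f(c(0, 20), c(30, 30)), stockpiling = FALSE)
  expect_equal(seg2$end_day - seg2$start_day, 50L)
})

test_that("stockpiling conserves total dispensed days over random streams", {
  set.seed(202)
  for (i in 1:50) {
    fills <- random_fill_stream()
    seg <- build_coverage(fills, stockpiling = TRUE)
    expect_equal(sum(seg$end_day - seg$start_day), sum(fills$days_supply))
    expect_true(all(seg$end_day > seg$start_day))
    expect_true(all(diff(seg$start_day) > 0))
    # segments disjoint
    if (nrow(seg) > 1) expect_true(all(seg$start_day[-1] > seg$end_day[-nrow(seg)]))
  }
})

test_that("episodes close when the refill gap exceeds the grace period", {
  f <- function(d, s) data.frame(person_id = "X", fill_day = d, days_supply = s)
  # single 60-day supply, grace 90: discontinuation at day 150
  ep <- derive_episodes(build_coverage(f(0, 60)), 90, 400)
  expect_equal(ep$discontinuation_day, 150L)
  expect_equal(ep$status, "discontinued")
  # gap 140 > 90: two episodes, reinitiation at 200
  ep2 <- derive_episodes(build_coverage(f(c(0, 200), c(60, 30))), 90, 1000)
  expect_equal(ep2$episode_index, c(1L, 2L))
  expect_equal(ep2$discontinuation_day, c(150L, 320L))
  expect_equal(ep2$reinitiation_day, c(200L, NA_integer_))
  # same fills, but follow-up ends before 320: second episode ongoing
  ep3 <- derive_episodes(build_coverage(f(c(0, 200), c(60, 30))), 90, 300)
  expect_equal(ep3$status, c("discontinued", "ongoing_at_censor"))
  expect_true(is.na(ep3$discontinuation_day[2]))
  # gap 80 <= 90: a single episode
  ep4 <- derive_episodes(build_coverage(f(c(0, 140), c(60, 30))), 90, 1000)
  expect_equal(nrow(ep4), 1L)
  expect_equal(ep4$supply_end_day, 170L)
})

test_that("derive_episodes is idempotent on its own episode spans", {
  set.seed(303)
  for (i in 1:20) {
    fills <- random_fill_stream()
    ep <- derive_episodes(build_coverage(fills), 90, 2000)
    again <- derive_episodes(
      data.frame(person_id = "X", start_day = ep$start_day,
                 end_day = ep$supply_end_day), 90, 2000)
    expect_equal(again$start_day, ep$start_day)
    expect_equal(again$supply_end_day, ep$supply_end_day)
    expect_equal(again$status, ep$status)
    expect_equal(again$discontinuation_day, ep$discontinuation_day)
  }
})

test_that("discontinuation records follow index -> first of event/death/censoring", {
  f <- data.frame(person_id = c("a", "b", "c"), fill_day = 0L, days_supply = 60L)
  coh <- toy_cohort(c("a", "b", "c"), index = 0L,
                    fu_end = c(400L, 100L, 120L),
                    reason = c("admin_censor", "death", "admin_censor"))
  ep <- derive_episodes(build_coverage(f), 90, coh)
  rec <- discontinuation_records(ep, coh)
  # a: discontinuation at 150; b: dies at 100 before reaching it; c: censored at 120
  expect_equal(rec$time, c(150, 100, 120))
  expect_equal(rec$event, c(1L, 2L, 0L))
  # supply-end convention moves the event time, not the definition
  rec2 <- discontinuation_records(ep, coh, event_time = "supply_end")
  expect_equal(rec2$time[1], 60)
  expect_equal(rec2$event, rec$event)
})

test_that("reinitiation follow-up starts at the discontinuation day", {
  f <- function(d, s, id) data.frame(person_id = id, fill_day = d, days_supply = s)
  fills <- rbind(f(c(0, 200), c(60, 30), "a"), f(0, 60, "b"), f(0, 60, "c"))
  coh <- toy_cohort(c("a", "b", "c"), index = 0L,
                    fu_end = c(500L, 500L, 180L),
                    reason = c("admin_censor", "admin_censor", "death"))
  ep <- derive_episodes(build_coverage(fills), 90, coh)
  rr <- reinitiation_followup(ep, coh)
  rr <- rr[order(rr$person_id), ]
  # a: discontinued 150, reinitiated 200 -> time 50
  # b: discontinued 150, censored 500 -> time 350
  # c: discontinued 150, dies 180 -> competing event at 30
  expect_equal(rr$time, c(50, 350, 30))
  expect_equal(rr$event, c(1L, 0L, 2L))
})

test_that("switches are fill-level code changes; 'other' internal moves count", {
  fills <- data.frame(
    person_id = "X",
    fill_day = c(0, 30, 60, 90, 120),
    drug_code = c("A10BJ02", "A10BJ02", "A10BJ06", "A10BJ01", "A10BJ03"),
    drug_category = c("liraglutide", "liraglutide", "semaglutide", "other", "other"))
  sw <- detect_switches(fills)
  expect_equal(nrow(sw), 3L)
  expect_equal(sw$from_category, c("liraglutide", "semaglutide", "other"))
  expect_equal(sw$to_category, c("semaglutide", "other", "other"))
  expect_equal(sw$day, c(60, 90, 120))
  # single code: no switches
  expect_equal(nrow(detect_switches(fills[1:2, ])), 0L)
})

test_that("derived episodes match a day-by-day scanner on randomized streams", {
  set.seed(404)
  graces <- c(30, 60, 90, 180, 365)
  for (i in 1:200) {
    fills <- random_fill_stream()
    fu_end <- sample(600:2200, 1)
    seg <- build_coverage(fills)
    for (g in graces) {
      got <- suppressMessages(derive_episodes(seg, g, fu_end))
      want <- brute_episodes(fills$fill_day, fills$days_supply, g, fu_end)
      expect_equal(got$start_day, want$start_day)
      expect_equal(got$supply_end_day, want$supply_end_day)
      expect_equal(got$status, want$status)
      expect_equal(got$discontinuation_day, want$discontinuation_day)
      expect_equal(got$reinitiation_day, as.integer(want$reinitiation_day))
    }
  }
})

test_that("observed discontinuations by a horizon are non-increasing in grace", {
  cfg <- sim_config(n_patients = 300, seed = 505)
  sim <- simulate_registry(cfg)
  coh <- assemble_new_users(sim$fills, sim$persons, cfg$drug_class,
                            cfg$entry_window, cfg$study_end_day)
  seg <- build_coverage(sim$fills[sim$fills$person_id %in% coh$person_id, ])
  n_disc_by <- vapply(c(60, 90, 180, 365), function(g) {
    ep <- derive_episodes(seg, g, coh)
    idx <- coh$index_day[match(ep$person_id, coh$person_id)]
    length(unique(ep$person_id[ep$status == "discontinued" &
                                 ep$discontinuation_day <= idx + 1095]))
  }, numeric(1))
  expect_true(all(diff(n_disc_by) <= 0))
})
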