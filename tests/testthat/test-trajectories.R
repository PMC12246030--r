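test_that("trajectory paths order events and carry the terminal state", {
  f <- function(id, d, s, code = "A10BJ02", cat = "liraglutide") {
    data.frame(person_id = id, fill_day = d, days_supply = s,
               drug_code = code, drug_category = cat)
  }
  fills <- rbind(
    f("cont", seq(0, 1170, by = 30), 30),              # continuous coverage
    f("dr", c(0, 600), c(310, 600)),                   # disc 400, reinit 600, covered at 1095
    rbind(f("sw", 0, 100), f("sw", 100, 710, code = "A10BJ06", cat = "semaglutide")))
  coh <- toy_cohort(c("cont", "dr", "sw"), index = 0L, fu_end = 2000L)
  ep <- derive_episodes(build_coverage(fills), 90, coh)
  sw <- detect_switches(fills)
  traj <- classify_trajectory(ep, sw, coh, study_end_day = 2000)
  traj <- traj[order(traj$person_id), ]
  expect_equal(traj$path[traj$person_id == "cont"], "continued")
  expect_equal(traj$path[traj$person_id == "dr"],
               "discontinuation > reinitiation > continued")
  # sw: switch at 100, supply ends 810, discontinuation 900, never reinitiates
  expect_equal(traj$path[traj$person_id == "sw"], "switch > discontinuation")
  expect_equal(traj$terminal, c("continued", "continued", "discontinued"))
  expect_equal(traj$ever_switched, c(FALSE, FALSE, TRUE))
  expect_equal(traj$reinitiated_later, c(FALSE, TRUE, FALSE))
  expect_equal(traj$first_switch_from[traj$person_id == "sw"], "liraglutide")
  expect_equal(traj$first_switch_to[traj$person_id == "sw"], "semaglutide")
})

test_that("death before the horizon terminates the path", {
  fills <- data.frame(person_id = "d", fill_day = 0L, days_supply = 60L,
                      drug_code = "A10BJ02", drug_category = "liraglutide")
  coh <- toy_cohort("d", index = 0L, fu_end = 500L, reason = "death")
  ep <- derive_episodes(build_coverage(fills), 90, coh)
  traj <- classify_trajectory(ep, detect_switches(fills), coh, study_end_day = 2000)
  expect_equal(traj$terminal, "died_or_emigrated")
  expect_equal(traj$path, "discontinuation > died_or_emigrated")
  # late initiators without full potential follow-up are not classified
  coh2 <- toy_cohort("d", index = 1500L, fu_end = 2000L)
  expect_equal(nrow(classify_trajectory(ep, detect_switches(fills), coh2,
                                        study_end_day = 2000)), 0L)
})

test_that("paths are truncated at max_events", {
  # four disc/reinit cycles -> 8 events before the horizon
  fills <- data.frame(person_id = "m", fill_day = c(0, 200, 400, 600, 800),
                      days_supply = 30, drug_code = "A10BJ02",
                      drug_category = "liraglutide")
  coh <- toy_cohort("m", index = 0L, fu_end = 2000L)
  ep <- derive_episodes(build_coverage(fills), 90, coh)
  traj <- classify_trajectory(ep, detect_switches(fills), coh, study_end_day = 2000)
  expect_equal(traj$n_events, 5L)
  expect_equal(traj$path,
               paste("discontinuation > reinitiation > discontinuation >",
                     "reinitiation > discontinuation"))
  traj3 <- classify_trajectory(ep, detect_switches(fills), coh,
                               study_end_day = 2000, max_events = 3)
  expect_equal(traj3$n_events, 3L)
})

test_that("trajectory summary reproduces hand-counted shares", {
  traj <- data.frame(
    person_id = c("a", "b", "c", "d"),
    path = c("discontinuation", "discontinuation > reinitiation > discontinuation",
             "continued", "died_or_emigrated"),
    n_events = c(1L, 3L, 1L, 1L),
    terminal = c("discontinued", "discontinued", "continued", "died_or_emigrated"),
    ever_switched = c(FALSE, FALSE, FALSE, FALSE),
    reinitiated_later = c(FALSE, TRUE, FALSE, FALSE),
    first_switch_from = NA_character_, first_switch_to = NA_character_)
  s <- summarize_trajectories(traj)
  expect_equal(unname(s$shares["pct_discontinued"]), 50.0)
  expect_equal(unname(s$shares["pct_reinitiated_among_discontinued"]), 50.0)
  expect_equal(unname(s$shares["pct_continued"]), 25.0)
  # terminal shares account for everyone
  expect_equal(sum(s$shares[c("pct_discontinued", "pct_continued",
                              "pct_died_or_emigrated")]), 100, tolerance = 0.11)
  # all continued -> zero discontinued
  traj2 <- traj; traj2$terminal <- "continued"
  expect_equal(unname(summarize_trajectories(traj2)$shares["pct_discontinued"]), 0)
  # empty cohort -> zero counts, no error
  s0 <- summarize_trajectories(traj[0, ])
  expect_equal(s0$counts$n_total, 0L)
})

test_that("terminal-state percentages sum to 100 up to rounding on simulated data", {
  cfg <- sim_config(n_patients = 400, seed = 42)
  sim <- simulate_registry(cfg)
  coh <- assemble_new_users(sim$fills, sim$persons, cfg$drug_class,
                            cfg$entry_window, cfg$study_end_day)
  f <- sim$fills[sim$fills$person_id %in% coh$person_id, ]
  ep <- derive_episodes(build_coverage(f), 90, coh)
  traj <- classify_trajectory(ep, detect_switches(f), coh, cfg$study_end_day)
  s <- summarize_trajectories(traj)
  expect_equal(s$counts$n_discontinued + s$counts$n_continued +
                 s$counts$n_died_or_emigrated, s$counts$n_total)
  expect_equal(sum(s$shares[c("pct_discontinued", "pct_continued",
                              "pct_died_or_emigrated")]), 100, tolerance = 0.2)
})
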