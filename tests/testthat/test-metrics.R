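test_that("pair scores follow the difference-in-proportion arithmetic", {
  # A named: 1.2 s on A, 0.8 s on B; B named: 0.9 s on A, 2.1 s on B
  expect_equal(pair_score_from_times(1200, 800, 2100, 900), 0.3)
  # perspective swap gives the same value: P_B = 1 - P_A
  expect_equal(pair_score_from_times(2100, 900, 1200, 800), 0.3)
  # identical looking distributions in both trials cancel
  expect_equal(pair_score_from_times(1000, 1000, 1000, 1000), 0)
  # zero AOI time is undefined, not zero
  expect_true(is.na(pair_score_from_times(0, 0, 1000, 500)))
})

test_that("scores are computed only for pairs with both trials retained", {
  # infant sees apple_foot twice (matching): apple named then foot named
  trials <- rbind(
    make_trial("p1", "t01", target_word = "eple", heard_word = "eple",
               target_side = "left"),
    make_trial("p1", "t02", target_word = "fot", heard_word = "fot",
               target_side = "right"),
    # second pair has only one surviving trial (other is all-invalid)
    make_trial("p1", "t03", pair_id = "bread_leg", target_word = "brod",
               heard_word = "brod", target_side = "left"),
    make_trial("p1", "t04", pair_id = "bread_leg", target_word = "bein",
               heard_word = "bein", target_side = "right"))
  # t01: 60% target; t02: 70% target -> score 0.3
  lab1 <- function(t) if (t %% 1000 < 600) "target" else "distractor"
  lab2 <- function(t) if (t %% 1000 < 700) "target" else "distractor"
  gaze <- rbind(
    grid_gaze("p1", "t01", 5500, lab1, target_side = "left"),
    grid_gaze("p1", "t02", 5500, lab2, target_side = "right"),
    grid_gaze("p1", "t03", 5500, lab1, target_side = "left"),
    grid_gaze("p1", "t04", 5500, function(t) "invalid",
              target_side = "right"))
  lab <- label_gaze(gaze, trials)
  rep <- screen_participants(screen_trials(
    trials, lab, full_questionnaire("p1"),
    exclusion_config(min_valid_trials = 1)), lab)
  sc <- pair_difference_scores(lab, rep)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$pair_id, "apple_foot")
  # post window [2367, 5500]: window cuts the 600/1000 cycles; compute
  # the exact dwell arithmetic the same way by hand
  hand_p <- function(on_ms) {
    t <- seq(0, 5490, by = 10)
    w <- pmax(pmin(t + 10, 5500) - pmax(t, 2367), 0)
    tgt <- sum(w[t %% 1000 < on_ms])
    dis <- sum(w[t %% 1000 >= on_ms])
    tgt / (tgt + dis)
  }
  expect_equal(sc$score, hand_p(600) + hand_p(700) - 1, tolerance = 1e-9)
})

test_that("aggregation averages by subject and by item", {
  sc <- data.table::data.table(
    participant_id = rep(c("p1", "p2"), each = 4),
    condition = "frequency", trial_type = "matching",
    pair_id = rep(c("a", "b", "c", "d"), 2),
    score = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8))
  bysub <- aggregate_scores(sc, by = "subject")
  expect_equal(bysub[participant_id == "p1", mean_score], 0.25)
  expect_equal(bysub[participant_id == "p2", mean_score], 0.65)
  byitem <- aggregate_scores(sc, by = "item")
  expect_equal(nrow(byitem), 4)
  expect_equal(byitem[pair_id == "a", mean_score], 0.3)
  # single score per group passes through
  one <- aggregate_scores(sc[1], by = "subject")
  expect_equal(one$mean_score, 0.1)
  expect_equal(nrow(aggregate_scores(sc[0], by = "item")), 0)
})

test_that("baseline correction subtracts the pre-naming preference", {
  trials <- make_trial("p1", "t01")
  # pre-naming 50/50, post-naming all target: (1 - 0) - 0 = 1
  sched <- function(t) {
    if (t < 2000) (if (t %% 100 < 50) "target" else "distractor")
    else "target"
  }
  lab <- label_gaze(grid_gaze("p1", "t01", 5500, sched), trials)
  rep <- screen_participants(screen_trials(
    trials, lab, full_questionnaire("p1"),
    exclusion_config(min_valid_trials = 1)), lab)
  bc <- baseline_corrected_scores(lab, rep)
  expect_equal(bc$value, 1, tolerance = 1e-9)
  # identical pre and post distributions give 0
  flat <- function(t) if (t %% 100 < 50) "target" else "distractor"
  lab2 <- label_gaze(grid_gaze("p1", "t01", 5500, flat), trials)
  rep2 <- screen_participants(screen_trials(
    trials, lab2, full_questionnaire("p1"),
    exclusion_config(min_valid_trials = 1)), lab2)
  bc2 <- baseline_corrected_scores(lab2, rep2)
  # pre-naming window [0, 2000) holds whole 100 ms cycles, so its
  # preference is exactly 0; the post-naming window starts mid-cycle at
  # 2367 ms, so compute its clipped dwell arithmetic by hand
  t <- seq(0, 5490, by = 10)
  w <- pmax(pmin(t + 10, 5500) - pmax(t, 2367), 0)
  is_t <- t %% 100 < 50
  expected <- (sum(w[is_t]) - sum(w[!is_t])) / sum(w)
  expect_equal(bc2$value, expected, tolerance = 1e-9)
  expect_true(all(abs(bc2$value) <= 2))
})

test_that("arcsine-square-root transform hits its anchor points", {
  expect_equal(arcsinsqrt(0.5), pi / 4)
  expect_equal(arcsinsqrt(0), 0)
  expect_equal(arcsinsqrt(1), pi / 2)
  expect_error(arcsinsqrt(1.2), "0, 1")
  expect_true(is.na(arcsinsqrt(NA)))
})

test_that("binned proportions match hand-computed dwell ratios", {
  trials <- make_trial("p1", "t01")
  # target dwell 2650-2680 ms, distractor 2680-2700, within bin
  # [650, 700) after onset; all other time off-AOI
  sched <- function(t) {
    if (t >= 2000 && t < 2650) "target"      # keeps screening happy
    else if (t >= 2650 && t < 2680) "target"
    else if (t >= 2680 && t < 2700) "distractor"
    else if (t < 2000) "target"
    else "neither"
  }
  lab <- label_gaze(grid_gaze("p1", "t01", 5500, sched), trials)
  b <- binned_target_proportion(lab)
  row <- b[bin_start_ms == 650]
  expect_equal(row$t_target_ms, 30)
  expect_equal(row$t_distractor_ms, 20)
  expect_equal(row$prop, 0.6)
  # a bin with no AOI looking is missing, not zero
  expect_true(is.na(b[bin_start_ms == 1000, prop]))
  # grid is uniform at 50 ms from -2000
  expect_equal(sort(unique(diff(sort(unique(b$bin_start_ms))))), 50)
  expect_equal(min(b$bin_start_ms), -2000)
})

test_that("the log-offset transform stays positive on every score", {
  fx <- get_fixture()
  sc <- pair_difference_scores(fx$labeled, fx$report)
  expect_true(all(sc$score >= -1 & sc$score <= 1))
  expect_true(all(sc$score + 2 >= 1))
  expect_equal(log(-1 + 2), 0)   # a score of -1 maps to log(1) = 0
})

test_that("null cohorts give by-subject means near zero", {
  coh <- simulate_cohort(cohort_config(n_infants = 16, seed = 501,
                                       effect_spec = zero_effect_spec()))
  lab <- label_gaze(coh$gaze, coh$trials)
  rep <- screen_participants(screen_trials(coh$trials, lab,
                                           coh$questionnaires), lab)
  sc <- pair_difference_scores(lab, rep)
  agg <- aggregate_scores(sc, by = "subject", groups = "trial_type")
  se <- sd(agg$mean_score) / sqrt(nrow(agg))
  expect_lt(abs(mean(agg$mean_score)), 3.5 * se + 0.01)
})
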