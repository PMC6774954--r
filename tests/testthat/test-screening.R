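# label schedules for hand-built trials ------------------------------------
# 0.4 s of post-naming AOI looking (rest off-AOI), healthy pre-naming look
short_post <- function(t) {
  if (t < 1000) "target"
  else if (t >= 2400 & t < 2800) "target"
  else "neither"
}
# generous looking throughout
good_look <- function(t) if (t < 3000) "target" else "distractor"
# no pre-naming AOI looking at all
no_pre <- function(t) if (t < 2000) "neither" else "target"

make_cohort_4trials <- function() {
  # one infant, the four apple_foot trials (2 matching + 2 related)
  trials <- rbind(
    make_trial("p1", "t01", trial_type = "matching", target_word = "eple",
               heard_word = "eple", target_side = "left"),
    make_trial("p1", "t02", trial_type = "matching", target_word = "fot",
               heard_word = "fot", target_side = "left"),
    make_trial("p1", "t03", trial_type = "related", target_word = "eple",
               heard_word = "kopp", target_side = "right"),
    make_trial("p1", "t04", trial_type = "related", target_word = "fot",
               heard_word = "bukse", target_side = "right"))
  gaze <- rbind(
    grid_gaze("p1", "t01", 5500, good_look, target_side = "left"),
    grid_gaze("p1", "t02", 5500, good_look, target_side = "left"),
    grid_gaze("p1", "t03", 5500, good_look, target_side = "right"),
    grid_gaze("p1", "t04", 5500, good_look, target_side = "right"))
  list(trials = trials, gaze = gaze)
}

test_that("a trial with under 0.5 s of post-naming AOI looking is dropped", {
  trials <- rbind(make_trial("p1", "t01"),
                  make_trial("p1", "t02", trial_id = "t02"))
  gaze <- rbind(grid_gaze("p1", "t01", 5500, short_post),
                grid_gaze("p1", "t02", 5500, good_look))
  lab <- label_gaze(gaze, trials)
  rep <- screen_trials(trials, lab, full_questionnaire("p1"))
  expect_false(rep$trials[trial_id == "t01", included])
  expect_equal(rep$trials[trial_id == "t01", reason], "short_post_look")
  expect_true(rep$trials[trial_id == "t02", included])
  # exactly at the threshold passes (>= 0.5 s)
  at_thresh <- function(t) if (t >= 2400 & t < 2900) "target" else "neither"
  g3 <- grid_gaze("p1", "t03", 5500, function(t)
    if (t < 1000) "target" else at_thresh(t))
  t3 <- make_trial("p1", "t03")
  rep3 <- screen_trials(t3, label_gaze(g3, t3), full_questionnaire("p1"))
  expect_true(rep3$trials$included[1])
})

test_that("a missing pre-naming look excludes the trial", {
  trials <- make_trial("p1", "t01")
  lab <- label_gaze(grid_gaze("p1", "t01", 5500, no_pre), trials)
  rep <- screen_trials(trials, lab, full_questionnaire("p1"))
  expect_equal(rep$trials$reason[1], "no_prenaming_look")
})

test_that("experimenter flags take precedence over gaze rules", {
  trials <- make_trial("p1", "t01", experimenter_flag = TRUE)
  lab <- label_gaze(grid_gaze("p1", "t01", 5500, short_post), trials)
  rep <- screen_trials(trials, lab, full_questionnaire("p1"))
  expect_equal(rep$trials$reason[1], "experimenter_flag")
})

test_that("a never-used matching word removes the whole picture-pair", {
  cohort <- make_cohort_4trials()
  q <- full_questionnaire("p1")
  q[word == "eple", familiarity := 0]
  lab <- label_gaze(cohort$gaze, cohort$trials)
  rep <- screen_trials(cohort$trials, lab, q)
  expect_true(all(!rep$trials$included))
  expect_true(all(rep$trials$reason == "unfamiliar_matching_word"))
})

test_that("a never-used related word removes only the related trials", {
  cohort <- make_cohort_4trials()
  q <- full_questionnaire("p1")
  q[word == "bukse", familiarity := 0]
  lab <- label_gaze(cohort$gaze, cohort$trials)
  rep <- screen_trials(cohort$trials, lab, q)
  expect_true(all(rep$trials[trial_type == "matching", included]))
  expect_true(all(!rep$trials[trial_type == "related", included]))
  expect_true(all(rep$trials[trial_type == "related", reason] ==
                    "unfamiliar_related_word"))
})

test_that("a word absent from the questionnaires is an error", {
  cohort <- make_cohort_4trials()
  q <- full_questionnaire("p1")[word != "kopp"]
  lab <- label_gaze(cohort$gaze, cohort$trials)
  expect_error(screen_trials(cohort$trials, lab, q), "kopp")
})

test_that("participants need six surviving trials to stay in", {
  fx <- get_fixture()
  rep <- fx$report
  pp <- rep$participants
  valid_counts <- rep$trials[trial_type != "control",
                             sum(included), by = participant_id]
  expect_equal(pp[order(participant_id), retained],
               valid_counts[order(participant_id), V1 >= 6])
  # forcing an absurd threshold excludes everyone
  strict <- exclusion_config(min_valid_trials = 33)
  pp2 <- screen_participants(screen_trials(
    fx$cohort$trials, fx$labeled, fx$cohort$questionnaires, strict),
    fx$labeled, strict)$participants
  expect_true(all(!pp2$retained))
})

test_that("screening is idempotent and participant-separable", {
  fx <- get_fixture()
  rep1 <- fx$report
  # re-screen only the surviving trials: nothing new gets excluded
  keep <- retained_trials(rep1)
  ids <- keep[, .(participant_id, trial_id)]
  gaze2 <- fx$cohort$gaze[ids, on = c("participant_id", "trial_id")]
  lab2 <- label_gaze(gaze2, keep)
  rep2 <- screen_trials(keep, lab2, fx$cohort$questionnaires,
                        rep1$config)
  expect_true(all(rep2$trials$included))
  # dropping one infant leaves the others' statuses untouched
  drop <- fx$cohort$trials$participant_id[1]
  tr3 <- fx$cohort$trials[participant_id != drop]
  g3 <- fx$cohort$gaze[participant_id != drop]
  rep3 <- screen_trials(tr3, label_gaze(g3, tr3),
                        fx$cohort$questionnaires)
  merged <- merge(rep1$trials[participant_id != drop,
                              .(participant_id, trial_id, included)],
                  rep3$trials[, .(participant_id, trial_id, included)],
                  by = c("participant_id", "trial_id"))
  expect_true(all(merged$included.x == merged$included.y))
})

test_that("reason counts reconcile with totals", {
  fx <- get_fixture()
  st <- fx$report$trials[trial_type != "control"]
  expect_equal(sum(fx$report$reason_counts$N), sum(!st$included))
  expect_true(all(!is.na(st[included == FALSE, reason])))
})

test_that("control summaries reproduce the engagement arithmetic", {
  # 1.36 s of target fixation in a 5.5 s trial is 25% at whole-percent
  # rounding
  fix_on <- function(t) if (t < 1360) "target" else "neither"
  trials <- make_trial("p1", "t01", condition = "control",
                       trial_type = "control", pair_id = "control_tree",
                       target_word = "tre", heard_word = "tre")
  lab <- label_gaze(grid_gaze("p1", "t01", 5500, fix_on), trials)
  cq <- control_quality(lab)
  expect_equal(cq$mean_fixation_s, 1.36, tolerance = 0.01)
  expect_equal(round(100 * cq$mean_prop_of_trial), 25)
  # saturated looking gives proportion 1
  lab2 <- label_gaze(grid_gaze("p1", "t01", 5500,
                               function(t) "target"), trials)
  cq2 <- control_quality(lab2)
  expect_equal(cq2$by_infant$mean_post_target_prop, 1)
  expect_error(control_quality(label_gaze(
    grid_gaze("p1", "t01", 5500, good_look), make_trial("p1", "t01"))),
    "control")
})

test_that("synthetic control trials hit the configured engagement level", {
  fx <- get_fixture()
  cq <- control_quality(fx$labeled)
  # generator default emulates ~1.4 s of target fixation (~25% of trial)
  expect_gt(cq$mean_fixation_s, 0.8)
  expect_lt(cq$mean_fixation_s, 2.0)
  expect_gt(mean(cq$by_infant$mean_post_target_prop), 0.75)
})
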