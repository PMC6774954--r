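suppressMessages(library(data.table))

# one shared 4-infant cohort, built once per test run
.fixture_env <- new.env()
get_fixture <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- fixture_cohort(seed = 101L)
    lab <- label_gaze(.fixture_env$cohort$gaze, .fixture_env$cohort$trials)
    rep <- screen_trials(.fixture_env$cohort$trials, lab,
                         .fixture_env$cohort$questionnaires)
    .fixture_env$labeled <- lab
    .fixture_env$report <- screen_participants(rep, lab)
  }
  .fixture_env
}

# gaze on a fixed 10 ms grid whose AOI label is a function of time;
# labels: "target", "distractor", "neither", "invalid"
grid_gaze <- function(participant_id, trial_id, end_ms, label_fn,
                      step = 10, target_side = "left",
                      layout = aoi_layout()) {
  t <- seq(0, end_ms - step, by = step)
  lab <- vapply(t, label_fn, character(1))
  tgt <- if (target_side == "left") layout$left_center_px else
    layout$right_center_px
  dis <- if (target_side == "left") layout$right_center_px else
    layout$left_center_px
  x <- ifelse(lab == "target", tgt[1],
              ifelse(lab == "distractor", dis[1],
                     layout$screen_px[1] / 2))
  y <- rep(layout$screen_px[2] / 2, length(t))
  y[lab %in% c("target", "distractor")] <- tgt[2]
  valid <- lab != "invalid"
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  data.table(participant_id = participant_id, trial_id = trial_id,
             t_ms = t, x_px = x, y_px = y, valid = valid)
}

# minimal single-trial metadata row
make_trial <- function(participant_id, trial_id, condition = "context",
                       trial_type = "matching", pair_id = "apple_foot",
                       target_word = "eple", heard_word = "eple",
                       target_side = "left", word_onset_ms = 2000,
                       end_ms = 5500, experimenter_flag = FALSE) {
  data.table(participant_id = participant_id, trial_id = trial_id,
             condition = condition, trial_type = trial_type,
             pair_id = pair_id, target_word = target_word,
             heard_word = heard_word, target_side = target_side,
             word_onset_ms = word_onset_ms, end_ms = end_ms,
             experimenter_flag = experimenter_flag)
}

# questionnaires marking every stimulus word as familiar
full_questionnaire <- function(participant_ids, age_days = 220,
                               familiarity = 5, cdi = FALSE) {
  stim <- read_stimulus_table()
  rbindlist(lapply(seq_along(participant_ids), function(i)
    data.table(participant_id = participant_ids[i],
               age_days = rep_len(age_days, length(participant_ids))[i],
               list_id = 1L, word = stim$word, familiarity = familiarity,
               cdi_understands = cdi)))
}
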