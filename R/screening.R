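#' Exclusion-screening configuration
#'
#' Trial- and participant-level exclusion rules for IPL experiments:
#' trials flagged by the experimenter, trials without any pre-naming
#' on-AOI looking, trials with less than `min_post_look_s` seconds of
#' summed looking at either image post-naming, and familiarity rules
#' (a heard word the parent reports as never used invalidates trials; a
#' never-used *matching* word removes the whole picture-pair, matching
#' and related, whereas a never-used *related* word removes only the
#' pair's related trials). Participants must contribute at least
#' `min_valid_trials` surviving experimental trials. The count threshold
#' (6 of 32) is authoritative; as a percentage it is 18.75%, commonly
#' rounded to 20%.
#'
#' @param min_post_look_s minimum summed target+distractor looking in
#'   the post-naming window, seconds.
#' @param require_pre_look require at least some valid on-AOI looking in
#'   the pre-naming window (`prenaming_rule = "aoi"`), or any valid
#'   sample at all (`"any_valid"`).
#' @param prenaming_rule see above.
#' @param min_valid_trials participant retention threshold (count).
#' @param familiarity_floor ratings strictly above this count as "used";
#'   0 means only "never used" excludes.
#' @param honor_experimenter_flags drop flagged trials first.
#' @param control_min_fix_s control-trial engagement check: minimum mean
#'   target fixation (s) on control trials for a participant to pass;
#'   0 disables the check.
#' @return an object of class `exclusion_config`.
#' @export
exclusion_config <- function(min_post_look_s = 0.5,
                             require_pre_look = TRUE,
                             prenaming_rule = c("aoi", "any_valid"),
                             min_valid_trials = 6L,
                             familiarity_floor = 0,
                             honor_experimenter_flags = TRUE,
                             control_min_fix_s = 0) {
  prenaming_rule <- match.arg(prenaming_rule)
  stopifnot(min_post_look_s > 0, min_valid_trials >= 1,
            familiarity_floor >= 0, control_min_fix_s >= 0)
  structure(list(min_post_look_s = min_post_look_s,
                 require_pre_look = require_pre_look,
                 prenaming_rule = prenaming_rule,
                 min_valid_trials = as.integer(min_valid_trials),
                 familiarity_floor = familiarity_floor,
                 honor_experimenter_flags = honor_experimenter_flags,
                 control_min_fix_s = control_min_fix_s),
            class = "exclusion_config")
}

#' Trial-level exclusion screening
#'
#' Applies the trial exclusion rules in order (experimenter flag, no
#' pre-naming look, short post-naming look, unfamiliar heard word); each
#' excluded trial carries exactly one primary reason, the first rule it
#' failed. Control trials are passed through unscreened (`reason`
#' `"control"`); the control engagement check is participant-level, see
#' [screen_participants()].
#'
#' @param trials trial sheet.
#' @param gaze_labeled labelled gaze ([label_gaze()]).
#' @param questionnaires questionnaire table; must rate every heard word.
#' @param config an [exclusion_config()].
#' @return an object of class `screening_report`: `$trials` has one row
#'   per trial with `included` and `reason`; `$reason_counts` tabulates
#'   exclusions.
#' @export
screen_trials <- function(trials, gaze_labeled, questionnaires,
                          config = exclusion_config()) {
  tr <- as.data.table(trials)
  q <- as.data.table(questionnaires)
  unknown <- setdiff(unique(tr[trial_type != "control", heard_word]),
                     unique(q$word))
  if (length(unknown))
    stop("heard word(s) missing from questionnaires: ",
         paste(unknown, collapse = ", "))

  looks <- prepost_looking(gaze_labeled)
  pre <- looks$pre
  post <- looks$post
  key <- c("participant_id", "trial_id")
  st <- merge(tr,
              pre[, .(participant_id, trial_id,
                      pre_aoi_ms = t_target_ms + t_distractor_ms,
                      pre_any_ms = t_target_ms + t_distractor_ms +
                        t_neither_ms)],
              by = key, all.x = TRUE)
  st <- merge(st,
              post[, .(participant_id, trial_id,
                       post_aoi_ms = t_target_ms + t_distractor_ms)],
              by = key, all.x = TRUE)
  for (cc in c("pre_aoi_ms", "pre_any_ms", "post_aoi_ms"))
    set(st, which(is.na(st[[cc]])), cc, 0)

  # familiarity of the heard word, and the pair-level matching-word rule
  fam <- q[, .(participant_id, word, familiarity)]
  st <- merge(st, fam, by.x = c("participant_id", "heard_word"),
              by.y = c("participant_id", "word"), all.x = TRUE)
  # a never-used matching (referent) word poisons its whole pair;
  # a never-used related word poisons only the pair's related trials
  bad_pair <- st[trial_type == "matching" &
                   familiarity <= config$familiarity_floor,
                 unique(.SD), .SDcols = c("participant_id", "pair_id")]
  bad_pair[, pair_poisoned := TRUE]
  st <- merge(st, bad_pair, by = c("participant_id", "pair_id"),
              all.x = TRUE)
  st[is.na(pair_poisoned), pair_poisoned := FALSE]
  bad_rel <- st[trial_type == "related" &
                  familiarity <= config$familiarity_floor,
                unique(.SD), .SDcols = c("participant_id", "pair_id")]
  bad_rel[, related_poisoned := TRUE]
  st <- merge(st, bad_rel, by = c("participant_id", "pair_id"),
              all.x = TRUE)
  st[is.na(related_poisoned), related_poisoned := FALSE]

  pre_ok <- if (!config$require_pre_look) TRUE
            else if (config$prenaming_rule == "aoi") st$pre_aoi_ms > 0
            else st$pre_any_ms > 0
  st[, reason := NA_character_]
  st[trial_type == "control", reason := "control"]
  exp_row <- st$trial_type != "control"
  prio <- function(cond, code) {
    st[exp_row & is.na(reason) & cond, reason := code]
  }
  prio(config$honor_experimenter_flags & st$experimenter_flag,
       "experimenter_flag")
  prio(!pre_ok, "no_prenaming_look")
  prio(st$post_aoi_ms < config$min_post_look_s * 1000, "short_post_look")
  prio(st$pair_poisoned, "unfamiliar_matching_word")
  prio(st$trial_type == "related" & st$related_poisoned,
       "unfamiliar_related_word")
  st[, included := is.na(reason) | reason == "control"]

  out <- st[, .(participant_id, trial_id, condition, trial_type, pair_id,
                target_word, heard_word, target_side, word_onset_ms, end_ms,
                experimenter_flag, pre_aoi_ms, post_aoi_ms, included,
                reason)]
  setkeyv(out, key)
  counts <- out[trial_type != "control" & !included, .N, by = reason]
  structure(list(trials = out, reason_counts = counts, config = config,
                 pre_looking = pre, post_looking = post),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  n_exp <- nrow(x$trials[trial_type != "control"])
  n_in <- nrow(x$trials[trial_type != "control" & included == TRUE])
  cat("Screening report:", n_in, "of", n_exp, "experimental trials retained\n")
  if (nrow(x$reason_counts)) {
    cat("Exclusions by primary reason:\n")
    print(x$reason_counts)
  }
  if (!is.null(x$participants)) {
    cat("Participants retained:", sum(x$participants$retained), "of",
        nrow(x$participants), "\n")
  }
  invisible(x)
}

#' Participant-level screening
#'
#' An infant is retained iff at least `min_valid_trials` experimental
#' trials survived trial screening and (when `control_min_fix_s > 0`)
#' the control engagement check passes.
#'
#' @param report a [screen_trials()] report.
#' @param gaze_labeled labelled gaze (needed only when the control check
#'   is enabled).
#' @param config an [exclusion_config()].
#' @return the report with a `$participants` table added and excluded
#'   infants' trials marked `included = FALSE`, reason
#'   `"participant_excluded"` kept separately in `$participants`.
#' @export
screen_participants <- function(report, gaze_labeled = NULL,
                                config = report$config) {
  stopifnot(inherits(report, "screening_report"))
  st <- report$trials
  pp <- st[trial_type != "control",
           .(n_valid = sum(included)), by = participant_id]
  pp[, retained := n_valid >= config$min_valid_trials]
  pp[, reason := ifelse(retained, NA_character_, "too_few_valid_trials")]
  if (config$control_min_fix_s > 0) {
    if (is.null(gaze_labeled))
      stop("control check enabled but no gaze supplied")
    cq <- control_quality(gaze_labeled, null = 0)
    pp <- merge(pp, cq$by_infant[, .(participant_id, mean_fixation_s)],
                by = "participant_id", all.x = TRUE)
    fail <- !is.na(pp$mean_fixation_s) &
      pp$mean_fixation_s < config$control_min_fix_s
    pp[fail & retained, reason := "failed_control_check"]
    pp[fail, retained := FALSE]
    pp[, mean_fixation_s := NULL]
  }
  report$participants <- pp[]
  report
}

#' Retained analysis trials
#'
#' Convenience accessor: experimental trials surviving both trial- and
#' participant-level screening.
#'
#' @param report a screened [screening_report] (after
#'   [screen_participants()]).
#' @return a `data.table` of retained trials.
#' @export
retained_trials <- function(report) {
  stopifnot(inherits(report, "screening_report"))
  st <- report$trials[trial_type != "control" & included == TRUE]
  if (!is.null(report$participants))
    st <- st[participant_id %in%
               report$participants[retained == TRUE, participant_id]]
  st[]
}

#' Control-trial quality check
#'
#' Summarizes looking on single-object control trials: the mean target
#' fixation time (s) over the whole trial, the mean fixation expressed
#' as a proportion of trial duration, and each infant's mean post-naming
#' target looking proportion, tested against a configurable null with a
#' one-sample Wilcoxon signed-rank test. (The null defaults to 0 — a
#' pure engagement check; note that testing a proportion against 0 is
#' close to trivially significant whenever infants look at all, so a
#' chance null of 0.5 may be preferred.)
#'
#' @param gaze_labeled labelled gaze containing control trials.
#' @param null null value for the engagement test.
#' @param alternative test direction.
#' @return list: `mean_fixation_s`, `mean_prop_of_trial`, `by_infant`
#'   table, and `test` (an `ipl_stat`).
#' @export
control_quality <- function(gaze_labeled, null = 0,
                            alternative = "greater") {
  g <- as.data.table(gaze_labeled)[trial_type == "control"]
  if (!nrow(g)) stop("no control trials in gaze table")
  full <- g[, {
    w <- c(0, end_ms[1])
    as.list(looking_times(t_ms, aoi, valid, w))
  }, by = .(participant_id, trial_id, end_ms)]
  post <- g[, {
    w <- analysis_windows(word_onset_ms[1], end_ms[1])$postnaming
    as.list(looking_times(t_ms, aoi, valid, w))
  }, by = .(participant_id, trial_id)]
  post[, p_target := ifelse(t_target_ms + t_distractor_ms > 0,
                            t_target_ms / (t_target_ms + t_distractor_ms),
                            NA_real_)]
  by_infant <- merge(
    full[, .(mean_fixation_s = mean(t_target_ms) / 1000,
             mean_prop_of_trial = mean(t_target_ms / end_ms)),
         by = participant_id],
    post[, .(mean_post_target_prop = mean(p_target, na.rm = TRUE)),
         by = participant_id],
    by = "participant_id")
  props <- by_infant$mean_post_target_prop
  test <- if (any(is.finite(props)))
    wilcoxon_one_sample(props[is.finite(props)], mu0 = null,
                        alternative = alternative) else NULL
  list(mean_fixation_s = mean(by_infant$mean_fixation_s),
       mean_prop_of_trial = mean(by_infant$mean_prop_of_trial),
       by_infant = by_infant, test = test)
}
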