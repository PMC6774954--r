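#' Pair difference score from raw looking times
#'
#' For a picture-pair (A, B) seen once with A named and once with B
#' named, the difference in looking proportion is
#' `P_A(A target) - P_A(A distractor)` where `P_A` is the proportion of
#' AOI looking spent on object A, `target/(target + distractor)`.
#' Because `P_A(A distractor) = 1 - P_B(B target)`, the score equals
#' `P1 + P2 - 1` with `P1`, `P2` the target proportions of the two
#' trials — symmetric in the pair, bounded in `[-1, 1]`, chance 0.
#'
#' @param t1_target,t1_distractor post-naming looking (ms) in the trial
#'   where A was named.
#' @param t2_target,t2_distractor same for the trial where B was named.
#' @return the score, or NA if either trial has zero AOI looking.
#' @examples
#' # A named: 1.2 s on A, 0.8 s on B; B named: 2.1 s on B, 0.9 s on A
#' pair_score_from_times(1200, 800, 2100, 900)  # 0.6 - 0.3 = 0.3
#' @export
pair_score_from_times <- function(t1_target, t1_distractor,
                                  t2_target, t2_distractor) {
  a1 <- t1_target + t1_distractor
  a2 <- t2_target + t2_distractor
  ifelse(a1 > 0 & a2 > 0,
         t1_target / a1 + t2_target / a2 - 1, NA_real_)
}

#' Per-pair difference-in-looking-proportion scores
#'
#' Computes one score per (participant, pair, trial type) from screened
#' trials' post-naming looking. A pair contributes only when both of its
#' trials (one per named word) survive screening; if a word was
#' presented more than once, its presentations are pooled at the
#' looking-time level before the proportion is taken.
#'
#' @param gaze_labeled labelled gaze ([label_gaze()]).
#' @param report a screened [screen_trials()] report (participant
#'   screening applied if available).
#' @return a `data.table` of scores: `participant_id`, `pair_id`,
#'   `condition`, `trial_type`, `score`.
#' @export
pair_difference_scores <- function(gaze_labeled, report) {
  keep <- retained_trials(report)
  post <- if (!is.null(report$post_looking)) report$post_looking
          else window_looking(gaze_labeled, "postnaming")
  post <- merge(keep[, .(participant_id, trial_id, target_word)],
                post, by = c("participant_id", "trial_id"))
  # pool presentations of the same named word, then one proportion per word
  per_word <- post[, .(t_target_ms = sum(t_target_ms),
                       t_distractor_ms = sum(t_distractor_ms)),
                   by = .(participant_id, condition, trial_type, pair_id,
                          target_word)]
  per_word[, p_target := ifelse(t_target_ms + t_distractor_ms > 0,
                                t_target_ms /
                                  (t_target_ms + t_distractor_ms),
                                NA_real_)]
  scores <- per_word[, .(n_words = .N,
                         score = sum(p_target) - 1),
                     by = .(participant_id, condition, trial_type, pair_id)]
  scores <- scores[n_words == 2L & !is.na(score)]
  scores[, n_words := NULL]
  scores[]
}

#' Average scores by subject or by item
#'
#' By-subject analysis averages each participant's pair scores over item
#' pairs (within the given grouping); by-item analysis averages each
#' pair's scores over participants.
#'
#' @param scores output of [pair_difference_scores()].
#' @param by `"subject"` or `"item"`.
#' @param groups extra grouping columns (default condition and trial
#'   type; drop `"condition"` to pool both conditions).
#' @return a `data.table` with `mean_score` and the group size `n`.
#' @export
aggregate_scores <- function(scores, by = c("subject", "item"),
                             groups = c("condition", "trial_type")) {
  by <- match.arg(by)
  s <- as.data.table(scores)
  if (!nrow(s)) return(s)
  unit <- if (by == "subject") "participant_id" else "pair_id"
  s[, .(mean_score = mean(score), n = .N), by = c(unit, groups)]
}

#' Baseline-corrected looking scores
#'
#' Per trial, the post-naming minus pre-naming difference between the
#' target-looking and distractor-looking proportions:
#' `(P_t - P_d)_post - (P_t - P_d)_pre`, bounded in `[-2, 2]`. Missing
#' when either window has no AOI looking.
#'
#' @inheritParams pair_difference_scores
#' @return a `data.table` with one `value` per retained trial.
#' @export
baseline_corrected_scores <- function(gaze_labeled, report) {
  keep <- retained_trials(report)
  pre <- if (!is.null(report$pre_looking)) copy(report$pre_looking)
         else window_looking(gaze_labeled, "prenaming")
  post <- if (!is.null(report$post_looking)) copy(report$post_looking)
          else window_looking(gaze_labeled, "postnaming")
  pd <- function(tt, td) ifelse(tt + td > 0, (tt - td) / (tt + td),
                                NA_real_)
  pre[, pre := pd(t_target_ms, t_distractor_ms)]
  post[, post := pd(t_target_ms, t_distractor_ms)]
  out <- merge(keep[, .(participant_id, trial_id, target_word, heard_word)],
               pre[, .(participant_id, trial_id, condition, trial_type,
                       pair_id, pre)],
               by = c("participant_id", "trial_id"))
  out <- merge(out, post[, .(participant_id, trial_id, post)],
               by = c("participant_id", "trial_id"))
  out[, value := post - pre]
  out[!is.na(value)][]
}

#' Arcsine-square-root transform
#'
#' Variance-stabilizing transform for proportions, `asin(sqrt(p))`:
#' 0 maps to 0, 0.5 to pi/4, 1 to pi/2.
#'
#' @param p proportions in `[0, 1]` (NA passes through).
#' @return transformed values.
#' @export
arcsinsqrt <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' Binned target-looking time course
#'
#' Tiles each trial's cluster-analysis window (2000 ms before word onset
#' to trial end) into `bin_ms` bins on a grid aligned to word onset and
#' computes the duration-weighted target looking proportion
#' `target/(target + distractor)` per bin. Bins with no AOI looking are
#' missing (NA), not zero — zero would read as distractor looking.
#'
#' @param gaze_labeled labelled gaze.
#' @param report optional screening report; when given only retained
#'   trials contribute.
#' @param bin_ms bin width, ms.
#' @return trial-level series: one row per (trial, bin), with
#'   `bin_start_ms` relative to word onset and `prop` in `[0, 1]` or NA.
#' @export
binned_target_proportion <- function(gaze_labeled, report = NULL,
                                     bin_ms = 50, cluster_pre_ms = 2000) {
  g <- as.data.table(gaze_labeled)
  if (!is.null(report)) {
    keep <- retained_trials(report)[, .(participant_id, trial_id)]
    g <- g[keep, on = c("participant_id", "trial_id")]
  } else {
    g <- copy(g[trial_type != "control"])
  }
  setkeyv(g, c("participant_id", "trial_id", "t_ms"))
  add_dwell(g)
  g[, gid := rleid(participant_id, trial_id)]
  trials <- unique(g[, .(gid, participant_id, trial_id, condition,
                         trial_type, pair_id, word_onset_ms, end_ms)])
  # bin grid anchored at word onset - cluster_pre_ms so bins align on a
  # common onset-relative grid across trials
  anchor <- g$word_onset_ms - cluster_pre_ms
  a <- pmax(g$t_ms, pmax(anchor, 0))
  b <- pmin(g$t_ms + g$dt_ms, g$end_ms)
  keep_row <- g$valid & g$aoi %in% c("target", "distractor") & b > a
  segs <- split_at_bins_grouped(a[keep_row], b[keep_row],
                                g$aoi[keep_row] == "target",
                                anchor[keep_row], g$gid[keep_row], bin_ms)
  sums <- segs[, .(w = sum(w)), by = .(gid, bin, is_target)]
  n_bins <- pmax(1L, as.integer(ceiling(
    (trials$end_ms - (trials$word_onset_ms - cluster_pre_ms)) / bin_ms)))
  out <- trials[rep(seq_len(.N), n_bins)]
  out[, bin := sequence(n_bins)]
  out[, bin_start_ms := (bin - 1) * bin_ms - cluster_pre_ms]
  out[, c("t_target_ms", "t_distractor_ms") := 0]
  out[sums[is_target == TRUE], on = c("gid", "bin"), t_target_ms := i.w]
  out[sums[is_target == FALSE], on = c("gid", "bin"),
      t_distractor_ms := i.w]
  out[, gid := NULL]
  out[, prop := ifelse(t_target_ms + t_distractor_ms > 0,
                       t_target_ms / (t_target_ms + t_distractor_ms),
                       NA_real_)]
  out[]
}

#' Participant-average binned series
#'
#' Averages trial-level binned proportions within participant, condition
#' and trial type; missing bins propagate (a participant-bin with no
#' contributing trial stays NA).
#'
#' @param binned output of [binned_target_proportion()].
#' @param groups grouping columns besides participant and bin.
#' @return a `data.table` with one `prop` per participant x group x bin.
#' @export
participant_series <- function(binned,
                               groups = c("condition", "trial_type")) {
  b <- as.data.table(binned)
  b[, .(prop = if (all(is.na(prop))) NA_real_ else
    mean(prop, na.rm = TRUE), n_trials = sum(!is.na(prop))),
    by = c("participant_id", groups, "bin_start_ms")]
}
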