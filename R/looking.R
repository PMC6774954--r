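#' Label a gaze table by area of interest
#'
#' Joins gaze samples to their trial's metadata and resolves each sample to
#' `"target"`, `"distractor"` or `"neither"` given the trial's target side.
#' Invalid samples keep `valid = FALSE` and contribute no looking time
#' downstream.
#'
#' @param gaze gaze samples ([read_gaze_table()] schema).
#' @param trials trial sheet ([read_trial_sheet()] schema).
#' @param layout an [aoi_layout()].
#' @return the gaze table with trial metadata and an `aoi` column.
#' @export
label_gaze <- function(gaze, trials, layout = aoi_layout()) {
  g <- as.data.table(gaze)
  tr <- as.data.table(trials)[, .(participant_id, trial_id, condition,
                                  trial_type, pair_id, target_side,
                                  word_onset_ms, end_ms)]
  out <- tr[g, on = c("participant_id", "trial_id")]
  if (anyNA(out$target_side))
    stop("gaze samples reference trials absent from the trial sheet")
  out[, aoi := assign_aoi(x_px, y_px, target_side, layout, valid = valid)]
  setkeyv(out, c("participant_id", "trial_id", "t_ms"))
  out[]
}

# per-sample dwell: each sample carries the interval to the next sample;
# the last sample of a trial carries the trial's median inter-sample step.
sample_dwell <- function(t_ms) {
  n <- length(t_ms)
  if (n == 0L) return(numeric())
  if (n == 1L) return(0)
  d <- diff(t_ms)
  c(d, median(d))
}

# vectorized dwell over a keyed (participant, trial, t) gaze table
add_dwell <- function(g) {
  g[, dt_ms := shift(t_ms, type = "lead") - t_ms,
    by = .(participant_id, trial_id)]
  med <- g[!is.na(dt_ms), .(med_dt = median(dt_ms)),
           by = .(participant_id, trial_id)]
  g[med, on = c("participant_id", "trial_id"),
    dt_ms := fifelse(is.na(dt_ms), i.med_dt, dt_ms)]
  g[is.na(dt_ms), dt_ms := 0]
  g
}

#' Time-weighted looking durations in a window
#'
#' Sums looking time per AOI label over one trial's gaze slice, clipped to
#' a window. Each sample contributes its inter-sample interval (the last
#' sample the trial's median interval), so the result is invariant to the
#' sampling rate in the dense limit. Invalid samples contribute nothing.
#'
#' @param t_ms sample times, ms from trial start (sorted).
#' @param aoi labels from [assign_aoi()].
#' @param valid logical validity per sample.
#' @param window numeric(2), `c(start, end)` in ms.
#' @return named numeric: `t_target_ms`, `t_distractor_ms`, `t_neither_ms`.
#' @export
looking_times <- function(t_ms, aoi, valid = TRUE, window) {
  stopifnot(length(window) == 2L, window[2] >= window[1])
  valid <- rep_len(valid, length(t_ms))
  dt <- sample_dwell(t_ms)
  a <- pmax(t_ms, window[1])
  b <- pmin(t_ms + dt, window[2])
  w <- pmax(b - a, 0) * valid
  c(t_target_ms = sum(w[aoi == "target"]),
    t_distractor_ms = sum(w[aoi == "distractor"]),
    t_neither_ms = sum(w[aoi == "neither"]))
}

# resolve per-trial window bounds for a named window
window_bounds <- function(g, which, windows_args) {
  uw <- unique(g[, .(word_onset_ms, end_ms)])
  bounds <- t(mapply(function(on, en) {
    do.call(analysis_windows,
            c(list(word_onset_ms = on, end_ms = en), windows_args)
    )[[if (which == "cluster") "cluster" else which]]
  }, uw$word_onset_ms, uw$end_ms))
  uw[, c("win_lo", "win_hi") := .(bounds[, 1], bounds[, 2])]
  uw
}

#' Per-trial looking durations for a named analysis window
#'
#' Applies the [looking_times()] accounting to every trial of a labelled
#' gaze table at once, with each trial's window resolved from its own
#' word onset and end time.
#'
#' @param gaze_labeled output of [label_gaze()].
#' @param which one of `"prenaming"`, `"postnaming"`, `"cluster"`.
#' @param windows_args extra arguments passed to [analysis_windows()];
#'   onset/end come from each trial.
#' @return a `data.table`, one row per trial, with the three durations.
#' @export
window_looking <- function(gaze_labeled, which = "postnaming",
                           windows_args = list()) {
  stopifnot(which %in% c("prenaming", "postnaming", "cluster"))
  g <- copy(as.data.table(gaze_labeled))
  setkeyv(g, c("participant_id", "trial_id", "t_ms"))
  add_dwell(g)
  uw <- window_bounds(g, which, windows_args)
  g[uw, on = c("word_onset_ms", "end_ms"),
    c("win_lo", "win_hi") := .(i.win_lo, i.win_hi)]
  a <- pmax(g$t_ms, g$win_lo)
  b <- pmin(g$t_ms + g$dt_ms, g$win_hi)
  w <- pmax(b - a, 0) * g$valid
  g[, c("wt", "wd", "wn") := .(w * (aoi == "target"),
                               w * (aoi == "distractor"),
                               w * (aoi == "neither"))]
  g[, .(t_target_ms = sum(wt), t_distractor_ms = sum(wd),
        t_neither_ms = sum(wn)),
    by = .(participant_id, trial_id, condition, trial_type, pair_id)]
}

# pre- and post-naming durations in one pass over the gaze table
# (the dwell computation is shared)
prepost_looking <- function(gaze_labeled, windows_args = list()) {
  g <- copy(as.data.table(gaze_labeled))
  setkeyv(g, c("participant_id", "trial_id", "t_ms"))
  add_dwell(g)
  one <- function(which) {
    uw <- window_bounds(g, which, windows_args)
    g[uw, on = c("word_onset_ms", "end_ms"),
      c("win_lo", "win_hi") := .(i.win_lo, i.win_hi)]
    a <- pmax(g$t_ms, g$win_lo)
    b <- pmin(g$t_ms + g$dt_ms, g$win_hi)
    w <- pmax(b - a, 0) * g$valid
    g[, c("wt", "wd", "wn") := .(w * (aoi == "target"),
                                 w * (aoi == "distractor"),
                                 w * (aoi == "neither"))]
    g[, .(t_target_ms = sum(wt), t_distractor_ms = sum(wd),
          t_neither_ms = sum(wn)),
      by = .(participant_id, trial_id, condition, trial_type, pair_id)]
  }
  list(pre = one("prenaming"), post = one("postnaming"))
}

# distribute sample dwell intervals over a uniform bin grid (one trial).
# bins are half-open [start, start + bin_ms) anchored at window[1].
bin_durations <- function(t_ms, aoi, valid, window, bin_ms) {
  n_bins <- max(1L, ceiling((window[2] - window[1]) / bin_ms))
  grid <- data.table(bin = seq_len(n_bins),
                     bin_start_ms = window[1] +
                       (seq_len(n_bins) - 1) * bin_ms)
  valid <- rep_len(valid, length(t_ms))
  keep <- valid & aoi %in% c("target", "distractor")
  grid[, c("t_target_ms", "t_distractor_ms") := 0]
  if (!any(keep)) return(grid)
  dt <- sample_dwell(t_ms)[keep]
  a <- pmax(t_ms[keep], window[1])
  b <- pmin(t_ms[keep] + dt, window[2])
  seg <- split_at_bins(a, b, aoi[keep] == "target", window[1], bin_ms)
  s <- seg[, .(w = sum(w)), by = .(bin, is_target)]
  grid[s[is_target == TRUE], on = "bin", t_target_ms := i.w]
  grid[s[is_target == FALSE], on = "bin", t_distractor_ms := i.w]
  grid[]
}

# split intervals [a, b) at bin boundaries; returns (bin, is_target, w).
# anchor is the grid origin. Peels one bin per pass; sample dwells rarely
# span more than two bins, so the loop runs twice in practice.
split_at_bins <- function(a, b, is_target, anchor, bin_ms) {
  seg <- split_at_bins_grouped(a, b, is_target,
                               rep_len(anchor, length(a)),
                               rep(1L, length(a)), bin_ms)
  seg[, gid := NULL]
  seg[]
}

# grouped variant: anchor may vary per interval; gid tags the source trial
split_at_bins_grouped <- function(a, b, is_target, anchor, gid, bin_ms) {
  ok <- b > a
  a <- a[ok]; b <- b[ok]; is_target <- is_target[ok]
  anchor <- anchor[ok]; gid <- gid[ok]
  pieces <- list()
  while (length(a)) {
    i <- floor((a - anchor) / bin_ms) + 1L
    cut <- pmin(b, anchor + i * bin_ms)
    pieces[[length(pieces) + 1L]] <-
      data.table(gid = gid, bin = as.integer(i), is_target = is_target,
                 w = cut - a)
    more <- cut < b
    a <- cut[more]; b <- b[more]; is_target <- is_target[more]
    anchor <- anchor[more]; gid <- gid[more]
  }
  rbindlist(pieces)
}
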