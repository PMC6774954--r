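#' Configuration for a synthetic IPL cohort
#'
#' Describes the study conditions a generated cohort emulates: a
#' two-block, two-condition (context / frequency) preferential-looking
#' design with 8 matching + 8 related trials per condition plus 4 control
#' trials (36 trials total), two counterbalancing lists, infants aged
#' 184-274 days, and naming-locked target-preference shifts whose size
#' may depend on condition, trial type and age.
#'
#' @param n_infants number of infants.
#' @param age_range_days integer(2), inclusive age range in days.
#' @param n_lists number of counterbalancing lists (2).
#' @param sampling_hz gaze sampling rate. The default 60 Hz is a
#'   desk-scale stand-in for 300 Hz research hardware; all downstream
#'   computation is duration-weighted and therefore rate-agnostic.
#' @param effect_spec list with `delta` and `age_slope`, each a named
#'   numeric over cells `context_matching`, `context_related`,
#'   `frequency_matching`, `frequency_related`, plus `age_center_days`.
#'   The injected naming-locked shift for a trial is
#'   `delta[cell] + age_slope[cell] * (age - age_center_days)`, in
#'   target-AOI occupancy units (a pair difference score has expectation
#'   twice the shift). The default mirrors an age-graded matching-trial
#'   effect that is absent in young infants and moderate near nine
#'   months; use [zero_effect_spec()] for null cohorts.
#' @param missingness list: `p_trial_dropout` (whole trial lost),
#'   `p_sample_loss` (per-sample tracker loss), `fussiness_hazard_s`
#'   (per-second hazard that the infant stops contributing for the rest
#'   of the trial), `p_experimenter_flag` (trial-level lab-log error).
#' @param familiarity_spec list: `p_never` (parent reports a word as
#'   never used; rating 0), `rating_probs` (probabilities of ratings
#'   1..5 otherwise), `p_cdi_understands`.
#' @param p_off probability mass of off-AOI dwell bouts on experimental
#'   trials; `control_p_off` and `control_occupancy` govern control
#'   trials (single object: sparser looking, strongly target-locked).
#' @param bout_mean_ms mean exponential dwell-bout duration.
#' @param side_bias_sd SD of a constant per-infant left-bias added to
#'   the target-occupancy probability (exercises counterbalancing).
#' @param word_onset_ms,end_ms target-word onset and trial end (ms).
#' @param seed integer seed; identical configs give identical cohorts.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_infants,
                          age_range_days = c(184L, 274L),
                          n_lists = 2L,
                          sampling_hz = 60,
                          effect_spec = default_effect_spec(),
                          missingness = list(p_trial_dropout = 0.15,
                                             p_sample_loss = 0.10,
                                             fussiness_hazard_s = 0.01,
                                             p_experimenter_flag = 0.01),
                          familiarity_spec = list(
                            p_never = 0.03,
                            rating_probs = c(0.05, 0.15, 0.25, 0.30, 0.25),
                            p_cdi_understands = 0.15),
                          p_off = 0.2,
                          control_p_off = 0.63,
                          control_occupancy = 0.9,
                          bout_mean_ms = 500,
                          side_bias_sd = 0,
                          word_onset_ms = 2000,
                          end_ms = 5500,
                          seed = 1L) {
  stopifnot(n_infants >= 1, length(age_range_days) == 2L,
            age_range_days[1] <= age_range_days[2],
            n_lists >= 1, sampling_hz > 0, bout_mean_ms > 0,
            end_ms >= word_onset_ms + 3500)
  probs <- c(unlist(missingness[c("p_trial_dropout", "p_sample_loss")]),
             familiarity_spec$p_never, familiarity_spec$p_cdi_understands,
             p_off, control_p_off, control_occupancy)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  if (missingness$fussiness_hazard_s < 0) stop("fussiness hazard must be >= 0")
  es <- effect_spec
  cells <- c("context_matching", "context_related",
             "frequency_matching", "frequency_related")
  stopifnot(all(cells %in% names(es$delta)),
            all(cells %in% names(es$age_slope)))
  dmax <- max(abs(es$delta[cells]) +
                abs(es$age_slope[cells]) * diff(range(age_range_days)))
  if (dmax > 0.5)
    stop("effect_spec implies |delta| > 0.5 somewhere in the age range")
  structure(list(n_infants = as.integer(n_infants),
                 age_range_days = as.integer(age_range_days),
                 n_lists = as.integer(n_lists), sampling_hz = sampling_hz,
                 effect_spec = es, missingness = missingness,
                 familiarity_spec = familiarity_spec, p_off = p_off,
                 control_p_off = control_p_off,
                 control_occupancy = control_occupancy,
                 bout_mean_ms = bout_mean_ms, side_bias_sd = side_bias_sd,
                 word_onset_ms = word_onset_ms, end_ms = end_ms,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_effect_spec <- function() {
  cells <- c("context_matching", "context_related",
             "frequency_matching", "frequency_related")
  list(delta = setNames(c(0.028, 0, 0.028, 0), cells),
       age_slope = setNames(c(0.0012, 0, 0.0012, 0), cells),
       age_center_days = 229)
}

#' @rdname cohort_config
#' @export
zero_effect_spec <- function() {
  spec <- default_effect_spec()
  spec$delta[] <- 0
  spec$age_slope[] <- 0
  spec
}

# the 36-trial layout for one list. Within each trial type each object
# appears once on the left and once on the right (mirrored layouts);
# target sides alternate across pairs, and list 2 flips every side.
make_trial_layout <- function(list_id = 1L, stimulus = read_stimulus_table(),
                              word_onset_ms = 2000, end_ms = 5500) {
  stim <- as.data.table(stimulus)
  rows <- list()
  flip <- function(s) ifelse(s == "left", "right", "left")
  for (cond in c("context", "frequency")) {
    pairs <- unique(stim[condition == cond, pair_id])
    for (i in seq_along(pairs)) {
      p <- pairs[i]
      ref <- stim[pair_id == p & role == "referent"][order(position)]
      rel <- stim[pair_id == p & role == "related"][order(position)]
      s <- if (i %% 2 == 1) "left" else "right"
      srel <- flip(s)
      if (list_id %% 2 == 0) { s <- flip(s); srel <- flip(srel) }
      rows[[length(rows) + 1L]] <- data.table(
        condition = cond,
        trial_type = c("matching", "matching", "related", "related"),
        pair_id = p,
        target_word = c(ref$word[1], ref$word[2], ref$word[1], ref$word[2]),
        heard_word = c(ref$word[1], ref$word[2], rel$word[1], rel$word[2]),
        target_side = c(s, s, srel, srel))
    }
  }
  exp_trials <- rbindlist(rows)
  ctrl <- data.table(
    condition = "control", trial_type = "control",
    pair_id = c("control_tree", "control_house", "control_tree",
                "control_house"),
    target_word = c("tre", "hus", "tre", "hus"),
    heard_word = c("tre", "hus", "tre", "hus"),
    target_side = if (list_id %% 2 == 1) c("left", "right", "right", "left")
                  else c("right", "left", "left", "right"))
  out <- rbind(exp_trials, ctrl)
  out[, word_onset_ms := word_onset_ms]
  out[, end_ms := end_ms]
  out[]
}

#' Simulate one trial's gaze stream
#'
#' Gaze is realized as alternating AOI dwell bouts with exponential
#' durations: each bout is off-AOI with probability `p_off`, otherwise on
#' the target with conditional probability 0.5 before the naming shift
#' point and `0.5 + delta` after it, so the expected post-naming target
#' looking proportion is `0.5 + delta`. Samples are then read off the
#' bout path at the configured rate; tracker loss and fussiness inject
#' invalid samples.
#'
#' @param delta naming-locked target-preference shift, in `[-0.5, 0.5]`.
#' @param target_side `"left"` or `"right"`.
#' @param word_onset_ms,end_ms trial timing (ms); the shift applies from
#'   `word_onset_ms + shift_lag_ms` onward.
#' @param shift_lag_ms latency of the naming shift after word onset.
#' @param sampling_hz sampling rate.
#' @param p_off off-AOI bout probability.
#' @param bout_mean_ms mean dwell-bout duration.
#' @param missingness list as in [cohort_config()].
#' @param side_bias additive left-bias on the target probability.
#' @param layout an [aoi_layout()] used to place sample coordinates.
#' @param occupancy baseline conditional target probability (0.5 for
#'   two-object trials; higher for single-object control trials).
#' @return a `data.table` with `t_ms`, `x_px`, `y_px`, `valid`.
#' @export
simulate_trial_gaze <- function(delta = 0, target_side = "left",
                                word_onset_ms = 2000, end_ms = 5500,
                                shift_lag_ms = 367, sampling_hz = 60,
                                p_off = 0.2, bout_mean_ms = 500,
                                missingness = list(p_trial_dropout = 0,
                                                   p_sample_loss = 0,
                                                   fussiness_hazard_s = 0),
                                side_bias = 0, layout = aoi_layout(),
                                occupancy = 0.5) {
  path <- sim_trial_path(delta, target_side, word_onset_ms, end_ms,
                         shift_lag_ms, sampling_hz, p_off, bout_mean_ms,
                         missingness, side_bias, layout, occupancy)
  data.table(t_ms = path$t_ms, x_px = path$x_px, y_px = path$y_px,
             valid = path$valid)
}

# vector core of the trial simulator (no table assembly)
sim_trial_path <- function(delta, target_side, word_onset_ms, end_ms,
                           shift_lag_ms, sampling_hz, p_off, bout_mean_ms,
                           missingness, side_bias, layout, occupancy) {
  if (!is.finite(delta) || abs(delta) > 0.5)
    stop("delta must lie in [-0.5, 0.5]")
  if (end_ms <= 0 || end_ms < word_onset_ms)
    stop("invalid trial duration")
  # alternating dwell bouts over the whole trial
  n_guess <- ceiling(end_ms / bout_mean_ms * 2) + 5L
  durs <- rexp(n_guess, rate = 1 / bout_mean_ms)
  while (sum(durs) < end_ms)
    durs <- c(durs, rexp(n_guess, rate = 1 / bout_mean_ms))
  starts <- cumsum(c(0, durs))
  durs <- durs[starts[-length(starts)] < end_ms]
  starts <- starts[seq_along(durs)]
  shift_at <- word_onset_ms + shift_lag_ms
  # split any bout straddling the shift point so occupancy switches cleanly
  straddle <- which(starts < shift_at & starts + durs > shift_at)
  if (length(straddle)) {
    i <- straddle[1]
    starts <- append(starts, shift_at, after = i)
    durs <- append(durs, starts[i + 2L] - shift_at, after = i)
    durs[i] <- shift_at - starts[i]
  }
  bias <- ifelse(target_side == "left", side_bias, -side_bias)
  p_t <- ifelse(starts >= shift_at,
                pmin(pmax(occupancy + delta + bias, 0), 1),
                pmin(pmax(occupancy + bias, 0), 1))
  u <- runif(length(starts))
  state <- ifelse(u < p_off, "neither",
                  ifelse((u - p_off) / (1 - p_off) < p_t,
                         "target", "distractor"))
  # sample the path
  t_ms <- seq(0, end_ms - 1e-9, by = 1000 / sampling_hz)
  s <- state[findInterval(t_ms, starts)]
  tgt_c <- if (target_side == "left") layout$left_center_px else
    layout$right_center_px
  dis_c <- if (target_side == "left") layout$right_center_px else
    layout$left_center_px
  n <- length(t_ms)
  jx <- runif(n, -150, 150); jy <- runif(n, -150, 150)
  x <- ifelse(s == "target", tgt_c[1] + jx,
              ifelse(s == "distractor", dis_c[1] + jx,
                     layout$screen_px[1] / 2 + runif(n, -60, 60)))
  y <- ifelse(s == "neither", layout$screen_px[2] / 2 + runif(n, -60, 60),
              540 + jy)
  valid <- rep(TRUE, n)
  if (missingness$p_trial_dropout > 0 &&
      runif(1) < missingness$p_trial_dropout) valid[] <- FALSE
  if (missingness$p_sample_loss > 0)
    valid <- valid & runif(n) >= missingness$p_sample_loss
  if (missingness$fussiness_hazard_s > 0) {
    fuss_ms <- rexp(1, rate = missingness$fussiness_hazard_s / 1000)
    valid <- valid & t_ms < fuss_ms
  }
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  list(t_ms = t_ms, x_px = round(x, 1), y_px = round(y, 1), valid = valid)
}

#' Simulate a complete synthetic study cohort
#'
#' Generates, for `config$n_infants` infants, the three analysis inputs
#' (gaze export, trial sheet, parental questionnaires) plus a truth
#' sidecar recording every injected quantity. The sidecar is for
#' validating the pipeline only; no analysis stage consumes it.
#'
#' @param config a [cohort_config()].
#' @param stimulus a stimulus table ([read_stimulus_table()]).
#' @return a list with class `ipl_cohort`: `gaze`, `trials`,
#'   `questionnaires`, `truth`, and the `config`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_infants = 2, seed = 42))
#' range(coh$questionnaires$age_days)
#' @export
simulate_cohort <- function(config, stimulus = read_stimulus_table()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  stim <- as.data.table(stimulus)
  words <- stim$word
  layout <- aoi_layout()
  es <- config$effect_spec
  ids <- sprintf("p%03d", seq_len(config$n_infants))
  ages <- sample(seq(config$age_range_days[1], config$age_range_days[2]),
                 config$n_infants, replace = TRUE)
  lists <- sample(seq_len(config$n_lists), config$n_infants, replace = TRUE)
  biases <- if (config$side_bias_sd > 0)
    stats::rnorm(config$n_infants, 0, config$side_bias_sd) else
      rep(0, config$n_infants)

  gaze_l <- vector("list", config$n_infants)
  trials_l <- vector("list", config$n_infants)
  quest_l <- vector("list", config$n_infants)
  truth_l <- vector("list", config$n_infants)
  layouts <- lapply(seq_len(config$n_lists), make_trial_layout, stim,
                    config$word_onset_ms, config$end_ms)

  for (k in seq_len(config$n_infants)) {
    sheet <- layouts[[lists[k]]]
    # pseudo-randomize experimental order within block; control trials
    # after every eighth trial
    blocks <- split(sheet[trial_type != "control"],
                    sheet[trial_type != "control", condition])
    blocks <- blocks[sample(names(blocks))]
    b1 <- blocks[[1]][sample(.N)]
    b2 <- blocks[[2]][sample(.N)]
    ctrl <- sheet[trial_type == "control"]
    ordered <- rbindlist(list(
      b1[1:8], ctrl[1], b1[9:16], ctrl[2],
      b2[1:8], ctrl[3], b2[9:16], ctrl[4]), use.names = TRUE)
    ordered[, trial_id := sprintf("t%02d", .I)]
    ordered[, participant_id := ids[k]]
    ordered[, experimenter_flag :=
              runif(.N) < config$missingness$p_experimenter_flag]

    cell <- paste(ordered$condition, ordered$trial_type, sep = "_")
    dlt <- ifelse(ordered$trial_type == "control", 0,
                  es$delta[cell] + es$age_slope[cell] *
                    (ages[k] - es$age_center_days))
    dlt <- pmin(pmax(dlt, -0.45), 0.45)

    paths <- vector("list", nrow(ordered))
    for (j in seq_len(nrow(ordered))) {
      is_ctrl <- ordered$trial_type[j] == "control"
      paths[[j]] <- sim_trial_path(
        delta = dlt[j], target_side = ordered$target_side[j],
        word_onset_ms = ordered$word_onset_ms[j],
        end_ms = ordered$end_ms[j], shift_lag_ms = 367,
        sampling_hz = config$sampling_hz,
        p_off = if (is_ctrl) config$control_p_off else config$p_off,
        bout_mean_ms = config$bout_mean_ms,
        missingness = config$missingness, side_bias = biases[k],
        layout = layout,
        occupancy = if (is_ctrl) config$control_occupancy else 0.5)
    }
    lens <- vapply(paths, function(p) length(p$t_ms), integer(1))
    gaze_l[[k]] <- data.table(
      participant_id = ids[k],
      trial_id = rep(ordered$trial_id, lens),
      t_ms = unlist(lapply(paths, `[[`, "t_ms")),
      x_px = unlist(lapply(paths, `[[`, "x_px")),
      y_px = unlist(lapply(paths, `[[`, "y_px")),
      valid = unlist(lapply(paths, `[[`, "valid")))
    trials_l[[k]] <- ordered

    fam <- ifelse(runif(length(words)) < config$familiarity_spec$p_never, 0L,
                  sample(1:5, length(words), replace = TRUE,
                         prob = config$familiarity_spec$rating_probs))
    quest_l[[k]] <- data.table(
      participant_id = ids[k], age_days = ages[k], list_id = lists[k],
      word = words, familiarity = fam,
      cdi_understands = runif(length(words)) <
        config$familiarity_spec$p_cdi_understands)
    truth_l[[k]] <- data.table(
      participant_id = ids[k], trial_id = ordered$trial_id,
      condition = ordered$condition, trial_type = ordered$trial_type,
      delta = dlt, age_days = ages[k], list_id = lists[k],
      side_bias = biases[k])
  }
  trials <- rbindlist(trials_l)
  setcolorder(trials, c("participant_id", "trial_id", "condition",
                        "trial_type", "pair_id", "target_word", "heard_word",
                        "target_side", "word_onset_ms", "end_ms",
                        "experimenter_flag"))
  structure(list(gaze = rbindlist(gaze_l), trials = trials,
                 questionnaires = rbindlist(quest_l),
                 truth = rbindlist(truth_l), config = config),
            class = "ipl_cohort")
}

#' @rdname simulate_cohort
#' @param cohort an `ipl_cohort`.
#' @param dir output directory; created if absent. Writes `gaze.tsv`,
#'   `trial_sheet.csv`, `questionnaires.csv` and `truth_sidecar.csv`
#'   (the sidecar is validation metadata, not an analysis input).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ipl_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gaze_table(cohort$gaze, file.path(dir, "gaze.tsv"))
  write_trial_sheet(cohort$trials, file.path(dir, "trial_sheet.csv"))
  write_questionnaires(cohort$questionnaires,
                       file.path(dir, "questionnaires.csv"))
  fwrite(cohort$truth, file.path(dir, "truth_sidecar.csv"))
  invisible(dir)
}

#' Minimal four-infant fixture cohort
#'
#' A small deterministic cohort used throughout the test suite: four
#' infants, modest missingness, default effects.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [cohort_config()].
#' @return an `ipl_cohort`.
#' @export
fixture_cohort <- function(seed = 101L, ...) {
  simulate_cohort(cohort_config(n_infants = 4, seed = seed, ...))
}
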