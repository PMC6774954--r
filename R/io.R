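#' Read a gaze export
#'
#' Gaze exports are tab-separated with one row per sample and columns
#' `participant_id`, `trial_id`, `t_ms` (ms from trial start), `x_px`,
#' `y_px` (screen pixels, origin top-left) and `valid` (0/1 tracker
#' validity). An empty file (header only) yields an empty table.
#'
#' @param path file path.
#' @return a `data.table` of gaze samples.
#' @seealso [write_gaze_table()]
#' @export
read_gaze_table <- function(path) {
  dt <- read_checked(path, sep = "\t",
                     cols = c("participant_id", "trial_id", "t_ms",
                              "x_px", "y_px", "valid"),
                     numeric_cols = c("t_ms", "x_px", "y_px"))
  dt[, valid := as.logical(valid)]
  if (nrow(dt) && any(dt$t_ms < 0, na.rm = TRUE))
    stop("parse error in ", path, ": negative t_ms")
  dt[]
}

#' @rdname read_gaze_table
#' @param gaze a gaze sample table as returned by [read_gaze_table()].
#' @export
write_gaze_table <- function(gaze, path) {
  out <- as.data.table(gaze)
  out <- out[, .(participant_id, trial_id, t_ms, x_px, y_px,
                 valid = as.integer(valid))]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a trial sheet
#'
#' The trial sheet is a CSV with one row per presented trial:
#' `participant_id`, `trial_id`, `condition` (`context`/`frequency`, or
#' `control`), `trial_type` (`matching`/`related`/`control`), `pair_id`,
#' `target_word`, `heard_word`, `target_side` (`left`/`right`),
#' `word_onset_ms`, `end_ms`, `experimenter_flag` (0/1 error flag).
#' Experimental trials must extend at least 3500 ms past word onset.
#'
#' @param path file path.
#' @return a `data.table` of trial metadata.
#' @export
read_trial_sheet <- function(path) {
  dt <- read_checked(path, sep = ",",
                     cols = c("participant_id", "trial_id", "condition",
                              "trial_type", "pair_id", "target_word",
                              "heard_word", "target_side", "word_onset_ms",
                              "end_ms", "experimenter_flag"),
                     numeric_cols = c("word_onset_ms", "end_ms"))
  dt[, experimenter_flag := as.logical(experimenter_flag)]
  bad <- dt[trial_type != "control" & end_ms < word_onset_ms + 3500]
  if (nrow(bad))
    stop("parse error in ", path, ": experimental trial(s) end before ",
         "word_onset_ms + 3500 (first: trial ", bad$trial_id[1], ")")
  if (!all(dt$target_side %in% c("left", "right")))
    stop("parse error in ", path, ": target_side must be left/right")
  dt[]
}

#' @rdname read_trial_sheet
#' @param trials a trial-sheet table.
#' @export
write_trial_sheet <- function(trials, path) {
  out <- as.data.table(trials)
  out[, experimenter_flag := as.integer(experimenter_flag)]
  fwrite(out, path)
  invisible(path)
}

#' Read a stimulus table
#'
#' One row per word: `condition`, `pair_id`, `role`
#' (`referent` = names a displayed object; `related` = contextually or
#' frequency-related word heard on related trials), `position`
#' (`first`/`second`, linking each related word to its referent), `word`,
#' `english` gloss and `cds_frequency` (occurrences in a child-directed
#' speech corpus; may be NA).
#'
#' @param path file path; the default is the study's 32-word table shipped
#'   with the package.
#' @return a `data.table`, one row per word.
#' @examples
#' stim <- read_stimulus_table()
#' nrow(stim)          # 32 words
#' length(unique(stim$pair_id))  # 8 picture-pairs
#' @export
read_stimulus_table <- function(path = system.file("extdata",
                                                   "stimulus_table.csv",
                                                   package = "iplgaze")) {
  dt <- read_checked(path, sep = ",",
                     cols = c("condition", "pair_id", "role", "position",
                              "word", "english", "cds_frequency"),
                     numeric_cols = character())
  dt[, cds_frequency := suppressWarnings(as.numeric(cds_frequency))]
  if (any(dt$cds_frequency < 0, na.rm = TRUE))
    stop("parse error in ", path, ": negative cds_frequency")
  chk <- dt[, .N, by = .(pair_id, role)]
  if (any(chk$N != 2L))
    stop("parse error in ", path,
         ": every pair must have exactly two words per role")
  dt[]
}

#' Read parental questionnaires
#'
#' Long-format CSV, one row per (participant, word):
#' `participant_id`, `age_days`, `list_id`, `word`, `familiarity`
#' (0 = never used ... 5 = very frequently) and `cdi_understands` (0/1 CDI
#' "understands" flag). Age and list are constant within participant.
#'
#' @param path file path.
#' @return a `data.table`.
#' @export
read_questionnaires <- function(path) {
  dt <- read_checked(path, sep = ",",
                     cols = c("participant_id", "age_days", "list_id",
                              "word", "familiarity", "cdi_understands"),
                     numeric_cols = c("age_days", "familiarity"))
  dt[, cdi_understands := as.logical(cdi_understands)]
  if (any(dt$familiarity < 0 | dt$familiarity > 5, na.rm = TRUE))
    stop("parse error in ", path, ": familiarity ratings must be in 0..5")
  dt[]
}

#' @rdname read_questionnaires
#' @param questionnaires a questionnaire table.
#' @export
write_questionnaires <- function(questionnaires, path) {
  out <- as.data.table(questionnaires)
  out[, cdi_understands := as.integer(cdi_understands)]
  fwrite(out, path)
  invisible(path)
}

# shared checked reader: structured errors name file and column
read_checked <- function(path, sep, cols, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, sep = sep, header = TRUE, colClasses = NULL,
              data.table = TRUE, na.strings = c("NA", ""))
  missing <- setdiff(cols, names(dt))
  if (length(missing))
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  dt <- dt[, cols, with = FALSE]
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(dt[[cc]]))
    bad <- which(is.na(v) & !is.na(dt[[cc]]))
    if (length(bad))
      stop("parse error in ", path, ": non-numeric value in column '", cc,
           "', line ", bad[1] + 1L)
    set(dt, j = cc, value = v)
  }
  dt
}
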