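#' Screen and area-of-interest geometry
#'
#' Two-picture IPL displays place one object in each half of the screen.
#' Looking is scored inside an invisible rectangle around each object
#' (default 800 x 680 px on a 1920 x 1080 display). The two rectangles are
#' mirror images about the vertical midline and must be disjoint and fully
#' on-screen; gaze between them (e.g. the midline gap) counts as "neither".
#'
#' The stimulus description fixes the AOI size but not its placement; the
#' default centers (480, 540) and (1440, 540) center each rectangle in its
#' half-screen. Coordinates are pixels with the origin at the top-left;
#' rectangles are half-open, `[x0, x1) x [y0, y1)`.
#'
#' @param screen_px integer(2), screen width and height in pixels.
#' @param aoi_size_px integer(2), AOI width and height in pixels.
#' @param left_center_px,right_center_px numeric(2), AOI centers.
#' @return An object of class `aoi_layout` with the rectangle bounds
#'   resolved (`left` and `right`, each `c(x0, x1, y0, y1)`).
#' @examples
#' layout <- aoi_layout()
#' assign_aoi(x = c(480, 960, 1440), y = c(540, 540, 540),
#'            target_side = "left", layout = layout)
#' @export
aoi_layout <- function(screen_px = c(1920L, 1080L),
                       aoi_size_px = c(800L, 680L),
                       left_center_px = c(480, 540),
                       right_center_px = NULL) {
  stopifnot(length(screen_px) == 2L, length(aoi_size_px) == 2L,
            all(screen_px > 0), all(aoi_size_px > 0))
  if (is.null(right_center_px)) {
    # mirror about the vertical midline
    right_center_px <- c(screen_px[1] - left_center_px[1], left_center_px[2])
  }
  half <- aoi_size_px / 2
  left <- c(left_center_px[1] - half[1], left_center_px[1] + half[1],
            left_center_px[2] - half[2], left_center_px[2] + half[2])
  right <- c(right_center_px[1] - half[1], right_center_px[1] + half[1],
             right_center_px[2] - half[2], right_center_px[2] + half[2])
  if (left[1] < 0 || right[2] > screen_px[1] || left[3] < 0 ||
      left[4] > screen_px[2])
    stop("AOI rectangles must lie fully on-screen")
  if (left[2] > right[1])
    stop("left and right AOI rectangles must be disjoint")
  structure(list(screen_px = screen_px, aoi_size_px = aoi_size_px,
                 left_center_px = left_center_px,
                 right_center_px = right_center_px,
                 left = left, right = right),
            class = "aoi_layout")
}

#' @export
print.aoi_layout <- function(x, ...) {
  cat("AOI layout:", x$screen_px[1], "x", x$screen_px[2], "px screen;",
      x$aoi_size_px[1], "x", x$aoi_size_px[2], "px AOIs centred at (",
      x$left_center_px[1], ",", x$left_center_px[2], ") and (",
      x$right_center_px[1], ",", x$right_center_px[2], ")\n")
  invisible(x)
}

#' Label gaze samples by area of interest
#'
#' Resolves raw screen coordinates to `"target"`, `"distractor"` or
#' `"neither"` given which side the named (target) object was on. Invalid
#' samples are always `"neither"`; the function never raises on bad
#' coordinates (NA or off-screen points fall outside both rectangles).
#'
#' @param x,y numeric vectors of gaze coordinates in pixels.
#' @param target_side `"left"` or `"right"` (scalar or vector).
#' @param layout an [aoi_layout()].
#' @param valid logical vector; invalid samples are labelled `"neither"`.
#' @return character vector of labels.
#' @export
assign_aoi <- function(x, y, target_side, layout = aoi_layout(),
                       valid = TRUE) {
  stopifnot(inherits(layout, "aoi_layout"))
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  target_side <- rep_len(as.character(target_side), n)
  valid <- rep_len(as.logical(valid), n)
  if (!all(target_side %in% c("left", "right")))
    stop("target_side must be 'left' or 'right'")
  in_rect <- function(r) !is.na(x) & !is.na(y) &
    x >= r[1] & x < r[2] & y >= r[3] & y < r[4]
  in_left <- in_rect(layout$left) & valid
  in_right <- in_rect(layout$right) & valid
  out <- rep("neither", n)
  out[in_left & target_side == "left"] <- "target"
  out[in_right & target_side == "right"] <- "target"
  out[in_left & target_side == "right"] <- "distractor"
  out[in_right & target_side == "left"] <- "distractor"
  out
}

#' Analysis windows for a naming trial
#'
#' Standard windows, all in ms relative to trial start: pre-naming runs from
#' trial start to the target-word onset (around 2000 ms into the trial);
#' post-naming from onset + 367 ms to onset + 3500 ms (3133 ms long,
#' closed at the right edge as printed); the cluster-analysis window from
#' onset - 2000 ms to the end of the trial, tiled in 50 ms bins.
#'
#' @param word_onset_ms target-word onset, ms from trial start.
#' @param end_ms trial end, ms from trial start.
#' @param bin_ms time-bin width for the binned time course.
#' @param post_lag_ms,post_len_ms post-naming window offset and end
#'   relative to word onset.
#' @param cluster_pre_ms extent of the cluster window before word onset.
#' @return An object of class `analysis_windows` with elements `prenaming`,
#'   `postnaming`, `cluster` (each `c(start, end)`) and `bin_ms`.
#' @export
analysis_windows <- function(word_onset_ms, end_ms, bin_ms = 50,
                             post_lag_ms = 367, post_len_ms = 3500,
                             cluster_pre_ms = 2000) {
  stopifnot(is.numeric(word_onset_ms), is.numeric(end_ms), bin_ms > 0)
  if (end_ms < word_onset_ms + post_len_ms)
    stop("trial must extend to at least word_onset_ms + ", post_len_ms, " ms")
  structure(list(
    prenaming = c(0, word_onset_ms),
    postnaming = c(word_onset_ms + post_lag_ms, word_onset_ms + post_len_ms),
    cluster = c(max(0, word_onset_ms - cluster_pre_ms), end_ms),
    bin_ms = bin_ms,
    word_onset_ms = word_onset_ms,
    end_ms = end_ms), class = "analysis_windows")
}
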