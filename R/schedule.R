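#' Build a dynamic-PET frame schedule
#'
#' Expands grouped frame definitions (count, duration) into a contiguous
#' schedule starting at injection (t = 0). Frames are non-overlapping and
#' back-to-back: each frame starts where the previous one ended.
#'
#' @param groups A list of length-2 numeric vectors `c(count, duration_s)`,
#'   or a two-column matrix/data.frame with columns count and duration in
#'   seconds.
#' @return An object of class `frame_schedule`: a list with `start_s`,
#'   `duration_s` (seconds from injection) and `mid_min` (frame mid-times in
#'   minutes).
#' @examples
#' sch <- make_frame_schedule(list(c(6, 30), c(4, 180), c(5, 600)))
#' n_frames(sch)            # 15
#' total_duration_s(sch)    # 3900 s = 65 min
#' @seealso [fluciclovine_schedule()] for the default acquisition.
#' @export
make_frame_schedule <- function(groups) {
  if (is.matrix(groups) || is.data.frame(groups)) {
    groups <- lapply(seq_len(nrow(groups)), function(i) as.numeric(groups[i, 1:2]))
  }
  if (!is.list(groups) || length(groups) == 0L)
    stop_("'groups' must be a non-empty list of (count, duration_s) pairs")
  counts <- vapply(groups, function(g) as.numeric(g[[1]]), numeric(1))
  durs <- vapply(groups, function(g) as.numeric(g[[2]]), numeric(1))
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts)))
    stop_("frame counts must be integers >= 1")
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop_("frame durations must be positive")
  duration_s <- rep(durs, times = counts)
  start_s <- cumsum(c(0, duration_s[-length(duration_s)]))
  structure(
    list(start_s = start_s, duration_s = duration_s,
         mid_min = (start_s + duration_s / 2) / 60),
    class = "frame_schedule")
}

#' Default dynamic fluciclovine acquisition schedule
#'
#' Fifteen frames (6 x 30 s, 4 x 180 s, 5 x 600 s) covering 0--65 min
#' post-injection; the final four frame mid-times fall at 30, 40, 50 and
#' 60 min, the window in which fluciclovine uptake shows influx/efflux
#' equilibrium.
#'
#' @return A [make_frame_schedule()] object with 15 frames.
#' @export
fluciclovine_schedule <- function() {
  make_frame_schedule(list(c(6, 30), c(4, 180), c(5, 600)))
}

#' @rdname make_frame_schedule
#' @param schedule A `frame_schedule`.
#' @export
n_frames <- function(schedule) length(schedule$start_s)

#' @rdname make_frame_schedule
#' @export
total_duration_s <- function(schedule) {
  n <- n_frames(schedule)
  schedule$start_s[n] + schedule$duration_s[n]
}

#' Indices of frames inside the equilibrium window
#'
#' @param schedule A `frame_schedule`.
#' @param window_min Minimum frame mid-time, minutes (default 30, the onset
#'   of apparent influx/efflux equilibrium).
#' @return Integer vector of frame indices with mid-time >= `window_min`.
#' @export
equilibrium_frames <- function(schedule, window_min = 30) {
  which(schedule$mid_min >= window_min)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %.0f s (%.1f min) total\n",
              n_frames(x), total_duration_s(x), total_duration_s(x) / 60))
  cat("  mid-times (min):", paste(signif(x$mid_min, 4), collapse = ", "), "\n")
  invisible(x)
}
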