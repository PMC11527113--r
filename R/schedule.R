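#' Excitation schedules
#'
#' An excitation schedule describes, frame by frame, whether the laser excites
#' the donor dye (FRET read-out frames) or the acceptor dye directly
#' (acceptor-presence check frames). It is stored as a tibble of contiguous,
#' non-overlapping half-open segments `[start_frame, end_frame)` using 0-based
#' frame indices, together covering `[0, n_frames)`.
#'
#' `schedule_cas9_snapshot()`, `schedule_muts_adp()` and `schedule_muts_atp()`
#' build the three standard movie layouts used throughout the package:
#' a short snapshot movie (10 donor-excitation frames followed by 10 direct
#' acceptor-excitation frames, 50 ms frames), a long mismatch-binding movie
#' with 200 ms frames (10 acceptor + 980 donor + 10 acceptor), and its 50 ms
#' variant with 1480 donor-excitation frames.
#'
#' @param segments A data frame with columns `start_frame`, `end_frame`
#'   (integer, half-open) and `channel` (`"donor_ex"` or `"acceptor_ex"`).
#' @param frame_interval Frame duration in seconds.
#' @return A tibble of class `fret_schedule` with attribute `frame_interval`.
#' @examples
#' sched <- schedule_cas9_snapshot()
#' n_frames(sched)
#' @export
excitation_schedule <- function(segments, frame_interval) {
  segments <- as_tibble(segments)
  stopifnot(all(c("start_frame", "end_frame", "channel") %in% names(segments)))
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    abort("`frame_interval` must be a single positive number (seconds).",
          class = "smfret_invalid_parameter")
  }
  segments <- arrange(segments, .data$start_frame)
  if (!all(segments$channel %in% c("donor_ex", "acceptor_ex"))) {
    abort("schedule channels must be 'donor_ex' or 'acceptor_ex'",
          class = "smfret_invalid_parameter")
  }
  if (segments$start_frame[1] != 0L ||
      any(segments$end_frame <= segments$start_frame) ||
      (nrow(segments) > 1 &&
       any(segments$start_frame[-1] != segments$end_frame[-nrow(segments)]))) {
    abort("schedule segments must be contiguous half-open ranges starting at frame 0",
          class = "smfret_invalid_parameter")
  }
  structure(segments,
            frame_interval = frame_interval,
            class = c("fret_schedule", class(segments)))
}

#' @rdname excitation_schedule
#' @export
schedule_cas9_snapshot <- function(frame_interval = 0.05) {
  excitation_schedule(
    tibble(start_frame = c(0L, 10L), end_frame = c(10L, 20L),
           channel = c("donor_ex", "acceptor_ex")),
    frame_interval = frame_interval
  )
}

#' @rdname excitation_schedule
#' @export
schedule_muts_adp <- function(frame_interval = 0.2) {
  excitation_schedule(
    tibble(start_frame = c(0L, 10L, 990L), end_frame = c(10L, 990L, 1000L),
           channel = c("acceptor_ex", "donor_ex", "acceptor_ex")),
    frame_interval = frame_interval
  )
}

#' @rdname excitation_schedule
#' @export
schedule_muts_atp <- function(frame_interval = 0.05) {
  excitation_schedule(
    tibble(start_frame = c(0L, 10L, 1490L), end_frame = c(10L, 1490L, 1500L),
           channel = c("acceptor_ex", "donor_ex", "acceptor_ex")),
    frame_interval = frame_interval
  )
}

#' @rdname excitation_schedule
#' @param schedule A `fret_schedule`.
#' @export
n_frames <- function(schedule) {
  max(schedule$end_frame)
}

#' Per-frame excitation channel
#'
#' Expands a schedule into one row per frame.
#'
#' @param schedule A [excitation_schedule()].
#' @return Tibble with `frame` (0-based), `time_s` (frame start) and
#'   `excitation`.
#' @export
schedule_frames <- function(schedule) {
  dt <- attr(schedule, "frame_interval")
  frames <- purrr::pmap(
    list(schedule$start_frame, schedule$end_frame, schedule$channel),
    function(s, e, ch) tibble(frame = seq.int(s, e - 1L), excitation = ch)
  )
  out <- bind_rows(frames)
  out$time_s <- out$frame * dt
  out[, c("frame", "time_s", "excitation")]
}
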