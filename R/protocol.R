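#' Block-design acquisition protocol
#'
#' The yes/no question protocol: an initial baseline rest period followed by
#' `n_cycles` alternating answer/rest blocks, sampled at one DTOF frame per
#' `frame_period_ms`.  Defaults give the standard 5:30-min run (30-s
#' baseline + 5 x (30-s answer + 30-s rest)) at 300-ms frames.
#'
#' @param baseline_s initial rest period, s
#' @param n_cycles number of answer/rest cycles
#' @param answer_s answer-block duration, s
#' @param rest_s rest-block duration, s
#' @param frame_period_ms DTOF frame period, ms
#' @return a `protocol_design` object with derived totals: `total_run_s`,
#'   `frames_per_run`, `frames_baseline`, answer-onset frame indices, and
#'   `session_min(q)` via [session_minutes()]
#' @export
build_protocol <- function(baseline_s = 30, n_cycles = 5, answer_s = 30,
                           rest_s = 30, frame_period_ms = 300) {
  if (baseline_s <= 0 || answer_s <= 0 || rest_s <= 0 || frame_period_ms <= 0)
    stop("all durations must be positive")
  if (n_cycles < 0) stop("n_cycles must be >= 0")
  dt_s <- frame_period_ms / 1000
  durs <- c(baseline_s, answer_s, rest_s)
  if (any(abs(durs / dt_s - round(durs / dt_s)) > 1e-9))
    stop("block durations must be whole multiples of the frame period")
  total_run_s <- baseline_s + n_cycles * (answer_s + rest_s)
  frames_per_run <- as.integer(round(total_run_s / dt_s))
  onsets <- if (n_cycles > 0)
    as.integer(round(baseline_s / dt_s) + round((answer_s + rest_s) / dt_s) *
               (seq_len(n_cycles) - 1) + 1L) else integer(0)
  structure(list(baseline_s = baseline_s, n_cycles = n_cycles,
                 answer_s = answer_s, rest_s = rest_s,
                 frame_period_ms = frame_period_ms,
                 frame_period_s = dt_s,
                 total_run_s = total_run_s,
                 frames_per_run = frames_per_run,
                 frames_baseline = as.integer(round(baseline_s / dt_s)),
                 answer_onset_frames = onsets),
            class = "protocol_design")
}

#' @export
print.protocol_design <- function(x, ...) {
  cat(sprintf("protocol_design: %gs baseline + %d x (%gs answer + %gs rest) = %gs (%d frames @ %g ms)\n",
              x$baseline_s, x$n_cycles, x$answer_s, x$rest_s,
              x$total_run_s, x$frames_per_run, x$frame_period_ms))
  invisible(x)
}

#' Session duration for a multi-question session
#'
#' @param protocol a `protocol_design`
#' @param n_questions number of questions asked in the session
#' @return total session duration in minutes
#' @export
session_minutes <- function(protocol, n_questions = 4) {
  n_questions * protocol$total_run_s / 60
}

# centre times (s, from run start) of each frame
frame_times_s <- function(protocol) {
  (seq_len(protocol$frames_per_run) - 0.5) * protocol$frame_period_s
}

# logical vector: is frame f inside an answer block?
answer_block_mask <- function(protocol) {
  f <- seq_len(protocol$frames_per_run)
  m <- rep(FALSE, protocol$frames_per_run)
  la <- round(protocol$answer_s / protocol$frame_period_s)
  for (on in protocol$answer_onset_frames)
    m[f >= on & f < on + la] <- TRUE
  m
}
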