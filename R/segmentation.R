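#' Analysis window specification
#'
#' Parameters of the sliding-window segmentation: window length and
#' increment in seconds, and the contraction time percentage (cTp) -- the
#' central fraction of each prompted contraction kept for analysis. The
#' protocol defaults are 200 ms windows, 50 ms increment and cTp = 0.7
#' (keeps the dynamic onset); cTp = 0.4 keeps only the static plateau.
#'
#' Sample counts are derived deterministically with half-up rounding:
#' `W = round(window_s * fs)`, `I = round(increment_s * fs)`.
#'
#' @param window_s window length in seconds (> 0).
#' @param increment_s window increment in seconds (> 0, <= `window_s`).
#' @param ctp contraction time percentage in (0, 1].
#' @return an object of class `WindowSpec`.
#' @export
window_spec <- function(window_s = 0.200, increment_s = 0.050, ctp = 0.7) {
  if (!is.numeric(window_s) || window_s <= 0)
    stop_param("window_s must be positive")
  if (!is.numeric(increment_s) || increment_s <= 0 || increment_s > window_s)
    stop_param("increment_s must be in (0, window_s]")
  if (!is.numeric(ctp) || ctp <= 0 || ctp > 1)
    stop_param("ctp must lie in (0, 1]")
  structure(list(window_s = window_s, increment_s = increment_s, ctp = ctp),
            class = "WindowSpec")
}

#' Trim a contraction to its central fraction
#'
#' Keeps the central `ctp` fraction of a contraction segment, discarding
#' the beginning (request-to-movement delay) and end (anticipatory
#' relaxation) symmetrically: `floor((1 - ctp)/2 * L)` samples are dropped
#' at the start and enough at the end to leave `round(ctp * L)` samples.
#'
#' @param segment channels x L matrix (or a vector, treated as one
#'   channel).
#' @param ctp contraction time percentage in (0, 1]; 1 is the identity.
#' @return channels x `round(ctp * L)` matrix.
#' @export
trim_contraction <- function(segment, ctp) {
  if (!is.numeric(ctp) || length(ctp) != 1L || ctp <= 0 || ctp > 1)
    stop_param("ctp must lie in (0, 1]")
  if (is.vector(segment)) segment <- matrix(segment, nrow = 1L)
  L <- ncol(segment)
  if (L < 1L) stop_param("empty segment")
  keep <- round_half_up(ctp * L)
  start <- floor((1 - ctp) / 2 * L)
  segment[, (start + 1L):(start + keep), drop = FALSE]
}

#' Segment a session into labeled analysis windows
#'
#' Applies the guided-recording schedule: each contraction block is
#' cTp-trimmed ([trim_contraction()]) and cut into sliding windows of
#' `W = round(window_s * fs)` samples advancing by
#' `I = round(increment_s * fs)`; a trimmed segment of length L' yields
#' `floor((L' - W)/I) + 1` windows. Windows never straddle repetition
#' boundaries and relaxation periods are not windowed ("rest", when it is
#' a scheduled class, is windowed like any other movement). A segment
#' shorter than one window contributes no windows and a warning.
#'
#' @param session a [recording_session()].
#' @param spec a [window_spec()].
#' @return list of `LabeledWindow` objects: each a list with `samples`
#'   (channels x W integer matrix), `movement`, `repetition`, and
#'   `subject_id` (from session metadata, if any).
#' @export
segment_session <- function(session, spec = window_spec()) {
  validate_session(session)
  stopifnot(inherits(spec, "WindowSpec"))
  fs <- session$sampling_rate_hz
  W <- round_half_up(spec$window_s * fs)
  I <- round_half_up(spec$increment_s * fs)
  sched <- session_schedule(session)
  subject_id <- session$metadata$subject_id
  windows <- list()
  for (b in seq_len(nrow(sched))) {
    seg <- session$signal[, sched$start[b]:sched$end[b], drop = FALSE]
    seg <- trim_contraction(seg, spec$ctp)
    Lp <- ncol(seg)
    if (W > Lp) {
      warning(sprintf(
        "window (%d samples) longer than trimmed segment (%d): %s rep %d skipped",
        W, Lp, sched$movement[b], sched$repetition[b]), call. = FALSE)
      next
    }
    n_win <- floor((Lp - W) / I) + 1L
    starts <- (seq_len(n_win) - 1L) * I + 1L
    for (s in starts) {
      windows[[length(windows) + 1L]] <- structure(
        list(samples = seg[, s:(s + W - 1L), drop = FALSE],
             movement = sched$movement[b],
             repetition = sched$repetition[b],
             subject_id = subject_id),
        class = "LabeledWindow")
    }
  }
  windows
}

#' Reduce the ADC bit depth of integer counts
#'
#' Emulates acquisition at a lower ADC resolution by an arithmetic right
#' shift of the counts: `v -> floor(v / 2^(from_bits - to_bits))` with
#' floor toward minus infinity, so the output lies in the signed
#' `to_bits` range. Merging quantization levels can only merge distinct
#' values, so the cardinality of any window is non-increasing under
#' requantization.
#'
#' @param signal integer vector or matrix within the `from_bits` range.
#' @param from_bits source bit depth.
#' @param to_bits target bit depth, `1 <= to_bits <= from_bits`.
#' @return requantized signal of the same shape.
#' @export
requantize <- function(signal, from_bits, to_bits) {
  if (!is_count(from_bits) || !is_count(to_bits) || from_bits > 32)
    stop_param("bit depths must be integers in 1..32")
  if (to_bits > from_bits)
    stop_param("to_bits (%d) exceeds from_bits (%d): cannot add precision",
               to_bits, from_bits)
  if (to_bits == from_bits) return(signal)
  out <- signal %/% 2^(from_bits - to_bits)
  storage.mode(out) <- "integer"
  out
}

# session-level convenience used by the ADC sweep
requantize_session <- function(session, to_bits) {
  s <- session
  s$signal <- requantize(s$signal, s$adc_bits, to_bits)
  s$adc_bits <- as.integer(to_bits)
  validate_session(s)
  s
}

#' Decimate a signal to emulate a lower sampling rate
#'
#' With `antialias = FALSE` (the default) keeps every `factor`-th sample,
#' emulating acquisition at `fs / factor` with no digital pre-filtering
#' (lower sampling rate treated purely as an acquisition condition). With
#' `antialias = TRUE` the signal is low-pass filtered below the new
#' Nyquist frequency (zero-phase 4th-order Butterworth at 0.9 of the new
#' Nyquist) before picking every `factor`-th sample, and the filtered
#' values are re-rounded to integer counts.
#'
#' @param signal integer vector or matrix (channels x samples).
#' @param factor integer decimation factor >= 1; 1 is the identity.
#' @param antialias apply a low-pass filter before subsampling.
#' @return decimated signal, integer counts.
#' @export
decimate <- function(signal, factor, antialias = FALSE) {
  if (!is_count(factor)) stop_param("factor must be a positive integer")
  factor <- as.integer(factor)
  vec <- is.vector(signal)
  if (vec) signal <- matrix(signal, nrow = 1L)
  if (factor == 1L && !antialias) {
    out <- signal
  } else {
    if (antialias) {
      bf <- signal::butter(4, 0.9 / factor, type = "low")
      signal <- t(apply(signal, 1L, function(x)
        signal::filtfilt(bf, as.numeric(x))))
      signal <- round_half_up(signal)
    }
    out <- signal[, seq(1L, ncol(signal), by = factor), drop = FALSE]
  }
  storage.mode(out) <- "integer"
  if (vec) out <- out[1L, ]
  out
}

# session-level decimation: adjusts sampling rate and (approximately)
# preserves the schedule since block boundaries scale with fs
decimate_session <- function(session, factor, antialias = FALSE) {
  s <- session
  s$signal <- decimate(s$signal, factor, antialias)
  s$sampling_rate_hz <- s$sampling_rate_hz / factor
  validate_session(s)
  s
}
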