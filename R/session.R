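#' Recording session
#'
#' A `RecordingSession` bundles a multichannel EMG recording stored as raw
#' integer ADC counts with the acquisition metadata and guided-recording
#' movement schedule needed to segment it: sampling rate, ADC bit depth,
#' ordered movement labels ("rest" is an ordinary class when present),
#' number of repetitions per movement, and the prompted contraction and
#' relaxation durations.
#'
#' The recording is assumed to follow the guided protocol: for each
#' movement, in order, `n_repetitions` blocks of `contraction_time_s`
#' seconds of contraction followed by `relax_time_s` seconds of relaxation.
#'
#' @param signal integer matrix, channels x samples, raw ADC counts.
#' @param sampling_rate_hz positive sampling rate in Hz.
#' @param adc_bits ADC bit depth B, 1..32; counts must lie in the signed
#'   B-bit range `[-2^(B-1), 2^(B-1)-1]` (or `[0, 2^B-1]` if
#'   `signed = FALSE`).
#' @param movements character vector of unique movement labels in schedule
#'   order.
#' @param n_repetitions repetitions of each movement (protocol default 3).
#' @param contraction_time_s prompted contraction duration in seconds.
#' @param relax_time_s relaxation duration between contractions in seconds.
#' @param channel_names optional channel names (default `"ch1"`, ...).
#' @param signed logical; whether counts are signed (bipolar EMG default).
#' @param metadata optional named list of extra metadata carried along.
#' @param validate run [validate_session()] before returning.
#'
#' @return an object of class `RecordingSession`.
#' @seealso [validate_session()], [read_session()], [generate_session()]
#' @export
recording_session <- function(signal, sampling_rate_hz, adc_bits, movements,
                              n_repetitions = 3L, contraction_time_s = 3,
                              relax_time_s = 3, channel_names = NULL,
                              signed = TRUE, metadata = list(),
                              validate = TRUE) {
  if (!is.matrix(signal)) stop_param("`signal` must be a channels x samples matrix")
  storage.mode(signal) <- "integer"
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(signal)))
  s <- structure(
    list(
      signal = signal,
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      adc_bits = as.integer(adc_bits),
      movements = as.character(movements),
      n_repetitions = as.integer(n_repetitions),
      contraction_time_s = as.numeric(contraction_time_s),
      relax_time_s = as.numeric(relax_time_s),
      channel_names = as.character(channel_names),
      signed = isTRUE(signed),
      metadata = metadata
    ),
    class = "RecordingSession"
  )
  if (validate) validate_session(s)
  s
}

#' Validate a recording session
#'
#' Checks the structural invariants of a [recording_session()]: counts
#' within the declared ADC range, unique movement labels, channel-name
#' length, and a duration check -- the recording must be at least as long
#' as the schedule implies (`n_movements * n_repetitions *
#' (contraction_time_s + relax_time_s)` seconds), within a relative
#' tolerance that absorbs prompt delays and lead-in present in guided
#' recordings.
#'
#' @param session a `RecordingSession`.
#' @param duration_tolerance relative slack on the schedule duration
#'   (default 0.1).
#' @return the session, invisibly; errors on any violated invariant.
#' @export
validate_session <- function(session, duration_tolerance = 0.1) {
  stopifnot(inherits(session, "RecordingSession"))
  s <- session
  if (!is_count(s$adc_bits) || s$adc_bits > 32)
    stop_param("adc_bits must be an integer in 1..32, got %s", s$adc_bits)
  if (!is.numeric(s$sampling_rate_hz) || s$sampling_rate_hz <= 0)
    stop_param("sampling_rate_hz must be positive")
  if (anyDuplicated(s$movements))
    stop_param("movement labels must be unique")
  if (length(s$channel_names) != nrow(s$signal))
    stop_param("channel_names length (%d) != number of channels (%d)",
               length(s$channel_names), nrow(s$signal))
  rng <- adc_range_counts(s$adc_bits, s$signed)
  for (c in seq_len(nrow(s$signal))) {
    v <- s$signal[c, ]
    if (anyNA(v)) stop_param("channel %s contains NA samples", s$channel_names[c])
    if (min(v) < rng[1] || max(v) > rng[2])
      stop_param(paste0("channel %s has samples outside the %s %d-bit range ",
                        "[%d, %d]"),
                 s$channel_names[c], if (s$signed) "signed" else "unsigned",
                 s$adc_bits, rng[1], rng[2])
  }
  expected <- length(s$movements) * s$n_repetitions *
    (s$contraction_time_s + s$relax_time_s) * s$sampling_rate_hz
  if (ncol(s$signal) < expected * (1 - duration_tolerance))
    stop_param(paste0("recording too short for its schedule: %d samples, ",
                      "schedule implies >= %.0f (tolerance %.0f%%)"),
               ncol(s$signal), expected, 100 * duration_tolerance)
  invisible(session)
}

#' @export
print.RecordingSession <- function(x, ...) {
  cat(sprintf("RecordingSession: %d channels x %d samples\n",
              nrow(x$signal), ncol(x$signal)))
  cat(sprintf("  %g Hz, %d-bit %s ADC\n", x$sampling_rate_hz, x$adc_bits,
              if (x$signed) "signed" else "unsigned"))
  cat(sprintf("  %d movements x %d repetitions (%gs contraction / %gs relax)\n",
              length(x$movements), x$n_repetitions, x$contraction_time_s,
              x$relax_time_s))
  cat("  movements:", paste(x$movements, collapse = ", "), "\n")
  invisible(x)
}

# schedule of contraction blocks implied by the guided protocol:
# per movement (in order), n_repetitions blocks of contraction + relaxation.
# Returns a data.frame with 1-based sample indices of each contraction.
session_schedule <- function(session) {
  s <- session
  fs <- s$sampling_rate_hz
  n_contr <- round_half_up(s$contraction_time_s * fs)
  n_block <- round_half_up((s$contraction_time_s + s$relax_time_s) * fs)
  n_mov <- length(s$movements)
  idx <- 0L
  out <- vector("list", n_mov * s$n_repetitions)
  for (m in seq_len(n_mov)) {
    for (r in seq_len(s$n_repetitions)) {
      start <- (( (m - 1L) * s$n_repetitions + (r - 1L)) * n_block) + 1L
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        movement = s$movements[m], repetition = r,
        start = start, end = start + n_contr - 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
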