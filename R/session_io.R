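#' Write a recording session to disk
#'
#' Serializes a [recording_session()] to a directory containing a
#' `session.json` metadata sidecar plus the signal payload. The native
#' payload is `signal.csv` (one row per sample, one column per channel,
#' integer counts -- diffable and language-neutral); for large sessions a
#' raw little-endian int32 payload (`signal.bin`) can be selected with
#' `signal_format = "int32le"` (stored sample-major, i.e. column after
#' column of the channels x samples matrix). Integer counts are preserved
#' exactly in both dialects; no float round-trip occurs.
#'
#' `session.json` keys: `sampling_rate_hz`, `adc_bits`, `signed`,
#' `movements`, `n_repetitions`, `contraction_time_s`, `relax_time_s`,
#' `channel_names`, `signal_format`.
#'
#' @param session a validated `RecordingSession`.
#' @param path directory to create/write into.
#' @param signal_format `"csv"` (default) or `"int32le"`.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(session, path, signal_format = c("csv", "int32le")) {
  validate_session(session)
  signal_format <- match.arg(signal_format)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop_param("cannot create session directory %s", path)
  meta <- list(
    sampling_rate_hz = session$sampling_rate_hz,
    adc_bits = session$adc_bits,
    signed = session$signed,
    movements = session$movements,
    n_repetitions = session$n_repetitions,
    contraction_time_s = session$contraction_time_s,
    relax_time_s = session$relax_time_s,
    channel_names = session$channel_names,
    signal_format = signal_format
  )
  if (length(session$metadata)) meta$extra <- session$metadata
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (signal_format == "csv") {
    dt <- data.table::as.data.table(t(session$signal))
    data.table::setnames(dt, session$channel_names)
    data.table::fwrite(dt, file.path(path, "signal.csv"))
  } else {
    con <- file(file.path(path, "signal.bin"), "wb")
    on.exit(close(con))
    writeBin(as.integer(t(session$signal)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a recording session from disk
#'
#' Reads a session directory written by [write_session()]: a
#' `session.json` sidecar plus `signal.csv` or `signal.bin` payload. The
#' returned session is validated; malformed metadata raises a format
#' error and out-of-range counts raise a range error naming the channel.
#'
#' @param path session directory.
#' @return a validated `RecordingSession`.
#' @export
read_session <- function(path) {
  meta_file <- file.path(path, "session.json")
  if (!file.exists(meta_file))
    stop_param("not a session directory (missing session.json): %s", path)
  meta <- tryCatch(jsonlite::read_json(meta_file, simplifyVector = TRUE),
                   error = function(e)
                     stop_param("malformed session.json in %s: %s", path,
                                conditionMessage(e)))
  required <- c("sampling_rate_hz", "adc_bits", "signed", "movements",
                "n_repetitions", "contraction_time_s", "relax_time_s",
                "channel_names", "signal_format")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop_param("session.json missing required keys: %s",
               paste(missing, collapse = ", "))
  if (identical(meta$signal_format, "csv")) {
    f <- file.path(path, "signal.csv")
    if (!file.exists(f)) stop_param("missing signal.csv in %s", path)
    dt <- data.table::fread(f, colClasses = "integer")
    sig <- t(as.matrix(dt))
  } else if (identical(meta$signal_format, "int32le")) {
    f <- file.path(path, "signal.bin")
    if (!file.exists(f)) stop_param("missing signal.bin in %s", path)
    n <- file.size(f) / 4L
    con <- file(f, "rb")
    on.exit(close(con))
    v <- readBin(con, "integer", n = n, size = 4L, endian = "little")
    n_ch <- length(meta$channel_names)
    sig <- matrix(v, nrow = n_ch, byrow = TRUE)
  } else {
    stop_param("unknown signal_format %s in session.json", meta$signal_format)
  }
  dimnames(sig) <- NULL
  recording_session(
    signal = sig,
    sampling_rate_hz = meta$sampling_rate_hz,
    adc_bits = meta$adc_bits,
    movements = meta$movements,
    n_repetitions = meta$n_repetitions,
    contraction_time_s = meta$contraction_time_s,
    relax_time_s = meta$relax_time_s,
    channel_names = meta$channel_names,
    signed = isTRUE(meta$signed),
    metadata = if (is.null(meta$extra)) list() else meta$extra
  )
}
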