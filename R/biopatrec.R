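#' Read a BioPatRec-style recording session from a MAT file
#'
#' Optional read-only bridge for recording sessions stored in the MAT
#' layout used by the BioPatRec platform: a struct variable (by default
#' the first struct in the file, conventionally named `recSession`) with
#' fields
#'
#' * `data` -- signal matrix, samples x channels (volts or integer counts)
#' * `sF` -- sampling frequency in Hz
#' * `mov` -- cell array of movement name strings
#' * `nR` -- repetitions per movement
#' * `cT`, `rT` -- contraction and relaxation times in seconds
#' * optional `adc_bits` (or `bits`) and `adc_range` (volts full scale)
#'
#' The bridge sniffs how the signal is stored rather than assuming: if
#' every sample is integral it is taken as raw ADC counts; otherwise the
#' values are treated as volts and rescaled to integer counts with
#' `counts = round(volts / LSB)`, `LSB = adc_range / 2^adc_bits`. Which
#' path was taken, and the scale used, is recorded in the session's
#' `metadata` (`$source` and `$volts_per_count`).
#'
#' Only uncompressed MAT v5 files are supported (see [read_mat5()]).
#' Writing MAT files is out of scope.
#'
#' @param path MAT file path.
#' @param adc_bits bit depth to assume when the file carries none; for
#'   integral data the default infers the smallest signed depth covering
#'   the observed counts, for volts data it defaults to 16.
#' @param adc_range_volts full-scale range used to derive the LSB when the
#'   file stores volts and carries no `adc_range` field (default: twice
#'   the largest absolute value, i.e. the data just fits).
#' @return a validated [recording_session()].
#' @export
read_biopatrec_session <- function(path, adc_bits = NULL,
                                   adc_range_volts = NULL) {
  vars <- read_mat5(path)
  is_struct <- vapply(vars, function(v) is.list(v) && !is.null(names(v)),
                      logical(1))
  if (!any(is_struct))
    stop_param("unsupported layout: no recording-session struct in %s", path)
  rec <- vars[[which(is_struct)[1]]]
  required <- c("data", "sF", "mov", "nR", "cT", "rT")
  missing <- setdiff(required, names(rec))
  if (length(missing))
    stop_param("unsupported BioPatRec layout, missing fields: %s",
               paste(missing, collapse = ", "))
  data <- rec$data                      # samples x channels
  movements <- unlist(rec$mov)
  bits <- if (!is.null(rec$adc_bits)) as.integer(rec$adc_bits[1])
          else if (!is.null(rec$bits)) as.integer(rec$bits[1])
          else if (!is.null(adc_bits)) as.integer(adc_bits)
          else NA_integer_

  metadata <- list(source = "biopatrec-mat")
  if (all(data == round(data))) {
    counts <- data
    metadata$stored_as <- "counts"
    if (is.na(bits)) {
      maxabs <- max(abs(range(counts)))
      bits <- max(2L, as.integer(ceiling(log2(maxabs + 1)) + 1L))
    }
  } else {
    if (is.na(bits)) bits <- 16L
    range_v <- if (!is.null(rec$adc_range)) as.numeric(rec$adc_range[1])
               else if (!is.null(adc_range_volts)) as.numeric(adc_range_volts)
               else 2 * max(abs(range(data)))
    lsb <- range_v / 2^bits
    counts <- round(data / lsb)
    # guard the signed range: the +full-scale sample maps to 2^(B-1),
    # one above the representable max
    counts <- pmin(counts, 2^(bits - 1) - 1)
    metadata$stored_as <- "volts"
    metadata$volts_per_count <- lsb
    metadata$adc_range_volts <- range_v
  }
  recording_session(
    signal = t(counts),
    sampling_rate_hz = as.numeric(rec$sF[1]),
    adc_bits = bits,
    movements = movements,
    n_repetitions = as.integer(rec$nR[1]),
    contraction_time_s = as.numeric(rec$cT[1]),
    relax_time_s = as.numeric(rec$rT[1]),
    metadata = metadata
  )
}
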