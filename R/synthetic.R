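#' Synthetic EMG session configuration
#'
#' Parameters of the synthetic surface-EMG generator. Each movement
#' repetition is modelled as amplitude-modulated band-limited Gaussian
#' noise: per channel,
#' `signal(t) = baseline(t) + envelope(t) * G[m, c] * colored_noise(t) + dc_offset[c]`
#' in volts, then quantized to `adc_bits` over `adc_range_volts`
#' (round-to-nearest LSB, signed counts). Blocks follow the guided
#' protocol: for each movement in order, `n_repetitions` contractions of
#' `contraction_time_s` seconds separated by `relax_time_s` seconds of
#' relaxation (baseline only).
#'
#' The envelope is a trapezoid preceded by an onset delay: zero for
#' `delay_frac` of the contraction (the request-to-movement reaction
#' delay), a linear ramp over `ramp_frac`, a plateau, and a symmetric
#' ramp down ending at the contraction end. With the defaults
#' (delay 0.10, ramps 0.15) the central 70% of the contraction still
#' contains ramp (dynamic) content while the central 40% is pure plateau,
#' matching the dynamic/static contrast that contraction-time-percentage
#' trimming is meant to probe.
#'
#' Default per-movement gains are a low-discrepancy pattern (fractional
#' parts of multiples of square-root-of-prime constants) scaled into
#' `[gain_min, gain_max]`, giving well-separated amplitude signatures
#' across channels; a movement named `"rest"` gets zero gain on all
#' channels. Per-channel DC offsets default to small nonzero values so
#' that offset-sensitive (`mabs`, `rms`, `zc`) and offset-invariant
#' (`card`, `wl`, `slpch`) features are genuinely distinguished.
#'
#' @param n_channels number of EMG channels.
#' @param movements character vector of class labels (may include
#'   `"rest"`).
#' @param gains optional movements x channels matrix of activation
#'   amplitudes in volts; defaults as described above.
#' @param dc_offset_volts per-channel DC offset (recycled); default
#'   `0.02 * channel index` volts.
#' @param noise_band_hz band of the colored noise (default 20--500 Hz,
#'   the usual surface-EMG bandwidth).
#' @param baseline_sd_volts baseline (rest) noise standard deviation.
#' @param ramp_frac envelope ramp fraction of the contraction.
#' @param delay_frac envelope onset-delay fraction of the contraction.
#' @param sampling_rate_hz sampling rate (default 2000).
#' @param adc_bits ADC bit depth (default 14, as in 4-channel
#'   individual-movement recordings).
#' @param adc_range_volts full-scale ADC range in volts (signed, so
#'   counts span +-`adc_range_volts / 2`; default 10, i.e. +-5 V of
#'   amplified EMG).
#' @param n_repetitions,contraction_time_s,relax_time_s guided-protocol
#'   schedule (defaults 3 repetitions, 3 s + 3 s).
#' @param seed mandatory RNG seed; generation is fully deterministic
#'   given the config.
#' @return an object of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_channels = 4L,
                             movements = c("open", "close", "flex", "extend",
                                           "pronate", "supinate", "side_grip",
                                           "fine_grip", "thumb_up", "point",
                                           "rest"),
                             gains = NULL,
                             dc_offset_volts = NULL,
                             noise_band_hz = c(20, 500),
                             baseline_sd_volts = 0.01,
                             ramp_frac = 0.15,
                             delay_frac = 0.10,
                             sampling_rate_hz = 2000,
                             adc_bits = 14L,
                             adc_range_volts = 10,
                             n_repetitions = 3L,
                             contraction_time_s = 3,
                             relax_time_s = 3,
                             seed) {
  if (missing(seed)) stop_param("a seed is mandatory for synthetic generation")
  movements <- as.character(movements)
  n_mov <- length(movements)
  if (is.null(gains)) gains <- default_gains(movements, n_channels)
  gains <- as.matrix(gains)
  if (!all(dim(gains) == c(n_mov, n_channels)))
    stop_param("gains must be a %d x %d matrix", n_mov, n_channels)
  if (any(gains < 0)) stop_param("gains must be non-negative")
  if (is.null(dc_offset_volts)) dc_offset_volts <- 0.02 * seq_len(n_channels)
  dc_offset_volts <- rep_len(dc_offset_volts, n_channels)
  cfg <- structure(
    list(n_channels = as.integer(n_channels), movements = movements,
         gains = gains, dc_offset_volts = dc_offset_volts,
         noise_band_hz = noise_band_hz,
         baseline_sd_volts = baseline_sd_volts,
         ramp_frac = ramp_frac, delay_frac = delay_frac,
         sampling_rate_hz = sampling_rate_hz,
         adc_bits = as.integer(adc_bits),
         adc_range_volts = adc_range_volts,
         n_repetitions = as.integer(n_repetitions),
         contraction_time_s = contraction_time_s,
         relax_time_s = relax_time_s, seed = as.integer(seed)),
    class = "SyntheticConfig")
  # 3-sigma excursion of the strongest class must fit the ADC range
  worst <- max(gains) * 3 + max(abs(dc_offset_volts)) + 3 * baseline_sd_volts
  if (worst >= adc_range_volts / 2)
    stop_param(paste0("ADC range %.2f V cannot accommodate worst-case ",
                      "amplitude ~%.2f V without clipping"),
               adc_range_volts, worst)
  cfg
}

# low-discrepancy gain patterns: fractional parts of m * sqrt(prime_c),
# scaled into [gain_min, gain_max]; "rest" rows are zero
default_gains <- function(movements, n_channels, gain_min = 0.12,
                          gain_max = 0.95) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)
  if (n_channels > length(primes))
    stop_param("default gains support at most %d channels", length(primes))
  g <- outer(seq_along(movements), sqrt(primes[seq_len(n_channels)]),
             function(m, s) (m * s) %% 1)
  g <- gain_min + (gain_max - gain_min) * g
  g[movements == "rest", ] <- 0
  rownames(g) <- movements
  g
}

# band-limited unit-variance Gaussian noise
colored_noise <- function(n, fs, band) {
  ny <- fs / 2
  w <- pmin(band / ny, 0.999)
  bf <- signal::butter(4, w, type = "pass")
  x <- signal::filtfilt(bf, rnorm(n + 2000))[-(1:2000)]  # discard edge transient
  x / stats::sd(x)
}

# trapezoidal envelope with onset delay, on [0, 1] normalized time
trapezoid_envelope <- function(n, delay_frac, ramp_frac) {
  t <- (seq_len(n) - 0.5) / n
  up0 <- delay_frac
  up1 <- delay_frac + ramp_frac
  dn0 <- 1 - ramp_frac
  env <- numeric(n)
  env[t >= up1 & t <= dn0] <- 1
  ramp_up <- t > up0 & t < up1
  env[ramp_up] <- (t[ramp_up] - up0) / ramp_frac
  ramp_dn <- t > dn0
  env[ramp_dn] <- pmax(0, (1 - t[ramp_dn]) / ramp_frac)
  env
}

#' Generate a synthetic recording session
#'
#' Produces a [recording_session()] from a [synthetic_config()]:
#' amplitude-modulated band-limited noise per movement block, plus
#' baseline noise and per-channel DC offsets, quantized to the configured
#' ADC depth (round to nearest LSB). Fully determined by the config's
#' seed. Raises a generation error, reporting the worst-case amplitude,
#' if any sample would clip the ADC range.
#'
#' @param config a `SyntheticConfig`.
#' @param subject_id optional id stored in session metadata.
#' @param clip if `TRUE`, out-of-range samples saturate at the ADC rails
#'   like a real converter; if `FALSE` (default) any clipped sample is a
#'   generation error reporting the worst-case amplitude.
#' @return a validated `RecordingSession`.
#' @export
generate_session <- function(config, subject_id = NULL, clip = FALSE) {
  stopifnot(inherits(config, "SyntheticConfig"))
  cfg <- config
  fs <- cfg$sampling_rate_hz
  n_contr <- round_half_up(cfg$contraction_time_s * fs)
  n_relax <- round_half_up(cfg$relax_time_s * fs)
  n_block <- n_contr + n_relax
  n_mov <- length(cfg$movements)
  n_total <- n_mov * cfg$n_repetitions * n_block
  env <- trapezoid_envelope(n_contr, cfg$delay_frac, cfg$ramp_frac)
  lsb <- cfg$adc_range_volts / 2^cfg$adc_bits
  rng <- adc_range_counts(cfg$adc_bits, signed = TRUE)

  volts <- withr::with_seed(cfg$seed, {
    v <- matrix(0, nrow = cfg$n_channels, ncol = n_total)
    for (c in seq_len(cfg$n_channels)) {
      base <- colored_noise(n_total, fs, cfg$noise_band_hz) *
        cfg$baseline_sd_volts
      v[c, ] <- base + cfg$dc_offset_volts[c]
    }
    pos <- 0L
    for (m in seq_len(n_mov)) {
      for (r in seq_len(cfg$n_repetitions)) {
        for (c in seq_len(cfg$n_channels)) {
          if (cfg$gains[m, c] > 0) {
            act <- colored_noise(n_contr, fs, cfg$noise_band_hz)
            idx <- pos + seq_len(n_contr)
            v[c, idx] <- v[c, idx] + env * cfg$gains[m, c] * act
          }
        }
        pos <- pos + n_block
      }
    }
    v
  })
  counts <- round_half_up(volts / lsb)
  if (min(counts) < rng[1] || max(counts) > rng[2]) {
    if (clip) {
      counts <- pmax(pmin(counts, rng[2]), rng[1])
    } else {
      stop_param(paste0("generated signal clips the %d-bit ADC range: ",
                        "worst-case amplitude %.3f V exceeds +-%.3f V"),
                 cfg$adc_bits, max(abs(volts)), cfg$adc_range_volts / 2)
    }
  }
  meta <- list(synthetic = TRUE, seed = cfg$seed)
  if (!is.null(subject_id)) meta$subject_id <- subject_id
  recording_session(
    signal = counts, sampling_rate_hz = fs, adc_bits = cfg$adc_bits,
    movements = cfg$movements, n_repetitions = cfg$n_repetitions,
    contraction_time_s = cfg$contraction_time_s,
    relax_time_s = cfg$relax_time_s, metadata = meta)
}

#' Generate a synthetic simultaneous-movement session
#'
#' Builds the class list from base movements plus combination classes
#' (e.g. the 27-class simultaneous-movement setup: 3 degrees of freedom,
#' 6 base movements, their feasible pairings and triples, and rest). A
#' combined class's gain vector is the elementwise sum of its components'
#' gains, capped so the combined amplitude keeps five-sigma headroom
#' inside the ADC range; singleton combinations reproduce the base
#' classes exactly.
#'
#' @param config a `SyntheticConfig` whose `movements` are the base
#'   movements.
#' @param combinations list of character vectors of base-movement labels;
#'   each becomes one class labelled by the components joined with `"+"`.
#' @param subject_id optional id stored in session metadata.
#' @return a validated `RecordingSession` whose movements are the
#'   combination labels.
#' @export
generate_simultaneous_session <- function(config, combinations,
                                          subject_id = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  base <- config$movements
  labels <- character(length(combinations))
  gains <- matrix(0, nrow = length(combinations), ncol = config$n_channels)
  for (i in seq_along(combinations)) {
    comp <- combinations[[i]]
    # "rest" is always a legal zero-gain component, listed in base or not
    unknown <- setdiff(comp, c(base, "rest"))
    if (length(unknown))
      stop_param("unknown component movement(s): %s",
                 paste(unknown, collapse = ", "))
    labels[i] <- paste(comp, collapse = "+")
    active <- comp[comp %in% base]
    if (length(active))
      gains[i, ] <- colSums(config$gains[match(active, base), , drop = FALSE])
  }
  gains <- pmin(gains, config$adc_range_volts / 10)
  cfg <- synthetic_config(
    n_channels = config$n_channels, movements = labels, gains = gains,
    dc_offset_volts = config$dc_offset_volts,
    noise_band_hz = config$noise_band_hz,
    baseline_sd_volts = config$baseline_sd_volts,
    ramp_frac = config$ramp_frac, delay_frac = config$delay_frac,
    sampling_rate_hz = config$sampling_rate_hz, adc_bits = config$adc_bits,
    adc_range_volts = config$adc_range_volts,
    n_repetitions = config$n_repetitions,
    contraction_time_s = config$contraction_time_s,
    relax_time_s = config$relax_time_s, seed = config$seed)
  generate_session(cfg, subject_id = subject_id)
}

#' Enumerate simultaneous-movement classes for paired degrees of freedom
#'
#' Given degrees of freedom as antagonist pairs (e.g. open/close,
#' flex/extend, pronate/supinate), enumerates every class obtainable by
#' activating each DoF in one direction or leaving it inactive, plus
#' rest: with 3 DoF that is `3^3 - 1` active combinations + rest = 27
#' classes.
#'
#' @param dof_pairs list of length-2 character vectors.
#' @param include_rest append a `"rest"` singleton class.
#' @return list of character vectors suitable for
#'   [generate_simultaneous_session()].
#' @export
enumerate_combinations <- function(dof_pairs, include_rest = TRUE) {
  options_per_dof <- lapply(dof_pairs, function(p) c(NA_character_, p))
  grid <- expand.grid(options_per_dof, stringsAsFactors = FALSE)
  combos <- apply(grid, 1L, function(row) row[!is.na(row)], simplify = FALSE)
  combos <- Filter(length, combos)
  if (include_rest) combos <- c(combos, list("rest"))
  combos
}

#' Generate a synthetic cohort of sessions
#'
#' Generates `n_sessions` sessions from a shared config, varying each
#' subject's gain matrix by a seeded multiplicative log-normal
#' perturbation (a synthetic stand-in for inter-subject variability,
#' which no single recording protocol pins down) and giving each session
#' its own derived seed.
#'
#' @param n_sessions number of sessions (subjects).
#' @param config base `SyntheticConfig`.
#' @param gain_jitter_sd standard deviation of the log-normal gain
#'   perturbation (default 0.1).
#' @return list of `RecordingSession`s with `subject_id`s `"S1"`, ...
#' @export
generate_cohort <- function(n_sessions, config, gain_jitter_sd = 0.1) {
  stopifnot(inherits(config, "SyntheticConfig"))
  lapply(seq_len(n_sessions), function(i) {
    cfg <- config
    cfg$seed <- as.integer((config$seed + 7919L * i) %% .Machine$integer.max)
    cfg$gains <- withr::with_seed(cfg$seed, {
      g <- config$gains * exp(matrix(
        rnorm(length(config$gains), 0, gain_jitter_sd),
        nrow = nrow(config$gains)))
      g[config$movements == "rest", ] <- 0
      pmin(g, config$adc_range_volts / 10)
    })
    generate_session(cfg, subject_id = paste0("S", i))
  })
}
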