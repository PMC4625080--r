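# internal helpers

# deterministic half-up rounding (round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

# signed/unsigned ADC count range for B bits
adc_range_counts <- function(bits, signed = TRUE) {
  if (signed) c(-2^(bits - 1), 2^(bits - 1) - 1) else c(0, 2^bits - 1)
}
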