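# shared fixtures: small synthetic configs and a bare FeatureMatrix builder

small_config <- function(seed = 1L, movements = c("open", "close", "flex",
                                                  "extend", "rest"),
                         n_channels = 4L, ...) {
  synthetic_config(n_channels = n_channels, movements = movements,
                   seed = seed, ...)
}

# a tiny session (short contractions) for fast structural tests
tiny_session <- function(seed = 1L, movements = c("a", "b", "c"),
                         contraction_time_s = 1, relax_time_s = 0.5,
                         sampling_rate_hz = 500, ...) {
  cfg <- synthetic_config(movements = movements, seed = seed,
                          contraction_time_s = contraction_time_s,
                          relax_time_s = relax_time_s,
                          sampling_rate_hz = sampling_rate_hz,
                          noise_band_hz = c(20, 200), ...)
  generate_session(cfg)
}

make_fm <- function(values, labels, feature_names = "f") {
  if (is.null(colnames(values)))
    colnames(values) <- paste0(feature_names[1], "_ch", seq_len(ncol(values)))
  structure(list(values = values, labels = labels,
                 feature_names = feature_names),
            class = "FeatureMatrix")
}

# separable gaussian blobs as a FeatureMatrix
blob_fm <- function(n_per_class, centers, sd = 0.3, seed = 1L) {
  if (is.null(rownames(centers)))
    rownames(centers) <- paste0("k", seq_len(nrow(centers)))
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(centers)), function(k) {
      matrix(rnorm(n_per_class * ncol(centers), mean = rep(centers[k, ],
                                                           each = n_per_class),
                   sd = sd), nrow = n_per_class)
    })
  })
  values <- do.call(rbind, rows)
  colnames(values) <- paste0("f_ch", seq_len(ncol(values)))
  make_fm(values, rep(rownames(centers), each = n_per_class))
}
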