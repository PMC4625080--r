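test_that("cardinality counts distinct values", {
  expect_equal(feat_card(c(1, 1, 2, 3, 3)), 3)   # worked multiset example
  expect_equal(feat_card(c(1, 2, 3)), 3)
  expect_equal(feat_card(rep(7L, 1000)), 1)
  expect_error(feat_card(numeric(0)), "empty")
  # brute-force nested distinct-count oracle on a random 12-bit window
  withr::with_seed(21, {
    for (i in 1:10) {
      x <- sample(-2048:2047, 400, replace = TRUE)
      brute <- sum(vapply(seq_along(x), function(j)
        !any(x[seq_len(j - 1L)] == x[j]), logical(1)))
      expect_equal(feat_card(x), brute)
    }
  })
})

test_that("cardinality is offset- and permutation-invariant within bounds", {
  withr::with_seed(22, {
    for (i in 1:25) {
      B <- sample(4:14, 1)
      n <- sample(50:400, 1)
      x <- sample(0:(2^B - 1), n, replace = TRUE)
      k <- feat_card(x)
      expect_gte(k, 1)
      expect_lte(k, min(n, 2^B))
      expect_equal(feat_card(x + sample(-500:500, 1)), k)  # DC offset
      expect_equal(feat_card(sample(x)), k)                # permutation
    }
  })
})

test_that("continuous jitter alienates cardinality to the window length", {
  withr::with_seed(23, {
    for (n in c(50, 400)) {
      x <- sample(-100:100, n, replace = TRUE)
      expect_equal(feat_card(x + runif(n)), n)
    }
  })
})

test_that("time-domain features match hand-evaluated values", {
  x <- c(1, -2, 3, -4)
  expect_equal(feat_timedomain(x, "mabs"), 2.5)
  expect_equal(feat_timedomain(x, "wl"), 15)
  expect_equal(feat_timedomain(x, "dam"), 5)
  expect_equal(feat_timedomain(x, "zc"), 3)
  expect_equal(feat_timedomain(x, "slpch"), 2)
  expect_equal(feat_timedomain(x, "rms"), sqrt(7.5))
  expect_equal(feat_timedomain(x, "var"), 29 / 3)
  expect_equal(feat_timedomain(x, "mfl"), log10(sqrt(83)))
  expect_error(feat_timedomain(x, "nope"), "unknown")
  expect_error(feat_timedomain(1, "wl"), "at least 2")
})

test_that("time-domain features agree with independent scalar oracles", {
  withr::with_seed(24, {
    for (i in 1:10) {
      x <- rnorm(200, sd = 50)
      d <- x[-1] - x[-length(x)]
      expect_equal(feat_timedomain(x, "mabs"), sum(abs(x)) / length(x))
      expect_equal(feat_timedomain(x, "wl"), sum(abs(d)))
      expect_equal(feat_timedomain(x, "dam"), sum(abs(d)) / (length(x) - 1))
      expect_equal(feat_timedomain(x, "rms"), sqrt(sum(x^2) / length(x)))
      expect_equal(feat_timedomain(x, "var"), stats::var(x))
      # zc oracle: continuous draws have no zeros or ties
      expect_equal(feat_timedomain(x, "zc"),
                   sum(x[-1] * x[-length(x)] < 0))
      expect_equal(feat_timedomain(x, "slpch"),
                   sum(d[-1] * d[-length(d)] < 0))
    }
  })
})

test_that("constant windows give the zero-case values", {
  x <- rep(5, 100)
  expect_equal(feat_timedomain(x, "wl"), 0)
  expect_equal(feat_timedomain(x, "zc"), 0)
  expect_equal(feat_timedomain(x, "slpch"), 0)
  expect_equal(feat_timedomain(x, "dam"), 0)
  expect_equal(feat_timedomain(x, "var"), 0)
  expect_equal(feat_complexity(x, "sampen"), 0)
  expect_equal(feat_complexity(x, "fd"), 1)
})

test_that("waveform length equals (N-1) times the mean absolute difference", {
  withr::with_seed(25, {
    for (i in 1:20) {
      n <- sample(2:500, 1)
      x <- sample(-2000:2000, n, replace = TRUE)
      expect_equal(feat_timedomain(x, "wl"),
                   (n - 1) * feat_timedomain(x, "dam"))
    }
  })
})

test_that("zc and slpch honour the threshold deadband and zero tie-break", {
  x <- c(1, 0, -1, 0, 1)       # zeros inherit the previous sign
  expect_equal(feat_timedomain(x, "zc"), 2)
  expect_equal(feat_timedomain(c(1, -1, 1), "zc", threshold = 3), 0)
  expect_equal(feat_timedomain(c(5, -5, 5), "zc", threshold = 3), 2)
  expect_equal(feat_timedomain(c(0, 2, -2, 2), "slpch", threshold = 3), 1)
})

test_that("Higuchi dimension is ~1 for a line and sampen matches its oracle", {
  expect_equal(feat_complexity(seq_len(200), "fd"), 1, tolerance = 0.05)
  # literal-transcription sample-entropy oracle, O(N^2) loops
  sampen_oracle <- function(x, m = 2, r = 0.2 * sd(x)) {
    n <- length(x); A <- 0; B <- 0
    for (i in 1:(n - m)) {
      for (j in 1:(n - m)) {
        if (i == j) next
        if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
          B <- B + 1
          if (abs(x[i + m] - x[j + m]) <= r &&
              max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1
        }
      }
    }
    -log((A / 2) / (B / 2))
  }
  withr::with_seed(26, {
    for (i in 1:3) {
      x <- round(rnorm(120, sd = 30))
      expect_equal(feat_complexity(x, "sampen"), sampen_oracle(x),
                   tolerance = 1e-9)
    }
  })
  expect_error(feat_complexity(1:10, "sampen"), "at least")
  expect_error(feat_complexity(1:5, "fd"), "at least")
})

test_that("sampen caps the no-match case at a finite documented value", {
  # (0, 0) templates match at length 2 but their extensions are spaced
  # far beyond the tolerance, so A = 0 and the entropy would be infinite
  x <- as.vector(rbind(0, 0, (1:7) * 1000))
  v <- feat_complexity(x, "sampen")
  expect_true(is.finite(v))
  expect_gt(v, log(10))  # capped high, not silently small
})

test_that("extraction produces the documented shape and column order", {
  s <- tiny_session(seed = 30)
  w <- segment_session(s, window_spec(0.2, 0.05, 0.7))
  fm1 <- extract_features(w, "card")
  expect_equal(dim(fm1$values), c(length(w), 4))
  expect_identical(colnames(fm1$values), paste0("card_ch", 1:4))
  fmh <- extract_features(w, "hudgins")
  expect_equal(ncol(fmh$values), 16)
  expect_identical(colnames(fmh$values)[1:4], paste0("mabs_ch", 1:4))
  expect_identical(fmh$labels, vapply(w, `[[`, character(1), "movement"))
  expect_true(all(is.finite(fmh$values)))
})

test_that("substituting one Hudgins feature by card changes only its columns", {
  s <- tiny_session(seed = 31)
  w <- segment_session(s)
  all_fm <- extract_features(w, c("mabs", "wl", "slpch", "zc", "card"))
  h <- emgcard:::subset_features(all_fm, feature_set("hudgins"))
  sub <- emgcard:::subset_features(all_fm, feature_set("hudgins-wl+card"))
  expect_equal(ncol(sub$values), ncol(h$values))
  same <- !grepl("^(wl|card)_", colnames(h$values))
  expect_identical(h$values[, same], sub$values[, same])
  expect_false(any(grepl("^wl_", colnames(sub$values))))
  plus <- emgcard:::subset_features(all_fm, feature_set("hudgins+card"))
  expect_equal(ncol(plus$values), ncol(h$values) + 4)
})

test_that("features are deterministic and rough entropy is refused", {
  withr::with_seed(32, x <- sample(-500:500, 300, replace = TRUE))
  bank <- feature_bank()
  for (f in names(bank)) expect_identical(bank[[f]](x), bank[[f]](x))
  expect_error(feature_bank("ren"), "not implemented")
  expect_error(feature_set("ren"), "not implemented")
})

test_that("mean window cardinality rises with envelope gain (monotonicity)", {
  # same noise seed, increasing gain: expected card non-decreasing
  gains <- c(0.05, 0.2, 0.5, 0.9)
  meds <- vapply(gains, function(g) {
    cfg <- synthetic_config(n_channels = 1L, movements = "m",
                            gains = matrix(g, 1, 1), dc_offset_volts = 0,
                            contraction_time_s = 1, relax_time_s = 0.5,
                            sampling_rate_hz = 500,
                            noise_band_hz = c(20, 200), seed = 99)
    s <- generate_session(cfg)
    w <- segment_session(s, window_spec(0.2, 0.05, 0.7))
    mean(extract_features(w, "card")$values)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("feature matrices serialize to CSV with a trailing label column", {
  s <- tiny_session(seed = 33)
  fm <- extract_features(segment_session(s), "hudgins")
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, f)
  df <- data.table::fread(f)
  expect_identical(names(df), c(colnames(fm$values), "label"))
  expect_equal(as.matrix(df[, setdiff(names(df), "label"), with = FALSE]),
               fm$values, ignore_attr = TRUE)
  expect_identical(df$label, fm$labels)
})
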