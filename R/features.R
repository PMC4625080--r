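#' Cardinality of an analysis window
#'
#' The cardinality feature: the number of distinct sample values in a
#' window of quantized signal. For integer ADC counts it satisfies
#' `1 <= card <= min(N, 2^B)` where N is the window length and B the ADC
#' bit depth, and it is invariant under any constant offset (so DC offsets
#' from electrode-impedance mismatch do not affect it) and under any
#' permutation of the samples.
#'
#' Calling it on continuous-valued input is legal but degenerate: with
#' i.i.d. continuous noise every sample is almost surely unique, so the
#' count saturates at N and carries no amplitude information. Features
#' should therefore be computed on the originally sampled integer counts,
#' never on values rescaled to volts or doubles.
#'
#' @param x non-empty numeric sequence (normally integer counts).
#' @return integer count of distinct values.
#' @export
#' @examples
#' feat_card(c(1, 1, 2, 3, 3))  # 3
feat_card <- function(x) {
  if (length(x) == 0L) stop_param("cardinality of an empty window is undefined")
  if (anyNA(x)) stop_param("window contains NA samples")
  length(unique(as.vector(x)))
}

#' Time-domain EMG features
#'
#' Scalar time-domain features of a single-channel window `x` of length N
#' (differences `d[i] = x[i+1] - x[i]`):
#'
#' * `mabs` -- mean absolute value, `mean(|x|)`
#' * `wl` -- waveform length, `sum(|d|)`
#' * `dam` -- difference absolute mean value, `mean(|d|)`; `wl = (N-1) * dam`
#' * `rms` -- root mean square, `sqrt(mean(x^2))`
#' * `var` -- sample variance (denominator N - 1)
#' * `zc` -- zero crossings: sign changes between consecutive samples
#'   whose step exceeds `threshold`; zero samples inherit the previous
#'   nonzero sign (deterministic tie-break)
#' * `slpch` -- slope-sign changes: sign changes between consecutive
#'   differences with both `|d| > threshold`
#' * `mfl` -- maximum fractal length, `log10(sqrt(sum(d^2)))` (log-scaled
#'   Euclidean length of the first-difference curve)
#'
#' `mabs`, `rms`, `var` and `zc` depend on the signal's DC level; `wl`,
#' `dam`, `slpch` and `mfl` are offset-invariant.
#'
#' @param x numeric window (length >= 2 for difference-based features).
#' @param name one of `"mabs"`, `"wl"`, `"zc"`, `"slpch"`, `"rms"`,
#'   `"var"`, `"dam"`, `"mfl"`.
#' @param threshold deadband for `zc` and `slpch` (default 0).
#' @return scalar feature value.
#' @export
feat_timedomain <- function(x, name, threshold = 0) {
  x <- as.numeric(x)
  n <- length(x)
  diff_based <- c("wl", "dam", "slpch", "mfl")
  if (name %in% diff_based && n < 2L)
    stop_param("feature %s needs at least 2 samples", name)
  if (n < 1L) stop_param("empty window")
  switch(name,
    mabs = mean(abs(x)),
    wl = sum(abs(diff(x))),
    dam = mean(abs(diff(x))),
    rms = sqrt(mean(x^2)),
    var = if (n < 2L) 0 else stats::var(x),
    zc = {
      s <- sign(x)
      # zeros inherit the previous nonzero sign
      for (i in seq_len(n)) if (s[i] == 0) s[i] <- if (i > 1L) s[i - 1L] else 0
      chg <- s[-1L] != s[-n] & s[-1L] != 0 & s[-n] != 0
      sum(chg & abs(diff(x)) > threshold)
    },
    slpch = {
      d <- diff(x)
      dd <- sign(d)
      both_big <- abs(d[-1L]) > threshold & abs(d[-length(d)]) > threshold
      sum(dd[-1L] * dd[-length(d)] < 0 & both_big)
    },
    mfl = {
      # constant window: zero curve length; return the integer-signal
      # floor log10(1) = 0 rather than -Inf so downstream stays finite
      s <- sum(diff(x)^2)
      if (s == 0) 0 else log10(sqrt(s))
    },
    stop_param("unknown time-domain feature '%s'", name)
  )
}

#' Complexity EMG features
#'
#' * `fd` -- Higuchi fractal dimension with curve scales `k = 1..kmax`
#'   (default `kmax = 8`): the negative slope of `log(L(k))` against
#'   `log(k)`, where `L(k)` is the mean normalized curve length over the
#'   k interleaved subsampled curves. A straight line has dimension 1.
#' * `sampen` -- sample entropy `-ln(A/B)` with embedding dimension `m`
#'   (default 2) and Chebyshev tolerance `r = r_coef * sd(x)` (default
#'   `r_coef = 0.2`), self-matches excluded.
#'
#' Degenerate inputs follow fixed conventions: a constant window returns
#' `sampen = 0` and `fd = 1`. When no template pairs match at length
#' `m + 1` (A = 0) or length `m` (B = 0) on non-constant input, the
#' infinite entropy is capped at `log(max(B, 1)) + log(N)` so downstream
#' classifiers never see non-finite values.
#'
#' @param x numeric window.
#' @param name `"fd"` or `"sampen"`.
#' @param kmax largest curve scale for `fd` (needs `N >= 2 * kmax`).
#' @param m embedding dimension for `sampen` (needs `N >= 10 * m`).
#' @param r_coef tolerance coefficient for `sampen`.
#' @return scalar feature value, always finite.
#' @export
feat_complexity <- function(x, name, kmax = 8L, m = 2L, r_coef = 0.2) {
  x <- as.numeric(x)
  n <- length(x)
  if (name == "fd") {
    if (n < 2L * kmax)
      stop_param("fd with kmax=%d needs at least %d samples", kmax, 2L * kmax)
    if (max(x) == min(x)) return(1)
    lk <- numeric(kmax)
    for (k in seq_len(kmax)) {
      lm <- numeric(k)
      for (m0 in seq_len(k)) {
        idx <- seq(m0, n, by = k)
        ni <- length(idx)
        # normalized length of the m0-th interleaved curve at scale k
        lm[m0] <- sum(abs(diff(x[idx]))) * (n - 1) / ((ni - 1) * k) / k
      }
      lk[k] <- mean(lm)
    }
    keep <- lk > 0
    if (sum(keep) < 2L) return(1)
    -unname(stats::coef(stats::lm(log(lk[keep]) ~ log(seq_len(kmax)[keep])))[2])
  } else if (name == "sampen") {
    if (n < 10L * m)
      stop_param("sampen with m=%d needs at least %d samples", m, 10L * m)
    if (max(x) == min(x)) return(0)
    r <- r_coef * stats::sd(x)
    counts <- sampen_counts(x, m, r)
    B <- as.numeric(counts[1]); A <- as.numeric(counts[2])
    if (A == 0 || B == 0) return(log(max(B, 1)) + log(n))
    -log(A / B)
  } else {
    stop_param("unknown complexity feature '%s'", name)
  }
}

# template match counts for sample entropy: B at length m, A at m + 1,
# self-matches excluded. Vectorized over template pairs via a running
# Chebyshev distance.
sampen_counts <- function(x, m, r) {
  n <- length(x)
  np <- n - m            # templates of length m that extend to m + 1
  # pairwise |x_i - x_j| for template starts 1..np
  d <- abs(outer(x[seq_len(np)], x[seq_len(np)], "-"))
  cheb <- d
  for (k in seq_len(m - 1L)) {
    dk <- abs(outer(x[seq_len(np) + k], x[seq_len(np) + k], "-"))
    cheb <- pmax(cheb, dk)
  }
  B <- (sum(cheb <= r) - np) / 2          # exclude self, unordered pairs
  dm <- abs(outer(x[seq_len(np) + m], x[seq_len(np) + m], "-"))
  chebA <- pmax(cheb, dm)
  A <- (sum(chebA <= r) - np) / 2
  c(B = B, A = A)
}

#' The feature bank
#'
#' Registry mapping feature names to per-channel window functions. The
#' registered features are `card`, `mabs`, `wl`, `zc`, `slpch`, `rms`,
#' `var`, `dam`, `mfl`, `fd` and `sampen`; every function is
#' deterministic and applied to each channel independently. `ren` (rough
#' entropy) is deliberately not implemented (see README) and requesting
#' it raises an informative error.
#'
#' @param names optional subset of feature names to return.
#' @return named list of functions `f(x) -> scalar`.
#' @export
feature_bank <- function(names = NULL) {
  bank <- list(
    card = function(x) feat_card(x),
    mabs = function(x) feat_timedomain(x, "mabs"),
    wl = function(x) feat_timedomain(x, "wl"),
    zc = function(x) feat_timedomain(x, "zc"),
    slpch = function(x) feat_timedomain(x, "slpch"),
    rms = function(x) feat_timedomain(x, "rms"),
    var = function(x) feat_timedomain(x, "var"),
    dam = function(x) feat_timedomain(x, "dam"),
    mfl = function(x) feat_timedomain(x, "mfl"),
    fd = function(x) feat_complexity(x, "fd"),
    sampen = function(x) feat_complexity(x, "sampen")
  )
  if (is.null(names)) return(bank)
  unknown <- setdiff(names, names(bank))
  if ("ren" %in% unknown)
    stop_param(paste0("feature 'ren' (rough entropy) is not implemented; ",
                      "see README for why"))
  if (length(unknown))
    stop_param("unknown feature(s): %s", paste(unknown, collapse = ", "))
  bank[names]
}

#' Named feature sets
#'
#' `feature_set("hudgins")` returns the classic Hudgins time-domain
#' quartet `c("mabs", "wl", "slpch", "zc")`. Substitution sets replace
#' one Hudgins feature by cardinality (`"hudgins-mabs+card"` etc.), and
#' `"hudgins+card"` appends cardinality as a fifth feature. Any
#' registered feature name is also accepted as a singleton set.
#'
#' @param name set name or a single feature name.
#' @return character vector of feature names.
#' @export
feature_set <- function(name) {
  hudgins <- c("mabs", "wl", "slpch", "zc")
  if (name == "hudgins") return(hudgins)
  if (name == "hudgins+card") return(c(hudgins, "card"))
  m <- regmatches(name, regexec("^hudgins-([a-z]+)\\+card$", name))[[1]]
  if (length(m) == 2L) {
    if (!m[2] %in% hudgins)
      stop_param("'%s' is not a Hudgins feature", m[2])
    out <- hudgins
    out[out == m[2]] <- "card"
    return(out)
  }
  feature_bank(name)  # errors on unknown names
  name
}

#' Extract a feature matrix from labeled windows
#'
#' Applies each requested feature to each channel of each window,
#' producing a `FeatureMatrix`: a windows x (features x channels) real
#' matrix with columns ordered feature-major then channel
#' (`card_ch1 ... card_chC, mabs_ch1 ...`), plus the movement label of
#' each window. All windows must share channel count and length.
#'
#' @param windows list of labeled windows from [segment_session()].
#' @param feature_names character vector of registered feature names (or
#'   a set name understood by [feature_set()]).
#' @return an object of class `FeatureMatrix`: list with `values`
#'   (numeric matrix with column names), `labels` (character vector) and
#'   `feature_names`.
#' @export
extract_features <- function(windows, feature_names) {
  if (length(windows) == 0L) stop_param("no windows to extract features from")
  if (length(feature_names) == 1L) feature_names <- feature_set(feature_names)
  funs <- feature_bank(feature_names)
  shapes <- vapply(windows, function(w) dim(w$samples), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop_param("windows have inconsistent shapes")
  n_ch <- shapes[1, 1]
  ch_names <- rownames(windows[[1]]$samples)
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(n_ch))
  cols <- as.vector(t(outer(feature_names, ch_names, paste, sep = "_")))
  values <- matrix(NA_real_, nrow = length(windows), ncol = length(cols),
                   dimnames = list(NULL, cols))
  for (i in seq_along(windows)) {
    w <- windows[[i]]$samples
    j <- 0L
    for (f in feature_names) {
      fn <- funs[[f]]
      for (c in seq_len(n_ch)) {
        j <- j + 1L
        values[i, j] <- fn(w[c, ])
      }
    }
  }
  if (any(!is.finite(values)))
    stop_param("feature extraction produced non-finite values")
  structure(
    list(values = values,
         labels = vapply(windows, `[[`, character(1), "movement"),
         repetitions = vapply(windows, `[[`, integer(1), "repetition"),
         feature_names = feature_names),
    class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix: %d windows x %d columns (%s), %d classes\n",
              nrow(x$values), ncol(x$values),
              paste(x$feature_names, collapse = ", "),
              length(unique(x$labels))))
  invisible(x)
}

# column subset of a FeatureMatrix by feature names (reuses an already
# extracted superset, e.g. hudgins+card, for set-substitution designs)
subset_features <- function(fm, feature_names) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  missing <- setdiff(feature_names, fm$feature_names)
  if (length(missing))
    stop_param("features not present in matrix: %s",
               paste(missing, collapse = ", "))
  keep <- unlist(lapply(feature_names, function(f)
    grep(paste0("^", f, "_"), colnames(fm$values))))
  structure(list(values = fm$values[, keep, drop = FALSE],
                 labels = fm$labels, repetitions = fm$repetitions,
                 feature_names = feature_names),
            class = "FeatureMatrix")
}

#' Write a feature matrix to CSV
#'
#' One row per window: the feature columns followed by a trailing
#' `label` column.
#'
#' @param fm a `FeatureMatrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  df <- data.frame(fm$values, check.names = FALSE)
  df$label <- fm$labels
  data.table::fwrite(df, path)
  invisible(path)
}

#' Jitter windows to continuous precision
#'
#' Adds i.i.d. continuous uniform jitter to every sample of every window,
#' emulating a processing chain that rescales raw counts to
#' double-precision volts. This alienates the discrimination power of
#' cardinality: with continuous values every sample is almost surely
#' unique, so `card = N` for all windows and the feature becomes
#' constant. Used by the precision-alienation robustness experiment.
#'
#' @param windows list of labeled windows.
#' @param seed RNG seed.
#' @param amount half-width of the uniform jitter in counts.
#' @return windows with real-valued samples.
#' @export
jitter_windows <- function(windows, seed = 1L, amount = 0.5) {
  withr::with_seed(seed, {
    lapply(windows, function(w) {
      w$samples <- w$samples +
        matrix(runif(length(w$samples), -amount, amount),
               nrow = nrow(w$samples))
      w
    })
  })
}
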