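# shared engine: one (session, feature set, classifier) evaluation,
# reusing a pre-extracted superset feature matrix per session

evaluate_feature_set <- function(fm_super, set_name, classifier_config,
                                 n_reps, base_seed, subject_id) {
  fm <- subset_features(fm_super, feature_set_names(set_name))
  cross_validate(fm, classifier_config, n_reps = n_reps,
                 base_seed = base_seed, feature_set_name = set_name,
                 subject_id = subject_id)
}

# resolve a set name to feature names (single feature names pass through)
feature_set_names <- function(name) feature_set(name)

session_subject <- function(session, i) {
  s <- session$metadata$subject_id
  if (is.null(s)) paste0("S", i) else s
}

summarize_cv <- function(cv_list, extra = NULL) {
  rows <- lapply(cv_list, function(cv) {
    data.frame(subject = cv$subject_id, classifier = cv$classifier_name,
               feature_set = cv$feature_set_name,
               global_accuracy = cv$global_accuracy,
               micro_accuracy = cv$micro_accuracy,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(extra)) out <- cbind(out, extra, row.names = NULL)
  out
}

# Wilcoxon comparison of a reference set against each other set,
# paired by movement on across-subject mean accuracies
compare_sets <- function(cv_list, reference) {
  df <- data.frame(set = vapply(cv_list, `[[`, character(1), "feature_set_name"),
                   clf = vapply(cv_list, `[[`, character(1), "classifier_name"),
                   stringsAsFactors = FALSE)
  out <- list()
  for (clf in unique(df$clf)) {
    sets <- unique(df$set[df$clf == clf])
    if (!reference %in% sets) next
    agg_of <- function(s) aggregate_subjects(
      cv_list[df$set == s & df$clf == clf])$per_movement_mean
    ref_vec <- agg_of(reference)
    for (s in setdiff(sets, reference)) {
      other <- agg_of(s)
      cmp <- tryCatch(wilcoxon_signed_rank(ref_vec, other[names(ref_vec)]),
                      error = function(e) NULL)
      out[[length(out) + 1L]] <- data.frame(
        classifier = clf, reference = reference, other = s,
        mean_reference = mean(ref_vec), mean_other = mean(other),
        W = if (is.null(cmp)) NA_real_ else cmp$statistic,
        p_value = if (is.null(cmp)) NA_real_ else cmp$p_value,
        n_pairs = if (is.null(cmp)) NA_integer_ else cmp$n_pairs,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

experiment_result <- function(cv_list, summary, comparisons = NULL) {
  structure(list(
    results = do.call(rbind, lapply(cv_list, as.data.frame)),
    summary = summary,
    comparisons = comparisons,
    cv = cv_list), class = "ExperimentResult")
}

#' @export
print.ExperimentResult <- function(x, ...) {
  cat("ExperimentResult\n")
  print(x$summary)
  if (!is.null(x$comparisons)) {
    cat("\nWilcoxon comparisons (paired per movement):\n")
    print(x$comparisons)
  }
  invisible(x)
}

#' Single-feature comparison experiment
#'
#' Evaluates each feature on its own, per session and classifier, with
#' full repeated cross-validation, then compares cardinality against
#' every other feature with Wilcoxon signed-rank tests paired per
#' movement (on across-subject per-movement mean accuracies). With a
#' single feature requested, no comparisons are made.
#'
#' @param sessions list of `RecordingSession`s (one per subject).
#' @param features character vector of single-feature names (default:
#'   cardinality plus the Hudgins features).
#' @param classifiers character subset of `c("lda", "mlp")`.
#' @param spec a [window_spec()].
#' @param n_reps cross-validation repetitions per subject.
#' @param base_seed base RNG seed.
#' @return `ExperimentResult`: tidy per-repetition `results`, per
#'   (session, feature, classifier) `summary`, and `comparisons`.
#' @export
run_single_feature_comparison <- function(sessions,
                                          features = c("card", "mabs", "wl",
                                                       "slpch", "zc"),
                                          classifiers = c("lda", "mlp"),
                                          spec = window_spec(),
                                          n_reps = 10L, base_seed = 100L) {
  cv_list <- list()
  for (i in seq_along(sessions)) {
    windows <- segment_session(sessions[[i]], spec)
    fm_super <- extract_features(windows, features)
    sid <- session_subject(sessions[[i]], i)
    for (clf in classifiers) {
      for (f in features) {
        cv_list[[length(cv_list) + 1L]] <- evaluate_feature_set(
          fm_super, f, list(type = clf), n_reps,
          base_seed + 1000L * i, sid)
      }
    }
  }
  comparisons <- if ("card" %in% features && length(features) > 1L)
    compare_sets(cv_list, "card") else NULL
  experiment_result(cv_list, summarize_cv(cv_list), comparisons)
}

#' Hudgins-set substitution experiment
#'
#' Evaluates the Hudgins set, the four sets obtained by substituting one
#' Hudgins feature with cardinality, and the five-feature set with
#' cardinality added -- six feature-set rows per classifier per session
#' -- and compares every modified set against the original Hudgins set.
#'
#' @inheritParams run_single_feature_comparison
#' @return `ExperimentResult`.
#' @export
run_set_substitution <- function(sessions, classifiers = c("lda", "mlp"),
                                 spec = window_spec(), n_reps = 10L,
                                 base_seed = 100L) {
  sets <- c("hudgins", "hudgins-mabs+card", "hudgins-wl+card",
            "hudgins-slpch+card", "hudgins-zc+card", "hudgins+card")
  cv_list <- list()
  for (i in seq_along(sessions)) {
    windows <- segment_session(sessions[[i]], spec)
    fm_super <- extract_features(windows, c("mabs", "wl", "slpch", "zc",
                                            "card"))
    sid <- session_subject(sessions[[i]], i)
    for (clf in classifiers) {
      for (s in sets) {
        cv_list[[length(cv_list) + 1L]] <- evaluate_feature_set(
          fm_super, s, list(type = clf), n_reps,
          base_seed + 1000L * i, sid)
      }
    }
  }
  experiment_result(cv_list, summarize_cv(cv_list),
                    compare_sets(cv_list, "hudgins"))
}

#' Robustness sweep over an acquisition axis
#'
#' Re-runs the evaluation while sweeping one acquisition condition and
#' holding everything else fixed:
#'
#' * `axis = "sampling_rate"` -- sessions are decimated to each target
#'   rate (default 2000/1000/500 Hz); window sample counts follow the
#'   new rate.
#' * `axis = "window_s"` -- the window length is varied (default
#'   100--300 ms).
#' * `axis = "adc_bits"` -- counts are requantized to each bit depth
#'   before feature extraction; requesting more bits than the source
#'   session's depth is a parameter error.
#' * `axis = "jitter"` -- values are logical; `TRUE` adds continuous
#'   jitter to the windows ([jitter_windows()]), the precision-
#'   alienation condition under which cardinality saturates at the
#'   window length.
#'
#' @param sessions list of `RecordingSession`s.
#' @param axis sweep axis (see above).
#' @param values axis values; defaults per axis.
#' @param feature_sets feature sets/single features to evaluate.
#' @param classifiers character subset of `c("lda", "mlp")`.
#' @param spec base [window_spec()].
#' @param n_reps,base_seed as in [run_single_feature_comparison()].
#' @param antialias low-pass filter before decimation (sampling sweep).
#' @return `ExperimentResult` whose `summary` carries an `axis_value`
#'   column; exactly one row per (axis value, feature set, classifier,
#'   session).
#' @export
run_sweep <- function(sessions,
                      axis = c("sampling_rate", "window_s", "adc_bits",
                               "jitter"),
                      values = NULL,
                      feature_sets = c("card", "mabs", "wl"),
                      classifiers = "lda",
                      spec = window_spec(), n_reps = 10L, base_seed = 100L,
                      antialias = FALSE) {
  axis <- match.arg(axis)
  if (is.null(values))
    values <- switch(axis,
      sampling_rate = c(2000, 1000, 500),
      window_s = c(0.100, 0.150, 0.200, 0.250, 0.300),
      adc_bits = c(16, 14, 12, 10, 8),
      jitter = c(FALSE, TRUE))
  if (axis == "adc_bits") {
    src_bits <- vapply(sessions, `[[`, integer(1), "adc_bits")
    if (any(values > min(src_bits)))
      stop_param("requested adc_bits above source depth (%d bits)",
                 min(src_bits))
  }
  cv_list <- list()
  extras <- list()
  for (i in seq_along(sessions)) {
    sid <- session_subject(sessions[[i]], i)
    for (v in values) {
      sess <- sessions[[i]]
      spec_v <- spec
      if (axis == "sampling_rate") {
        factor <- sess$sampling_rate_hz / v
        if (abs(factor - round(factor)) > 1e-9)
          stop_param("sampling rate %g is not an integer divisor of %g",
                     v, sess$sampling_rate_hz)
        sess <- decimate_session(sess, as.integer(round(factor)), antialias)
      } else if (axis == "adc_bits") {
        sess <- requantize_session(sess, v)
      } else if (axis == "window_s") {
        spec_v <- window_spec(v, min(spec$increment_s, v), spec$ctp)
      }
      windows <- segment_session(sess, spec_v)
      if (axis == "jitter" && isTRUE(v))
        windows <- jitter_windows(windows, seed = base_seed + i)
      feats <- unique(unlist(lapply(feature_sets, feature_set_names)))
      fm_super <- extract_features(windows, feats)
      for (clf in classifiers) {
        for (s in feature_sets) {
          cv_list[[length(cv_list) + 1L]] <- evaluate_feature_set(
            fm_super, s, list(type = clf), n_reps,
            base_seed + 1000L * i, sid)
          extras[[length(extras) + 1L]] <-
            data.frame(axis = axis, axis_value = v)
        }
      }
    }
  }
  summary <- summarize_cv(cv_list, do.call(rbind, extras))
  res <- experiment_result(cv_list, summary)
  res$results <- cbind(res$results,
                       do.call(rbind, lapply(seq_along(cv_list), function(j)
                         extras[[j]][rep(1L, nrow(as.data.frame(cv_list[[j]]))), ,
                                     drop = FALSE])),
                       row.names = NULL)
  res
}

#' Static-versus-dynamic contraction experiment
#'
#' Runs the requested feature sets at both contraction-time percentages
#' -- cTp = 0.7 (dynamic onset included) and cTp = 0.4 (static plateau
#' only) -- and tabulates per-condition accuracies plus the
#' static-minus-dynamic delta for every (feature set, classifier,
#' session).
#'
#' @inheritParams run_sweep
#' @param ctps the two contraction-time percentages to contrast.
#' @return `ExperimentResult`; `summary` has a `ctp` column and the
#'   result carries a `deltas` data.frame.
#' @export
run_static_vs_dynamic <- function(sessions,
                                  feature_sets = c("card", "wl", "hudgins"),
                                  classifiers = c("lda", "mlp"),
                                  spec = window_spec(),
                                  ctps = c(0.7, 0.4),
                                  n_reps = 10L, base_seed = 100L) {
  cv_list <- list(); extras <- list()
  for (i in seq_along(sessions)) {
    sid <- session_subject(sessions[[i]], i)
    for (ctp in ctps) {
      spec_c <- window_spec(spec$window_s, spec$increment_s, ctp)
      windows <- segment_session(sessions[[i]], spec_c)
      feats <- unique(unlist(lapply(feature_sets, feature_set_names)))
      fm_super <- extract_features(windows, feats)
      for (clf in classifiers) {
        for (s in feature_sets) {
          cv_list[[length(cv_list) + 1L]] <- evaluate_feature_set(
            fm_super, s, list(type = clf), n_reps,
            base_seed + 1000L * i, sid)
          extras[[length(extras) + 1L]] <- data.frame(ctp = ctp)
        }
      }
    }
  }
  summary <- summarize_cv(cv_list, do.call(rbind, extras))
  agg <- stats::aggregate(global_accuracy ~ feature_set + classifier + ctp,
                          data = summary, FUN = mean)
  wide <- stats::reshape(agg, idvar = c("feature_set", "classifier"),
                         timevar = "ctp", direction = "wide")
  lo <- paste0("global_accuracy.", min(ctps))
  hi <- paste0("global_accuracy.", max(ctps))
  wide$delta_static_minus_dynamic <- wide[[lo]] - wide[[hi]]
  res <- experiment_result(cv_list, summary)
  res$deltas <- wide
  res
}
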