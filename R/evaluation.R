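#' Random stratified train/validation/test split
#'
#' Randomly assigns feature vectors to training, validation and test
#' sets (protocol fractions 40/20/40). The split is stratified by
#' movement label: within each class the rows are shuffled by a seeded
#' RNG and cut at `floor(f * n)` boundaries, remainders going to the
#' test set, so the three parts are disjoint and exhaustive and each
#' class's fractions are within one row of nominal.
#'
#' With `by_repetition = TRUE` whole contraction repetitions (rather
#' than individual windows) are assigned to the three parts, so windows
#' from the same contraction never appear on both sides of the
#' train/test divide. This avoids the temporal correlation the random
#' window assignment of the standard protocol induces, at the cost of a
#' much coarser split (each class needs at least 3 repetitions); it is
#' an extension, off by default.
#'
#' @param fm a `FeatureMatrix`.
#' @param fractions train/validation/test fractions, positive, summing
#'   to 1.
#' @param seed RNG seed; identical seeds give identical splits.
#' @param by_repetition assign whole repetitions instead of windows.
#' @return list of `FeatureMatrix`: `train`, `val`, `test` (plus
#'   `indices`, the row indices of each part).
#' @export
split_features <- function(fm, fractions = c(0.4, 0.2, 0.4), seed = 1L,
                           by_repetition = FALSE) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop_param("fractions must be three positive numbers summing to 1")
  labels <- fm$labels
  classes <- unique(labels)
  counts <- table(factor(labels, classes))
  if (any(counts < 3L))
    stop_param("class(es) with fewer than 3 rows cannot be split: %s",
               paste(names(counts)[counts < 3L], collapse = ", "))
  if (by_repetition && is.null(fm$repetitions))
    stop_param("feature matrix carries no repetition indices")
  idx <- list(train = integer(), val = integer(), test = integer())
  withr::with_seed(as.integer(seed), {
    for (k in classes) {
      if (by_repetition) {
        reps <- sample(unique(fm$repetitions[labels == k]))
        n <- length(reps)
        if (n < 3L)
          stop_param("class %s has %d repetitions; by-repetition splits need 3",
                     k, n)
        n_tr <- max(1L, floor(fractions[1] * n))
        n_va <- max(1L, floor(fractions[2] * n))
        in_part <- function(part) which(labels == k & fm$repetitions %in% part)
        idx$train <- c(idx$train, in_part(reps[seq_len(n_tr)]))
        idx$val <- c(idx$val, in_part(reps[n_tr + seq_len(n_va)]))
        idx$test <- c(idx$test, in_part(reps[(n_tr + n_va + 1L):n]))
      } else {
        rows <- sample(which(labels == k))
        n <- length(rows)
        n_tr <- floor(fractions[1] * n)
        n_va <- floor(fractions[2] * n)
        idx$train <- c(idx$train, rows[seq_len(n_tr)])
        idx$val <- c(idx$val, rows[n_tr + seq_len(n_va)])
        idx$test <- c(idx$test, rows[(n_tr + n_va + 1L):n])
      }
    }
  })
  take <- function(i) structure(
    list(values = fm$values[i, , drop = FALSE], labels = fm$labels[i],
         repetitions = fm$repetitions[i],
         feature_names = fm$feature_names), class = "FeatureMatrix")
  list(train = take(idx$train), val = take(idx$val), test = take(idx$test),
       indices = idx)
}

# fit + predict once for a classifier_config list(type = "lda"|"mlp", ...)
fit_and_predict <- function(train, val, test, classifier_config,
                            seed = 1L) {
  cc <- classifier_config
  norm <- normalize_fit_apply(train, list(val, test))
  train_n <- norm$train; val_n <- norm$others[[1]]; test_n <- norm$others[[2]]
  if (identical(cc$type, "lda")) {
    model <- lda_train(train_n, eps = cc$eps)
    pred <- lda_predict(model, test_n)
  } else if (identical(cc$type, "mlp")) {
    model <- mlp_train(
      train_n, val_n,
      hidden_units = cc$hidden_units,
      max_iterations = if (is.null(cc$max_iterations)) 400L else cc$max_iterations,
      learning_rate = if (is.null(cc$learning_rate)) 0.1 else cc$learning_rate,
      momentum = if (is.null(cc$momentum)) 0.9 else cc$momentum,
      patience = if (is.null(cc$patience)) 20L else cc$patience,
      seed = seed)
    pred <- mlp_predict(model, test_n)
  } else {
    stop_param("unknown classifier type '%s'", cc$type)
  }
  list(model = model, predicted = pred, truth = test_n$labels)
}

#' Train once and evaluate on the test set
#'
#' Trains the configured classifier on the training set (the validation
#' set drives MLP early stopping; LDA keeps it aside purely for protocol
#' symmetry), predicts the test set only, and tabulates the confusion
#' matrix (rows = true class) and per-movement accuracy
#' `correct_m / total_m`.
#'
#' @param train,val,test `FeatureMatrix` objects with consistent labels.
#' @param classifier_config list with `type` (`"lda"` or `"mlp"`) plus
#'   optional classifier parameters (`eps`; `hidden_units`,
#'   `max_iterations`, `learning_rate`, `momentum`, `patience`).
#' @param seed seed for the MLP weight initialization.
#' @return list with `confusion` (matrix), `per_movement_accuracy`
#'   (named vector) and `global_accuracy` (macro mean over movements).
#' @export
evaluate_once <- function(train, val, test, classifier_config, seed = 1L) {
  res <- fit_and_predict(train, val, test, classifier_config, seed)
  classes <- sort(unique(c(train$labels, test$labels)))
  confusion <- table(factor(res$truth, classes), factor(res$predicted, classes))
  confusion <- unclass(as.matrix(confusion))
  names(dimnames(confusion)) <- c("true", "predicted")
  per_mov <- diag(confusion) / rowSums(confusion)
  list(confusion = confusion,
       per_movement_accuracy = per_mov,
       global_accuracy = mean(per_mov))
}

#' Repeated random-split cross-validation
#'
#' Runs the 40/20/40 split + train + test cycle `n_reps` times (protocol
#' default 10); repetition `r` uses seed `base_seed + r` for both the
#' split and the MLP initialization. Accuracies are aggregated per
#' movement: `per_movement_mean` is the column mean of the
#' `n_reps x n_movements` accuracy matrix and `global_accuracy` the
#' macro mean over movements (the micro-averaged window accuracy is also
#' reported).
#'
#' @param fm a `FeatureMatrix`.
#' @param classifier_config see [evaluate_once()].
#' @param n_reps number of repetitions (default 10).
#' @param base_seed base RNG seed.
#' @param fractions split fractions.
#' @param split_by_repetition use leakage-free by-repetition splits (see
#'   [split_features()]); off by default, matching the standard protocol
#'   of random window assignment.
#' @param feature_set_name,subject_id bookkeeping strings carried into
#'   the result.
#' @return an object of class `CrossValResult`.
#' @export
cross_validate <- function(fm, classifier_config, n_reps = 10L,
                           base_seed = 1L, fractions = c(0.4, 0.2, 0.4),
                           split_by_repetition = FALSE,
                           feature_set_name = NULL, subject_id = NULL) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  if (!is_count(n_reps)) stop_param("n_reps must be a positive integer")
  classes <- sort(unique(fm$labels))
  acc <- matrix(NA_real_, nrow = n_reps, ncol = length(classes),
                dimnames = list(NULL, classes))
  micro <- numeric(n_reps)
  confusions <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    seed_r <- as.integer(base_seed) + r
    parts <- split_features(fm, fractions, seed = seed_r,
                            by_repetition = split_by_repetition)
    ev <- evaluate_once(parts$train, parts$val, parts$test,
                        classifier_config, seed = seed_r)
    acc[r, names(ev$per_movement_accuracy)] <- ev$per_movement_accuracy
    micro[r] <- sum(diag(ev$confusion)) / sum(ev$confusion)
    confusions[[r]] <- ev$confusion
  }
  per_movement_mean <- colMeans(acc)
  structure(
    list(per_rep_per_movement_accuracy = acc,
         per_movement_mean = per_movement_mean,
         global_accuracy = mean(per_movement_mean),
         micro_accuracy = mean(micro),
         confusions = confusions,
         classifier_name = classifier_config$type,
         feature_set_name = feature_set_name,
         subject_id = subject_id),
    class = "CrossValResult")
}

#' @export
print.CrossValResult <- function(x, ...) {
  cat(sprintf(
    "CrossValResult [%s%s]: %d reps x %d movements, macro accuracy %.3f\n",
    if (is.null(x$feature_set_name)) "" else paste0(x$feature_set_name, ", "),
    x$classifier_name, nrow(x$per_rep_per_movement_accuracy),
    ncol(x$per_rep_per_movement_accuracy), x$global_accuracy))
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' @param x a `CrossValResult`.
#' @param ... unused.
#' @return data.frame with one row per (repetition, movement):
#'   `subject`, `classifier`, `feature_set`, `repetition`, `movement`,
#'   `accuracy`.
#' @export
as.data.frame.CrossValResult <- function(x, ...) {
  acc <- x$per_rep_per_movement_accuracy
  data.frame(
    subject = if (is.null(x$subject_id)) NA_character_ else x$subject_id,
    classifier = x$classifier_name,
    feature_set = if (is.null(x$feature_set_name)) NA_character_ else
      x$feature_set_name,
    repetition = rep(seq_len(nrow(acc)), times = ncol(acc)),
    movement = rep(colnames(acc), each = nrow(acc)),
    accuracy = as.vector(acc),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Wilcoxon signed-rank test for paired accuracies
#'
#' Paired two-sided Wilcoxon signed-rank test as used to compare two
#' methods' per-movement mean accuracies. Zero differences are discarded
#' (their count is reported); ties among `|d|` receive midranks. The
#' statistic is `W = min(W+, W-)`. For `n <= 25` retained pairs the
#' two-sided p-value is exact -- the probability, over all `2^n`
#' equiprobable sign assignments, of a statistic at most the observed
#' one (computed by the equivalent rank-sum distribution recursion) --
#' and above that a normal approximation with continuity correction and
#' tie-corrected variance is used.
#'
#' @param a,b equal-length numeric vectors of paired values.
#' @return an object of class `ComparisonResult`: list with `statistic`
#'   (W), `p_value`, `n_pairs` (after zero removal), `n_discarded_zeros`
#'   and `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop_param("a and b must have equal length")
  if (length(a) < 1L) stop_param("need at least one pair")
  d <- a - b
  zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop_param("all paired differences are zero: test undefined")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  total <- n * (n + 1) / 2
  if (n <= 25L) {
    # distribution of W+ over all 2^n sign assignments; midranks doubled
    # to integers so the generating-function recursion stays exact
    r2 <- round(2 * r)
    probs <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), probs)
      probs <- c(probs, numeric(ri)) + shifted
    }
    probs <- probs / 2^n           # probs[k+1] = P(2*W+ = k)
    w2 <- round(2 * w)
    t2 <- round(2 * total)
    p <- sum(probs[seq_len(w2 + 1L)]) +
      sum(probs[(t2 - w2 + 1L):(t2 + 1L)])
    p <- min(1, p)
    method <- "exact"
  } else {
    ties <- table(r)
    mu <- total / 2
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w - mu + 0.5) / sqrt(sigma2)  # continuity-corrected, lower tail
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal approximation"
  }
  structure(
    list(statistic = w, w_pos = w_pos, w_neg = w_neg, p_value = p,
         n_pairs = n, n_discarded_zeros = zeros, method = method),
    class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank (%s): W = %g, p = %.4g (n = %d pairs, %d zero%s discarded)\n",
    x$method, x$statistic, x$p_value, x$n_pairs, x$n_discarded_zeros,
    if (x$n_discarded_zeros == 1) "" else "s"))
  invisible(x)
}

#' Aggregate cross-validation results across subjects
#'
#' Averages each subject's per-movement mean accuracies (each already
#' the mean of the cross-validation repetitions) by movement across
#' subjects, yielding the paired-by-movement vectors that feed
#' [wilcoxon_signed_rank()], plus a per-movement mean/sd summary table.
#'
#' @param results list of `CrossValResult` with identical movement sets.
#' @return list with `per_movement_mean` (named vector: mean across
#'   subjects), `per_subject` (subjects x movements matrix) and
#'   `summary` (data.frame movement/mean/sd).
#' @export
aggregate_subjects <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "CrossValResult")))
  movs <- colnames(results[[1]]$per_rep_per_movement_accuracy)
  mats <- lapply(results, function(r) {
    m <- colnames(r$per_rep_per_movement_accuracy)
    if (!identical(sort(m), sort(movs)))
      stop_param("subjects have mismatched movement sets")
    r$per_movement_mean[movs]
  })
  per_subject <- do.call(rbind, mats)
  rownames(per_subject) <- vapply(seq_along(results), function(i) {
    s <- results[[i]]$subject_id
    if (is.null(s)) paste0("subject", i) else s
  }, character(1))
  means <- colMeans(per_subject)
  sds <- apply(per_subject, 2L, stats::sd)
  list(per_movement_mean = means,
       per_subject = per_subject,
       summary = data.frame(movement = movs, mean = unname(means),
                            sd = unname(sds), stringsAsFactors = FALSE))
}
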