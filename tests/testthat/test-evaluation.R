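test_that("the 40/20/40 split is exact on a 100-row class", {
  fm <- make_fm(matrix(rnorm(100), ncol = 1), rep("only", 100))
  parts <- split_features(fm, seed = 1)
  expect_equal(nrow(parts$train$values), 40)
  expect_equal(nrow(parts$val$values), 20)
  expect_equal(nrow(parts$test$values), 40)
})

test_that("split parts are disjoint, exhaustive and stratified", {
  withr::with_seed(70, {
    for (i in 1:5) {
      n_per <- sample(5:40, 3)
      labels <- rep(c("a", "b", "c"), n_per)
      fm <- make_fm(matrix(rnorm(2 * length(labels)), ncol = 2), labels)
      parts <- split_features(fm, seed = i)
      idx <- parts$indices
      all_idx <- sort(c(idx$train, idx$val, idx$test))
      expect_identical(all_idx, seq_along(labels))  # conservation
      # per-class fractions within one row of nominal
      for (k in c("a", "b", "c")) {
        nk <- sum(labels == k)
        expect_lte(abs(sum(fm$labels[idx$train] == k) - 0.4 * nk), 1)
        expect_lte(abs(sum(fm$labels[idx$val] == k) - 0.2 * nk), 1)
      }
    }
  })
})

test_that("splits are seed-deterministic and seed-sensitive", {
  fm <- make_fm(matrix(rnorm(300), ncol = 3), rep(c("a", "b"), each = 50))
  s1 <- split_features(fm, seed = 5)
  s2 <- split_features(fm, seed = 5)
  expect_identical(s1$indices, s2$indices)
  differs <- vapply(6:10, function(seed)
    !identical(split_features(fm, seed = seed)$indices, s1$indices),
    logical(1))
  expect_true(any(differs))
})

test_that("a class with fewer than 3 rows cannot be split", {
  fm <- make_fm(matrix(rnorm(10), ncol = 1),
                c(rep("a", 8), "tiny", "tiny"))
  expect_error(split_features(fm), "tiny")
})

test_that("evaluate_once on separable data gives a diagonal confusion", {
  # class-indicator features make the LDA a perfect classifier
  labels <- rep(c("a", "b", "c"), each = 30)
  values <- cbind(f_ch1 = (labels == "a") + 0, f_ch2 = (labels == "b") + 0) +
    withr::with_seed(71, matrix(rnorm(180, sd = 0.01), ncol = 2))
  fm <- make_fm(values, labels)
  parts <- split_features(fm, seed = 2)
  ev <- evaluate_once(parts$train, parts$val, parts$test, list(type = "lda"))
  expect_true(all(ev$per_movement_accuracy == 1))
  expect_true(all(ev$confusion[row(ev$confusion) != col(ev$confusion)] == 0))
  expect_equal(ev$global_accuracy, 1)
  # confusion row sums equal the test-set class counts
  expect_equal(rowSums(ev$confusion),
               table(parts$test$labels)[rownames(ev$confusion)],
               ignore_attr = TRUE)
})

test_that("uninformative features collapse to chance-level accuracy", {
  # constant features: LDA ties, deterministic tie-break to one class,
  # macro accuracy = 1/n_classes on balanced data
  labels <- rep(letters[1:11], each = 12)
  fm <- make_fm(matrix(1, nrow = length(labels), ncol = 3), labels)
  parts <- split_features(fm, seed = 3)
  ev <- evaluate_once(parts$train, parts$val, parts$test, list(type = "lda"))
  expect_equal(ev$global_accuracy, 1 / 11)
})

test_that("cross_validate aggregates per movement with the stated identities", {
  fm <- blob_fm(40, matrix(c(0, 0, 4, 4, 0, 4), 3, byrow = TRUE,
                           dimnames = list(c("a", "b", "c"), NULL)),
                sd = 0.8, seed = 72)
  cv <- cross_validate(fm, list(type = "lda"), n_reps = 4, base_seed = 9)
  expect_equal(dim(cv$per_rep_per_movement_accuracy), c(4, 3))
  expect_true(all(cv$per_rep_per_movement_accuracy >= 0 &
                    cv$per_rep_per_movement_accuracy <= 1))
  expect_equal(cv$per_movement_mean,
               colMeans(cv$per_rep_per_movement_accuracy))
  expect_equal(cv$global_accuracy, mean(cv$per_movement_mean))
  # n_reps = 1 reduces to evaluate_once on that seed's split
  cv1 <- cross_validate(fm, list(type = "lda"), n_reps = 1, base_seed = 9)
  parts <- split_features(fm, seed = 10)
  ev <- evaluate_once(parts$train, parts$val, parts$test, list(type = "lda"),
                      seed = 10)
  expect_equal(unname(cv1$per_rep_per_movement_accuracy[1, ]),
               unname(ev$per_movement_accuracy))
  # tidy output bookkeeping
  df <- as.data.frame(cv)
  expect_equal(nrow(df), 4 * 3)
  expect_identical(names(df), c("subject", "classifier", "feature_set",
                                "repetition", "movement", "accuracy"))
})

test_that("Wilcoxon matches the n=5 all-positive exact value and contracts", {
  res <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(res$p_value, 0.0625)  # 2 / 2^5
  expect_equal(res$statistic, 0)
  expect_equal(res$n_pairs, 5)
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "all paired differences")
  expect_error(wilcoxon_signed_rank(1:3, 1:2), "equal length")
  # zeros are discarded and reported
  res2 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 4), c(1, 1, 1, 1, 4))
  expect_equal(res2$n_discarded_zeros, 2)
  expect_equal(res2$n_pairs, 3)
})

test_that("exact p equals full 2^n sign enumeration on random inputs", {
  enum_oracle <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    total <- n * (n + 1) / 2
    w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- signs %*% r            # W+ of every assignment
    w_min <- pmin(w_all, total - w_all)
    mean(w_min <= w_obs)
  }
  withr::with_seed(73, {
    for (i in 1:8) {
      n <- sample(4:12, 1)
      a <- rnorm(n); b <- rnorm(n)
      if (i %% 2 == 0) a <- round(a, 1) + b  # induce ties in |d|
      if (all(a == b)) a[1] <- a[1] + 1
      expect_equal(wilcoxon_signed_rank(a, b)$p_value,
                   enum_oracle(a - b), tolerance = 1e-12)
    }
  })
})

test_that("exact p agrees with the reference signed-rank test (no ties)", {
  withr::with_seed(74, {
    for (i in 1:5) {
      n <- sample(6:20, 1)
      a <- rnorm(n); b <- rnorm(n)
      ours <- wilcoxon_signed_rank(a, b)$p_value
      ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})

test_that("the large-sample normal approximation tracks the reference", {
  withr::with_seed(75, {
    a <- rnorm(40); b <- rnorm(40) + 0.3
    ours <- wilcoxon_signed_rank(a, b)
    expect_identical(ours$method, "normal approximation")
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                              correct = TRUE)$p.value
    expect_equal(ours$p_value, ref, tolerance = 1e-10)
  })
})

test_that("aggregate_subjects averages per movement and reports sd", {
  mk_cv <- function(acc_matrix, sid) {
    structure(list(per_rep_per_movement_accuracy = acc_matrix,
                   per_movement_mean = colMeans(acc_matrix),
                   global_accuracy = mean(colMeans(acc_matrix)),
                   classifier_name = "lda", feature_set_name = "card",
                   subject_id = sid), class = "CrossValResult")
  }
  m1 <- matrix(c(0.8, 0.9, 0.6, 0.7), 2,
               dimnames = list(NULL, c("open", "close")))
  m2 <- matrix(c(0.9, 1.0, 0.8, 0.9), 2,
               dimnames = list(NULL, c("open", "close")))
  agg <- aggregate_subjects(list(mk_cv(m1, "S1"), mk_cv(m2, "S2")))
  expect_equal(unname(agg$per_movement_mean), c((0.85 + 0.95) / 2,
                                                (0.65 + 0.85) / 2))
  expect_equal(agg$summary$sd, c(sd(c(0.85, 0.95)), sd(c(0.65, 0.85))))
  # single subject: identity passthrough
  agg1 <- aggregate_subjects(list(mk_cv(m1, "S1")))
  expect_equal(unname(agg1$per_movement_mean), unname(colMeans(m1)))
  # identical subjects: unchanged mean, zero sd
  agg2 <- aggregate_subjects(list(mk_cv(m1, "S1"), mk_cv(m1, "S1b")))
  expect_equal(unname(agg2$per_movement_mean), unname(colMeans(m1)))
  expect_equal(agg2$summary$sd, c(0, 0))
  # mismatched movement sets are refused
  m3 <- matrix(0.5, 2, 2, dimnames = list(NULL, c("open", "flex")))
  expect_error(aggregate_subjects(list(mk_cv(m1, "a"), mk_cv(m3, "b"))),
               "mismatched")
})

test_that("by-repetition splits keep whole contractions together", {
  s <- tiny_session(seed = 95, movements = c("a", "b"))
  fm <- extract_features(segment_session(s), "card")
  parts <- split_features(fm, seed = 4, by_repetition = TRUE)
  groups <- list(parts$train, parts$val, parts$test)
  seen <- lapply(groups, function(g) unique(paste(g$labels, g$repetitions)))
  # each (movement, repetition) block lands in exactly one part
  expect_equal(sum(lengths(seen)), length(unique(paste(fm$labels,
                                                       fm$repetitions))))
  expect_length(Reduce(intersect, seen), 0)
  # conservation still holds
  expect_identical(sort(unname(unlist(parts$indices))),
                   seq_along(fm$labels))
  # plain matrices without repetition info are refused
  fm2 <- make_fm(matrix(rnorm(60), ncol = 2), rep(c("a", "b"), 15))
  expect_error(split_features(fm2, by_repetition = TRUE),
               "no repetition indices")
})
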