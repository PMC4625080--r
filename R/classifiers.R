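#' Min-max normalization fitted on training data only
#'
#' Fits a per-column affine map sending each training column's `[min,
#' max]` to `[0, 1]` and applies the same map to any number of other
#' matrices (validation, test). Constant training columns map to 0.
#' Values of the other matrices may fall outside `[0, 1]`; no clipping
#' is applied. Normalization parameters are derived from the training
#' rows alone, so test data can never leak into the fitted map.
#'
#' @param train a `FeatureMatrix` (or plain numeric matrix).
#' @param others list of `FeatureMatrix`/matrices to transform with the
#'   training map.
#' @return list with `train`, `others` (both transformed, same classes
#'   as the inputs) and `params` (list with `min`, `range`).
#' @export
normalize_fit_apply <- function(train, others = list()) {
  tv <- if (inherits(train, "FeatureMatrix")) train$values else train
  if (nrow(tv) == 0L) stop_param("empty training matrix")
  mins <- apply(tv, 2L, min)
  maxs <- apply(tv, 2L, max)
  rng <- maxs - mins
  rng[rng == 0] <- 1  # constant columns -> (x - min)/1 = 0
  apply_map <- function(m) sweep(sweep(m, 2L, mins, "-"), 2L, rng, "/")
  wrap <- function(orig, m) {
    if (inherits(orig, "FeatureMatrix")) { orig$values <- m; orig } else m
  }
  list(
    train = wrap(train, apply_map(tv)),
    others = lapply(others, function(o) {
      ov <- if (inherits(o, "FeatureMatrix")) o$values else o
      wrap(o, apply_map(ov))
    }),
    params = list(min = mins, range = rng)
  )
}

#' Train a linear discriminant analysis classifier
#'
#' Classic LDA with a shared (pooled) within-class covariance: class
#' means `mu_k`, pooled covariance `S_w` regularized to `S_w + eps * I`
#' and inverted, and discriminant scores
#' `score_k(x) = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log(prior_k)`.
#' Priors are uniform by default. The default ridge scales with the
#' problem, `eps = 1e-6 * trace(S_w) / d`, so regularization is
#' scale-free.
#'
#' @param train a `FeatureMatrix`; every class needs >= 2 rows.
#' @param eps ridge added to the pooled covariance diagonal; `NULL` for
#'   the scale-free default.
#' @param priors optional named prior vector (must sum to 1); default
#'   uniform.
#' @return an object of class `LDAModel`.
#' @export
lda_train <- function(train, eps = NULL, priors = NULL) {
  stopifnot(inherits(train, "FeatureMatrix"))
  x <- train$values
  y <- train$labels
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop_param("LDA needs at least 2 classes")
  small <- classes[table(factor(y, classes)) < 2L]
  if (length(small))
    stop_param("class(es) with fewer than 2 training rows: %s",
               paste(small, collapse = ", "))
  d <- ncol(x)
  means <- vapply(classes, function(k) colMeans(x[y == k, , drop = FALSE]),
                  numeric(d))
  means <- if (d == 1L) matrix(means, ncol = 1L) else t(means)
  sw <- matrix(0, d, d)
  for (k in classes) {
    xk <- x[y == k, , drop = FALSE]
    xc <- sweep(xk, 2L, colMeans(xk))
    sw <- sw + crossprod(xc)
  }
  sw <- sw / (nrow(x) - length(classes))
  if (is.null(eps)) eps <- 1e-6 * sum(diag(sw)) / d
  if (eps == 0) eps <- 1e-12  # fully degenerate (all-constant) features
  sinv <- solve(sw + diag(eps, d))
  if (is.null(priors)) priors <- rep(1 / length(classes), length(classes))
  if (abs(sum(priors) - 1) > 1e-8) stop_param("priors must sum to 1")
  structure(
    list(class_means = means, pooled_covariance_inverse = sinv,
         priors = priors, class_labels = classes,
         regularization_eps = eps, d = d,
         column_names = colnames(x)),
    class = "LDAModel")
}

#' Predict with an LDA model
#'
#' Computes the linear discriminant score of every class for every row
#' and returns the argmax labels; ties break deterministically toward
#' the earlier class in the model's class order.
#'
#' @param model an `LDAModel`.
#' @param features `FeatureMatrix` or numeric matrix with the training
#'   column count.
#' @param scores also return the n x n_classes score matrix.
#' @return character vector of predicted labels (with attribute
#'   `"scores"` when `scores = TRUE`).
#' @export
lda_predict <- function(model, features, scores = FALSE) {
  stopifnot(inherits(model, "LDAModel"))
  x <- if (inherits(features, "FeatureMatrix")) features$values else features
  if (ncol(x) != model$d)
    stop_param("feature count %d does not match training dimension %d",
               ncol(x), model$d)
  a <- model$pooled_covariance_inverse %*% t(model$class_means)  # d x K
  sc <- x %*% a
  const <- -0.5 * colSums(t(model$class_means) * a) + log(model$priors)
  sc <- sweep(sc, 2L, const, "+")
  pred <- model$class_labels[max.col(sc, ties.method = "first")]
  if (scores) attr(pred, "scores") <- sc
  pred
}

#' Train a multi-layer perceptron classifier
#'
#' One hidden layer of logistic-sigmoid units and per-class sigmoid
#' outputs trained against one-hot targets by full-batch gradient
#' descent with momentum. After every iteration the validation accuracy
#' is measured and the best-scoring weights are kept (early stopping);
#' training halts at `max_iterations` (default 400) or after
#' `patience` iterations without validation improvement.
#'
#' The topology and optimizer follow common myoelectric-pattern-
#' recognition practice: hidden units default to half of (inputs +
#' classes) with a floor of 8, learning rate 0.1, momentum 0.9. Training
#' is fully reproducible given `seed`.
#'
#' @param train,val `FeatureMatrix` objects sharing columns and label
#'   set (validation labels must occur in training).
#' @param hidden_units hidden-layer width; `NULL` for the default.
#' @param max_iterations iteration cap (default 400).
#' @param learning_rate,momentum optimizer parameters.
#' @param patience early-stopping patience in iterations (default 20).
#' @param seed RNG seed for weight initialization.
#' @return an object of class `MLPModel`.
#' @export
mlp_train <- function(train, val, hidden_units = NULL, max_iterations = 400L,
                      learning_rate = 0.1, momentum = 0.9, patience = 20L,
                      seed = 1L) {
  stopifnot(inherits(train, "FeatureMatrix"), inherits(val, "FeatureMatrix"))
  x <- train$values
  classes <- sort(unique(train$labels))
  unseen <- setdiff(unique(val$labels), classes)
  if (length(unseen))
    stop_param("validation labels unseen in training: %s",
               paste(unseen, collapse = ", "))
  n <- nrow(x); d <- ncol(x); K <- length(classes)
  if (is.null(hidden_units)) hidden_units <- max(8L, round((d + K) / 2))
  H <- hidden_units
  t_onehot <- outer(train$labels, classes, "==") * 1
  sigm <- function(z) 1 / (1 + exp(-z))
  forward <- function(xm, w1, b1, w2, b2) {
    h <- sigm(sweep(xm %*% w1, 2L, b1, "+"))
    o <- sigm(sweep(h %*% w2, 2L, b2, "+"))
    list(h = h, o = o)
  }
  acc_of <- function(o, labels)
    mean(classes[max.col(o, ties.method = "first")] == labels)

  withr::with_seed(as.integer(seed), {
    w1 <- matrix(rnorm(d * H, 0, 0.5), d, H); b1 <- rnorm(H, 0, 0.5)
    w2 <- matrix(rnorm(H * K, 0, 0.5), H, K); b2 <- rnorm(K, 0, 0.5)
  })
  vw1 <- w1 * 0; vb1 <- b1 * 0; vw2 <- w2 * 0; vb2 <- b2 * 0
  best <- list(w1 = w1, b1 = b1, w2 = w2, b2 = b2, acc = -Inf, iter = 0L)
  stall <- 0L
  for (it in seq_len(max_iterations)) {
    fw <- forward(x, w1, b1, w2, b2)
    # cross-entropy gradient through sigmoid outputs: delta = o - t
    delta_o <- (fw$o - t_onehot) / n
    grad_w2 <- crossprod(fw$h, delta_o)
    grad_b2 <- colSums(delta_o)
    delta_h <- (delta_o %*% t(w2)) * fw$h * (1 - fw$h)
    grad_w1 <- crossprod(x, delta_h)
    grad_b1 <- colSums(delta_h)
    vw2 <- momentum * vw2 - learning_rate * grad_w2
    vb2 <- momentum * vb2 - learning_rate * grad_b2
    vw1 <- momentum * vw1 - learning_rate * grad_w1
    vb1 <- momentum * vb1 - learning_rate * grad_b1
    w2 <- w2 + vw2; b2 <- b2 + vb2; w1 <- w1 + vw1; b1 <- b1 + vb1
    val_acc <- acc_of(forward(val$values, w1, b1, w2, b2)$o, val$labels)
    if (val_acc > best$acc) {
      best <- list(w1 = w1, b1 = b1, w2 = w2, b2 = b2, acc = val_acc,
                   iter = it)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  structure(
    list(w1 = best$w1, b1 = best$b1, w2 = best$w2, b2 = best$b2,
         hidden_units = H, class_labels = classes, d = d,
         max_iterations = max_iterations, rng_seed = as.integer(seed),
         best_val_accuracy = best$acc, best_iteration = best$iter,
         column_names = colnames(x)),
    class = "MLPModel")
}

#' Predict with an MLP model
#'
#' Forward pass and argmax over the per-class sigmoid output
#' activations; ties break toward the earlier class in the model's
#' class order.
#'
#' @param model an `MLPModel`.
#' @param features `FeatureMatrix` or numeric matrix.
#' @param activations also return the output activation matrix.
#' @return character vector of predicted labels (with attribute
#'   `"activations"` when requested).
#' @export
mlp_predict <- function(model, features, activations = FALSE) {
  stopifnot(inherits(model, "MLPModel"))
  x <- if (inherits(features, "FeatureMatrix")) features$values else features
  if (ncol(x) != model$d)
    stop_param("feature count %d does not match training dimension %d",
               ncol(x), model$d)
  sigm <- function(z) 1 / (1 + exp(-z))
  h <- sigm(sweep(x %*% model$w1, 2L, model$b1, "+"))
  o <- sigm(sweep(h %*% model$w2, 2L, model$b2, "+"))
  pred <- model$class_labels[max.col(o, ties.method = "first")]
  if (activations) attr(pred, "activations") <- o
  pred
}

#' Save / load classifier models as JSON
#'
#' Serializes an `LDAModel` or `MLPModel` (weights included) to a single
#' JSON document and restores it losslessly; numeric payloads are
#' written at full precision.
#'
#' @param model an `LDAModel` or `MLPModel`.
#' @param path JSON file path.
#' @return `save_model`: `path`, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  kind <- class(model)[1]
  if (!kind %in% c("LDAModel", "MLPModel"))
    stop_param("unsupported model class %s", kind)
  payload <- lapply(unclass(model), function(v) {
    if (is.matrix(v)) list(.matrix = TRUE, dim = dim(v), data = as.vector(v))
    else v
  })
  payload$.model_class <- kind
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- p$.model_class
  p$.model_class <- NULL
  p <- lapply(p, function(v) {
    if (is.list(v) && isTRUE(v$.matrix)) matrix(v$data, v$dim[1], v$dim[2])
    else v
  })
  structure(p, class = kind)
}
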