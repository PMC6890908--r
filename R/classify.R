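#' Feature standardization
#'
#' Estimates per-feature mean and standard deviation on training data;
#' applying the parameters maps each feature x to (x - mean) / sd.
#'
#' @param x numeric matrix or data frame of training features (rows =
#'   subjects).
#' @return object of class `standardization_params`.
#' @export
standardize_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 training rows", call. = FALSE)
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  if (any(s <= 0 | !is.finite(s))) {
    bad <- colnames(x)[s <= 0 | !is.finite(s)]
    stop("constant feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(mean = m, sd = s), class = "standardization_params")
}

#' @rdname standardize_fit
#' @param params a `standardization_params` object.
#' @export
standardize_apply <- function(params, x) {
  x <- as.matrix(x)
  stopifnot(inherits(params, "standardization_params"),
            ncol(x) == length(params$mean))
  sweep(sweep(x, 2, params$mean, "-"), 2, params$sd, "/")
}

#' Stratified train/test split
#'
#' Splits subjects into train and test parts preserving class proportions.
#' Per-class test counts follow the largest-remainder rule: class counts
#' are floored and the remaining seats (up to the half-up-rounded overall
#' test size) go to the classes with the largest fractional remainders, so
#' both parts match the overall proportions to within one subject.
#'
#' @param labels class label per subject.
#' @param test_fraction fraction held out for testing (0 < f < 1).
#' @param seed integer RNG seed controlling membership.
#' @return object of class `split_plan`: `train` and `test` index vectors,
#'   plus the fraction and seed.
#' @export
stratified_split <- function(labels, test_fraction = 0.25, seed = 1) {
  labels <- as.character(labels)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("'test_fraction' must be in (0, 1)", call. = FALSE)
  }
  tab <- table(labels)
  if (length(tab) < 2L) stop("both classes must be present", call. = FALSE)
  if (any(tab < 2L)) stop("every class needs at least 2 members",
                          call. = FALSE)
  raw <- test_fraction * as.numeric(tab)
  base <- floor(raw)
  target <- round_half_up(test_fraction * length(labels), 0)
  extra <- target - sum(base)
  ord <- order(raw - base, as.numeric(tab), decreasing = TRUE)
  take <- stats::setNames(base, names(tab))
  if (extra > 0) take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1
  test_idx <- with_seed(seed, {
    unlist(lapply(names(tab), function(cl) {
      idx <- which(labels == cl)
      sample(idx, take[[cl]])
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  structure(list(train = setdiff(seq_along(labels), test_idx),
                 test = test_idx, stratified = TRUE,
                 fraction = test_fraction, seed = as.integer(seed)),
            class = "split_plan")
}

# order-canonical stratified fold assignment: rows are ranked by their
# feature values within each class before the seeded shuffle, so permuting
# the training rows leaves the fold partition (as a set of subjects) intact
cv_fold_assignment <- function(x, y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      canon <- idx[do.call(order, as.data.frame(x[idx, , drop = FALSE]))]
      canon <- sample(canon)
      folds[canon] <- rep_len(seq_len(k), length(canon))
    }
  })
  folds
}

#' Fit a linear soft-margin SVM with cross-validated regularization
#'
#' Trains a linear support-vector classifier (hinge loss with L2 penalty,
#' libsvm backend) on standardized features. The cost parameter is chosen
#' from `c_grid` by stratified k-fold cross-validated accuracy (ties go to
#' the smallest cost), then the model is refit on the full training set.
#' The decision orientation is fixed so that the positive class scores
#' positively.
#'
#' @param x standardized feature matrix (rows = subjects).
#' @param y class labels (two classes).
#' @param c_grid candidate soft-margin cost values.
#' @param k_folds number of CV folds (must not exceed the smaller class).
#' @param seed integer RNG seed for fold assignment.
#' @param positive label of the positive (disease) class; default `"PS"`,
#'   falling back to the second factor level.
#' @param standardization optional `standardization_params` stored with the
#'   model and applied by [decision_score()].
#' @return object of class `svm_model`: weights `w`, bias `b`, chosen
#'   `cost`, CV accuracy table, fold assignments, seed.
#' @export
fit_linear_svm <- function(x, y, c_grid = c(0.01, 0.1, 1, 10, 100),
                           k_folds = 10, seed = 1, positive = "PS",
                           standardization = NULL) {
  x <- as.matrix(x)
  y <- factor(as.character(y))
  if (nlevels(y) != 2L) stop("training labels must contain two classes",
                             call. = FALSE)
  if (!positive %in% levels(y)) positive <- levels(y)[2]
  if (k_folds > min(table(y))) {
    stop("'k_folds' exceeds the smaller class size", call. = FALSE)
  }
  folds <- cv_fold_assignment(x, y, k_folds, seed)
  cv_acc <- vapply(c_grid, function(cost) {
    pred <- character(length(y))
    for (f in seq_len(k_folds)) {
      tr <- folds != f
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], type = "C-classification",
                        kernel = "linear", cost = cost, scale = FALSE)
      pred[!tr] <- as.character(stats::predict(fit, x[!tr, , drop = FALSE]))
    }
    mean(pred == as.character(y))
  }, numeric(1))
  best <- which(cv_acc == max(cv_acc))
  cost <- min(c_grid[best])
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  score <- drop(x %*% w) + b
  if (mean(score[y == positive]) < mean(score[y != positive])) {
    w <- -w; b <- -b
  }
  structure(list(w = w, b = b, cost = cost, positive = positive,
                 levels = levels(y),
                 cv = data.frame(cost = c_grid, accuracy = cv_acc),
                 folds = folds, seed = as.integer(seed),
                 standardization = standardization,
                 n_features = ncol(x), features = colnames(x)),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("Linear SVM (%d features, cost %.3g): score = W.x' %+.3f\n",
              x$n_features, x$cost, x$b))
  print(round(x$w, 4))
  invisible(x)
}

#' Decision score of a trained linear SVM
#'
#' Signed distance surrogate `W . x' + b` on standardized input; positive
#' scores predict the positive (disease) class. If the model carries
#' standardization parameters they are applied to the raw input first.
#'
#' @param model an `svm_model`.
#' @param x feature matrix or vector (raw scale when the model stores
#'   standardization parameters, already-standardized otherwise).
#' @return numeric score vector.
#' @export
decision_score <- function(model, x) {
  stopifnot(inherits(model, "svm_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != model$n_features) {
    stop(sprintf("expected %d features, got %d", model$n_features, ncol(x)),
         call. = FALSE)
  }
  if (!is.null(model$standardization)) {
    x <- standardize_apply(model$standardization, x)
  }
  drop(x %*% model$w) + model$b
}

#' Train and score an index-triplet SVM on a labeled panel table
#'
#' Convenience wrapper for the full classification stage: stratified
#' train/test split, standardization fitted on the training part (reused on
#' the test part unless `leak_standardization`), CV-tuned linear SVM, and
#' decision scores for both parts.
#'
#' @param panels data frame with a `label` column and the feature columns.
#' @param features character vector of feature column names (a triplet,
#'   e.g. `c("sbr_q", "pcr_q", "ai_q")`).
#' @param split_seed,svm_seed seeds for the split and the CV folds.
#' @param test_fraction held-out fraction.
#' @param c_grid,k_folds forwarded to [fit_linear_svm()].
#' @param positive positive class label.
#' @param leak_standardization if `TRUE`, standardization is estimated on
#'   the full cohort (sensitivity check only).
#' @return list with the fitted `model`, the `split`, and data frames
#'   `train`/`test` carrying labels and decision scores.
#' @export
svm_stage <- function(panels, features, split_seed = 1, svm_seed = 1,
                      test_fraction = 0.25,
                      c_grid = c(0.01, 0.1, 1, 10, 100), k_folds = 10,
                      positive = "PS", leak_standardization = FALSE) {
  stopifnot(all(c("label", features) %in% names(panels)))
  split <- stratified_split(panels$label, test_fraction, split_seed)
  xs <- as.matrix(panels[, features])
  std <- standardize_fit(if (leak_standardization) xs else
    xs[split$train, , drop = FALSE])
  model <- fit_linear_svm(
    standardize_apply(std, xs[split$train, , drop = FALSE]),
    panels$label[split$train], c_grid = c_grid, k_folds = k_folds,
    seed = svm_seed, positive = positive, standardization = std)
  list(model = model, split = split,
       train = data.frame(subject = split$train,
                          label = panels$label[split$train],
                          score = decision_score(model,
                                                 xs[split$train, , drop = FALSE])),
       test = data.frame(subject = split$test,
                         label = panels$label[split$test],
                         score = decision_score(model,
                                                xs[split$test, , drop = FALSE])))
}

#' Serialize / restore an SVM model as JSON
#'
#' @param model an `svm_model`.
#' @param path output (input) JSON path.
#' @export
write_svm_model <- function(model, path) {
  obj <- model[c("w", "b", "cost", "positive", "levels", "seed",
                 "n_features", "features")]
  if (!is.null(model$standardization)) {
    obj$standardization <- list(mean = model$standardization$mean,
                                sd = model$standardization$sd)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  std <- NULL
  if (!is.null(obj$standardization)) {
    std <- structure(list(mean = unlist(obj$standardization$mean),
                          sd = unlist(obj$standardization$sd)),
                     class = "standardization_params")
  }
  structure(list(w = unlist(obj$w), b = obj$b, cost = obj$cost,
                 positive = obj$positive, levels = obj$levels,
                 cv = NULL, folds = NULL, seed = obj$seed,
                 standardization = std, n_features = obj$n_features,
                 features = obj$features),
            class = "svm_model")
}
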