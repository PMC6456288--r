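#' Classification accuracy from correct/incorrect counts
#'
#' \eqn{Acc = 100 \cdot C_{num} / (C_{num} + I_{num})}, in percent.
#'
#' @param c_num,i_num Counts of correctly and incorrectly classified
#'   instances; their sum must be at least 1.
#' @return Accuracy as a percentage in `[0, 100]`.
#' @examples
#' accuracy_pct(9, 1) # 90
#' @export
accuracy_pct <- function(c_num, i_num) {
  if (c_num < 0 || i_num < 0) stop("counts must be non-negative")
  if (c_num + i_num < 1) stop("no classified instances")
  100 * c_num / (c_num + i_num)
}

#' Composite performance score balancing accuracy and sparsity
#'
#' \eqn{w_1 \cdot Acc + w_2 (1 - n/N)}, where `acc` is the accuracy as a
#' fraction, `n` the number of selected features and `N` the total. The
#' default weights (0.999, 0.001) make accuracy dominate, with subset size
#' as a tie-breaker.
#'
#' @param acc Accuracy as a fraction in `[0, 1]`.
#' @param n Number of selected features (`0 <= n <= total`).
#' @param total Total number of features (>= 1).
#' @param w1,w2 Weights; must sum to 1.
#' @return The weighted score.
#' @examples
#' performance_score(1, 34, 2000)
#' @export
performance_score <- function(acc, n, total, w1 = 0.999, w2 = 0.001) {
  if (total < 1) stop("total must be >= 1")
  if (n < 0 || n > total) stop("n must be between 0 and total")
  if (abs(w1 + w2 - 1) > 1e-12) stop("w1 and w2 must sum to 1")
  w1 * acc + w2 * (1 - n / total)
}

# fit + predict, returning the predicted factor on the test rows.
# Hyperparameters fixed: rf 10 trees, knn k = 1, svm linear kernel;
# everything else at the backing library's defaults.
.fit_predict <- function(classifier, train_x, train_y, test_x) {
  train_x <- as.data.frame(train_x)
  test_x <- as.data.frame(test_x)
  switch(classifier,
    rf = {
      fit <- randomForest::randomForest(x = train_x, y = train_y, ntree = 10)
      stats::predict(fit, newdata = test_x)
    },
    knn = {
      class::knn(train = train_x, test = test_x, cl = train_y, k = 1)
    },
    svm = {
      fit <- e1071::svm(x = train_x, y = train_y, kernel = "linear")
      stats::predict(fit, newdata = test_x)
    },
    stop("unknown classifier: ", classifier)
  )
}

# fold assignment preserving class proportions; returns an integer vector
# of fold ids in 1..n_folds
.stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    if (length(idx) < n_folds) {
      stop("class '", lev, "' has fewer instances (", length(idx),
           ") than folds (", n_folds, ")")
    }
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

#' Repeated stratified k-fold cross-validation
#'
#' Evaluates a classifier — optionally preceded by feature selection — by
#' stratified k-fold cross-validation repeated `n_repeats` times with
#' independent fold assignments. When a `selector` is supplied it is run on
#' the training portion of each fold only (no information from the held-out
#' fold reaches the selection), the classifier is fit on the selected
#' features, and the held-out fold is scored. `selector = NULL` evaluates
#' the full feature set.
#'
#' @param data Data frame of numeric features plus one class column.
#' @param selector `NULL`, or a function `(data) -> character vector` of
#'   selected feature names, e.g. [fsbrr_selector()].
#' @param classifier `"rf"` (random forest, 10 trees), `"knn"` (1-nearest
#'   neighbour) or `"svm"` (linear kernel).
#' @param class_col Name of the class column.
#' @param n_folds Folds per repeat (default 10).
#' @param n_repeats Repeats (default 5; the full published-protocol scale
#'   is 100).
#' @param w1,w2 Weights of the composite performance score.
#' @param seed Integer seed controlling fold assignment and any classifier
#'   randomness; identical inputs and seed give an identical report.
#' @param outside_folds If `TRUE`, run the selector once on the full table
#'   before cross-validation instead of inside each training fold
#'   (compatibility mode; the default leak-free protocol is recommended).
#'
#' @return An object of class `"cv_eval"`: a list with `accuracies` (tibble
#'   of per-fold accuracies in percent, with `repeat_id` and `fold`),
#'   `mean_fn` (mean number of features used), `report` (one-row tibble:
#'   `mean`, `max`, `min`, `std` of fold-level accuracy, `std_repeat` over
#'   repeat means, `mean_fn`, `performance`, `runtime_seconds`) and
#'   `config`.
#' @examples
#' d <- synth_table(n_instances = 60, n_informative = 2, n_irrelevant = 2,
#'                  shift = 4, seed = 2)
#' cv <- cross_validate(d, classifier = "knn", n_folds = 3, n_repeats = 2,
#'                      seed = 1)
#' glance(cv)
#' @export
cross_validate <- function(data, selector = NULL,
                           classifier = c("rf", "knn", "svm"),
                           class_col = "class", n_folds = 10L,
                           n_repeats = 5L, w1 = 0.999, w2 = 0.001,
                           seed = 1L, outside_folds = FALSE) {
  classifier <- match.arg(classifier)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  if (abs(w1 + w2 - 1) > 1e-12) stop("w1 and w2 must sum to 1")
  data <- as.data.frame(data)
  if (!class_col %in% names(data)) {
    stop("class column '", class_col, "' not found")
  }
  y <- factor(data[[class_col]])
  x <- data[setdiff(names(data), class_col)]
  n_total <- ncol(x)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  t0 <- proc.time()[["elapsed"]]
  global_sel <- NULL
  if (!is.null(selector) && outside_folds) {
    global_sel <- selector(data)
  }

  acc <- tibble::tibble(repeat_id = integer(0), fold = integer(0),
                        accuracy = numeric(0))
  fn_used <- numeric(0)
  for (r in seq_len(n_repeats)) {
    folds <- .stratified_folds(y, n_folds)
    for (k in seq_len(n_folds)) {
      test <- folds == k
      feats <- names(x)
      if (!is.null(selector)) {
        feats <- if (outside_folds) {
          global_sel
        } else {
          selector(cbind(x[!test, , drop = FALSE],
                         stats::setNames(data.frame(y[!test]), class_col)))
        }
        fn_used <- c(fn_used, length(feats))
      } else {
        fn_used <- c(fn_used, n_total)
      }
      pred <- .fit_predict(classifier,
                           x[!test, feats, drop = FALSE], y[!test],
                           x[test, feats, drop = FALSE])
      c_num <- sum(as.character(pred) == as.character(y[test]))
      acc <- dplyr::bind_rows(acc, tibble::tibble(
        repeat_id = r, fold = k,
        accuracy = accuracy_pct(c_num, sum(test) - c_num)
      ))
    }
  }
  runtime <- proc.time()[["elapsed"]] - t0

  mean_fn <- mean(fn_used)
  repeat_means <- dplyr::summarise(dplyr::group_by(acc, .data$repeat_id),
                                   m = mean(.data$accuracy))$m
  report <- tibble::tibble(
    mean = mean(acc$accuracy),
    max = max(acc$accuracy),
    min = min(acc$accuracy),
    std = stats::sd(acc$accuracy),
    std_repeat = if (n_repeats > 1L) stats::sd(repeat_means) else NA_real_,
    mean_fn = mean_fn,
    performance = performance_score(mean(acc$accuracy) / 100, mean_fn,
                                    n_total, w1, w2),
    runtime_seconds = runtime
  )

  structure(
    list(accuracies = acc, mean_fn = mean_fn, report = report,
         config = list(classifier = classifier, n_folds = as.integer(n_folds),
                       n_repeats = as.integer(n_repeats), w1 = w1, w2 = w2,
                       seed = as.integer(seed),
                       outside_folds = outside_folds,
                       hyperparameters = switch(classifier,
                         rf = list(ntree = 10), knn = list(k = 1),
                         svm = list(kernel = "linear")),
                       n_total_features = n_total)),
    class = "cv_eval"
  )
}

#' Build an FSBRR selector for use inside cross-validation
#'
#' Returns a closure suitable for [cross_validate()]'s `selector` argument:
#' it runs [fsbrr()] on the (training) table it is given and returns the
#' selected feature names.
#'
#' @inheritParams fsbrr
#' @return A function `(data) -> character vector of feature names`.
#' @export
fsbrr_selector <- function(class_col = "class", tau = 0, delta = 0.08,
                           alpha = 0.64, binning = "equal_width",
                           n_bins = 10L) {
  force(list(class_col, tau, delta, alpha, binning, n_bins))
  function(data) {
    fit <- suppressWarnings(
      fsbrr(data, class_col = class_col, tau = tau, delta = delta,
            alpha = alpha, binning = binning, n_bins = n_bins)
    )
    fit$selected$feature
  }
}

#' @export
print.cv_eval <- function(x, ...) {
  cat(sprintf("Repeated stratified %d-fold CV x %d repeats (%s)\n",
              x$config$n_folds, x$config$n_repeats, x$config$classifier))
  r <- x$report
  cat(sprintf("  accuracy: mean %.2f%%  max %.2f%%  min %.2f%%  sd %.2f\n",
              r$mean, r$max, r$min, r$std))
  cat(sprintf("  mean features used: %.1f of %d   performance: %.5f\n",
              r$mean_fn, x$config$n_total_features, r$performance))
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' @param x An object returned by [cross_validate()].
#' @param ... Unused.
#' @return A tibble of per-fold accuracies (`repeat_id`, `fold`,
#'   `accuracy` in percent).
#' @export
tidy.cv_eval <- function(x, ...) x$accuracies

#' Glance at a cross-validation result
#'
#' One row in the conventional evaluation layout: mean/max/min/std of
#' fold-level accuracy (percent), mean number of features used, composite
#' performance score and runtime.
#'
#' @param x An object returned by [cross_validate()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.cv_eval <- function(x, ...) x$report

#' Plot a cross-validation result
#'
#' Fold-level accuracy distribution across repeats.
#'
#' @param object An object returned by [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_eval <- function(object, ...) {
  d <- object$accuracies
  d$repeat_id <- factor(d$repeat_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$repeat_id, y = .data$accuracy)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::labs(x = "repeat", y = "fold accuracy (%)") +
    ggplot2::theme_minimal()
}
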