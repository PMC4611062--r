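#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity (true-positive rate for the positive class, by
#' convention the patient group) and specificity (true-negative rate).
#'
#' @param pred,truth Equal-length label vectors.
#' @param positive The positive-class label (default `"patient"`).
#' @return Named list `accuracy`, `sensitivity`, `specificity` in `[0, 1]`;
#'   a metric whose class is absent from `truth` is `NA`.
#' @examples
#' confusion_metrics(rep("patient", 4), c("patient", "patient", "control", "patient"))
#' @export
confusion_metrics <- function(pred, truth, positive = "patient") {
  stopifnot(length(pred) == length(truth))
  pred <- as.character(pred)
  truth <- as.character(truth)
  pos <- truth == positive
  acc <- mean(pred == truth)
  sens <- if (any(pos)) mean(pred[pos] == positive) else NA_real_
  spec <- if (any(!pos)) mean(pred[!pos] != positive) else NA_real_
  list(accuracy = acc, sensitivity = sens, specificity = spec)
}

# Train on z-scored training features, predict test rows. Scaling statistics
# come from the training fold only. classifier: "svm" (linear, C = cost) or
# "knn" (k nearest neighbours, requires the class package).
fit_predict <- function(x_train, y_train, x_test, classifier = "svm",
                        cost = 1, knn_k = 3) {
  mu <- colMeans(x_train)
  sd <- apply(x_train, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  zt <- sweep(sweep(x_train, 2L, mu), 2L, sd, "/")
  zs <- sweep(sweep(x_test, 2L, mu), 2L, sd, "/")
  y_train <- factor(y_train)
  if (classifier == "svm") {
    m <- e1071::svm(zt, y_train, kernel = "linear", cost = cost,
                    scale = FALSE)
    as.character(predict(m, zs))
  } else if (classifier == "knn") {
    if (!requireNamespace("class", quietly = TRUE)) {
      stop("classifier = \"knn\" requires the 'class' package")
    }
    as.character(class::knn(zt, zs, y_train, k = knn_k))
  } else {
    stop("unknown classifier: ", classifier)
  }
}

make_cv_result <- function(scheme, per_fold, positive, extra = list()) {
  pred <- unlist(lapply(per_fold, `[[`, "pred"))
  truth <- unlist(lapply(per_fold, `[[`, "truth"))
  m <- confusion_metrics(pred, truth, positive)
  structure(
    c(list(scheme = scheme, accuracy = m$accuracy,
           sensitivity = m$sensitivity, specificity = m$specificity,
           per_fold = per_fold), extra),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%>\n",
              x$scheme, 100 * x$accuracy, 100 * x$sensitivity,
              100 * x$specificity))
  if (identical(x$mode, "paper_faithful")) {
    cat("  (feature selection on the full cohort: optimistically biased;\n",
        "  use mode = \"nested\" for leakage-controlled estimates)\n")
  }
  invisible(x)
}

#' Leave-one-out cross-validation of the feature-ranked classifier
#'
#' Each subject in turn is held out; a linear SVM is trained on the z-scored
#' top-`p` features of the remaining subjects and predicts the held-out
#' subject. Two feature-selection protocols are offered:
#' `mode = "nested"` (default) reruns [bootstrap_wscore_star()] and
#' [select_top()] inside every training fold, so the held-out subject never
#' influences which features are used -- the unbiased protocol.
#' `mode = "paper_faithful"` selects features once on the full cohort before
#' the folds; this reproduces the common pre-selection protocol but lets the
#' test subject leak into selection and is optimistically biased on null data.
#'
#' @param fm A [feature_matrix()] with >= 4 subjects, both classes present.
#' @param p Number of features fed to the classifier (default 30).
#' @param mode `"nested"` or `"paper_faithful"`.
#' @param n_boot Bootstrap replicates for the ranking stage (default 1000).
#' @param seed Integer seed (per-fold ranking seeds are derived from it).
#' @param classifier `"svm"` (default) or `"knn"`.
#' @param cost Linear-SVM regularisation constant C (default 1).
#' @param positive Positive-class label for sensitivity (default `"patient"`).
#' @return A `cv_result` with aggregate metrics and per-fold detail.
#' @export
loocv <- function(fm, p = 30, mode = c("nested", "paper_faithful"),
                  n_boot = 1000, seed = 1, classifier = "svm", cost = 1,
                  positive = "patient") {
  stopifnot(inherits(fm, "feature_matrix"), nrow(fm$features) >= 4L)
  mode <- match.arg(mode)
  n <- nrow(fm$features)
  seeds <- child_seeds(seed, n + 1L)
  sel_full <- NULL
  if (mode == "paper_faithful") {
    tab <- bootstrap_wscore_star(fm, n_boot = n_boot, seed = seeds[n + 1L])
    sel_full <- select_top(tab, p)
  }
  per_fold <- vector("list", n)
  for (i in seq_len(n)) {
    tr_lab <- fm$labels[-i]
    if (length(unique(tr_lab)) < 2L) {
      warning(sprintf("fold %d skipped: training fold lost a class", i))
      next
    }
    sel <- if (mode == "nested") {
      fm_tr <- feature_matrix(fm$features[-i, , drop = FALSE], tr_lab, fm$ids)
      select_top(bootstrap_wscore_star(fm_tr, n_boot = n_boot,
                                       seed = seeds[i]), p)
    } else {
      sel_full
    }
    pred <- fit_predict(fm$features[-i, sel, drop = FALSE], tr_lab,
                        fm$features[i, sel, drop = FALSE],
                        classifier = classifier, cost = cost)
    per_fold[[i]] <- list(test = i, pred = pred, truth = fm$labels[i],
                          selected = names(sel))
  }
  per_fold <- per_fold[!vapply(per_fold, is.null, TRUE)]
  make_cv_result("loocv", per_fold, positive,
                 list(mode = mode, p = p, seed = seed))
}

# Class-stratified test-fold indices of size n_test (largest-remainder split).
stratified_test_fold <- function(labels, n_test) {
  classes <- sort(unique(labels))
  n <- length(labels)
  quota <- n_test * table(labels)[classes] / n
  base <- floor(quota)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  unlist(lapply(seq_along(classes), function(k) {
    idx <- which(labels == classes[k])
    sample(idx, base[k])
  }), use.names = FALSE)
}

#' Repeated random-split cross-validation
#'
#' Repeatedly splits the cohort into a training set of `train_n` subjects and
#' a test fold of the rest (class-stratified by default, e.g. 3 patients +
#' 2 controls out of a 25/15 cohort when `n - train_n = 5`), trains the
#' ranked-feature classifier on the training set and predicts the test fold.
#' Mean accuracy, sensitivity and specificity over repeats are reported;
#' repeats whose (unstratified) test fold misses a class contribute to
#' accuracy only, with a logged count.
#'
#' @inheritParams loocv
#' @param train_n Training-set size (default 35).
#' @param n_repeats Number of random splits (default 200).
#' @param stratified Class-stratified splits (default `TRUE`).
#' @return A `cv_result`; `accuracy`/`sensitivity`/`specificity` are means
#'   over repeats.
#' @export
repeated_split <- function(fm, p = 30, train_n = 35, n_repeats = 200,
                           seed = 1, mode = c("nested", "paper_faithful"),
                           n_boot = 1000, stratified = TRUE,
                           classifier = "svm", cost = 1,
                           positive = "patient") {
  stopifnot(inherits(fm, "feature_matrix"))
  mode <- match.arg(mode)
  n <- nrow(fm$features)
  if (train_n >= n) stop("train_n must be smaller than the cohort")
  n_test <- n - train_n
  seeds <- child_seeds(seed, 2L * n_repeats + 1L)
  sel_full <- NULL
  if (mode == "paper_faithful") {
    tab <- bootstrap_wscore_star(fm, n_boot = n_boot,
                                 seed = seeds[2L * n_repeats + 1L])
    sel_full <- select_top(tab, p)
  }
  per_fold <- vector("list", n_repeats)
  acc <- sens <- spec <- rep(NA_real_, n_repeats)
  n_partial <- 0L
  for (r in seq_len(n_repeats)) {
    test <- with_seed(seeds[r], {
      if (stratified) stratified_test_fold(fm$labels, n_test)
      else sample(n, n_test)
    })
    tr <- setdiff(seq_len(n), test)
    tr_lab <- fm$labels[tr]
    if (length(unique(tr_lab)) < 2L) {
      warning(sprintf("repeat %d skipped: training set lost a class", r))
      next
    }
    sel <- if (mode == "nested") {
      fm_tr <- feature_matrix(fm$features[tr, , drop = FALSE], tr_lab, fm$ids)
      select_top(bootstrap_wscore_star(fm_tr, n_boot = n_boot,
                                       seed = seeds[n_repeats + r]), p)
    } else {
      sel_full
    }
    pred <- fit_predict(fm$features[tr, sel, drop = FALSE], tr_lab,
                        fm$features[test, sel, drop = FALSE],
                        classifier = classifier, cost = cost)
    m <- confusion_metrics(pred, fm$labels[test], positive)
    acc[r] <- m$accuracy
    sens[r] <- m$sensitivity
    spec[r] <- m$specificity
    if (is.na(m$sensitivity) || is.na(m$specificity)) {
      n_partial <- n_partial + 1L
    }
    per_fold[[r]] <- list(test = test, pred = pred, truth = fm$labels[test])
  }
  if (n_partial > 0L) {
    message(sprintf(
      "repeated_split: %d repeat(s) missed a class in the test fold; %s",
      n_partial, "their sensitivity/specificity were excluded from the means"))
  }
  per_fold <- per_fold[!vapply(per_fold, is.null, TRUE)]
  structure(
    list(scheme = "repeated_split",
         accuracy = mean(acc, na.rm = TRUE),
         sensitivity = mean(sens, na.rm = TRUE),
         specificity = mean(spec, na.rm = TRUE),
         per_fold = per_fold, n_repeats = n_repeats, seed = seed,
         mode = mode, p = p),
    class = "cv_result"
  )
}
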