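# Linear SVM recursive feature elimination (RFE) with repeated
# cross-validation stability selection. Features are ranked by the squared
# weight they receive in the linear decision function (Guyon's criterion),
# which operationalizes "contribution to the separating hyper-plane"; 5% of
# the current subset is eliminated per iteration until no feature remains,
# and the best-performing visited subset is kept.

#' Fit a soft-margin linear SVM
#'
#' Thin wrapper around a standard hinge-loss linear SVM solver returning
#' the primal weight vector and bias of the decision function
#' `sign(w . x + b)`, where positive decision values vote for the second
#' factor level of `y`. Deterministic for fixed input.
#'
#' @param x Numeric matrix (samples x features), complete.
#' @param y Two-level factor (or vector coercible to one).
#' @param cost Soft-margin cost parameter C, default 1.
#' @return List with `weights` (named per-feature vector), `bias`, and
#'   `model` (the underlying fit, usable with `predict`).
#' @export
fit_linear_svm <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) {
    stopf("fit_linear_svm: need exactly 2 classes, got %d", nlevels(y))
  }
  fit <- e1071::svm(x = x, y = y, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  names(w) <- colnames(x)
  b <- -fit$rho
  # libsvm orients its decision values towards the class of the first
  # training sample; normalize so positive values vote for the SECOND
  # factor level, using the stored fitted classes to detect the
  # orientation of this particular fit
  dv <- drop(x %*% w) + b
  i <- which.max(abs(dv))
  if (abs(dv[i]) > 0 &&
      (dv[i] > 0) != (as.character(stats::fitted(fit)[i]) == levels(y)[2L])) {
    w <- -w
    b <- -b
  }
  list(weights = w, bias = b, model = fit)
}

#' Decision values of a fitted linear SVM
#' @param svm_fit Result of [fit_linear_svm()].
#' @param x New data matrix with the same feature columns.
#' @return Numeric vector of signed distances (positive = second level).
#' @export
svm_decision_values <- function(svm_fit, x) {
  drop(as.matrix(x) %*% svm_fit$weights) + svm_fit$bias
}

# one RFE iteration worth of cross-validation: for each fold, scale on the
# training part only (no leakage), fit a linear SVM, score the held-out
# part, and accumulate the squared primal weights of the fold-trained
# models. Returns the CV accuracy and the summed w^2 ranking criterion, so
# feature ranking is driven by training data alone.
cv_fit_and_rank <- function(x, y, fold, cost) {
  correct <- 0L
  w2 <- numeric(ncol(x))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    xtr <- x[tr, , drop = FALSE]
    ctr <- colMeans(xtr)
    sds <- apply(xtr, 2L, stats::sd)
    sds[sds == 0 | is.na(sds)] <- 1
    xtr <- sweep(sweep(xtr, 2L, ctr), 2L, sds, "/")
    xte <- sweep(sweep(x[!tr, , drop = FALSE], 2L, ctr), 2L, sds, "/")
    fit <- e1071::svm(x = xtr, y = droplevels(as.factor(y[tr])),
                      kernel = "linear", cost = cost, scale = FALSE)
    w <- drop(crossprod(fit$coefs, fit$SV))
    w2 <- w2 + w^2
    pred <- stats::predict(fit, xte)
    correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
  }
  list(accuracy = correct / length(y), w2 = w2)
}

#' Recursive feature elimination path
#'
#' Starting from all features, each iteration fits a linear SVM per
#' training fold of a stratified partition, records the cross-validated
#' accuracy of the current subset, ranks features by the squared weight
#' they receive in the fold-trained models (summed over folds, so ranking
#' never sees held-out samples), and removes the
#' `max(1, floor(drop_fraction * subset size))` lowest-ranked features,
#' until the subset is empty. The best-performing subset is the largest one
#' achieving the maximum accuracy (accuracy ties along the path are broken
#' towards the earlier, larger subset; see the package vignette).
#'
#' @param x Numeric matrix (samples x features), at least 2 features.
#' @param y Two-level class labels; each class needs at least `inner_folds`
#'   members.
#' @param drop_fraction Fraction of the current subset eliminated per
#'   iteration, default 0.05.
#' @param inner_folds Folds for the accuracy estimate, default 3.
#' @param seed Optional seed for the fold draw (ignored when `folds` given).
#' @param folds Optional precomputed fold assignment (integer vector), as
#'   supplied by [stability_select()].
#' @param cost SVM cost, default 1.
#' @return An object of class `rfe_path`: `subsets` (list of feature-name
#'   vectors, strictly decreasing in size), `accuracy` (per subset),
#'   `best` (index of the best subset), `best_subset`, `best_accuracy`.
#' @export
rfe_path <- function(x, y, drop_fraction = 0.05, inner_folds = 3L,
                     seed = NULL, folds = NULL, cost = 1) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  y <- droplevels(as.factor(y))
  if (ncol(x) < 2L) stopf("rfe_path: need at least 2 features")
  if (nlevels(y) != 2L) stopf("rfe_path: need exactly 2 classes")
  if (min(table(y)) < inner_folds) {
    stopf("rfe_path: smallest class (%d) has fewer members than inner_folds (%d)",
          min(table(y)), inner_folds)
  }
  if (is.null(folds)) {
    folds <- with_local_seed(seed, stratified_folds(y, inner_folds))
  }

  current <- colnames(x)
  subsets <- list()
  accuracy <- numeric(0)
  while (length(current) > 0L) {
    xs <- x[, current, drop = FALSE]
    subsets[[length(subsets) + 1L]] <- current
    it <- cv_fit_and_rank(xs, y, folds, cost)
    accuracy[length(subsets)] <- it$accuracy
    if (length(current) == 1L) break
    n_drop <- max(1L, floor(drop_fraction * length(current)))
    current <- current[order(it$w2, decreasing = TRUE)][
      seq_len(length(current) - n_drop)]
  }
  best <- which.max(accuracy)   # first max = largest subset
  structure(list(subsets = subsets, accuracy = accuracy, best = best,
                 best_subset = subsets[[best]],
                 best_accuracy = accuracy[best]),
            class = "rfe_path")
}

#' SVM-RFE stability selection over repeated cross-validation
#'
#' Repeats `n_repeats` times: draw a fresh stratified `k_folds` partition,
#' run the full [rfe_path()] with that partition as the accuracy
#' cross-validation, and record the best-performing subset and its
#' accuracy. A feature's selection frequency is the fraction of repetitions
#' whose best subset contains it; features with frequency at or above
#' `threshold` are selected. Classification performance is summarized as
#' the mean and sample SD of the per-repetition accuracies, in percent.
#' Fully reproducible from `seed`.
#'
#' @param x Numeric matrix (samples x features).
#' @param y Two-level class labels; class sizes must be >= `k_folds`.
#' @param n_repeats Number of repetitions, default 100.
#' @param k_folds Cross-validation folds per repetition, default 3.
#' @param threshold Selection-frequency cutoff, default 0.8.
#' @param seed Integer seed.
#' @param drop_fraction,cost Passed to [rfe_path()].
#' @param contrast Optional label recorded in the result.
#' @return An object of class `selection_result`: `frequency` (named,
#'   multiples of `1/n_repeats`), `selected` (names with frequency >=
#'   threshold), `accuracy_mean`, `accuracy_sd` (percent), `n_repeats`,
#'   `k_folds`, `threshold`, `contrast`.
#' @export
stability_select <- function(x, y, n_repeats = 100L, k_folds = 3L,
                             threshold = 0.8, seed = 1L,
                             drop_fraction = 0.05, cost = 1,
                             contrast = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stopf("stability_select: need exactly 2 classes")
  if (min(table(y)) < k_folds) {
    stopf("stability_select: smallest class (%d) smaller than k_folds (%d)",
          min(table(y)), k_folds)
  }
  counts <- stats::setNames(numeric(ncol(x)), colnames(x))
  acc <- numeric(n_repeats)
  with_local_seed(seed, {
    for (r in seq_len(n_repeats)) {
      folds <- stratified_folds(y, k_folds)
      path <- tryCatch(
        rfe_path(x, y, drop_fraction = drop_fraction, folds = folds,
                 inner_folds = k_folds, cost = cost),
        error = function(e) stopf("stability_select: repetition %d failed: %s",
                                  r, conditionMessage(e)))
      counts[path$best_subset] <- counts[path$best_subset] + 1
      acc[r] <- path$best_accuracy
    }
  })
  frequency <- counts / n_repeats
  structure(list(
    contrast = contrast,
    frequency = frequency,
    selected = names(frequency)[frequency >= threshold],
    accuracy_mean = 100 * mean(acc),
    accuracy_sd = 100 * stats::sd(acc),
    n_repeats = as.integer(n_repeats),
    k_folds = as.integer(k_folds),
    threshold = threshold),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("SVM-RFE stability selection%s\n",
              if (!is.null(x$contrast)) paste0(" [", x$contrast, "]") else ""))
  cat(sprintf("  %d x %d-fold CV; frequency threshold %.2f\n",
              x$n_repeats, x$k_folds, x$threshold))
  cat(sprintf("  selected features: %d of %d\n", length(x$selected),
              length(x$frequency)))
  cat(sprintf("  accuracy: %.2f%% +/- %.2f%%\n", x$accuracy_mean, x$accuracy_sd))
  invisible(x)
}

#' Write selection frequencies to CSV
#' @param result A `selection_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_result <- function(result, path) {
  df <- data.frame(metabolite = names(result$frequency),
                   frequency = unname(result$frequency),
                   selected = as.integer(names(result$frequency) %in% result$selected),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
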