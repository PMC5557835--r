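# NIPALS principal component analysis with cumulative explained variance
# (R2X) and row-wise cross-validated predicted variance (Q2), the two
# figures of merit conventionally quoted for metabolomics PCA models.

nipals_component <- function(x, max_iter, tol, t_prev = NULL) {
  # start from the column with the largest variance; t_prev holds the
  # orthonormalized earlier scores, against which each iterate is
  # re-orthogonalized (Gram-Schmidt) so finite convergence cannot leak
  # correlation between components
  v <- apply(x, 2L, stats::var)
  t_ <- x[, which.max(v)]
  if (all(abs(t_) < .Machine$double.eps)) t_ <- x[, 1L] + 1e-12
  for (iter in seq_len(max_iter)) {
    p <- crossprod(x, t_) / sum(t_ * t_)
    p <- p / sqrt(sum(p * p))
    t_new <- x %*% p
    if (!is.null(t_prev)) {
      t_new <- t_new - t_prev %*% crossprod(t_prev, t_new)
    }
    delta <- sum((t_new - t_)^2) / max(sum(t_new^2), .Machine$double.eps)
    t_ <- t_new
    if (delta < tol) {
      # deterministic sign: largest-magnitude loading is positive
      s <- sign(p[which.max(abs(p))])
      return(list(t = as.numeric(t_) * s, p = as.numeric(p) * s))
    }
  }
  NULL
}

#' Fit a PCA model by NIPALS
#'
#' Sequentially extracts components maximizing explained variance from an
#' already centred (typically UV-scaled) complete matrix. `r2x[k]` is the
#' cumulative fraction of total sum of squares explained after k
#' components. `q2[k]` is the cross-validated analogue: rows are split into
#' `cv_folds` contiguous-interleaved folds, the model is refit without each
#' fold, held-out rows are projected onto the fold model's loadings
#' (regression on loadings), and `q2[k] = 1 - PRESS(k) / totalSS`.
#'
#' @param x Complete numeric matrix, samples in rows; should already be
#'   UV-scaled (see [uv_scale()]).
#' @param n_components Number of components, at most `min(nrow - 1, ncol)`.
#' @param cv_folds Folds for the Q2 cross-validation (default 7). Fold
#'   membership is deterministic (row index modulo fold count).
#' @param max_iter,tol NIPALS iteration cap and relative convergence
#'   tolerance.
#' @return An object of class `pca_model`: `scores` (n x k), `loadings`
#'   (p x k, orthonormal columns), `r2x`, `q2` (cumulative vectors) and
#'   `n_components`.
#' @export
fit_pca <- function(x, n_components = 2L, cv_folds = 7L, max_iter = 5000L,
                    tol = 1e-16) {
  x <- as.matrix(x)
  if (anyNA(x)) stopf("fit_pca: matrix contains missing values")
  n_components <- as.integer(n_components)
  if (n_components > min(nrow(x) - 1L, ncol(x))) {
    stopf("fit_pca: n_components must be <= min(rows - 1, columns) = %d",
          min(nrow(x) - 1L, ncol(x)))
  }
  total_ss <- sum(x^2)
  res <- x
  scores <- matrix(0, nrow(x), n_components)
  loadings <- matrix(0, ncol(x), n_components,
                     dimnames = list(colnames(x), NULL))
  r2x <- numeric(n_components)
  t_prev <- NULL
  for (k in seq_len(n_components)) {
    comp <- nipals_component(res, max_iter, tol, t_prev)
    if (is.null(comp)) {
      stopf("fit_pca: NIPALS did not converge for component %d within %d iterations",
            k, max_iter)
    }
    scores[, k] <- comp$t
    loadings[, k] <- comp$p
    t_prev <- cbind(t_prev, comp$t / sqrt(sum(comp$t^2)))
    res <- res - tcrossprod(comp$t, comp$p)
    r2x[k] <- 1 - sum(res^2) / total_ss
  }

  q2 <- pca_q2(x, n_components, cv_folds, max_iter, tol)

  structure(list(scores = scores, loadings = loadings, r2x = r2x, q2 = q2,
                 n_components = n_components),
            class = "pca_model")
}

# row-wise K-fold PRESS: refit NIPALS without each fold, predict held-out
# rows from their projection onto the fold loadings
pca_q2 <- function(x, n_components, cv_folds, max_iter, tol) {
  n <- nrow(x)
  cv_folds <- min(cv_folds, n)
  fold <- rep_len(seq_len(cv_folds), n)
  press <- numeric(n_components)
  for (f in seq_len(cv_folds)) {
    hold <- fold == f
    res_train <- x[!hold, , drop = FALSE]
    res_hold <- x[hold, , drop = FALSE]
    t_prev <- NULL
    for (k in seq_len(n_components)) {
      comp <- nipals_component(res_train, max_iter, tol, t_prev)
      if (is.null(comp)) {
        stopf("fit_pca: NIPALS did not converge for component %d (fold %d)", k, f)
      }
      t_hold <- res_hold %*% comp$p
      res_hold <- res_hold - tcrossprod(t_hold, comp$p)
      res_train <- res_train - tcrossprod(comp$t, comp$p)
      t_prev <- cbind(t_prev, comp$t / sqrt(sum(comp$t^2)))
      press[k] <- press[k] + sum(res_hold^2)
    }
  }
  1 - press / sum(x^2)
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA model (NIPALS), %d component(s)\n", x$n_components))
  cat("  cumulative R2X:", paste(sprintf("%.3f", x$r2x), collapse = ", "), "\n")
  cat("  cumulative Q2: ", paste(sprintf("%.3f", x$q2), collapse = ", "), "\n")
  invisible(x)
}
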