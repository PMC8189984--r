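#' Leave-one-out cross-validated RMSE
#'
#' Removes one sample at a time, refits the model on the remaining samples
#' with `fit_fun`, predicts the held-out sample, and returns
#' `sqrt(mean((y_i - yhat_(-i))^2))` over all folds.
#'
#' @param fit_fun function `(X, y) -> model`.
#' @param X samples x features matrix.
#' @param y numeric response (n >= 3).
#' @param predict_fun function `(model, newX) -> prediction` (defaults to
#'   [predict()]).
#' @return RMSECV as a numeric scalar (same units as `y`, here % structure).
#' @export
loo_rmsecv <- function(fit_fun, X, y, predict_fun = stats::predict) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out needs n >= 3")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  preds <- vapply(seq_len(n), function(i) {
    tryCatch(
      as.numeric(predict_fun(fit_fun(X[-i, , drop = FALSE], y[-i]),
                             X[i, , drop = FALSE]))[1L],
      error = function(e) stop("fit failure in fold ", i, ": ",
                               conditionMessage(e))
    )
  }, numeric(1))
  sqrt(mean((y - preds)^2))
}

#' Standard deviation of the reference structure content
#'
#' The sample standard deviation (n - 1 denominator) of the reference values;
#' the prediction error that guessing the set mean for every protein would
#' give.
#'
#' @param y numeric reference contents (%), `n >= 2`.
#' @return Numeric scalar (%).
#' @export
stddev_ref <- function(y) {
  if (length(y) < 2L) stop("need at least 2 reference values")
  stats::sd(y)
}

#' Prediction-efficiency ratio zeta
#'
#' `zeta = stddev_ref / rmse`: how much better the spectroscopic model
#' predicts than guessing the set mean (1 = no better). Reported rounded to
#' 2 decimals; the full-precision ratio is returned.
#'
#' @param stddev_ref standard deviation of the reference contents (%).
#' @param rmse prediction error (RMSECV or test-set RMSE, %), > 0.
#' @return Numeric scalar (dimensionless).
#' @examples
#' round(zeta(17.94, 5.68), 2)  # 3.16
#' @export
zeta <- function(stddev_ref, rmse) {
  if (!is.finite(rmse) || rmse <= 0) stop("rmse must be > 0")
  stddev_ref / rmse
}

#' Kennard-Stone selection of a uniformly covering subset
#'
#' Classic max-min selection: the two mutually most distant samples seed the
#' subset, then the sample with the largest minimum distance to the selected
#' set is added repeatedly. Deterministic; all ties resolve to the lowest
#' sample index. By default operates on the 1-D reference structure content
#' (each structure's test set is selected independently); `values` may also
#' be a matrix of spectra, in which case Euclidean distance in spectral
#' space is used.
#'
#' @param values numeric vector (1-D reference content) or samples x features
#'   matrix.
#' @param n_select number of samples to select (the test set; default 25).
#' @return An object of class `ks_split`: `test_indices` (in selection
#'   order), `train_indices` (ascending) and `n`.
#' @export
kennard_stone_select <- function(values, n_select = 25L) {
  M <- if (is.matrix(values)) values else matrix(as.numeric(values), ncol = 1L)
  n <- nrow(M)
  n_select <- as.integer(n_select)
  if (n_select < 1L || n_select > n) stop("n_select must lie in 1..n")
  D <- as.matrix(stats::dist(M))
  if (n_select == 1L) {
    sel <- 1L
  } else {
    # seed: most distant pair, lowest indices on ties (column-major scan)
    flat <- which(D == max(D))[1L]
    i <- (flat - 1L) %% n + 1L
    j <- (flat - 1L) %/% n + 1L
    sel <- sort(c(i, j))
    while (length(sel) < n_select) {
      rest <- setdiff(seq_len(n), sel)
      dmin <- apply(D[rest, sel, drop = FALSE], 1L, min)
      sel <- c(sel, rest[which.max(dmin)])
    }
  }
  structure(
    list(test_indices = sel,
         train_indices = setdiff(seq_len(n), sel),
         n = n),
    class = "ks_split"
  )
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("<ks_split> %d test / %d train of %d samples\n",
              length(x$test_indices), length(x$train_indices), x$n))
  invisible(x)
}
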