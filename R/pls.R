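#' Partial least squares regression (NIPALS)
#'
#' Univariate-response PLS fitted by the NIPALS algorithm with mean centering
#' and no variance scaling (spectra are already vector-normalized).
#' Deterministic; with `n_lv` equal to the number of features on full-rank
#' tall data, the fit coincides with ordinary least squares.
#'
#' @param X numeric matrix, samples x features (no NA).
#' @param y numeric response (structure content, %).
#' @param n_lv number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @param interval optional label of the wavenumber block the model was
#'   trained on (bookkeeping only).
#' @return An object of class `pls_model` carrying weights `W`, loadings `P`,
#'   response loadings `q`, centering vectors and the coefficient path.
#' @export
fit_pls <- function(X, y, n_lv, interval = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (anyNA(X) || anyNA(y)) stop("NA values in X or y")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n_lv < 1L || n_lv > min(n - 1L, p)) {
    stop(sprintf("n_lv must lie in 1..min(n-1, p) = 1..%d", min(n - 1L, p)))
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  W <- matrix(0, p, n_lv)
  P <- matrix(0, p, n_lv)
  q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xc, yc)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12 * max(1, sqrt(sum(yc^2)))) {
      stop(sprintf("rank error: residual X carries no covariance with y at LV %d",
                   a))
    }
    w <- w / wn
    t_ <- Xc %*% w
    tt <- sum(t_^2)
    if (tt < .Machine$double.eps) stop(sprintf("rank error at LV %d", a))
    p_a <- crossprod(Xc, t_) / tt
    q[a] <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p_a)
    yc <- yc - q[a] * t_
    W[, a] <- w
    P[, a] <- p_a
  }
  structure(
    list(n_lv = n_lv, W = W, P = P, q = q, x_mean = x_mean, y_mean = y_mean,
         interval = interval),
    class = "pls_model"
  )
}

# Regression coefficients using the first `a` latent variables.
.pls_coef <- function(m, a = m$n_lv) {
  Wa <- m$W[, seq_len(a), drop = FALSE]
  Pa <- m$P[, seq_len(a), drop = FALSE]
  b <- Wa %*% solve(crossprod(Pa, Wa), m$q[seq_len(a)])
  list(b = as.numeric(b), b0 = m$y_mean - sum(m$x_mean * b))
}

#' @param object a `pls_model`.
#' @param newdata numeric matrix of samples x features.
#' @param n_lv number of latent variables to use (defaults to the fitted
#'   count; any smaller value reuses the same decomposition).
#' @param ... unused.
#' @rdname fit_pls
#' @export
predict.pls_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  newdata <- matrix(as.numeric(newdata), ncol = length(object$x_mean))
  co <- .pls_coef(object, n_lv)
  as.numeric(newdata %*% co$b + co$b0)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variable(s), %d features%s\n",
              x$n_lv, nrow(x$W),
              if (is.null(x$interval)) "" else paste0(", interval ", x$interval)))
  invisible(x)
}

#' Leave-one-out RMSECV profile of PLS over a latent-variable range
#'
#' For each left-out sample, one PLS decomposition at `max(lv_range)` latent
#' variables yields the nested predictions for every smaller count, giving
#' the full RMSECV-vs-LV profile in one pass over the folds.
#'
#' @param X samples x features matrix.
#' @param y response vector.
#' @param lv_range integer vector of latent-variable counts to evaluate;
#'   `max(lv_range)` must be `< n - 1`.
#' @return Named numeric vector of RMSECV (%) per latent-variable count.
#' @export
pls_loo_profile <- function(X, y, lv_range = 1:10) {
  X <- as.matrix(X)
  n <- nrow(X)
  lv_range <- sort(unique(as.integer(lv_range)))
  if (max(lv_range) >= n - 1L) {
    stop("range error: max(lv_range) must be smaller than n - 1")
  }
  if (max(lv_range) > ncol(X)) {
    stop("range error: max(lv_range) exceeds the number of features")
  }
  preds <- matrix(NA_real_, n, length(lv_range))
  for (i in seq_len(n)) {
    # on rank-limited (e.g. noiseless) data, fall back to the largest
    # reachable decomposition; larger LV counts reuse it (profile flattens)
    a_max <- max(lv_range)
    m <- NULL
    while (is.null(m) && a_max >= 1L) {
      m <- tryCatch(fit_pls(X[-i, , drop = FALSE], y[-i], a_max),
                    error = function(e) NULL)
      if (is.null(m)) a_max <- a_max - 1L
    }
    if (is.null(m)) stop("PLS failed in fold ", i)
    preds[i, ] <- vapply(
      lv_range, function(a) predict(m, X[i, , drop = FALSE],
                                    n_lv = min(a, a_max)),
      numeric(1)
    )
  }
  rmse <- sqrt(colMeans((preds - y)^2))
  stats::setNames(rmse, as.character(lv_range))
}

#' Interval PLS scan
#'
#' Evaluates an independent PLS model per spectral interval of a concatenated
#' feature matrix: for every interval and every latent-variable count in
#' `lv_range`, the leave-one-out RMSECV is computed; the best count per
#' interval is the argmin (ties resolved toward fewer latent variables).
#'
#' @param X samples x features matrix (e.g. concatenated timepoint blocks).
#' @param y response vector (structure content, %).
#' @param intervals list of integer column-index vectors partitioning the
#'   feature axis, or a single integer number of equal consecutive blocks
#'   (default 4, the HDX timepoint blocks).
#' @param lv_range latent-variable counts to scan.
#' @return A data.frame with one row per interval (`interval`, `best_lv`,
#'   `rmsecv`); the full RMSECV matrix (LV x interval) is attached as
#'   attribute `profile`.
#' @export
ipls_scan <- function(X, y, intervals = 4L, lv_range = 1:10) {
  X <- as.matrix(X)
  if (is.numeric(intervals) && length(intervals) == 1L) {
    k <- as.integer(intervals)
    if (ncol(X) %% k != 0L) stop("feature count not divisible into equal blocks")
    bl <- ncol(X) %/% k
    intervals <- lapply(seq_len(k), function(b) ((b - 1L) * bl + 1L):(b * bl))
  }
  idx <- sort(unlist(intervals))
  if (length(idx) != ncol(X) || any(idx != seq_len(ncol(X)))) {
    stop("intervals must partition the feature axis")
  }
  prof <- sapply(intervals, function(cols) {
    pls_loo_profile(X[, cols, drop = FALSE], y, lv_range)
  })
  prof <- matrix(prof, nrow = length(lv_range),
                 dimnames = list(as.character(lv_range), NULL))
  best <- apply(prof, 2L, which.min)  # first minimum = fewest LVs on ties
  out <- data.frame(
    interval = seq_along(intervals),
    best_lv = lv_range[best],
    rmsecv = prof[cbind(best, seq_along(intervals))]
  )
  attr(out, "profile") <- prof
  out
}
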