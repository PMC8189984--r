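# Squared Euclidean distances between rows of A and rows of B.
.sqdist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d[d < 0] <- 0
  d
}

.rbf_kernel <- function(A, B, sigma2) exp(-.sqdist(A, B) / sigma2)

#' Least-squares support vector machine regression
#'
#' Fits LS-SVM regression with a radial basis function kernel
#' `K(x, x') = exp(-||x - x'||^2 / sigma2)` by solving the dual linear
#' system
#' \deqn{\begin{pmatrix} 0 & 1^\top \\ 1 & K + I/\gamma \end{pmatrix}
#'       \begin{pmatrix} b \\ \alpha \end{pmatrix} =
#'       \begin{pmatrix} 0 \\ y \end{pmatrix}}
#' where `gamma` is the regularization constant. Deterministic.
#'
#' @param X samples x features matrix.
#' @param y numeric response.
#' @param gamma regularization constant, > 0 (larger = closer to
#'   interpolation).
#' @param sigma2 RBF kernel width (squared length scale), > 0.
#' @return An object of class `lssvm_model` with dual coefficients `alpha`,
#'   bias `b`, the kernel parameters and the training features.
#' @export
fit_lssvm <- function(X, y, gamma = 10, sigma2 = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0")
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0")
  K <- .rbf_kernel(X, X, sigma2)
  A <- rbind(
    c(0, rep(1, n)),
    cbind(1, K + diag(n) / gamma)
  )
  z <- tryCatch(
    solve(A, c(0, y)),
    error = function(e) stop("conditioning error: LS-SVM system is singular (",
                             conditionMessage(e), ")")
  )
  structure(
    list(alpha = z[-1L], b = z[1L], gamma = gamma, sigma2 = sigma2, X = X),
    class = "lssvm_model"
  )
}

#' @param object an `lssvm_model`.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @rdname fit_lssvm
#' @export
predict.lssvm_model <- function(object, newdata, ...) {
  newdata <- matrix(as.numeric(newdata), ncol = ncol(object$X))
  as.numeric(.rbf_kernel(newdata, object$X, object$sigma2) %*% object$alpha +
               object$b)
}

#' @export
print.lssvm_model <- function(x, ...) {
  cat(sprintf("<lssvm_model> n = %d, gamma = %g, sigma2 = %g\n",
              nrow(x$X), x$gamma, x$sigma2))
  invisible(x)
}

# Closed-form leave-one-out residuals of LS-SVM: with the bordered system
# matrix A and solution (b, alpha), the LOO residual of sample i equals
# alpha_i / (A^-1)_{i+1, i+1} (Cawley-Talbot identity). Used to make the
# hyperparameter grid search affordable; equality with fold-by-fold refits
# is asserted in the test suite.
.lssvm_loo_rmse <- function(X, y, gamma, sigma2) {
  X <- as.matrix(X)
  n <- nrow(X)
  K <- .rbf_kernel(X, X, sigma2)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / gamma))
  Ai <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ai)) return(Inf)
  z <- Ai %*% c(0, y)
  alpha <- z[-1L]
  d <- diag(Ai)[-1L]
  sqrt(mean((alpha / d)^2))
}

#' Grid search of LS-SVM hyperparameters by leave-one-out RMSECV
#'
#' Scans a log-spaced grid of regularization constants and kernel widths,
#' scoring each pair by closed-form leave-one-out RMSECV, and returns the
#' winning pair together with the full grid (for the run report).
#'
#' @param X samples x features matrix.
#' @param y numeric response.
#' @param gammas,sigma2s candidate values (defaults: `10^(-1..4)` and
#'   `10^(-1..3)`).
#' @return List with `gamma`, `sigma2`, `rmsecv` of the best pair and the
#'   scored `grid` data.frame.
#' @export
lssvm_grid_search <- function(X, y, gammas = 10^(-1:4), sigma2s = 10^(-1:3)) {
  grid <- expand.grid(gamma = gammas, sigma2 = sigma2s)
  grid$rmsecv <- vapply(seq_len(nrow(grid)), function(k) {
    .lssvm_loo_rmse(X, y, grid$gamma[k], grid$sigma2[k])
  }, numeric(1))
  best <- which.min(grid$rmsecv)
  list(gamma = grid$gamma[best], sigma2 = grid$sigma2[best],
       rmsecv = grid$rmsecv[best], grid = grid)
}
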