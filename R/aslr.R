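# Leave-one-out RMSECV of an ordinary least-squares fit on design Z
# (including intercept column), via the PRESS identity e_loo = e / (1 - h).
# Returns Inf for rank-deficient designs or leverage-1 points.
.ols_loo_rmse <- function(Z, y) {
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) return(Inf)
  e <- qr.resid(qz, y)
  h <- rowSums(qr.Q(qz)[, seq_len(qz$rank), drop = FALSE]^2)
  if (any(h > 1 - 1e-10)) return(Inf)
  sqrt(mean((e / (1 - h))^2))
}

#' Ascending stepwise linear regression
#'
#' Greedy forward selection of single wavenumbers: at each step, every
#' not-yet-selected wavenumber is tried in a multiple linear regression
#' (with intercept) together with the already selected ones, scored by
#' leave-one-out RMSECV, and the argmin is retained. Ties resolve to the
#' first candidate along the (descending) wavenumber axis, i.e. the higher
#' wavenumber. The full RMSECV-vs-wavenumber profile of every step is kept
#' so the information content of the axis can be inspected.
#'
#' @param X samples x features matrix, columns ordered along the descending
#'   wavenumber axis.
#' @param y numeric response (structure content, %).
#' @param max_vars maximum number of wavenumbers to select (default 5).
#' @param wavenumbers optional numeric labels for the columns (e.g. cm^-1
#'   values, possibly repeated across concatenated timepoint blocks).
#' @return An object of class `aslr_model`: `selected` (column indices in
#'   order of relevance), `selected_wavenumbers`, `coefficients` and
#'   `intercept` of the final regression, `rmsecv` (per-step minima),
#'   `rmsecv_profile` (list of per-step candidate RMSECV vectors) and
#'   `dropped` (collinear candidates discarded, per step).
#' @export
fit_aslr <- function(X, y, max_vars = 5L, wavenumbers = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (max_vars < 1L) stop("max_vars must be >= 1")
  if (n <= max_vars + 1L) stop("need n_samples > max_vars + 1")
  if (!is.null(wavenumbers) && length(wavenumbers) != p) {
    stop("wavenumbers must label every column")
  }
  selected <- integer(0)
  step_min <- numeric(0)
  profiles <- vector("list", max_vars)
  dropped <- vector("list", max_vars)
  for (step in seq_len(max_vars)) {
    cand_rmse <- rep(NA_real_, p)
    for (j in setdiff(seq_len(p), selected)) {
      Z <- cbind(1, X[, c(selected, j), drop = FALSE])
      cand_rmse[j] <- .ols_loo_rmse(Z, y)
    }
    profiles[[step]] <- cand_rmse
    dropped[[step]] <- which(is.infinite(cand_rmse))
    if (all(!is.finite(cand_rmse) | is.na(cand_rmse))) {
      stop("no admissible candidate left at step ", step)
    }
    best <- which.min(cand_rmse)  # first index = higher wavenumber on ties
    selected <- c(selected, best)
    step_min <- c(step_min, cand_rmse[best])
  }
  fit <- stats::lm.fit(cbind(1, X[, selected, drop = FALSE]), y)
  structure(
    list(
      selected = selected,
      selected_wavenumbers = if (is.null(wavenumbers)) NULL
                             else wavenumbers[selected],
      intercept = unname(fit$coefficients[1L]),
      coefficients = unname(fit$coefficients[-1L]),
      rmsecv = step_min,
      rmsecv_profile = profiles,
      dropped = dropped
    ),
    class = "aslr_model"
  )
}

#' @param object an `aslr_model`.
#' @param newdata samples x features matrix with the same columns as the
#'   training matrix.
#' @param n_vars number of selected wavenumbers to use (default all); the
#'   truncated model is refitted on the stored coefficients' scale by the
#'   caller if needed -- here truncation simply drops trailing terms of the
#'   stepwise path and refits internally.
#' @param ... unused.
#' @rdname fit_aslr
#' @export
predict.aslr_model <- function(object, newdata, n_vars = length(object$selected),
                               ...) {
  newdata <- as.matrix(newdata)
  sel <- object$selected[seq_len(n_vars)]
  if (n_vars == length(object$selected)) {
    b0 <- object$intercept
    b <- object$coefficients
  } else {
    stop("predict with truncated n_vars requires refitting; use fit_aslr with",
         " a smaller max_vars")
  }
  as.numeric(newdata[, sel, drop = FALSE] %*% b + b0)
}

#' @export
print.aslr_model <- function(x, ...) {
  cat(sprintf(
    "<aslr_model> %d wavenumber(s) selected%s; RMSECV path: %s\n",
    length(x$selected),
    if (is.null(x$selected_wavenumbers)) ""
    else paste0(" (", paste(round(x$selected_wavenumbers, 1), collapse = ", "),
                " cm-1)"),
    paste(round(x$rmsecv, 3), collapse = " -> ")
  ))
  invisible(x)
}

#' Export ASLR RMSECV profiles as a CSV table
#'
#' One row per candidate wavenumber, one column per selection step -- the
#' per-step RMSECV curves over the whole axis.
#'
#' @param model an `aslr_model`.
#' @param path output CSV path.
#' @param wavenumbers optional axis labels (defaults to the model's, or
#'   column indices).
#' @return `path`, invisibly.
#' @export
write_aslr_profile <- function(model, path, wavenumbers = NULL) {
  np <- length(model$rmsecv_profile[[1L]])
  if (is.null(wavenumbers)) wavenumbers <- seq_len(np)
  df <- data.frame(wavenumber = wavenumbers)
  for (k in seq_along(model$rmsecv_profile)) {
    df[[paste0("step", k)]] <- model$rmsecv_profile[[k]]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
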