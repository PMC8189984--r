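test_that("PLS recovers single-factor data and reduces to OLS at full rank", {
  set.seed(11)
  # rank-1 X with y collinear to the single factor
  t1 <- rnorm(20)
  p1 <- rnorm(8)
  X1 <- tcrossprod(t1, p1)
  y1 <- 3 * t1 + 2
  m1 <- fit_pls(X1, y1, 1)
  expect_equal(predict(m1, X1), y1, tolerance = 1e-10)
  # full-rank tall X at n_lv = p equals the OLS oracle
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- as.numeric(X %*% rnorm(6) + rnorm(40))
  m <- fit_pls(X, y, 6)
  expect_lt(max(abs(predict(m, X) - ols_oracle_predict(X, y, X))), 1e-8)
  # shifting y by a constant shifts every prediction by that constant
  mc <- fit_pls(X, y + 17.5, 6)
  expect_equal(predict(mc, X), predict(m, X) + 17.5, tolerance = 1e-8)
  # latent-variable count validation
  expect_error(fit_pls(X, y, 0), "n_lv")
  expect_error(fit_pls(X, y, 7), "n_lv")
  expect_error(fit_pls(X1, y1, 5), "rank")
})

test_that("PLS models are deterministic and support nested LV prediction", {
  set.seed(12)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- as.numeric(X[, 1] - 0.5 * X[, 4] + rnorm(30, 0, 0.1))
  m1 <- fit_pls(X, y, 5)
  m2 <- fit_pls(X, y, 5)
  expect_identical(predict(m1, X), predict(m2, X))
  m3 <- fit_pls(X, y, 3)
  expect_equal(predict(m1, X, n_lv = 3), predict(m3, X), tolerance = 1e-10)
})

test_that("interval PLS scan matches an independent exhaustive re-scan", {
  set.seed(13)
  n <- 24
  # block 1 carries the y-correlated band, block 2 is pure noise
  amp <- runif(n, 0, 1)
  nu <- seq_len(30)
  band <- exp(-(nu - 15)^2 / 18)
  B1 <- outer(amp, band) + matrix(rnorm(n * 30, 0, 0.02), n)
  B2 <- matrix(rnorm(n * 30, 0, 0.5), n)
  X <- cbind(B1, B2)
  y <- 100 * amp
  sc <- ipls_scan(X, y, intervals = list(1:30, 31:60), lv_range = 1:4)
  expect_lt(sc$rmsecv[1], sc$rmsecv[2] / 5)
  # brute-force oracle: explicit fold loop per interval and LV count
  for (iv in 1:2) {
    cols <- list(1:30, 31:60)[[iv]]
    rm <- vapply(1:4, function(a) {
      preds <- vapply(seq_len(n), function(i) {
        m <- fit_pls(X[-i, cols, drop = FALSE], y[-i], a)
        predict(m, X[i, cols, drop = FALSE])
      }, numeric(1))
      sqrt(mean((y - preds)^2))
    }, numeric(1))
    expect_equal(unname(attr(sc, "profile")[, iv]), rm, tolerance = 1e-10)
    expect_identical(sc$best_lv[iv], (1:4)[which.min(rm)])
  }
  # a single all-spanning interval is plain PLS LOO
  sc1 <- ipls_scan(X, y, intervals = list(1:60), lv_range = 1:3)
  expect_equal(unname(attr(sc1, "profile")[, 1]),
               unname(pls_loo_profile(X, y, 1:3)), tolerance = 1e-12)
  expect_error(ipls_scan(X, y, intervals = list(1:10, 21:60), lv_range = 1:3),
               "partition")
  expect_error(ipls_scan(X, y, intervals = list(1:30, 31:60), lv_range = 1:24),
               "range error")
})

test_that("LS-SVM near-interpolates at huge gamma and behaves like a kernel method", {
  set.seed(14)
  X <- matrix(rnorm(5 * 2), 5, 2)
  y <- rnorm(5)
  m <- fit_lssvm(X, y, gamma = 1e8, sigma2 = 1)
  expect_lt(max(abs(predict(m, X) - y)), 1e-4)
  # RBF kernel matrix is symmetric with unit diagonal
  K <- ftirhdx:::.rbf_kernel(X, X, 2)
  expect_equal(K, t(K))
  expect_equal(diag(K), rep(1, 5))
  # constant response gives constant predictions
  mc <- fit_lssvm(X, rep(4.2, 5), gamma = 10, sigma2 = 1)
  expect_equal(predict(mc, matrix(rnorm(6), 3, 2)), rep(4.2, 3),
               tolerance = 1e-8)
  expect_error(fit_lssvm(X, y, gamma = -1, sigma2 = 1), "gamma")
  expect_error(fit_lssvm(X, y, gamma = 1, sigma2 = 0), "sigma2")
})

test_that("LS-SVM tends to ridge regression as the kernel width grows", {
  set.seed(15)
  X <- scale(matrix(rnorm(40 * 3), 40, 3))
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  y <- as.numeric(X %*% c(2, -1, 0.5) + rnorm(40, 0, 0.3))
  gamma <- 10
  sigma2 <- 1e6
  m <- fit_lssvm(X, y, gamma, sigma2)
  # ridge oracle with the equivalent penalty lambda = sigma2 / (2 gamma)
  lambda <- sigma2 / (2 * gamma)
  Xc <- scale(X, scale = FALSE)
  beta <- solve(crossprod(Xc) + lambda * diag(ncol(X)), crossprod(Xc, y - mean(y)))
  ridge <- as.numeric(Xc %*% beta) + mean(y)
  expect_lt(max(abs(predict(m, X) - ridge)), 1e-3)
})

test_that("closed-form LS-SVM LOO equals fold-by-fold refitting", {
  set.seed(16)
  X <- matrix(rnorm(15 * 2), 15, 2)
  y <- rnorm(15)
  fast <- ftirhdx:::.lssvm_loo_rmse(X, y, 5, 2)
  naive <- loo_rmsecv(function(Xt, yt) fit_lssvm(Xt, yt, 5, 2), X, y)
  expect_equal(fast, naive, tolerance = 1e-10)
  gs <- lssvm_grid_search(X, y, gammas = c(1, 10), sigma2s = c(0.5, 5))
  expect_identical(nrow(gs$grid), 4L)
  expect_equal(gs$rmsecv, min(gs$grid$rmsecv))
})

test_that("ASLR selects perfect predictors first and matches the greedy oracle", {
  set.seed(17)
  X <- matrix(rnorm(40 * 12), 40, 12)
  # y is exactly column 7
  m <- fit_aslr(X, X[, 7], max_vars = 2)
  expect_identical(m$selected[1L], 7L)
  expect_lt(m$rmsecv[1L], 1e-8)
  # noisy two-column signal: both true columns among the first three picks,
  # and the whole path equals an independently coded brute-force greedy
  y <- as.numeric(X[, 3] + 0.5 * X[, 9] + rnorm(40, 0, 0.01))
  m2 <- fit_aslr(X, y, max_vars = 3)
  expect_true(all(c(3L, 9L) %in% m2$selected))
  expect_identical(m2$selected, aslr_greedy_oracle(X, y, 3))
  # per-step candidate RMSECV agrees with the literal fold loop
  expect_equal(m2$rmsecv_profile[[1L]][5L], ols_loo_oracle(X, y, 5L),
               tolerance = 1e-10)
  # in-sample RMSE is non-increasing along the nested path
  ins <- vapply(seq_along(m2$selected), function(k) {
    cols <- m2$selected[seq_len(k)]
    sqrt(mean(stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)$residuals^2))
  }, numeric(1))
  expect_true(all(diff(ins) <= 1e-12))
  expect_error(fit_aslr(X[1:5, ], y[1:5], max_vars = 5), "n_samples")
})

test_that("ASLR records wavenumber labels and RMSECV profiles for export", {
  set.seed(18)
  nu <- seq(1720, 1480, by = -20)
  X <- matrix(rnorm(30 * length(nu)), 30)
  y <- as.numeric(X %*% rnorm(length(nu), 0, 0.3))
  m <- fit_aslr(X, y, max_vars = 2, wavenumbers = nu)
  expect_identical(m$selected_wavenumbers, nu[m$selected])
  path <- withr::local_tempfile(fileext = ".csv")
  write_aslr_profile(m, path, nu)
  prof <- utils::read.csv(path)
  expect_identical(names(prof), c("wavenumber", "step1", "step2"))
  expect_equal(prof$step1, m$rmsecv_profile[[1L]])
})
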