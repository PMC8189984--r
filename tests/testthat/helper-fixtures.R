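# Shared fixture builders and independent oracles, constructed in code.

gauss_spectrum <- function(center, sigma, amp = 1, step = 2,
                           hi = 1800, lo = 1400, baseline = function(nu) 0,
                           protein_id = "fx", timepoint = "t0") {
  nu <- seq(hi, lo, by = -step)
  ftir_spectrum(nu, amp * exp(-(nu - center)^2 / (2 * sigma^2)) + baseline(nu),
                protein_id, timepoint)
}

# noiseless, drift-free generator settings used when a test needs the pure
# physical model
quiet_config <- function(...) {
  generator_config(noise_sd = 0, baseline_offset_range = c(0, 0),
                   baseline_slope_range = c(0, 0), ...)
}

# preprocess a generated library into the concatenated feature matrix
prep_library <- function(lib) {
  pre <- lapply(lib$series, function(se) {
    hdx_series(lapply(se$spectra, function(s) {
      vector_normalize(baseline_correct(s))
    }))
  })
  c1 <- concatenate_series(pre[[1L]])
  list(X = t(vapply(pre, concatenate_series, numeric(length(c1)))),
       bl = attr(c1, "block_length"))
}

timepoint_block <- function(d, k) d$X[, ((k - 1L) * d$bl + 1L):(k * d$bl)]

# DSSP fixture residue tables ---------------------------------------------

dssp_helix_fixture <- function() {
  data.frame(
    aa = strsplit("MKVLAEGHIKDE", "")[[1L]],
    ss_code = c(rep("H", 10L), " ", " "),
    stringsAsFactors = FALSE
  )
}

# two-strand hairpin: 4 E residues per strand joined by a turn; `ladder`
# case encodes the bridge sense
dssp_hairpin_fixture <- function(sense = c("antiparallel", "parallel")) {
  sense <- match.arg(sense)
  lad <- if (sense == "antiparallel") "A" else "a"
  data.frame(
    aa = strsplit("VKTLTGKTIT", "")[[1L]],
    ss_code = c("E", "E", "E", "E", "T", "T", "E", "E", "E", "E"),
    ladder = c(rep(lad, 4L), "", "", rep(lad, 4L)),
    stringsAsFactors = FALSE
  )
}

# Independent oracles -----------------------------------------------------

# OLS predictions via the normal equations (full-rank tall X)
ols_oracle_predict <- function(X, y, newX) {
  Z <- cbind(1, X)
  beta <- solve(crossprod(Z), crossprod(Z, y))
  as.numeric(cbind(1, newX) %*% beta)
}

# literal fold-by-fold LOO RMSE of an OLS fit on the given columns
ols_loo_oracle <- function(X, y, cols) {
  n <- nrow(X)
  preds <- vapply(seq_len(n), function(i) {
    Z <- cbind(1, X[-i, cols, drop = FALSE])
    beta <- qr.coef(qr(Z), y[-i])
    sum(c(1, X[i, cols]) * beta)
  }, numeric(1))
  sqrt(mean((y - preds)^2))
}

# brute-force ascending stepwise selection, coded independently of fit_aslr
aslr_greedy_oracle <- function(X, y, max_vars) {
  sel <- integer(0)
  for (step in seq_len(max_vars)) {
    cand <- setdiff(seq_len(ncol(X)), sel)
    scores <- vapply(cand, function(j) ols_loo_oracle(X, y, c(sel, j)),
                     numeric(1))
    sel <- c(sel, cand[which.min(scores)])
  }
  sel
}

# exhaustive stepwise max-min selection for Kennard-Stone
ks_oracle <- function(v, n_select) {
  D <- as.matrix(stats::dist(matrix(v, ncol = 1L)))
  n <- length(v)
  best <- -Inf; pair <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (D[i, j] > best) { best <- D[i, j]; pair <- c(i, j) }
  }
  sel <- pair
  while (length(sel) < n_select) {
    cand <- setdiff(seq_len(n), sel)
    dmin <- vapply(cand, function(k) min(D[k, sel]), numeric(1))
    sel <- c(sel, cand[which.max(dmin)])
  }
  sel
}
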