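test_that("spectrum construction enforces the grid invariants", {
  nu <- seq(1800, 1400, by = -2)
  expect_s3_class(ftir_spectrum(nu, rep(0.1, length(nu)), "p", "t0"),
                  "ftir_spectrum")
  expect_error(ftir_spectrum(rev(nu), rep(0.1, length(nu))), "descending")
  expect_error(ftir_spectrum(nu, rep(0.1, length(nu) - 1L)), "length")
  expect_error(ftir_spectrum(nu, c(NA, rep(0.1, length(nu) - 1L))), "NA")
  expect_error(ftir_spectrum(nu, rep(0.1, length(nu)), "p", "t7"))
})

test_that("baseline correction zeroes the anchors and removes straight lines", {
  nu <- seq(1800, 1400, by = -2)
  # constant spectrum: the chord equals the data
  s <- ftir_spectrum(nu, rep(0.5, length(nu)), "p", "t0")
  b <- baseline_correct(s)
  expect_true(all(b$absorbance == 0))
  expect_equal(range(b$wavenumbers), c(1480, 1720))
  # linear ramp removed exactly
  s2 <- ftir_spectrum(nu, 0.2 + 0.003 * nu, "p", "t0")
  expect_equal(max(abs(baseline_correct(s2)$absorbance)), 0, tolerance = 1e-12)
  # Gaussian + ramp: interior equals the Gaussian minus its anchor chord
  g <- function(x) exp(-(x - 1655)^2 / (2 * 10^2))
  s3 <- ftir_spectrum(nu, g(nu) + 0.001 * nu, "p", "t0")
  b3 <- baseline_correct(s3)
  full <- function(x) g(x) + 0.001 * x
  chord <- function(x) {
    full(1480) + (full(1720) - full(1480)) / (1720 - 1480) * (x - 1480)
  }
  expect_equal(b3$absorbance, full(b3$wavenumbers) - chord(b3$wavenumbers),
               tolerance = 1e-12)
  expect_identical(b3$absorbance[b3$wavenumbers == 1720], 0)
  expect_identical(b3$absorbance[b3$wavenumbers == 1480], 0)
  # anchors outside the grid span
  expect_error(baseline_correct(ftir_spectrum(seq(1700, 1500, -2),
                                              rep(1, 101))),
               "outside grid span")
})

test_that("vector normalization has unit window norm, scale invariance and idempotence", {
  s <- baseline_correct(gauss_spectrum(1655, 12, amp = 3))
  v <- vector_normalize(s)
  w <- v$wavenumbers >= 1590 & v$wavenumbers <= 1720
  expect_equal(sqrt(sum(v$absorbance[w]^2)), 1, tolerance = 1e-12)
  # scaling the input by 5 changes nothing
  s5 <- ftir_spectrum(s$wavenumbers, 5 * s$absorbance, s$protein_id, s$timepoint)
  expect_equal(vector_normalize(s5)$absorbance, v$absorbance, tolerance = 1e-12)
  # idempotent
  expect_equal(vector_normalize(v)$absorbance, v$absorbance, tolerance = 1e-12)
  # the amide II region is divided by the same factor
  nrm <- sqrt(sum(s$absorbance[w]^2))
  expect_equal(v$absorbance, s$absorbance / nrm, tolerance = 1e-12)
  # degenerate input
  z <- ftir_spectrum(s$wavenumbers, rep(0, length(s$wavenumbers)))
  expect_error(vector_normalize(z), "zero norm")
})

test_that("peak localization reaches sub-gridpoint accuracy", {
  # exact parabola: the cubic fit reproduces a quadratic exactly
  nu <- seq(1800, 1400, by = -2)
  par <- 5 - 0.01 * (nu - 1655)^2
  sp <- ftir_spectrum(nu, par - min(par) + 0.1, "p", "t0")
  expect_equal(find_peak_position(sp, 1655), 1655, tolerance = 1e-9)
  # noiseless Gaussians vs the dense-grid analytic argmax (= the center)
  expect_equal(find_peak_position(gauss_spectrum(1652.3, 9), 1652.3), 1652.3,
               tolerance = 0.2)
  expect_equal(find_peak_position(gauss_spectrum(1636, 8, step = 4), 1636),
               1636, tolerance = 0.3)
  # error below half the grid spacing across off-grid centers
  for (c0 in c(1650.7, 1653.2, 1655.9)) {
    expect_lt(abs(find_peak_position(gauss_spectrum(c0, 8), c0) - c0), 1)
  }
  # window truncated at the grid edge
  expect_error(find_peak_position(gauss_spectrum(1790, 8), 1790), "edge")
})

test_that("series concatenation orders blocks canonically and round-trips", {
  nu <- seq(1800, 1400, by = -2)
  mk <- function(tp, val) ftir_spectrum(nu, rep(val, length(nu)), "p", tp)
  # permuted input order: storage is still t0, t15, t105, t24h
  ser <- hdx_series(list(mk("t105", 3), mk("t0", 1), mk("t24h", 4),
                         mk("t15", 2)))
  cc <- concatenate_series(ser)
  bl <- attr(cc, "block_length")
  expect_identical(bl, sum(nu >= 1480 & nu <= 1720))
  expect_length(cc, 4L * bl)
  expect_equal(unique(extract_block(cc, "t15")), 2)
  expect_equal(unique(extract_block(cc, 4)), 4)
  # block extraction recovers each input block exactly
  expect_equal(extract_block(cc, "t0"), rep(1, bl))
  # incomplete series and grid mismatch
  expect_error(hdx_series(list(mk("t0", 1), mk("t15", 2), mk("t105", 3))),
               "incomplete")
  bad <- ftir_spectrum(seq(1800, 1402, by = -2), rep(4, 200), "p", "t24h")
  expect_error(hdx_series(list(mk("t0", 1), mk("t15", 2), mk("t105", 3), bad)),
               "grid mismatch")
})

test_that("difference spectra subtract pointwise and flag operand order", {
  a <- gauss_spectrum(1655, 9, timepoint = "t0")
  expect_true(all(difference_spectrum(a, a)$absorbance == 0))
  b <- ftir_spectrum(a$wavenumbers, a$absorbance + 0.1, "fx", "t15")
  expect_equal(unique(round(difference_spectrum(b, a)$absorbance, 12)), 0.1)
  expect_match(difference_spectrum(b, a)$protein_id, "t15-fx@t0")
  # exchanged irregular structure: t15 - t0 has its positive lobe where the
  # deuterated coil band lands
  cfg <- quiet_config()
  po <- structure_profile(H = 0, E = 0, Others = 100)
  d <- difference_spectrum(
    synthesize_spectrum(po, NULL, 15 + 25 / 60, cfg),
    synthesize_spectrum(po, NULL, 0, cfg)
  )
  peak_at <- d$wavenumbers[which.max(d$absorbance)]
  expect_gt(max(d$absorbance), 0)
  expect_true(peak_at >= 1630 && peak_at <= 1645)
})

test_that("spectra CSV I/O round-trips at 12 significant digits", {
  nu <- seq(1800, 1400, by = -2)
  set.seed(7)
  sp <- list(
    ftir_spectrum(nu, abs(rnorm(length(nu))), "alpha", "t0"),
    ftir_spectrum(nu, abs(rnorm(length(nu))), "alpha", "t15"),
    ftir_spectrum(nu, abs(rnorm(length(nu))), "beta", "t0")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(sp, path)
  back <- read_spectra_csv(path)
  expect_length(back, 3L)
  expect_identical(back[[2L]]$protein_id, "alpha")
  expect_identical(back[[2L]]$timepoint, "t15")
  expect_equal(back[[1L]]$absorbance, sp[[1L]]$absorbance, tolerance = 1e-11)
  expect_equal(back[[3L]]$wavenumbers, nu)
})
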