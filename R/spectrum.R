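HDX_TIMEPOINTS <- c("t0", "t15", "t105", "t24h")

#' HDX timepoints in chronological order
#'
#' The four sampling times of the deuterium-exchange experiment: `t0`
#' (no deuteration), `t15` (15 min 25 s), `t105` (1 h 45 min) and `t24h`
#' (24 h), returned as an ordered character vector.
#'
#' @return Character vector of length 4.
#' @export
hdx_timepoints <- function() HDX_TIMEPOINTS

#' Timepoint labels to minutes
#'
#' @param tp character vector of timepoint labels (`t0`, `t15`, `t105`, `t24h`).
#' @return Numeric vector of exchange times in minutes.
#' @export
timepoint_minutes <- function(tp) {
  map <- c(t0 = 0, t15 = 15 + 25 / 60, t105 = 105, t24h = 1440)
  bad <- setdiff(tp, names(map))
  if (length(bad) > 0L) {
    stop("unknown timepoint label(s): ", paste(bad, collapse = ", "))
  }
  unname(map[tp])
}

#' Construct an FTIR spectrum
#'
#' A spectrum is a wavenumber grid (cm^-1, strictly descending, the FTIR
#' convention) with one absorbance value per grid point, tagged with a
#' protein identifier and an HDX timepoint.
#'
#' @param wavenumbers numeric, strictly monotonically descending, in cm^-1.
#' @param absorbance numeric of the same length, no NA.
#' @param protein_id character scalar label.
#' @param timepoint one of `"t0"`, `"t15"`, `"t105"`, `"t24h"`.
#' @return An object of class `ftir_spectrum`.
#' @examples
#' nu <- seq(1800, 1400, by = -2)
#' s <- ftir_spectrum(nu, exp(-(nu - 1655)^2 / 200), "demo", "t0")
#' s
#' @export
ftir_spectrum <- function(wavenumbers, absorbance, protein_id = "unknown",
                          timepoint = "t0") {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance)) {
    stop("wavenumbers and absorbance must have the same length")
  }
  if (anyNA(wavenumbers) || anyNA(absorbance)) {
    stop("spectrum contains NA values")
  }
  if (length(wavenumbers) >= 2L && any(diff(wavenumbers) >= 0)) {
    stop("wavenumbers must be strictly monotonically descending")
  }
  timepoint <- match.arg(timepoint, HDX_TIMEPOINTS)
  structure(
    list(
      wavenumbers = wavenumbers,
      absorbance = absorbance,
      protein_id = as.character(protein_id)[1L],
      timepoint = timepoint
    ),
    class = "ftir_spectrum"
  )
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ftir_spectrum> %s @ %s: %d points, %.1f..%.1f cm-1\n",
    x$protein_id, x$timepoint, length(x$wavenumbers),
    max(x$wavenumbers), min(x$wavenumbers)
  ))
  invisible(x)
}

# Index of the grid point matching `nu`; nearest point with a message if the
# value does not lie on the grid.
.grid_anchor <- function(wavenumbers, nu, quiet = FALSE) {
  i <- which.min(abs(wavenumbers - nu))
  if (abs(wavenumbers[i] - nu) > 1e-9 && !quiet) {
    message(sprintf(
      "anchor %.4g cm-1 not on grid; using nearest grid point %.4g cm-1",
      nu, wavenumbers[i]
    ))
  }
  i
}

.in_window <- function(wavenumbers, lo, hi) {
  wavenumbers >= lo - 1e-9 & wavenumbers <= hi + 1e-9
}

#' Straight-line baseline correction
#'
#' Subtracts the straight line interpolated between the absorbance values at
#' the `hi` and `lo` anchor wavenumbers (defaults 1720 and 1480 cm^-1) and
#' crops the spectrum to that window. The anchors themselves are exactly zero
#' in the result.
#'
#' @param s an [ftir_spectrum].
#' @param lo,hi window bounds in cm^-1; must lie within the grid span. Off-grid
#'   anchors are snapped to the nearest grid point (with a message).
#' @return A baseline-corrected `ftir_spectrum` restricted to `[lo, hi]`.
#' @export
baseline_correct <- function(s, lo = 1480, hi = 1720) {
  stopifnot(inherits(s, "ftir_spectrum"), lo < hi)
  nu <- s$wavenumbers
  if (hi > max(nu) + 1e-9 || lo < min(nu) - 1e-9) {
    stop(sprintf(
      "baseline anchors [%g, %g] outside grid span [%g, %g]",
      lo, hi, min(nu), max(nu)
    ))
  }
  i_hi <- .grid_anchor(nu, hi)
  i_lo <- .grid_anchor(nu, lo)
  nu_hi <- nu[i_hi]; nu_lo <- nu[i_lo]
  a_hi <- s$absorbance[i_hi]; a_lo <- s$absorbance[i_lo]
  slope <- (a_hi - a_lo) / (nu_hi - nu_lo)
  keep <- .in_window(nu, nu_lo, nu_hi)
  corrected <- s$absorbance[keep] - (a_lo + slope * (nu[keep] - nu_lo))
  # force the anchors to exact zero against rounding
  out_nu <- nu[keep]
  corrected[abs(out_nu - nu_hi) < 1e-9] <- 0
  corrected[abs(out_nu - nu_lo) < 1e-9] <- 0
  ftir_spectrum(out_nu, corrected, s$protein_id, s$timepoint)
}

#' Vector normalization over a spectral window
#'
#' Scales the whole spectrum by the Euclidean norm of its restriction to
#' `[lo, hi]` (defaults 1590-1720 cm^-1), so that the restricted block has
#' unit norm afterwards. The amide II region (below 1590 cm^-1) is divided by
#' the same factor, preserving relative amide I / amide II intensity.
#'
#' @param s an [ftir_spectrum] (normally baseline-corrected first).
#' @param lo,hi normalization window bounds in cm^-1.
#' @return A normalized `ftir_spectrum` on the same grid as the input.
#' @export
vector_normalize <- function(s, lo = 1590, hi = 1720) {
  stopifnot(inherits(s, "ftir_spectrum"), lo < hi)
  keep <- .in_window(s$wavenumbers, lo, hi)
  if (sum(keep) < 2L) stop("fewer than 2 grid points in normalization window")
  nrm <- sqrt(sum(s$absorbance[keep]^2))
  if (nrm <= 0) stop("degenerate spectrum: zero norm in normalization window")
  ftir_spectrum(s$wavenumbers, s$absorbance / nrm, s$protein_id, s$timepoint)
}

# Derivative root of a cubic least-squares fit through the 23 grid points
# centered at index i, nearest to `approx`; NA when no admissible root.
.cubic_peak_root <- function(nu, a, i, approx) {
  win <- (i - 11L):(i + 11L)
  x <- nu[win] - nu[i]   # center for conditioning
  y <- a[win]
  co <- stats::lm.fit(cbind(1, x, x^2, x^3), y)$coefficients
  # derivative 3 c3 x^2 + 2 c2 x + c1 = 0
  c1 <- co[2]; c2 <- co[3]; c3 <- co[4]
  if (abs(c3) < 1e-12 * max(abs(co))) {
    if (abs(c2) < .Machine$double.eps) return(NA_real_)
    roots <- -c1 / (2 * c2)
  } else {
    disc <- (2 * c2)^2 - 4 * (3 * c3) * c1
    if (disc < 0) return(NA_real_)
    roots <- (-2 * c2 + c(1, -1) * sqrt(disc)) / (2 * 3 * c3)
  }
  cand <- roots + nu[i]
  inside <- cand <= max(nu[win]) + 1e-9 & cand >= min(nu[win]) - 1e-9
  if (!any(inside)) return(NA_real_)
  cand <- cand[inside]
  unname(cand[which.min(abs(cand - approx))])
}

#' Sub-gridpoint peak localization by local cubic fit
#'
#' Fits a third-order polynomial through 11 grid points on each side of the
#' grid maximum nearest `approx` (a 23-point window) and locates the real
#' root of the polynomial's derivative inside the window, giving
#' sub-gridpoint resolution. Because the least-squares cubic has a
#' window-asymmetry bias that is first order in the offset between the true
#' peak and the window center, a second fit on the window shifted one grid
#' step toward the peak is used to cancel that bias: with roots `r1`, `r2`
#' from windows centered at `c1`, `c2`, the bias slope is
#' `beta = (r1 - r2) / (c1 - c2)` and the de-biased position is
#' `(r1 - beta * c1) / (1 - beta)`. For an exact parabola `beta = 0` and the
#' single-window root is returned unchanged.
#'
#' @param s an [ftir_spectrum].
#' @param approx approximate peak position in cm^-1; must lie within the grid.
#' @return Peak position in cm^-1 (numeric scalar).
#' @export
find_peak_position <- function(s, approx) {
  stopifnot(inherits(s, "ftir_spectrum"))
  nu <- s$wavenumbers
  a <- s$absorbance
  n <- length(nu)
  if (approx > max(nu) + 1e-9 || approx < min(nu) - 1e-9) {
    stop("approx outside the wavenumber grid")
  }
  # hill-climb from the grid point nearest approx to the local maximum
  i <- which.min(abs(nu - approx))
  repeat {
    if (i > 1L && a[i - 1L] > a[i]) i <- i - 1L
    else if (i < n && a[i + 1L] > a[i]) i <- i + 1L
    else break
  }
  if (i - 11L < 1L || i + 11L > n) {
    stop("peak window truncated by grid edge (need 11 points on each side)")
  }
  r1 <- .cubic_peak_root(nu, a, i, approx)
  if (is.na(r1)) stop("no real derivative root in window: no peak found")
  # shift one grid step toward the higher neighbour (the side the true peak
  # falls on when it lies between grid points)
  j <- if (i > 1L && a[i - 1L] >= a[i + 1L]) i - 1L else i + 1L
  if (j - 11L >= 1L && j + 11L <= n) {
    r2 <- .cubic_peak_root(nu, a, j, approx)
    if (!is.na(r2)) {
      beta <- (r1 - r2) / (nu[i] - nu[j])
      if (is.finite(beta) && abs(1 - beta) > 0.1) {
        debiased <- (r1 - beta * nu[i]) / (1 - beta)
        # keep the correction local: never move past the shifted window
        if (abs(debiased - r1) <= 2 * abs(nu[1L] - nu[2L])) return(debiased)
      }
    }
  }
  r1
}

#' Assemble the four HDX timepoint spectra of one protein
#'
#' @param spectra list of four [ftir_spectrum] objects of the same protein on
#'   identical grids, one per timepoint (any order; stored in time order).
#' @return An object of class `hdx_series`.
#' @export
hdx_series <- function(spectra) {
  stopifnot(is.list(spectra))
  tps <- vapply(spectra, function(s) s$timepoint, character(1))
  if (length(spectra) != 4L || !setequal(tps, HDX_TIMEPOINTS)) {
    stop("incomplete series: need exactly one spectrum per timepoint ",
         paste(HDX_TIMEPOINTS, collapse = ", "))
  }
  spectra <- spectra[match(HDX_TIMEPOINTS, tps)]
  names(spectra) <- HDX_TIMEPOINTS
  ids <- unique(vapply(spectra, function(s) s$protein_id, character(1)))
  if (length(ids) != 1L) stop("spectra belong to different proteins")
  ref <- spectra[[1L]]$wavenumbers
  for (s in spectra[-1L]) {
    if (length(s$wavenumbers) != length(ref) ||
        any(abs(s$wavenumbers - ref) > 1e-9)) {
      stop("grid mismatch between timepoint spectra")
    }
  }
  structure(list(spectra = spectra, protein_id = ids),
            class = "hdx_series")
}

#' @export
print.hdx_series <- function(x, ...) {
  cat(sprintf("<hdx_series> %s: 4 timepoints, %d grid points\n",
              x$protein_id, length(x$spectra[[1]]$wavenumbers)))
  invisible(x)
}

#' Concatenate the four timepoint blocks into one feature vector
#'
#' Restricts each timepoint spectrum to `[lo, hi]` (default 1480-1720 cm^-1)
#' and places the four blocks side by side in time order t0, t15, t105, t24h,
#' forming one combined spectrum per protein.
#'
#' @param series an [hdx_series].
#' @param lo,hi block window bounds in cm^-1.
#' @return Numeric vector of length 4 x block length, with attributes
#'   `block_length`, `wavenumbers` (one block's grid) and `timepoints`.
#' @export
concatenate_series <- function(series, lo = 1480, hi = 1720) {
  stopifnot(inherits(series, "hdx_series"))
  keep <- .in_window(series$spectra[[1L]]$wavenumbers, lo, hi)
  if (!any(keep)) stop("concatenation window contains no grid points")
  blocks <- lapply(series$spectra, function(s) s$absorbance[keep])
  out <- unlist(blocks, use.names = FALSE)
  attr(out, "block_length") <- sum(keep)
  attr(out, "wavenumbers") <- series$spectra[[1L]]$wavenumbers[keep]
  attr(out, "timepoints") <- HDX_TIMEPOINTS
  out
}

#' Extract one timepoint block from a concatenated feature vector
#'
#' @param concat vector produced by [concatenate_series()].
#' @param timepoint block to extract, by label or by index 1-4.
#' @return Numeric vector of one block's absorbance values.
#' @export
extract_block <- function(concat, timepoint) {
  bl <- attr(concat, "block_length")
  if (is.null(bl)) stop("not a concatenated series (missing block_length)")
  k <- if (is.character(timepoint)) match(timepoint, HDX_TIMEPOINTS)
       else as.integer(timepoint)
  if (is.na(k) || k < 1L || k > 4L) stop("timepoint must be a label or 1..4")
  as.numeric(concat[((k - 1L) * bl + 1L):(k * bl)])
}

#' Pointwise difference of two spectra
#'
#' Computes `a - b` on a shared grid; the operand order is recorded in the
#' result's protein id (e.g. deuteration-induced change is usually shown as
#' t0 - t15 or t15 - t0; both orders are supported, neither is implied).
#'
#' @param a,b [ftir_spectrum] objects on identical grids.
#' @return An `ftir_spectrum` holding `a$absorbance - b$absorbance`, labelled
#'   `"<id_a>-<id_b>"`, carrying `a`'s timepoint.
#' @export
difference_spectrum <- function(a, b) {
  stopifnot(inherits(a, "ftir_spectrum"), inherits(b, "ftir_spectrum"))
  if (length(a$wavenumbers) != length(b$wavenumbers) ||
      any(abs(a$wavenumbers - b$wavenumbers) > 1e-9)) {
    stop("grid mismatch between operands")
  }
  ftir_spectrum(
    a$wavenumbers, a$absorbance - b$absorbance,
    paste0(a$protein_id, "@", a$timepoint, "-", b$protein_id, "@", b$timepoint),
    a$timepoint
  )
}

#' Write spectra to a CSV matrix
#'
#' One row per wavenumber, first column `wavenumber_cm-1`, one column per
#' `protein_id@timepoint`. Values are written with 12 significant digits and
#' round-trip through [read_spectra_csv()] to that precision.
#'
#' @param spectra list of [ftir_spectrum] objects sharing one grid.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(length(spectra) >= 1L)
  ref <- spectra[[1L]]$wavenumbers
  cols <- lapply(spectra, function(s) {
    if (length(s$wavenumbers) != length(ref) ||
        any(abs(s$wavenumbers - ref) > 1e-9)) {
      stop("all spectra must share one wavenumber grid")
    }
    s$absorbance
  })
  names(cols) <- vapply(
    spectra, function(s) paste0(s$protein_id, "@", s$timepoint), character(1)
  )
  df <- data.frame(`wavenumber_cm-1` = ref, cols, check.names = FALSE)
  df[] <- lapply(df, function(x) formatC(x, digits = 12, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spectra from a CSV matrix
#'
#' Inverse of [write_spectra_csv()]: expects a `wavenumber_cm-1` first column
#' and `protein_id@timepoint` headers on the remaining columns.
#'
#' @param path CSV file path.
#' @return A list of [ftir_spectrum] objects.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "wavenumber_cm-1") {
    stop("first column must be 'wavenumber_cm-1'")
  }
  nu <- as.numeric(df[[1L]])
  lapply(names(df)[-1L], function(nm) {
    parts <- strsplit(nm, "@", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("column name not 'protein_id@timepoint': ", nm)
    ftir_spectrum(nu, as.numeric(df[[nm]]), parts[1L], parts[2L])
  })
}
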