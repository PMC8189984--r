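# Area-normalized band shapes shared by the side-chain model and the
# synthetic generator. `area` is the integrated intensity in absorbance*cm-1.
.band_shape <- function(nu, center, width, area, shape = "gaussian") {
  if (shape == "lorentzian") {
    area / pi * width / ((nu - center)^2 + width^2)
  } else {
    area * exp(-(nu - center)^2 / (2 * width^2)) / (width * sqrt(2 * pi))
  }
}

#' Mean amino-acid composition of a soluble-protein calibration set
#'
#' Percent composition used as the default by the synthetic generator's
#' composition sampler and by the side-chain calibration check. Arginine and
#' glutamine are set to the calibration-set means reported for soluble
#' protein libraries (4.3% and 3.7%); the remaining residues follow average
#' globular-protein frequencies. Sums to 100.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
average_aa_composition <- function() {
  c(A = 8.3, R = 4.3, N = 4.3, D = 5.9, C = 1.4, Q = 3.7, E = 6.7, G = 7.5,
    H = 2.2, I = 5.9, L = 9.7, K = 5.8, M = 2.4, F = 3.9, P = 4.7, S = 7.1,
    T = 5.3, W = 1.1, Y = 2.9, V = 6.9)
}

#' Default amino-acid side-chain band library
#'
#' Absorption bands of the infrared-active side chains (N, Q, R, D, E, K, Y,
#' H) in the 1720-1480 cm^-1 window, in the protonated and deuterated states.
#' The glutamine principal band lies at 1672 cm^-1 protonated and 1635 cm^-1
#' deuterated; the remaining centers, widths and relative intensities are
#' editable defaults compiled from published side-chain band reviews
#' (configurable, not asserted). `global_scale` ties the summed side-chain
#' intensity to the amide intensity so that an average composition
#' contributes about 20% of the amide integral.
#'
#' @param global_scale overall intensity factor applied to every band.
#' @param shape `"gaussian"` (default) or `"lorentzian"` band shape.
#' @return An object of class `sidechain_library`: a data.frame of bands
#'   (`residue`, `state`, `center`, `width`, `rel_intensity`) with
#'   `global_scale` and `shape` attributes.
#' @export
sidechain_library <- function(global_scale = 1.0, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  b <- function(res, state, center, width, rel) {
    data.frame(residue = res, state = state, center = center, width = width,
               rel_intensity = rel, stringsAsFactors = FALSE)
  }
  bands <- rbind(
    b("N", "protonated", 1678, 9, 1.00), b("N", "deuterated", 1648, 9, 1.00),
    b("Q", "protonated", 1672, 9, 1.05), b("Q", "deuterated", 1635, 9, 1.05),
    b("R", "protonated", 1673, 10, 0.60), b("R", "protonated", 1633, 10, 0.60),
    b("R", "deuterated", 1608, 9, 0.70), b("R", "deuterated", 1586, 9, 0.70),
    b("D", "protonated", 1574, 12, 0.80), b("D", "deuterated", 1584, 12, 0.80),
    b("E", "protonated", 1560, 12, 1.00), b("E", "deuterated", 1567, 12, 0.90),
    b("K", "protonated", 1629, 12, 0.25), b("K", "deuterated", 1611, 12, 0.30),
    b("Y", "protonated", 1602, 6, 0.35), b("Y", "protonated", 1518, 6, 0.50),
    b("Y", "deuterated", 1590, 6, 0.35), b("Y", "deuterated", 1515, 6, 0.50),
    b("H", "protonated", 1596, 8, 0.30), b("H", "deuterated", 1569, 8, 0.30)
  )
  stopifnot(all(bands$center > 1400 & bands$center < 1750),
            all(bands$width > 0), all(bands$rel_intensity >= 0))
  structure(bands, class = c("sidechain_library", "data.frame"),
            global_scale = global_scale, shape = shape)
}

#' Build the summed side-chain spectrum of a composition
#'
#' Sums the composition-weighted side-chain bands of the requested
#' protonation state on the given grid. Linear in the composition. Residues
#' absent from the library contribute zero (with a warning when their
#' composition is non-zero).
#'
#' @param composition named percent composition (as from [aa_composition()]);
#'   entries may cover any subset of residues.
#' @param state `"protonated"` or `"deuterated"`.
#' @param grid wavenumber grid (cm^-1, descending).
#' @param library a [sidechain_library()].
#' @return An [ftir_spectrum] of the summed side-chain contribution.
#' @export
build_sidechain_spectrum <- function(composition, state = c("protonated", "deuterated"),
                                     grid, library = sidechain_library()) {
  state <- match.arg(state)
  stopifnot(all(composition >= 0))
  scale <- attr(library, "global_scale")
  shape <- attr(library, "shape")
  bands <- library[library$state == state, , drop = FALSE]
  a <- numeric(length(grid))
  active <- names(composition)[composition > 0]
  missing <- setdiff(active, bands$residue)
  covered <- setdiff(missing, c("A", "C", "G", "I", "L", "M", "F", "P",
                                "S", "T", "W", "V"))
  if (length(covered) > 0L) {
    warning("residue(s) missing from side-chain library, contributing zero: ",
            paste(covered, collapse = ", "))
  }
  for (k in seq_len(nrow(bands))) {
    c_r <- composition[bands$residue[k]]
    if (is.na(c_r) || c_r == 0) next
    a <- a + .band_shape(grid, bands$center[k], bands$width[k],
                         scale * (c_r / 100) * bands$rel_intensity[k], shape)
  }
  ftir_spectrum(grid, a, "sidechain_sum", "t0")
}

#' Subtract the side-chain contribution from a protein spectrum
#'
#' Stoichiometric subtraction: the composition-weighted side-chain sum of
#' [build_sidechain_spectrum()] is removed at unit scale, so adding the
#' contribution back reproduces the input exactly. Negative absorbance in
#' the result is permitted (a message flags it).
#'
#' @param s protein [ftir_spectrum].
#' @param composition named percent composition.
#' @param state `"protonated"` or `"deuterated"`.
#' @param library a [sidechain_library()].
#' @return The corrected `ftir_spectrum` on the grid of `s`.
#' @export
subtract_sidechains <- function(s, composition,
                                state = c("protonated", "deuterated"),
                                library = sidechain_library()) {
  stopifnot(inherits(s, "ftir_spectrum"))
  state <- match.arg(state)
  sc <- build_sidechain_spectrum(composition, state, s$wavenumbers, library)
  out <- ftir_spectrum(s$wavenumbers, s$absorbance - sc$absorbance,
                       s$protein_id, s$timepoint)
  if (min(out$absorbance) < 0) {
    message("side-chain correction produced negative absorbance (min ",
            signif(min(out$absorbance), 3), ")")
  }
  out
}

#' Write a side-chain library to a JSON config
#'
#' @param library a [sidechain_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sidechain_library <- function(library, path) {
  obj <- list(
    global_scale = attr(library, "global_scale"),
    shape = attr(library, "shape"),
    bands = as.data.frame(library)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a side-chain library from a JSON config
#'
#' @param path path written by [write_sidechain_library()].
#' @return A `sidechain_library` object.
#' @export
read_sidechain_library <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(as.data.frame(obj$bands),
            class = c("sidechain_library", "data.frame"),
            global_scale = obj$global_scale, shape = obj$shape)
}
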