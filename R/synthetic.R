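AMIDE1_CLASSES <- c("H_ordered", "H_disordered", "Others", "E_main",
                    "E_anti_high")

#' Default amide I band table of the synthetic generator
#'
#' Band anchors per secondary-structure class, protonated and deuterated.
#' Helix and irregular structure absorb at 1655 cm^-1 before exchange; the
#' rapidly exchanging irregular fraction moves down to overlap the beta-sheet
#' region (1636 cm^-1) on deuteration (the exchanged-coil band is narrower
#' than the protonated irregular envelope); disordered helix tips deuterate
#' to an intermediate 1647 cm^-1; antiparallel sheet carries an extra
#' high-wavenumber component near 1684 cm^-1 at a quarter of the main
#' amplitude. All downshifts lie within 3-15 cm^-1. Bands are
#' area-normalized, so the broader irregular-structure band is flatter at
#' equal content (amplitudes are integrated areas per unit fraction). The
#' amide II (1548 cm^-1) and amide II' (1452 cm^-1, about 100 cm^-1 below)
#' bands are carried as attributes. Only the 1655/1636 anchors and the shift
#' range are anchored to measured spectra; everything else is a configurable
#' default.
#'
#' @return A data.frame (`class`, `center_p`, `center_d`, `width_p`,
#'   `width_d`, `rel_amp`) with `amide2` and `amide2p` list attributes.
#' @export
band_table_default <- function() {
  bt <- data.frame(
    class = AMIDE1_CLASSES,
    center_p = c(1655, 1655, 1655, 1636, 1684),
    center_d = c(1650, 1647, 1640, 1630, 1678),
    width_p = c(7, 10, 14, 8, 7),
    width_d = c(7, 11, 10, 8, 7),
    rel_amp = c(1, 1, 1, 1, 0.25),
    stringsAsFactors = FALSE
  )
  shift <- bt$center_p - bt$center_d
  stopifnot(all(shift >= 3 & shift <= 15))
  attr(bt, "amide2") <- list(center = 1548, width = 12, rel_amp = 0.5)
  attr(bt, "amide2p") <- list(center = 1452, width = 14, rel_amp = 0.45)
  bt
}

#' Default per-class exchange kinetics
#'
#' First-order exchange toward a plateau, `f(t) = plateau (1 - exp(-k t))`,
#' with rates ordered Others >> disordered helix > ordered helix > sheet:
#' solvent-exposed irregular structure is essentially exchanged within
#' 15 min, while sheet exchange is still incomplete after 24 h. Side chains
#' exchange fastest. Rates are free parameters chosen to realize that
#' phenomenology, not measured values.
#'
#' @return A data.frame with columns `class`, `k` (min^-1) and `plateau`.
#' @export
hdx_kinetics_default <- function() {
  kin <- data.frame(
    class = c("Others", "H_disordered", "H_ordered", "E", "sidechain"),
    k = c(0.20, 0.05, 0.005, 0.0008, 0.5),
    plateau = c(1.0, 1.0, 0.95, 0.7, 1.0),
    stringsAsFactors = FALSE
  )
  stopifnot(kin$k[1] > kin$k[2], kin$k[2] > kin$k[3], kin$k[3] > kin$k[4],
            kin$plateau[kin$class == "E"] < 1)
  kin
}

#' Exchanged fraction of a structure class at a given time
#'
#' @param cls class name (one of the rows of the kinetics table).
#' @param t exchange time in minutes, >= 0.
#' @param kinetics a kinetics table as from [hdx_kinetics_default()].
#' @return Fraction in `[0, plateau]`, monotone non-decreasing in `t`.
#' @export
exchange_fraction <- function(cls, t, kinetics = hdx_kinetics_default()) {
  if (any(t < 0)) stop("exchange time must be >= 0")
  row <- match(cls, kinetics$class)
  if (anyNA(row)) stop("unknown kinetics class: ", cls[is.na(row)][1L])
  kinetics$plateau[row] * (1 - exp(-kinetics$k[row] * t))
}

#' Configuration of the synthetic spectra generator
#'
#' Bundles everything [generate_library()] needs: the wavenumber grid, band
#' table, exchange kinetics, the Dirichlet concentration used to sample
#' (H, E, Others) reference fractions, the Beta laws splitting helix into
#' ordered/disordered and sheet into antiparallel/parallel, the amino-acid
#' composition sampler, noise and baseline-drift levels, library size and
#' seed.
#'
#' The default Dirichlet concentration gives mean fractions of about
#' 30% helix, 20% sheet and 50% Others with an Others standard deviation
#' near 10%, mirroring a soluble-protein calibration set.
#'
#' @param n library size (number of proteins), >= 2.
#' @param seed integer RNG seed; a fixed seed makes the library byte-identical
#'   across runs.
#' @param grid_hi,grid_lo,grid_step wavenumber grid bounds and spacing
#'   (cm^-1); default 1800..1400 at 2 cm^-1 (descending storage).
#' @param bands band table ([band_table_default()]).
#' @param kinetics kinetics table ([hdx_kinetics_default()]).
#' @param dirichlet_alpha Dirichlet concentration for (H, E, Others).
#' @param ordered_beta Beta(a, b) for the ordered share of helix.
#' @param anti_beta Beta(a, b) for the antiparallel share of sheet.
#' @param comp_mean,comp_concentration mean amino-acid composition (%) and
#'   Dirichlet concentration of the per-protein composition sampler.
#' @param kinetics_jitter_sd standard deviation (log scale) of the per-protein,
#'   per-class lognormal multipliers applied to the exchange rate constants:
#'   protection factors differ between proteins, so the exchanged fraction at
#'   a given time varies around the class mean. Zero disables the
#'   heterogeneity. Leaves t0 spectra untouched (nothing has exchanged yet).
#' @param deut_center_jitter_sd per-class standard deviations (cm^-1) of the
#'   per-protein normal shifts applied to the deuterated band centers: the
#'   position a band reaches on deuteration varies with hydration and
#'   exchange extent, most strongly for the conformationally heterogeneous
#'   irregular ("Others") class. Shifts are clipped so every deuterated
#'   center stays at least 1 cm^-1 below its protonated counterpart. Zeros
#'   disable it; t0 spectra are untouched.
#' @param amide_scale overall intensity factor converting the unit-area band
#'   system to absorbance units; the default puts the mean amide I maximum
#'   near 0.5 AU, typical of dried protein films. Applied to the amide and
#'   side-chain contributions alike, so relative intensities (and the
#'   side-chain/amide ratio) are unaffected.
#' @param noise_sd additive Gaussian noise standard deviation (absorbance
#'   units; 0.002 AU against a ~0.5 AU amide I maximum).
#' @param baseline_offset_range,baseline_slope_range uniform ranges of the
#'   linear baseline drift (offset in absorbance, slope per cm^-1).
#' @param sidechain side-chain band library ([sidechain_library()]).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n = 85L, seed = 1L,
                             grid_hi = 1800, grid_lo = 1400, grid_step = 2,
                             bands = band_table_default(),
                             kinetics = hdx_kinetics_default(),
                             dirichlet_alpha = c(H = 7.2, E = 4.8, Others = 12),
                             ordered_beta = c(6, 4),
                             anti_beta = c(7.5, 2.5),
                             comp_mean = average_aa_composition(),
                             comp_concentration = 60,
                             kinetics_jitter_sd = 0,
                             deut_center_jitter_sd = c(H_ordered = 0.5,
                                                       H_disordered = 0.5,
                                                       Others = 2.5,
                                                       E_main = 0.5,
                                                       E_anti_high = 0.5),
                             amide_scale = 30,
                             noise_sd = 0.002,
                             baseline_offset_range = c(0, 0.02),
                             baseline_slope_range = c(-2e-5, 2e-5),
                             sidechain = sidechain_library()) {
  if (n < 2L) stop("library size n must be >= 2")
  if (grid_lo >= grid_hi || grid_step <= 0) stop("invalid grid specification")
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         grid = seq(grid_hi, grid_lo, by = -grid_step),
         bands = bands, kinetics = kinetics,
         dirichlet_alpha = dirichlet_alpha,
         ordered_beta = ordered_beta, anti_beta = anti_beta,
         comp_mean = comp_mean, comp_concentration = comp_concentration,
         kinetics_jitter_sd = kinetics_jitter_sd,
         deut_center_jitter_sd = deut_center_jitter_sd,
         amide_scale = amide_scale, noise_sd = noise_sd,
         baseline_offset_range = baseline_offset_range,
         baseline_slope_range = baseline_slope_range,
         sidechain = sidechain),
    class = "generator_config"
  )
}

# Exchanged fractions of the five amide I classes plus backbone classes at
# time t, as a named vector; `rate_factors` (named per kinetics class)
# multiply the rate constants.
.class_fractions_at <- function(t, kinetics, rate_factors = NULL) {
  if (!is.null(rate_factors)) {
    m <- rate_factors[kinetics$class]
    m[is.na(m)] <- 1
    kinetics$k <- kinetics$k * m
  }
  cls <- c(H_ordered = "H_ordered", H_disordered = "H_disordered",
           Others = "Others", E_main = "E", E_anti_high = "E", E = "E",
           sidechain = "sidechain")
  stats::setNames(exchange_fraction(unname(cls), t, kinetics), names(cls))
}

#' Synthesize one protein spectrum at a given exchange time
#'
#' Builds the noiseless physical model -- per-class amide I bands mixed
#' between protonated and deuterated positions according to the exchanged
#' fraction, amide II decaying and amide II' growing with the
#' residue-weighted mean exchange, plus state-mixed side-chain bands -- and
#' then adds a linear baseline drift and Gaussian noise drawn from the
#' current RNG stream (both zero when the config ranges/sd are zero). The
#' noiseless part is linear in the structure profile.
#'
#' @param profile a [structure_profile] (fractions in %).
#' @param composition named percent amino-acid composition, or `NULL` for no
#'   side-chain contribution.
#' @param t exchange time in minutes.
#' @param cfg a [generator_config()].
#' @param timepoint timepoint label to stamp on the spectrum (defaults to the
#'   label matching `t` when there is one).
#' @param protein_id label.
#' @param rate_factors optional named multipliers of the per-class exchange
#'   rate constants (the per-protein kinetic heterogeneity drawn by
#'   [generate_library()]); `NULL` uses the class means.
#' @param deut_center_shifts optional named per-class shifts (cm^-1) of the
#'   deuterated amide I band centers; `NULL` uses the band-table values.
#' @return An [ftir_spectrum] on the config grid.
#' @export
synthesize_spectrum <- function(profile, composition = NULL, t, cfg,
                                timepoint = NULL, protein_id = "synthetic",
                                rate_factors = NULL,
                                deut_center_shifts = NULL) {
  stopifnot(inherits(profile, "structure_profile"))
  if (abs(profile[["H"]] + profile[["E"]] + profile[["Others"]] - 100) > 1e-9) {
    stop("profile error: fractions do not sum to 100")
  }
  if (is.null(timepoint)) {
    known <- timepoint_minutes(HDX_TIMEPOINTS)
    hit <- which(abs(known - t) < 1e-9)
    timepoint <- if (length(hit) == 1L) HDX_TIMEPOINTS[hit] else "t0"
  }
  nu <- cfg$grid
  f <- .class_fractions_at(t, cfg$kinetics, rate_factors)
  frac <- c(H_ordered = profile[["ordered_H"]],
            H_disordered = profile[["disordered_H"]],
            Others = profile[["Others"]],
            E_main = profile[["E"]],
            E_anti_high = profile[["E_antiparallel"]])
  a <- numeric(length(nu))
  bt <- cfg$bands
  if (!is.null(deut_center_shifts)) {
    sh <- deut_center_shifts[bt$class]
    sh[is.na(sh)] <- 0
    bt$center_d <- pmin(bt$center_d + sh, bt$center_p - 1)
  }
  for (k in seq_len(nrow(bt))) {
    cl <- bt$class[k]
    w <- frac[[cl]] / 100 * bt$rel_amp[k]
    if (w == 0) next
    fk <- f[[cl]]
    a <- a +
      w * (1 - fk) * .band_shape(nu, bt$center_p[k], bt$width_p[k], 1) +
      w * fk * .band_shape(nu, bt$center_d[k], bt$width_d[k], 1)
  }
  # amide II decays and amide II' grows with the residue-weighted exchange
  backbone <- c(H_ordered = profile[["ordered_H"]],
                H_disordered = profile[["disordered_H"]],
                Others = profile[["Others"]],
                E = profile[["E"]])
  a2 <- attr(cfg$bands, "amide2")
  a2p <- attr(cfg$bands, "amide2p")
  protonated_w <- sum(backbone / 100 * (1 - f[names(backbone)]))
  deuterated_w <- sum(backbone / 100 * f[names(backbone)])
  a <- a + a2$rel_amp * protonated_w * .band_shape(nu, a2$center, a2$width, 1)
  a <- a + a2p$rel_amp * deuterated_w * .band_shape(nu, a2p$center, a2p$width, 1)
  if (!is.null(composition)) {
    fsc <- f[["sidechain"]]
    scp <- build_sidechain_spectrum(composition, "protonated", nu, cfg$sidechain)
    scd <- build_sidechain_spectrum(composition, "deuterated", nu, cfg$sidechain)
    a <- a + (1 - fsc) * scp$absorbance + fsc * scd$absorbance
  }
  a <- a * cfg$amide_scale
  if (diff(cfg$baseline_offset_range) > 0 || any(cfg$baseline_offset_range != 0) ||
      any(cfg$baseline_slope_range != 0)) {
    off <- stats::runif(1, cfg$baseline_offset_range[1],
                        cfg$baseline_offset_range[2])
    slp <- stats::runif(1, cfg$baseline_slope_range[1],
                        cfg$baseline_slope_range[2])
    a <- a + off + slp * (nu - mean(nu))
  }
  if (cfg$noise_sd > 0) a <- a + stats::rnorm(length(nu), 0, cfg$noise_sd)
  ftir_spectrum(nu, a, protein_id, timepoint)
}

# One Dirichlet draw via independent gammas.
.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Sample a reference structure profile
#'
#' Draws (H, E, Others) from the config's Dirichlet, the ordered-helix share
#' from `ordered_beta` and the antiparallel share of sheet from `anti_beta`.
#' Uses the current RNG stream.
#'
#' @param cfg a [generator_config()].
#' @return A [structure_profile].
#' @export
sample_structure_profile <- function(cfg) {
  fr <- 100 * .rdirichlet1(cfg$dirichlet_alpha)
  u <- stats::rbeta(1, cfg$ordered_beta[1], cfg$ordered_beta[2])
  v <- stats::rbeta(1, cfg$anti_beta[1], cfg$anti_beta[2])
  structure_profile(
    H = fr[1L], E = fr[2L], Others = fr[3L],
    ordered_H = u * fr[1L], disordered_H = (1 - u) * fr[1L],
    E_parallel = (1 - v) * fr[2L], E_antiparallel = v * fr[2L]
  )
}

#' Generate a synthetic HDX spectral library
#'
#' Draws `cfg$n` proteins -- reference structure profile, amino-acid
#' composition and the four timepoint spectra (t0, t15, t105, t24h) -- from
#' one RNG stream seeded with `cfg$seed`, so the same config yields
#' byte-identical output.
#'
#' @param cfg a [generator_config()].
#' @return A list with elements `series` (list of [hdx_series]), `profiles`
#'   (named list of [structure_profile]), `compositions` (n x 20 percent
#'   matrix) and `config`.
#' @export
generate_library <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  ids <- sprintf("P%03d", seq_len(cfg$n))
  tmins <- timepoint_minutes(HDX_TIMEPOINTS)
  series <- vector("list", cfg$n)
  profiles <- vector("list", cfg$n)
  comps <- matrix(0, cfg$n, length(cfg$comp_mean),
                  dimnames = list(ids, names(cfg$comp_mean)))
  for (i in seq_len(cfg$n)) {
    prof <- sample_structure_profile(cfg)
    comp <- 100 * .rdirichlet1(cfg$comp_concentration * cfg$comp_mean / 100)
    names(comp) <- names(cfg$comp_mean)
    rf <- NULL
    if (cfg$kinetics_jitter_sd > 0) {
      rf <- stats::setNames(
        exp(stats::rnorm(nrow(cfg$kinetics), 0, cfg$kinetics_jitter_sd)),
        cfg$kinetics$class
      )
    }
    dsh <- NULL
    if (any(cfg$deut_center_jitter_sd > 0)) {
      sds <- cfg$deut_center_jitter_sd[cfg$bands$class]
      sds[is.na(sds)] <- 0
      dsh <- stats::setNames(stats::rnorm(nrow(cfg$bands), 0, sds),
                             cfg$bands$class)
    }
    sp <- lapply(seq_along(HDX_TIMEPOINTS), function(k) {
      synthesize_spectrum(prof, comp, tmins[k], cfg,
                          timepoint = HDX_TIMEPOINTS[k], protein_id = ids[i],
                          rate_factors = rf, deut_center_shifts = dsh)
    })
    series[[i]] <- hdx_series(sp)
    profiles[[i]] <- prof
    comps[i, ] <- comp
  }
  names(series) <- ids
  names(profiles) <- ids
  list(series = series, profiles = profiles, compositions = comps,
       config = cfg)
}

#' Reference fraction matrix of a generated library
#'
#' @param lib result of [generate_library()].
#' @return Numeric matrix, proteins x structure fractions.
#' @export
library_profiles_matrix <- function(lib) {
  do.call(rbind, lapply(lib$profiles, function(p) unclass(p)))
}

#' Export a generated library to plain-text files
#'
#' Writes the raw spectra (CSV, [write_spectra_csv()] dialect), the reference
#' fractions (TSV) and the sampled compositions as synthetic sequences
#' (FASTA; each sequence is a deterministic 200-residue realization of the
#' protein's composition, not a real protein sequence).
#'
#' @param lib result of [generate_library()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spectra <- unlist(lapply(lib$series, function(s) s$spectra), recursive = FALSE)
  p_spec <- file.path(dir, "spectra.csv")
  write_spectra_csv(spectra, p_spec)
  p_prof <- file.path(dir, "profiles.tsv")
  write_fraction_report(lib$profiles, p_prof)
  p_fa <- file.path(dir, "compositions.fasta")
  seq_len_target <- 200L
  lines <- unlist(lapply(rownames(lib$compositions), function(id) {
    counts <- round(lib$compositions[id, ] * seq_len_target / 100)
    counts[1L] <- counts[1L] + (seq_len_target - sum(counts))  # pad to length
    counts[counts < 0] <- 0
    s <- paste(rep(names(counts), counts), collapse = "")
    c(paste0(">", id, " synthetic_composition_realization"), s)
  }))
  writeLines(lines, p_fa)
  invisible(c(spectra = p_spec, profiles = p_prof, fasta = p_fa))
}
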