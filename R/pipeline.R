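STRUCTURE_TARGETS <- c("H", "ordered_H", "Others", "E", "E_antiparallel")
CONDITIONS <- c("t0", "t15", "t105", "t24h", "t_GM")

#' Configuration of a full structure-prediction experiment
#'
#' @param generator a [generator_config()] describing the synthetic library,
#'   or `NULL` when `spectra_csv`/`profiles_tsv` point to existing files.
#' @param spectra_csv,profiles_tsv optional paths to a spectra matrix
#'   ([read_spectra_csv()] dialect) and a reference-fraction TSV; used
#'   instead of the generator when both are given.
#' @param structures structure fractions to predict (subset of `"H"`,
#'   `"ordered_H"`, `"Others"`, `"E"`, `"E_antiparallel"`).
#' @param models regression engines to run (subset of `"PLS"`, `"SVM"`,
#'   `"ASLR"`).
#' @param conditions spectral conditions: individual timepoints and/or
#'   `"t_GM"`, the global model on the concatenated four-timepoint spectra.
#' @param ks_test_size Kennard-Stone test-set size (default 25).
#' @param lv_range latent-variable counts scanned for PLS.
#' @param aslr_max_vars maximum wavenumbers selected by ASLR.
#' @param svm_gammas,svm_sigma2s LS-SVM hyperparameter grid.
#' @param outdir output directory for the report files.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(),
                              spectra_csv = NULL, profiles_tsv = NULL,
                              structures = c("H", "Others", "E"),
                              models = c("PLS", "ASLR"),
                              conditions = CONDITIONS,
                              ks_test_size = 25L,
                              lv_range = 1:10,
                              aslr_max_vars = 5L,
                              svm_gammas = 10^(-1:4),
                              svm_sigma2s = 10^(-1:3),
                              outdir = tempfile("ftirhdx_run")) {
  bad <- setdiff(structures, STRUCTURE_TARGETS)
  if (length(bad) > 0L) {
    stop("configuration error: unknown structure name(s): ",
         paste(bad, collapse = ", "))
  }
  bad <- setdiff(models, c("PLS", "SVM", "ASLR"))
  if (length(bad) > 0L) {
    stop("configuration error: unknown model(s): ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(conditions, CONDITIONS)
  if (length(bad) > 0L) {
    stop("configuration error: unknown condition(s): ",
         paste(bad, collapse = ", "))
  }
  if (length(structures) == 0L || length(models) == 0L ||
      length(conditions) == 0L) {
    stop("configuration error: need at least one structure, model and condition")
  }
  if (is.null(generator) && (is.null(spectra_csv) || is.null(profiles_tsv))) {
    stop("configuration error: need a generator or spectra_csv + profiles_tsv")
  }
  structure(
    list(generator = generator, spectra_csv = spectra_csv,
         profiles_tsv = profiles_tsv, structures = structures, models = models,
         conditions = conditions, ks_test_size = as.integer(ks_test_size),
         lv_range = lv_range, aslr_max_vars = as.integer(aslr_max_vars),
         svm_gammas = svm_gammas, svm_sigma2s = svm_sigma2s, outdir = outdir),
    class = "experiment_config"
  )
}

# Preprocess one series: baseline correction then vector normalization,
# per timepoint spectrum.
.preprocess_series <- function(series) {
  hdx_series(lapply(series$spectra, function(s) {
    vector_normalize(baseline_correct(s))
  }))
}

# Feature matrices per condition from preprocessed series.
.condition_matrices <- function(series_list) {
  c1 <- concatenate_series(series_list[[1L]])
  bl <- attr(c1, "block_length")
  nu <- attr(c1, "wavenumbers")
  concat <- t(vapply(series_list, concatenate_series, numeric(length(c1))))
  mats <- list(t_GM = concat)
  for (k in seq_along(HDX_TIMEPOINTS)) {
    mats[[HDX_TIMEPOINTS[k]]] <- concat[, ((k - 1L) * bl + 1L):(k * bl),
                                        drop = FALSE]
  }
  attr(mats, "block_wavenumbers") <- nu
  mats
}

# RMSECV and variable count of one model on (X, y) by LOO.
.model_loo <- function(model, X, y, cfg) {
  switch(model,
    PLS = {
      prof <- pls_loo_profile(X, y, cfg$lv_range)
      best <- which.min(prof)
      list(rmse = unname(prof[best]), n_var = cfg$lv_range[best],
           n_var_label = paste0(cfg$lv_range[best], " LVs"))
    },
    SVM = {
      gs <- lssvm_grid_search(X, y, cfg$svm_gammas, cfg$svm_sigma2s)
      list(rmse = gs$rmsecv, n_var = NA_integer_, n_var_label = "",
           gamma = gs$gamma, sigma2 = gs$sigma2)
    },
    ASLR = {
      m <- fit_aslr(X, y, cfg$aslr_max_vars)
      best <- which.min(m$rmsecv)
      list(rmse = m$rmsecv[best], n_var = best,
           n_var_label = paste0(best, " wvnbs"), model = m)
    }
  )
}

# Test-set RMSE of one model trained on the KS training set.
.model_ks <- function(model, Xtr, ytr, Xte, yte, cfg) {
  switch(model,
    PLS = {
      prof <- pls_loo_profile(Xtr, ytr, cfg$lv_range)
      lv <- cfg$lv_range[which.min(prof)]
      m <- fit_pls(Xtr, ytr, lv)
      list(rmse = sqrt(mean((yte - predict(m, Xte))^2)), n_var = lv,
           n_var_label = paste0(lv, " LVs"))
    },
    SVM = {
      gs <- lssvm_grid_search(Xtr, ytr, cfg$svm_gammas, cfg$svm_sigma2s)
      m <- fit_lssvm(Xtr, ytr, gs$gamma, gs$sigma2)
      list(rmse = sqrt(mean((yte - predict(m, Xte))^2)), n_var = NA_integer_,
           n_var_label = "")
    },
    ASLR = {
      m <- fit_aslr(Xtr, ytr, cfg$aslr_max_vars)
      list(rmse = sqrt(mean((yte - predict(m, Xte))^2)),
           n_var = length(m$selected),
           n_var_label = paste0(length(m$selected), " wvnbs"))
    }
  )
}

#' Run the full structure-prediction experiment
#'
#' Generates (or loads) the spectral library, preprocesses every spectrum
#' (baseline correction, vector normalization), assembles the per-timepoint
#' and concatenated global-model feature matrices, and evaluates every
#' requested model x condition x structure combination by leave-one-out
#' cross-validation and on an independent Kennard-Stone test set. Writes
#' TSV reports plus the intermediate artifacts (spectra CSV, reference
#' fraction TSV, ASLR profiles, run log); a rerun with the same config
#' produces identical files.
#'
#' @param cfg an [experiment_config()].
#' @return Invisibly, a list with `loo` and `ks` metric data.frames (columns
#'   `model`, `condition`, `structure`, `rmse`, `n_var`, `stddev_ref`,
#'   `zeta`), `aslr_tables`, and `paths` of the written files.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("ftirhdx run log", "===============")
  if (!is.null(cfg$spectra_csv) && !is.null(cfg$profiles_tsv)) {
    spectra <- read_spectra_csv(cfg$spectra_csv)
    ids <- unique(vapply(spectra, function(s) s$protein_id, character(1)))
    series_list <- lapply(ids, function(id) {
      hdx_series(Filter(function(s) s$protein_id == id, spectra))
    })
    names(series_list) <- ids
    prof_df <- utils::read.delim(cfg$profiles_tsv)
    Yref <- as.matrix(prof_df[match(ids, prof_df$protein_id),
                              STRUCTURE_TARGETS])
    rownames(Yref) <- ids
    log_lines <- c(log_lines, paste("input spectra:", cfg$spectra_csv),
                   paste("input profiles:", cfg$profiles_tsv))
  } else {
    lib <- generate_library(cfg$generator)
    series_list <- lib$series
    Yref <- library_profiles_matrix(lib)[, STRUCTURE_TARGETS, drop = FALSE]
    write_library(lib, cfg$outdir)
    log_lines <- c(log_lines,
                   paste("synthetic library: n =", cfg$generator$n,
                         "seed =", cfg$generator$seed,
                         "noise_sd =", cfg$generator$noise_sd))
  }
  pre <- lapply(series_list, .preprocess_series)
  mats <- .condition_matrices(pre)
  nu_block <- attr(mats, "block_wavenumbers")

  rows_loo <- list()
  rows_ks <- list()
  aslr_tables <- list()
  for (st in cfg$structures) {
    y <- Yref[, st]
    sdref <- stddev_ref(y)
    ks <- kennard_stone_select(y, min(cfg$ks_test_size, nrow(Yref) - 2L))
    log_lines <- c(log_lines, sprintf(
      "KS split for %s: test = %s", st,
      paste(sort(ks$test_indices), collapse = ",")
    ))
    for (md in cfg$models) {
      for (cond in cfg$conditions) {
        X <- mats[[cond]]
        r <- .model_loo(md, X, y, cfg)
        rows_loo[[length(rows_loo) + 1L]] <- data.frame(
          model = md, condition = cond, structure = st, rmse = r$rmse,
          n_var = r$n_var, stddev_ref = sdref, zeta = zeta(sdref, r$rmse)
        )
        if (md == "SVM" && !is.null(r$gamma)) {
          log_lines <- c(log_lines, sprintf(
            "SVM %s %s: gamma = %g sigma2 = %g", st, cond, r$gamma, r$sigma2))
        }
        if (md == "ASLR" && cond == "t_GM") {
          m <- r$model
          bl <- length(nu_block)
          tp_idx <- (m$selected - 1L) %/% bl + 1L
          aslr_tables[[st]] <- data.frame(
            structure = st, rank = seq_along(m$selected),
            wavenumber = nu_block[(m$selected - 1L) %% bl + 1L],
            timepoint = HDX_TIMEPOINTS[tp_idx],
            rmsecv = m$rmsecv
          )
          write_aslr_profile(
            m, file.path(cfg$outdir, paste0("aslr_profile_", st, ".csv")),
            rep(nu_block, 4L)
          )
        }
        rk <- .model_ks(md, X[ks$train_indices, , drop = FALSE],
                        y[ks$train_indices],
                        X[ks$test_indices, , drop = FALSE],
                        y[ks$test_indices], cfg)
        sdref_ks <- stddev_ref(y[ks$test_indices])
        rows_ks[[length(rows_ks) + 1L]] <- data.frame(
          model = md, condition = cond, structure = st, rmse = rk$rmse,
          n_var = rk$n_var, stddev_ref = sdref_ks,
          zeta = zeta(sdref_ks, rk$rmse)
        )
      }
    }
  }
  loo <- do.call(rbind, rows_loo)
  ksdf <- do.call(rbind, rows_ks)

  fmt <- function(df) {
    df$rmse <- round(df$rmse, 2)
    df$stddev_ref <- round(df$stddev_ref, 2)
    df$zeta <- round(df$zeta, 2)
    df
  }
  p1 <- file.path(cfg$outdir, "table_loo.tsv")
  p2 <- file.path(cfg$outdir, "table_ks.tsv")
  utils::write.table(fmt(loo), p1, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(fmt(ksdf), p2, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(loo = p1, ks = p2)
  if (length(aslr_tables) > 0L) {
    p3 <- file.path(cfg$outdir, "aslr_wavenumbers.tsv")
    at <- do.call(rbind, aslr_tables)
    at$rmsecv <- round(at$rmsecv, 2)
    utils::write.table(at, p3, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, aslr = p3)
  }
  log_lines <- c(log_lines,
                 paste("models:", paste(cfg$models, collapse = ", ")),
                 paste("conditions:", paste(cfg$conditions, collapse = ", ")),
                 paste("structures:", paste(cfg$structures, collapse = ", ")),
                 paste("lv_range:", paste(range(cfg$lv_range), collapse = "..")),
                 paste("aslr_max_vars:", cfg$aslr_max_vars),
                 paste("ks_test_size:", cfg$ks_test_size))
  plog <- file.path(cfg$outdir, "run_log.txt")
  writeLines(log_lines, plog)
  paths <- c(paths, log = plog)
  invisible(list(loo = loo, ks = ksdf, aslr_tables = aslr_tables,
                 paths = paths))
}
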