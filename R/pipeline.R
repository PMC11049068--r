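#' Subset a spectra table to a set of channels
#'
#' @param x spectra table.
#' @param channels 1-based channel indices (into the current axis).
#' @return a spectra table with the retained channels.
#' @export
select_channels <- function(x, channels) {
  check_spectra(x)
  chan_cols <- setdiff(names(x), "sample_id")
  if (any(channels < 1) || any(channels > length(chan_cols))) {
    stop("select_channels: channel indices out of range", call. = FALSE)
  }
  x[c("sample_id", chan_cols[channels])]
}

# pretreat all samples with the MSC reference (when used) frozen on the
# calibration partition, so nothing leaks across the split
pretreat_with_partition <- function(spectra, method, partition, window = 7, gap = 5) {
  if (method == "msc") {
    ref <- msc_fit(filter_samples(spectra, partition$calibration_ids))
    pretreat(spectra, "msc", reference = ref)
  } else {
    pretreat(spectra, method, window = window, gap = gap)
  }
}

#' Sweep spectral pretreatments for one analyte
#'
#' Fits a full-spectrum PLS model (component count chosen by cross-validated
#' RMSECV) for each candidate pretreatment, evaluates each on the prediction
#' set, and picks the winner by highest prediction R² (ties broken by lower
#' RMSEP). The MSC reference spectrum is always computed on the calibration
#' partition only.
#'
#' @param spectra spectra table (all samples).
#' @param reference reference tibble (`sample_id` + analyte columns).
#' @param analyte analyte column name.
#' @param partition a `ks_partition` over the samples of `spectra`.
#' @param methods pretreatments to try (subset of
#'   `c("raw", "smooth", "d1_sg", "d2_sg", "msc", "snv")`).
#' @param ncomp_max largest component count considered.
#' @param window,gap smoothing halfwidth and derivative gap (channels).
#' @param folds cross-validation scheme.
#' @return a list of class `pretreat_sweep`: `best_method`, `sweep` (tibble
#'   with one evaluation row per method).
#' @export
run_pretreatment_sweep <- function(spectra, reference, analyte, partition,
                                   methods = c("raw", "smooth", "d1_sg",
                                               "d2_sg", "msc", "snv"),
                                   ncomp_max = 18, window = 7, gap = 5,
                                   folds = "loo") {
  if (!length(methods)) stop("run_pretreatment_sweep: empty `methods`", call. = FALSE)
  rows <- lapply(methods, function(m) {
    pp <- tryCatch(
      pretreat_with_partition(spectra, m, partition, window, gap),
      error = function(e) stop("pretreatment `", m, "` failed: ",
                               conditionMessage(e), call. = FALSE)
    )
    cal <- filter_samples(pp, partition$calibration_ids)
    prd <- filter_samples(pp, partition$prediction_ids)
    y_cal <- reference_vector(reference, analyte, cal$sample_id)
    y_prd <- reference_vector(reference, analyte, prd$sample_id)
    cv <- pls_cv(cal, y_cal, ncomp_max, folds)
    fit <- pls_fit(cal, y_cal, cv$optimal_ncomp)
    evaluate_model(fit, cal, y_cal, prd, y_prd,
                   rmsecv = cv$metrics$rmsecv[cv$optimal_ncomp],
                   model_label = m, analyte = analyte)
  })
  sweep_tbl <- dplyr::bind_rows(rows)
  best <- sweep_tbl |>
    dplyr::arrange(dplyr::desc(.data$r2_p), .data$rmsep) |>
    dplyr::slice(1)
  structure(list(best_method = best$model, sweep = sweep_tbl),
            class = "pretreat_sweep")
}

#' @export
print.pretreat_sweep <- function(x, ...) {
  cat("<pretreat_sweep> best: ", x$best_method, "\n", sep = "")
  print(x$sweep[, c("model", "ncomp", "r2_c", "rmsec", "r2_p", "rmsep")])
  invisible(x)
}

#' Configure an end-to-end calibration experiment
#'
#' Collects every setting of the full workflow — data source, outlier
#' screening, partitioning, pretreatment sweep, wavelength selection, model
#' sizing and the master seed — into one validated object for
#' [run_full_experiment()].
#'
#' @param spectra,reference in-memory spectra table and reference tibble, or
#'   `NULL` to use `synthetic`/file paths.
#' @param spectra_path,reference_path delimited-text inputs (used when the
#'   in-memory tables are `NULL`).
#' @param synthetic a [synthetic_config()]; when given, data are generated
#'   (seed overridden by `seed` for reproducibility of the whole run).
#' @param analytes analyte column names; default: every non-id reference
#'   column.
#' @param pretreat_methods candidate pretreatments for the sweep.
#' @param selection_methods any of `"uve"`, `"cars"`; `character(0)` runs the
#'   full-spectrum model only.
#' @param screen_outliers run the Mahalanobis screen first?
#' @param k_components,sd_multiplier screen parameters.
#' @param calibration_fraction fraction of retained samples placed in the
#'   calibration set by Kennard-Stone (`n_cal = round(fraction * n)`), unless
#'   `n_calibration` is given explicitly.
#' @param n_calibration optional explicit calibration-set size.
#' @param ncomp_max largest component count considered anywhere.
#' @param window,gap pretreatment parameters (channels).
#' @param cars_runs,mc_fraction CARS schedule length and Monte-Carlo sample
#'   fraction.
#' @param folds cross-validation scheme (`"loo"` or integer folds) used in
#'   every RMSECV.
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it, so one seed fixes the whole experiment.
#' @param out_dir optional directory; when set, every stage artifact is
#'   written there as plain text.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(spectra = NULL, reference = NULL,
                            spectra_path = NULL, reference_path = NULL,
                            synthetic = NULL,
                            analytes = NULL,
                            pretreat_methods = c("raw", "smooth", "d1_sg",
                                                 "d2_sg", "msc", "snv"),
                            selection_methods = c("uve", "cars"),
                            screen_outliers = TRUE,
                            k_components = 5, sd_multiplier = 3,
                            calibration_fraction = 0.8, n_calibration = NULL,
                            ncomp_max = 18, window = 7, gap = 5,
                            cars_runs = 100, mc_fraction = 0.8,
                            folds = "loo", seed = 1L, out_dir = NULL) {
  has_source <- !is.null(spectra) || !is.null(spectra_path) || !is.null(synthetic)
  if (!has_source) {
    stop("pipeline_config: provide `spectra`, `spectra_path` or `synthetic`",
         call. = FALSE)
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config")) {
    stop("pipeline_config: `synthetic` must be a synthetic_config()", call. = FALSE)
  }
  if (!is.null(spectra_path) && !file.exists(spectra_path)) {
    stop("pipeline_config: spectra_path does not exist: ", spectra_path, call. = FALSE)
  }
  if (!is.null(reference_path) && !file.exists(reference_path)) {
    stop("pipeline_config: reference_path does not exist: ", reference_path,
         call. = FALSE)
  }
  bad_sel <- setdiff(selection_methods, c("uve", "cars"))
  if (length(bad_sel)) {
    stop("pipeline_config: unknown selection method(s): ",
         paste(bad_sel, collapse = ", "), call. = FALSE)
  }
  structure(
    list(spectra = spectra, reference = reference,
         spectra_path = spectra_path, reference_path = reference_path,
         synthetic = synthetic, analytes = analytes,
         pretreat_methods = pretreat_methods,
         selection_methods = selection_methods,
         screen_outliers = isTRUE(screen_outliers),
         k_components = k_components, sd_multiplier = sd_multiplier,
         calibration_fraction = calibration_fraction,
         n_calibration = n_calibration,
         ncomp_max = as.integer(ncomp_max), window = window, gap = gap,
         cars_runs = as.integer(cars_runs), mc_fraction = mc_fraction,
         folds = folds, seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

# deterministic per-stage seed derivation from the master seed
stage_seed <- function(seed, analyte_index, offset) {
  (seed * 1009L + analyte_index * 97L + offset) %% 2147483647L
}

#' Run the full calibration experiment
#'
#' Executes the complete workflow from one config: (optional) Mahalanobis
#' outlier screen, Kennard-Stone calibration/prediction split, pretreatment
#' sweep per analyte, full-spectrum / UVE / CARS PLS models, and the
#' three-way comparison table with percent RMSEP reduction of CARS relative
#' to the full spectrum. All cross-validation, selection and the MSC
#' reference use calibration samples only; the prediction set is touched only
#' at evaluation. One seed fixes every stochastic stage.
#'
#' @param config a [pipeline_config()].
#' @return a list of class `nir_experiment`: `comparison` (tibble),
#'   `reports`, `sweeps` (per analyte), `selections` (per analyte, per
#'   method), `partition`, `outliers`, `manifest` (config echo, per-stage
#'   seeds and timings, sample counts, artifact paths).
#' @export
run_full_experiment <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  timings <- list()
  tick <- function(name, expr) {
    s <- Sys.time()
    out <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    out
  }

  # --- data ---------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    syn_cfg <- config$synthetic
    syn_cfg$seed <- stage_seed(config$seed, 0L, 1L)
    dataset <- tick("generate", generate_nir(syn_cfg))
    spectra <- dataset$spectra
    reference <- dataset$references
  } else if (!is.null(config$spectra)) {
    dataset <- NULL
    spectra <- config$spectra
    reference <- config$reference
  } else {
    dataset <- NULL
    spectra <- read_spectra(config$spectra_path)
    reference <- read_reference(config$reference_path)
  }
  check_spectra(spectra)
  analytes <- config$analytes %||% setdiff(names(reference), "sample_id")
  missing_an <- setdiff(analytes, names(reference))
  if (length(missing_an)) {
    stop("run_full_experiment: analyte(s) not in reference table: ",
         paste(missing_an, collapse = ", "), call. = FALSE)
  }

  # --- screen and split ---------------------------------------------------
  outliers <- NULL
  retained <- spectra
  if (config$screen_outliers) {
    outliers <- tick("screen",
                     mahalanobis_screen(spectra, config$k_components,
                                        config$sd_multiplier))
    retained <- filter_samples(spectra, outliers$retained_ids)
  }
  n_ret <- nrow(retained)
  n_cal <- config$n_calibration %||% round(config$calibration_fraction * n_ret)
  partition <- tick("partition", kennard_stone(retained, n_cal))

  # --- per-analyte modelling ----------------------------------------------
  reports <- list()
  sweeps <- list()
  selections <- list()
  for (ai in seq_along(analytes)) {
    an <- analytes[ai]
    sweep <- tick(paste0("sweep_", an),
                  run_pretreatment_sweep(retained, reference, an, partition,
                                         methods = config$pretreat_methods,
                                         ncomp_max = config$ncomp_max,
                                         window = config$window, gap = config$gap,
                                         folds = config$folds))
    sweeps[[an]] <- sweep
    pp <- pretreat_with_partition(retained, sweep$best_method, partition,
                                  config$window, config$gap)
    cal <- filter_samples(pp, partition$calibration_ids)
    prd <- filter_samples(pp, partition$prediction_ids)
    y_cal <- reference_vector(reference, an, cal$sample_id)
    y_prd <- reference_vector(reference, an, prd$sample_id)

    # full-spectrum benchmark
    cv_full <- pls_cv(cal, y_cal, config$ncomp_max, config$folds)
    fit_full <- pls_fit(cal, y_cal, cv_full$optimal_ncomp)
    reports[[paste(an, "full", sep = ".")]] <-
      evaluate_model(fit_full, cal, y_cal, prd, y_prd,
                     rmsecv = cv_full$metrics$rmsecv[cv_full$optimal_ncomp],
                     model_label = "full_pls", analyte = an)

    for (method in config$selection_methods) {
      sel <- tick(paste(method, an, sep = "_"), {
        if (method == "uve") {
          # UVE always resamples beta over leave-one-out folds; k-fold CV
          # would leave too few coefficient draws for a stable h ratio
          uve_select(cal, y_cal, ncomp = cv_full$optimal_ncomp,
                     folds = "loo",
                     seed = stage_seed(config$seed, ai, 2L))
        } else {
          cars_select(cal, y_cal, ncomp_max = config$ncomp_max,
                      n_runs = config$cars_runs,
                      mc_fraction = config$mc_fraction,
                      folds = config$folds,
                      seed = stage_seed(config$seed, ai, 3L))
        }
      })
      selections[[paste(an, method, sep = ".")]] <- sel
      chans <- sel$selected_channels
      if (length(chans) < 2) {
        warning("selection `", method, "` for ", an,
                " retained fewer than 2 channels; row omitted")
        next
      }
      cal_s <- select_channels(cal, chans)
      prd_s <- select_channels(prd, chans)
      cv_s <- pls_cv(cal_s, y_cal, config$ncomp_max, config$folds)
      fit_s <- pls_fit(cal_s, y_cal, cv_s$optimal_ncomp)
      reports[[paste(an, method, sep = ".")]] <-
        evaluate_model(fit_s, cal_s, y_cal, prd_s, y_prd,
                       rmsecv = cv_s$metrics$rmsecv[cv_s$optimal_ncomp],
                       model_label = paste0(method, "_pls"), analyte = an)
    }
  }

  required <- c("full_pls",
                if ("cars" %in% config$selection_methods &&
                      any(grepl("\\.cars$", names(reports)))) "cars_pls")
  comparison <- compare_models(reports, required = required)

  manifest <- list(
    seed = config$seed,
    analytes = analytes,
    n_samples = nrow(spectra),
    n_retained = n_ret,
    n_calibration = length(partition$calibration_ids),
    n_prediction = length(partition$prediction_ids),
    flagged_outliers = if (is.null(outliers)) character(0) else outliers$flagged_ids,
    best_pretreatment = vapply(sweeps, `[[`, character(1), "best_method"),
    selection_sizes = vapply(selections, function(s) length(s$selected_channels),
                             integer(1)),
    timings_sec = timings,
    total_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    artifacts = character(0)
  )

  result <- structure(
    list(comparison = comparison, reports = reports, sweeps = sweeps,
         selections = selections, partition = partition, outliers = outliers,
         dataset = dataset, manifest = manifest),
    class = "nir_experiment"
  )

  if (!is.null(config$out_dir)) {
    result$manifest$artifacts <- write_experiment(result, spectra, reference,
                                                  config$out_dir)
  }
  result
}

write_experiment <- function(result, spectra, reference, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    spectra = file.path(dir, "spectra.csv"),
    references = file.path(dir, "references.csv"),
    partition = file.path(dir, "partition.json"),
    comparison = file.path(dir, "comparison.csv"),
    comparison_txt = file.path(dir, "comparison.txt"),
    manifest = file.path(dir, "manifest.yaml")
  )
  write_spectra(spectra, paths[["spectra"]])
  write_reference(reference, paths[["references"]])
  write_partition(result$partition, paths[["partition"]])
  readr::write_csv(result$comparison, paths[["comparison"]])
  writeLines(format_comparison(result$comparison), paths[["comparison_txt"]])
  for (nm in names(result$selections)) {
    p <- file.path(dir, paste0("selection_", gsub("\\.", "_", nm), ".json"))
    write_selection(result$selections[[nm]], p)
    paths[nm] <- p
  }
  yaml::write_yaml(result$manifest[setdiff(names(result$manifest), "artifacts")],
                   paths[["manifest"]])
  paths
}

#' @export
print.nir_experiment <- function(x, ...) {
  cat("<nir_experiment> ", x$manifest$n_retained, " samples (",
      x$manifest$n_calibration, "/", x$manifest$n_prediction, " split), ",
      length(x$manifest$analytes), " analyte(s)\n", sep = "")
  print(x$comparison[, c("analyte", "model", "ncomp", "n_variables",
                         "r2_p", "rmsep", "rpd", "rmsep_reduction_pct")])
  invisible(x)
}
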