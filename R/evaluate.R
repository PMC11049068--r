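#' Root mean squared error
#'
#' `sqrt(mean((predicted - measured)^2))` with the plain count divisor (not
#' count - 1), the convention behind RMSEC, RMSEP and RMSECV.
#'
#' @param predicted,measured numeric vectors of equal length >= 1.
#' @return a single non-negative number (g kg^-1 when the inputs are).
#' @export
rmse <- function(predicted, measured) {
  if (length(predicted) == 0) stop("rmse: empty input", call. = FALSE)
  if (length(predicted) != length(measured)) {
    stop("rmse: predicted and measured lengths differ", call. = FALSE)
  }
  sqrt(mean((predicted - measured)^2))
}

#' Coefficient of determination, calibration and prediction conventions
#'
#' `1 - SSE/SST` where `SSE = sum((measured - predicted)^2)`. The calibration
#' convention (`"measured_mean"`) centers SST on the mean of the measured
#' values — the classical R². The prediction convention (`"predicted_mean"`)
#' centers SST on the mean of the *predicted* values, the form some NIR
#' reporting uses for the prediction set; the two coincide exactly when the
#' two means are equal.
#'
#' @param predicted,measured numeric vectors of equal length.
#' @param convention `"measured_mean"` (default) or `"predicted_mean"`.
#' @return a single number <= 1 (can be negative for poor models).
#' @export
r_squared <- function(predicted, measured,
                      convention = c("measured_mean", "predicted_mean")) {
  convention <- match.arg(convention)
  if (length(predicted) != length(measured)) {
    stop("r_squared: predicted and measured lengths differ", call. = FALSE)
  }
  centre <- if (convention == "measured_mean") mean(measured) else mean(predicted)
  sst <- sum((measured - centre)^2)
  if (sst <= 0) stop("r_squared: zero total sum of squares", call. = FALSE)
  1 - sum((measured - predicted)^2) / sst
}

#' Residual predictive deviation (RPD)
#'
#' The standard deviation of the measured prediction-set values (n - 1
#' denominator) divided by the RMSEP. Interpretation bands: RPD > 2
#' exceptional, 1.4 < RPD < 2 general, RPD < 1.4 poor.
#'
#' @param measured numeric vector of reference values (>= 2 samples).
#' @param rmsep positive root mean squared error of prediction.
#' @return a single positive number; `rpd_band()` returns the band label.
#' @export
rpd <- function(measured, rmsep) {
  if (length(measured) < 2) stop("rpd: need at least 2 measured values", call. = FALSE)
  if (!is.numeric(rmsep) || rmsep <= 0) stop("rpd: rmsep must be > 0", call. = FALSE)
  stats::sd(measured) / rmsep
}

#' @rdname rpd
#' @param x an RPD value (vectorized).
#' @export
rpd_band <- function(x) {
  ifelse(x > 2, "exceptional", ifelse(x > 1.4, "general", "poor"))
}

#' Evaluate one fitted model on a calibration/prediction split
#'
#' Computes the full report for one model on one analyte: calibration R² and
#' RMSEC, prediction R² and RMSEP, cross-validated RMSECV (recomputed on the
#' final channel subset at the final component count), and the RPD of the
#' prediction set.
#'
#' @param model an `nir_pls` fit on the calibration set.
#' @param cal_x,cal_y calibration spectra (matching the model's channels) and
#'   concentrations.
#' @param pred_x,pred_y prediction-set spectra and concentrations.
#' @param rmsecv optional precomputed RMSECV; if `NULL` it is recomputed by
#'   cross-validation on the calibration set at the model's component count.
#' @param folds cross-validation scheme when recomputing RMSECV.
#' @param r2_prediction_convention convention passed to [r_squared()] for the
#'   prediction set (default `"predicted_mean"`).
#' @param model_label,analyte optional labels carried into the report.
#' @return a one-row tibble of class `evaluation_report` with columns
#'   `analyte`, `model`, `ncomp`, `n_variables`, `r2_c`, `rmsecv`, `rmsec`,
#'   `r2_p`, `rmsep`, `rpd`, `n_calibration`, `n_prediction`.
#' @export
evaluate_model <- function(model, cal_x, cal_y, pred_x, pred_y,
                           rmsecv = NULL, folds = "loo",
                           r2_prediction_convention = "predicted_mean",
                           model_label = "pls", analyte = "analyte") {
  stopifnot(inherits(model, "nir_pls"))
  cal_pred <- predict(model, cal_x)
  pred_pred <- predict(model, pred_x)
  if (is.null(rmsecv)) {
    X <- as_x_matrix(cal_x)
    err2 <- cv_sqerr(X, as.numeric(cal_y), model$ncomp, folds)
    rmsecv <- sqrt(mean(err2[, model$ncomp]))
  }
  rmsep <- rmse(pred_pred, pred_y)
  ncomp <- model$ncomp
  n_variables <- model$p
  out <- tibble::tibble(
    analyte = analyte,
    model = model_label,
    ncomp = ncomp,
    n_variables = n_variables,
    r2_c = r_squared(cal_pred, cal_y, "measured_mean"),
    rmsecv = rmsecv,
    rmsec = rmse(cal_pred, cal_y),
    r2_p = r_squared(pred_pred, pred_y, r2_prediction_convention),
    rmsep = rmsep,
    rpd = rpd(pred_y, rmsep),
    n_calibration = length(cal_y),
    n_prediction = length(pred_y)
  )
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Percent RMSEP reduction of one model relative to another
#'
#' `100 * (rmsep_reference - rmsep_model) / rmsep_reference`: the headline
#' figure for how much a wavelength-selected model improves on the
#' full-spectrum benchmark.
#'
#' @param rmsep_reference RMSEP of the benchmark (e.g. full-spectrum) model.
#' @param rmsep_model RMSEP of the improved model.
#' @return percent reduction (positive when the model improves).
#' @export
rmsep_reduction <- function(rmsep_reference, rmsep_model) {
  if (any(rmsep_reference <= 0)) stop("rmsep_reduction: reference RMSEP must be > 0",
                                      call. = FALSE)
  100 * (rmsep_reference - rmsep_model) / rmsep_reference
}

#' Assemble the three-way model comparison table
#'
#' Binds per-model evaluation reports and appends, per analyte, the percent
#' RMSEP reduction of the CARS-selected model relative to the full-spectrum
#' model. Rows are ordered analyte-major with models in the order full_pls,
#' cars_pls, uve_pls.
#'
#' @param reports a list (or single tibble) of `evaluation_report` rows; the
#'   `model` column must use the labels `full_pls`, `uve_pls`, `cars_pls`.
#' @param required models that must be present per analyte; an absent one is
#'   an error naming it. Drivers that run the full-spectrum model only relax
#'   this to `"full_pls"`.
#' @return a tibble with one row per (analyte, model) and a
#'   `rmsep_reduction_pct` column on the `cars_pls` rows.
#' @export
compare_models <- function(reports, required = c("full_pls", "cars_pls")) {
  tbl <- if (is.data.frame(reports)) tibble::as_tibble(reports) else dplyr::bind_rows(reports)
  need <- c("analyte", "model", "rmsep")
  if (!all(need %in% names(tbl))) {
    stop("compare_models: reports must carry columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  for (an in unique(tbl$analyte)) {
    models <- tbl$model[tbl$analyte == an]
    for (m in required) {
      if (!m %in% models) {
        stop("compare_models: missing model `", m, "` for analyte `", an, "`",
             call. = FALSE)
      }
    }
  }
  order_lv <- c("full_pls", "cars_pls", "uve_pls")
  tbl |>
    dplyr::group_by(.data$analyte) |>
    dplyr::mutate(
      rmsep_reduction_pct = dplyr::if_else(
        .data$model == "cars_pls" & any(.data$model == "full_pls"),
        rmsep_reduction(.data$rmsep[.data$model == "full_pls"][1], .data$rmsep),
        NA_real_
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$analyte,
                   match(.data$model, order_lv, nomatch = length(order_lv) + 1L))
}

#' Render a comparison table in the standard reporting layout
#'
#' Formats a [compare_models()] tibble with the conventional column order
#' (PCs, Variables, R_c^2, RMSECV, RMSEC, R_p^2, RMSEP, RPD), numbers to 4
#' significant figures, one row per (analyte, model).
#'
#' @param comparison a tibble from [compare_models()].
#' @return a character vector of tab-separated lines (header first).
#' @export
format_comparison <- function(comparison) {
  fmt <- function(v) vapply(v, function(x) format(signif(x, 4), trim = TRUE),
                            character(1))
  header <- paste("Analyte", "Model", "PCs", "Variables", "R_c^2", "RMSECV",
                  "RMSEC", "R_p^2", "RMSEP", "RPD", sep = "\t")
  rows <- vapply(seq_len(nrow(comparison)), function(i) {
    r <- comparison[i, ]
    paste(r$analyte, r$model, r$ncomp, r$n_variables, fmt(r$r2_c),
          fmt(r$rmsecv), fmt(r$rmsec), fmt(r$r2_p), fmt(r$rmsep), fmt(r$rpd),
          sep = "\t")
  }, character(1))
  c(header, rows)
}
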