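#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted PLS model
#'
#' One row per channel: wavelength, regression coefficient (at the fitted
#' component count) and the first-component weight.
#'
#' @param x an `nir_pls`.
#' @param ... unused.
#' @return a tibble with columns `channel`, `wavelength`, `coefficient`,
#'   `weight`.
#' @method tidy nir_pls
#' @export
tidy.nir_pls <- function(x, ...) {
  tibble::tibble(
    channel = seq_len(x$p),
    wavelength = x$wavelengths %||% NA_real_,
    coefficient = x$coefficients,
    weight = x$weights[, 1]
  )
}

#' @rdname tidy.nir_pls
#' @method glance nir_pls
#' @export
glance.nir_pls <- function(x, ...) {
  tibble::tibble(ncomp = x$ncomp, n = x$n, n_variables = x$p)
}

#' Tidy cross-validation results
#'
#' @param x an `nir_cv`.
#' @param ... unused.
#' @return `tidy()`: the RMSECV-by-components tibble; `glance()`: one row
#'   with the optimum.
#' @method tidy nir_cv
#' @export
tidy.nir_cv <- function(x, ...) x$metrics

#' @rdname tidy.nir_cv
#' @method glance nir_cv
#' @export
glance.nir_cv <- function(x, ...) {
  tibble::tibble(optimal_ncomp = x$optimal_ncomp,
                 rmsecv_min = x$metrics$rmsecv[x$optimal_ncomp])
}

#' Tidy a UVE selection result
#'
#' One row per channel of the augmented (real + noise) matrix, with the
#' stability ratio and retention flag.
#'
#' @param x a `uve_result`.
#' @param ... unused.
#' @return a tibble with columns `channel`, `block` (`"real"`/`"noise"`),
#'   `wavelength` (NA for the noise block), `stability`, `selected`.
#' @method tidy uve_result
#' @export
tidy.uve_result <- function(x, ...) {
  p <- x$p
  tibble::tibble(
    channel = seq_len(2 * p),
    block = rep(c("real", "noise"), each = p),
    wavelength = c(x$wavelengths %||% rep(NA_real_, p), rep(NA_real_, p)),
    stability = x$stability,
    selected = c(seq_len(p) %in% x$selected_channels, rep(FALSE, p))
  )
}

#' @rdname tidy.uve_result
#' @method glance uve_result
#' @export
glance.uve_result <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected_channels), p = x$p,
                 threshold = x$threshold, ncomp = x$ncomp)
}

#' Tidy a CARS selection result
#'
#' @param x a `cars_result`.
#' @param ... unused.
#' @return `tidy()`: the per-run history (run, retention ratio, budget,
#'   subset size, component count, RMSECV); `glance()`: one row with the best
#'   run and final subset size.
#' @method tidy cars_result
#' @export
tidy.cars_result <- function(x, ...) x$history

#' @rdname tidy.cars_result
#' @method glance cars_result
#' @export
glance.cars_result <- function(x, ...) {
  tibble::tibble(best_run = x$best_run, n_runs = x$n_runs,
                 n_selected = length(x$selected_channels), p = x$p,
                 rmsecv_best = x$history$rmsecv[x$best_run])
}

#' Tidy an outlier report
#'
#' @param x an `outlier_report`.
#' @param ... unused.
#' @return `tidy()`: per-sample distances and flags; `glance()`: one row of
#'   summary counts.
#' @method tidy outlier_report
#' @export
tidy.outlier_report <- function(x, ...) x$samples

#' @rdname tidy.outlier_report
#' @method glance outlier_report
#' @export
glance.outlier_report <- function(x, ...) {
  tibble::tibble(n = nrow(x$samples), n_flagged = length(x$flagged_ids),
                 threshold = x$threshold, k_components = x$k_components,
                 sd_multiplier = x$sd_multiplier)
}
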