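#' Specify a pure-component absorber for synthetic spectra
#'
#' A component is a sum of Gaussian absorption bands on the wavelength axis.
#' Band heights are absorbance per unit concentration (g kg^-1), so the
#' component contributes `concentration * pure_spectrum` to each sample under
#' linear (Beer-Lambert-like) mixing.
#'
#' @param name analyte name (used as the reference-table column).
#' @param band_centers,band_widths,band_heights equal-length numeric vectors:
#'   Gaussian centers (nm), sigmas (nm, > 0), peak heights
#'   (absorbance per g kg^-1).
#' @param concentration_min,concentration_max concentration range sampled
#'   uniformly per sample (g kg^-1); `max > min >= 0`.
#' @return an object of class `component_spec`.
#' @export
component_spec <- function(name, band_centers, band_widths, band_heights,
                           concentration_min, concentration_max) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop("component_spec: `name` must be a non-empty string", call. = FALSE)
  }
  n_band <- length(band_centers)
  if (length(band_widths) != n_band || length(band_heights) != n_band) {
    stop("component_spec: band_centers, band_widths, band_heights must have equal lengths",
         call. = FALSE)
  }
  if (any(band_widths <= 0)) stop("component_spec: band_widths must be > 0", call. = FALSE)
  if (!(concentration_max > concentration_min) || concentration_min < 0) {
    stop("component_spec: need concentration_max > concentration_min >= 0", call. = FALSE)
  }
  structure(
    list(name = name, band_centers = as.numeric(band_centers),
         band_widths = as.numeric(band_widths),
         band_heights = as.numeric(band_heights),
         concentration_min = concentration_min,
         concentration_max = concentration_max),
    class = "component_spec"
  )
}

# three-analyte default loosely modelled on -OH / -CH overtone features of a
# dried-plant powder: one hydroxyl-rich sugar alcohol, one saponin-like
# absorber and one trace flavonoid with aromatic C-H bands
default_components <- function() {
  list(
    component_spec("total_saponins",
                   band_centers = c(1505, 2150), band_widths = c(35, 28),
                   band_heights = c(0.060, 0.045),
                   concentration_min = 0.79, concentration_max = 5.79),
    component_spec("mannitol",
                   band_centers = c(1450, 1940), band_widths = c(40, 45),
                   band_heights = c(0.050, 0.080),
                   concentration_min = 1.57, concentration_max = 5.91),
    component_spec("naringenin",
                   band_centers = c(1680, 2315), band_widths = c(25, 22),
                   band_heights = c(6.0, 9.0),
                   concentration_min = 0.0038, concentration_max = 0.0369)
  )
}

#' Configure the synthetic NIR spectra generator
#'
#' The generator emulates diffuse-reflectance NIR spectra of powdered plant
#' material: linear concentration-to-absorbance mixing over Gaussian-band
#' pure-component spectra, a per-sample low-order polynomial baseline,
#' per-sample multiplicative/additive scatter (the particle-size effect that
#' SNV and MSC are designed to remove), and additive white noise. Defaults
#' mirror a 120-sample, 1557-channel, 1000-2500 nm study design.
#'
#' @param n_samples number of samples (>= 2).
#' @param wavelength_start_nm,wavelength_end_nm axis limits, end > start.
#' @param n_channels number of (uniformly spaced) channels, >= 2.
#' @param components list of [component_spec()] objects.
#' @param baseline_amplitude sd of the random polynomial baseline
#'   coefficients (absorbance units); 0 disables the baseline.
#' @param baseline_degree polynomial degree of the drift term.
#' @param scatter_slope_sd sd of `log(m_i)` for the per-sample multiplicative
#'   scatter factor `m_i` (lognormal, so always positive); 0 means `m_i = 1`.
#' @param scatter_offset_sd sd of the per-sample additive offset `b_i`
#'   (absorbance units).
#' @param noise_sd sd of additive white noise per channel (absorbance units).
#' @param seed integer seed; the dataset is a pure function of the config.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 120,
                             wavelength_start_nm = 1000,
                             wavelength_end_nm = 2500,
                             n_channels = 1557,
                             components = default_components(),
                             baseline_amplitude = 0.05,
                             baseline_degree = 2,
                             scatter_slope_sd = 0.05,
                             scatter_offset_sd = 0.02,
                             noise_sd = 5e-4,
                             seed = 1L) {
  fail <- function(field, msg) {
    stop("synthetic_config: invalid `", field, "`: ", msg, call. = FALSE)
  }
  if (!is.numeric(n_samples) || n_samples < 2) fail("n_samples", "need >= 2")
  if (!is.numeric(n_channels) || n_channels < 2) fail("n_channels", "need >= 2")
  if (!(wavelength_end_nm > wavelength_start_nm)) {
    fail("wavelength_end_nm", "must exceed wavelength_start_nm")
  }
  for (f in c("baseline_amplitude", "scatter_slope_sd", "scatter_offset_sd", "noise_sd")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || v < 0) fail(f, "must be a single number >= 0")
  }
  if (baseline_degree < 0) fail("baseline_degree", "must be >= 0")
  if (!length(components)) fail("components", "need at least one component")
  if (!all(vapply(components, inherits, logical(1), "component_spec"))) {
    fail("components", "all entries must be component_spec objects")
  }
  structure(
    list(n_samples = as.integer(n_samples),
         wavelength_start_nm = wavelength_start_nm,
         wavelength_end_nm = wavelength_end_nm,
         n_channels = as.integer(n_channels),
         components = components,
         baseline_amplitude = baseline_amplitude,
         baseline_degree = as.integer(baseline_degree),
         scatter_slope_sd = scatter_slope_sd,
         scatter_offset_sd = scatter_offset_sd,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic NIR dataset with known ground truth
#'
#' Each spectrum is built as
#' `m_i * (sum_c conc[i, c] * pure_c + baseline_i) + b_i + noise_i`,
#' where `m_i = exp(N(0, scatter_slope_sd))` and `b_i ~ N(0, scatter_offset_sd)`
#' form a per-sample affine scatter distortion, `baseline_i` is a random
#' low-order polynomial in the (scaled) wavelength, and the noise is i.i.d.
#' Gaussian. Concentrations are drawn uniformly and independently per
#' component. The returned truth records the pure-component spectra, the
#' per-sample scatter parameters and, per component, the channels where the
#' pure spectrum exceeds 1% of its maximum (the "informative" channels a
#' wavelength-selection algorithm should find).
#'
#' @param config a [synthetic_config()].
#' @return a list of class `nir_dataset` with elements `spectra` (spectra
#'   table), `references` (tibble: `sample_id` + one column per component,
#'   g kg^-1) and `truth` (list: `wavelengths`, `pure` p x C matrix,
#'   `concentrations`, `scatter` tibble, `informative` named list of channel
#'   index vectors, 1-based).
#' @examples
#' d <- generate_nir(synthetic_config(n_samples = 10, n_channels = 50, seed = 7))
#' dim(spectra_matrix(d$spectra))
#' @export
generate_nir <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    n <- config$n_samples
    p <- config$n_channels
    wl <- seq(config$wavelength_start_nm, config$wavelength_end_nm, length.out = p)
    comps <- config$components
    cnames <- vapply(comps, `[[`, character(1), "name")

    pure <- vapply(comps, function(cs) {
      rowSums(vapply(seq_along(cs$band_centers), function(b) {
        cs$band_heights[b] * exp(-0.5 * ((wl - cs$band_centers[b]) / cs$band_widths[b])^2)
      }, numeric(p)))
    }, numeric(p))
    colnames(pure) <- cnames

    conc <- vapply(comps, function(cs) {
      stats::runif(n, cs$concentration_min, cs$concentration_max)
    }, numeric(n))
    colnames(conc) <- cnames

    chem <- conc %*% t(pure)                       # n x p noiseless mixture

    t01 <- (wl - wl[1]) / (wl[p] - wl[1])
    baseline <- matrix(0, n, p)
    if (config$baseline_amplitude > 0) {
      coef <- matrix(stats::rnorm(n * (config$baseline_degree + 1),
                                  sd = config$baseline_amplitude),
                     n, config$baseline_degree + 1)
      basis <- outer(t01, 0:config$baseline_degree, `^`)  # p x (deg+1)
      baseline <- coef %*% t(basis)
    }

    m_i <- if (config$scatter_slope_sd > 0) exp(stats::rnorm(n, sd = config$scatter_slope_sd)) else rep(1, n)
    b_i <- if (config$scatter_offset_sd > 0) stats::rnorm(n, sd = config$scatter_offset_sd) else rep(0, n)
    noise <- if (config$noise_sd > 0) matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p) else matrix(0, n, p)

    absorb <- m_i * (chem + baseline) + b_i + noise

    informative <- lapply(cnames, function(nm) {
      which(pure[, nm] > 0.01 * max(pure[, nm]))
    })
    names(informative) <- cnames

    ids <- sprintf("s%03d", seq_len(n))
    structure(
      list(
        spectra = spectra_table(absorb, wl, ids),
        references = dplyr::bind_cols(tibble::tibble(sample_id = ids),
                                      tibble::as_tibble(conc)),
        truth = list(
          wavelengths = wl,
          pure = pure,
          concentrations = conc,
          scatter = tibble::tibble(sample_id = ids, slope = m_i, offset = b_i),
          informative = informative
        )
      ),
      class = "nir_dataset"
    )
  })
}

#' @export
print.nir_dataset <- function(x, ...) {
  m <- spectra_matrix(x$spectra)
  cat("<nir_dataset> ", nrow(m), " samples x ", ncol(m), " channels, analytes: ",
      paste(names(x$truth$informative), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `spectra.csv` (wavelength-header spectra table), `references.csv`
#' and `truth.yaml` (the answer key: informative channel indices, scatter
#' parameters and generator config echo) under `dir`.
#'
#' @param dataset an `nir_dataset` from [generate_nir()].
#' @param dir output directory (created if needed).
#' @return the paths written, invisibly.
#' @export
write_nir_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "nir_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(spectra = file.path(dir, "spectra.csv"),
             references = file.path(dir, "references.csv"),
             truth = file.path(dir, "truth.yaml"))
  write_spectra(dataset$spectra, paths[["spectra"]])
  write_reference(dataset$references, paths[["references"]])
  truth <- dataset$truth
  yaml::write_yaml(
    list(
      informative_channels = lapply(truth$informative, as.integer),
      scatter = list(sample_id = truth$scatter$sample_id,
                     slope = truth$scatter$slope,
                     offset = truth$scatter$offset),
      wavelength_start_nm = truth$wavelengths[1],
      wavelength_end_nm = truth$wavelengths[length(truth$wavelengths)],
      n_channels = length(truth$wavelengths)
    ),
    paths[["truth"]]
  )
  invisible(paths)
}
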