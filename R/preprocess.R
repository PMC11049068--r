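#' Moving-window smoothing
#'
#' Smooths each spectrum with a symmetric weighted moving average of
#' halfwidth `w`: the value at channel k becomes
#' `sum(x[k + i] * h[i], i = -w..w) / H` with `H = sum(h)`. The default
#' weights are uniform (a plain moving average). Near the edges the window
#' shrinks symmetrically so no data are fabricated; the output keeps the full
#' wavelength axis.
#'
#' @param x spectra table.
#' @param w window halfwidth in channels (>= 1); the full window spans
#'   `2w + 1` channels.
#' @param weights optional numeric vector of length `2w + 1` of positive
#'   window weights (centre at position `w + 1`).
#' @return a spectra table of the same shape.
#' @export
sg_smooth <- function(x, w = 7, weights = NULL) {
  m <- spectra_matrix(x)
  wl <- spectra_wavelengths(x)
  p <- ncol(m)
  w <- as.integer(w)
  if (w < 1) stop("sg_smooth: `w` must be >= 1", call. = FALSE)
  if (p < 2 * w + 1) {
    stop("sg_smooth: window (2*", w, "+1) wider than spectrum (", p, " channels)",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, 2 * w + 1)
  if (length(weights) != 2 * w + 1) {
    stop("sg_smooth: `weights` must have length 2*w + 1", call. = FALSE)
  }
  if (sum(weights) <= 0) stop("sg_smooth: weights must sum to > 0", call. = FALSE)

  out <- matrix(0, nrow(m), p)
  for (k in seq_len(p)) {
    ww <- min(w, k - 1, p - k)           # shrink symmetrically at the edges
    h <- weights[(w + 1 - ww):(w + 1 + ww)]
    out[, k] <- (m[, (k - ww):(k + ww), drop = FALSE] %*% h) / sum(h)
  }
  spectra_table(out, wl, x$sample_id)
}

#' Gap (finite-difference) derivative spectra
#'
#' First order: `(x[k + g] - x[k - g]) / g`; second order:
#' `(x[k + g] - 2 x[k] + x[k - g]) / g^2`, with the gap `g` counted in
#' channels. The `g` channels at each edge, where the stencil overruns, are
#' trimmed from the output and the wavelength axis is trimmed to match, so
#' channel indices stay aligned with wavelengths downstream.
#'
#' The first-order divisor is `g`, matching the convention of the moving-gap
#' derivative as used in NIR pretreatment suites; set
#' `divisor = "conventional"` for the central-difference divisor `2g`.
#'
#' @param x spectra table.
#' @param order derivative order, 1 or 2.
#' @param gap gap size g in channels (>= 1).
#' @param divisor `"gap"` (default, divide first differences by g) or
#'   `"conventional"` (divide by 2g).
#' @return a spectra table with `p - 2g` channels.
#' @export
gap_derivative <- function(x, order = 1, gap = 5, divisor = c("gap", "conventional")) {
  divisor <- match.arg(divisor)
  m <- spectra_matrix(x)
  wl <- spectra_wavelengths(x)
  p <- ncol(m)
  g <- as.integer(gap)
  if (g < 1) stop("gap_derivative: `gap` must be >= 1", call. = FALSE)
  if (!order %in% c(1, 2)) stop("gap_derivative: `order` must be 1 or 2", call. = FALSE)
  if (p < 2 * g + 1) {
    stop("gap_derivative: gap ", g, " too large for ", p, " channels", call. = FALSE)
  }
  keep <- (g + 1):(p - g)
  out <- if (order == 1) {
    den <- if (divisor == "gap") g else 2 * g
    (m[, keep + g, drop = FALSE] - m[, keep - g, drop = FALSE]) / den
  } else {
    (m[, keep + g, drop = FALSE] - 2 * m[, keep, drop = FALSE] +
       m[, keep - g, drop = FALSE]) / g^2
  }
  spectra_table(out, wl[keep], x$sample_id)
}

#' Multiplicative scatter correction
#'
#' MSC models each observed spectrum as an affine distortion
#' `x = m_i * ref + b_i` of a reference spectrum and inverts it:
#' the corrected spectrum is `(x - b_i) / m_i`, with `(m_i, b_i)` from an
#' ordinary least-squares fit of the spectrum on the reference.
#' `msc_fit()` computes the reference as the column-wise mean of the
#' calibration spectra; it must be frozen from the calibration partition and
#' reused on prediction spectra so no information leaks across the split.
#'
#' @param calibration,x spectra tables.
#' @param reference a reference mean spectrum from [msc_fit()] (named numeric
#'   vector, one entry per channel).
#' @return `msc_fit()`: the mean spectrum; `msc_transform()`: a corrected
#'   spectra table.
#' @export
msc_fit <- function(calibration) {
  m <- spectra_matrix(calibration)
  if (nrow(m) < 2) stop("msc_fit: need at least 2 calibration spectra", call. = FALSE)
  colMeans(m)
}

#' @rdname msc_fit
#' @export
msc_transform <- function(x, reference) {
  m <- spectra_matrix(x)
  if (length(reference) != ncol(m)) {
    stop("msc_transform: reference length ", length(reference),
         " does not match ", ncol(m), " channels", call. = FALSE)
  }
  ref_c <- reference - mean(reference)
  ss <- sum(ref_c^2)
  if (ss <= .Machine$double.eps * length(reference)) {
    stop("msc_transform: reference spectrum is constant; slope undefined", call. = FALSE)
  }
  # closed-form simple regression of each row on the reference
  slope <- as.numeric(m %*% ref_c) / ss
  intercept <- rowMeans(m) - slope * mean(reference)
  bad <- abs(slope) < 1e-12
  if (any(bad)) {
    stop("msc_transform: fitted slope is zero for sample(s) ",
         paste(x$sample_id[bad], collapse = ", "), call. = FALSE)
  }
  out <- (m - intercept) / slope
  spectra_table(out, spectra_wavelengths(x), x$sample_id)
}

#' Standard normal variate transformation
#'
#' Centers each spectrum on its own mean and scales by its own standard
#' deviation (with the n - 1 denominator), removing per-sample multiplicative
#' scatter and offset. Every output row has mean 0 and unit sd.
#'
#' @param x spectra table.
#' @return a spectra table of the same shape.
#' @export
snv <- function(x) {
  m <- spectra_matrix(x)
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  bad <- s <= 0 | !is.finite(s)
  if (any(bad)) {
    stop("snv: constant spectrum for sample(s) ",
         paste(x$sample_id[bad], collapse = ", "), call. = FALSE)
  }
  spectra_table((m - mu) / s, spectra_wavelengths(x), x$sample_id)
}

#' Apply a named pretreatment
#'
#' Dispatches to the individual operators; `"d1_sg"` / `"d2_sg"` smooth first
#' and then take the gap derivative, the usual composition in NIR practice.
#' For `"msc"` a calibration-set reference must be supplied (see [msc_fit()]).
#'
#' @param x spectra table.
#' @param method one of `"raw"`, `"smooth"`, `"d1_sg"`, `"d2_sg"`, `"msc"`,
#'   `"snv"`.
#' @param window halfwidth for smoothing steps.
#' @param gap gap size for derivative steps.
#' @param reference MSC reference spectrum (required for `method = "msc"`).
#' @param ... passed through to the underlying operator.
#' @return a spectra table.
#' @export
pretreat <- function(x, method = c("raw", "smooth", "d1_sg", "d2_sg", "msc", "snv"),
                     window = 7, gap = 5, reference = NULL, ...) {
  method <- match.arg(method)
  switch(method,
    raw = {
      check_spectra(x)
      tibble::as_tibble(x)
    },
    smooth = sg_smooth(x, w = window, ...),
    d1_sg = gap_derivative(sg_smooth(x, w = window), order = 1, gap = gap, ...),
    d2_sg = gap_derivative(sg_smooth(x, w = window), order = 2, gap = gap, ...),
    msc = {
      if (is.null(reference)) {
        stop("pretreat: method 'msc' needs a `reference` from msc_fit()", call. = FALSE)
      }
      msc_transform(x, reference)
    },
    snv = snv(x)
  )
}
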