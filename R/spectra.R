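#' Spectra tables
#'
#' `nirquant` represents a set of NIR spectra as an ordinary wide data frame:
#' a `sample_id` character column followed by one numeric column per
#' wavelength channel, with column names equal to the wavelength in nm
#' (e.g. `"1000"`, `"1000.965"`). Every pretreatment takes such a table and
#' returns one of the same form, so stages chain with the pipe. These helpers
#' convert between the table form and the matrix form used internally.
#'
#' @param absorbance n x p numeric matrix of absorbance values.
#' @param wavelengths strictly increasing numeric vector of length p (nm).
#' @param sample_ids character vector of length n; defaults to `s001`, ...
#' @return `spectra_table()` returns a tibble with `sample_id` plus one
#'   column per channel.
#' @examples
#' s <- spectra_table(matrix(1:6, 2, 3), c(1000, 1100, 1200))
#' spectra_matrix(s)
#' spectra_wavelengths(s)
#' @export
spectra_table <- function(absorbance, wavelengths, sample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%03d", seq_len(nrow(absorbance)))
  }
  stopifnot(length(wavelengths) == ncol(absorbance),
            length(sample_ids) == nrow(absorbance))
  check_wavelengths(wavelengths)
  colnames(absorbance) <- format_wl(wavelengths)
  dplyr::bind_cols(
    tibble::tibble(sample_id = as.character(sample_ids)),
    tibble::as_tibble(absorbance)
  )
}

# wavelength column names carry full double precision so they round-trip
format_wl <- function(wl) format(wl, digits = 15, trim = TRUE, scientific = FALSE)

check_wavelengths <- function(wl) {
  if (anyNA(wl)) stop("wavelength axis contains missing values", call. = FALSE)
  if (length(wl) >= 2 && any(diff(wl) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  invisible(wl)
}

#' @rdname spectra_table
#' @param x a spectra table (as produced by [spectra_table()]).
#' @export
spectra_matrix <- function(x) {
  check_spectra(x)
  m <- as.matrix(x[setdiff(names(x), "sample_id")])
  rownames(m) <- x$sample_id
  storage.mode(m) <- "double"
  m
}

#' @rdname spectra_table
#' @export
spectra_wavelengths <- function(x) {
  check_spectra(x)
  as.numeric(setdiff(names(x), "sample_id"))
}

check_spectra <- function(x) {
  if (!is.data.frame(x) || !"sample_id" %in% names(x)) {
    stop("expected a spectra table with a `sample_id` column", call. = FALSE)
  }
  chan <- setdiff(names(x), "sample_id")
  if (length(chan) < 2) stop("spectra need at least 2 channels", call. = FALSE)
  wl <- suppressWarnings(as.numeric(chan))
  if (anyNA(wl)) stop("channel columns must be named by wavelength (nm)", call. = FALSE)
  check_wavelengths(wl)
  if (anyNA(x[chan])) stop("spectra contain missing values", call. = FALSE)
  invisible(x)
}

#' Read and write spectra and reference tables
#'
#' Spectra files are comma-delimited text: header row of wavelengths (nm)
#' preceded by a `sample_id` field, one row per sample. Reference files hold
#' a `sample_id` column plus one numeric column per analyte (g kg^-1).
#'
#' @param x a spectra table or reference tibble.
#' @param path file path.
#' @return the input (writers, invisibly) or a tibble (readers).
#' @export
write_spectra <- function(x, path) {
  check_spectra(x)
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(sample_id = readr::col_character(),
                                               .default = readr::col_double()))
  check_spectra(x)
  x
}

#' @rdname write_spectra
#' @export
write_reference <- function(x, path) {
  stopifnot(is.data.frame(x), "sample_id" %in% names(x))
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname write_spectra
#' @export
read_reference <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(sample_id = readr::col_character(),
                                          .default = readr::col_double()))
}

# align a reference tibble to the rows of a spectra table, by sample_id
reference_vector <- function(reference, analyte, sample_ids) {
  if (!analyte %in% names(reference)) {
    stop("analyte `", analyte, "` not found in reference table", call. = FALSE)
  }
  idx <- match(sample_ids, reference$sample_id)
  if (anyNA(idx)) {
    stop("reference table is missing samples: ",
         paste(utils::head(sample_ids[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  }
  reference[[analyte]][idx]
}

# wavelength axis of a spectra table, or an NA axis for bare matrices
axis_of <- function(x, X) {
  if (is.data.frame(x)) return(spectra_wavelengths(x))
  wl <- suppressWarnings(as.numeric(colnames(X)))
  if (length(wl) != ncol(X) || anyNA(wl)) rep(NA_real_, ncol(X)) else wl
}
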