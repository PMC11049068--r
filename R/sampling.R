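#' Mahalanobis-distance outlier screening
#'
#' Spectral matrices have many more channels than samples, so the full-space
#' covariance is singular; distances are therefore computed in the
#' `k_components`-dimensional principal-component score space of the
#' (centered) spectra, with the covariance estimated from the scores. A
#' sample is flagged when its distance exceeds
#' `mean(distance) + sd_multiplier * sd(distance)`.
#'
#' @param x spectra table.
#' @param k_components dimension of the PCA score space (>= 1, < n).
#' @param sd_multiplier threshold multiplier; `Inf` flags nothing.
#' @return an object of class `outlier_report`: a list with `samples`
#'   (tibble: `sample_id`, `distance`, `flagged`), `threshold`, `flagged_ids`
#'   and `retained_ids` (original order preserved).
#' @export
mahalanobis_screen <- function(x, k_components = 5, sd_multiplier = 3) {
  m <- spectra_matrix(x)
  n <- nrow(m)
  k <- as.integer(k_components)
  if (k < 1 || k >= n) {
    stop("mahalanobis_screen: need n > k_components >= 1 (n = ", n, ")", call. = FALSE)
  }
  pca <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = k)
  scores <- pca$x[, seq_len(k), drop = FALSE]
  cv <- stats::cov(scores)
  if (!is.finite(rcond_sym(cv)) || rcond_sym(cv) < 1e-12) {
    stop("mahalanobis_screen: singular covariance in the score space; ",
         "try a smaller k_components", call. = FALSE)
  }
  d <- sqrt(stats::mahalanobis(scores, colMeans(scores), cv))
  threshold <- mean(d) + sd_multiplier * stats::sd(d)
  flagged <- d > threshold
  structure(
    list(
      samples = tibble::tibble(sample_id = x$sample_id, distance = d,
                               flagged = flagged),
      threshold = threshold,
      k_components = k,
      sd_multiplier = sd_multiplier,
      flagged_ids = x$sample_id[flagged],
      retained_ids = x$sample_id[!flagged]
    ),
    class = "outlier_report"
  )
}

rcond_sym <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  min(ev) / max(ev)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report> ", nrow(x$samples), " samples, threshold ",
      signif(x$threshold, 4), ", flagged: ",
      if (length(x$flagged_ids)) paste(x$flagged_ids, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Kennard-Stone calibration/prediction partition
#'
#' Deterministic max-min sample selection in spectral (Euclidean) space: the
#' pair of samples at maximal distance seeds the calibration set, then each
#' step adds the candidate whose minimum distance to the already-selected set
#' is largest, until `n_calibration` samples are chosen. The remainder form
#' the prediction set. Ties are broken toward the lowest sample index, so the
#' partition is reproducible.
#'
#' @param x spectra table.
#' @param n_calibration calibration-set size, `2 <= n_calibration <= n`.
#' @return an object of class `ks_partition`: list with `calibration_ids`,
#'   `prediction_ids` (both in original sample order) and `order_selected`
#'   (the selection sequence).
#' @export
kennard_stone <- function(x, n_calibration) {
  m <- spectra_matrix(x)
  n <- nrow(m)
  nc <- as.integer(n_calibration)
  if (nc < 2 || nc > n) {
    stop("kennard_stone: n_calibration must be in [2, ", n, "]", call. = FALSE)
  }
  d <- as.matrix(stats::dist(m))
  # seed pair: maximal pairwise distance, lowest index pair on ties
  upper <- d
  upper[lower.tri(upper, diag = TRUE)] <- -Inf
  seed <- arrayInd(which.max(upper), dim(upper))
  selected <- sort(seed[1, ])
  candidates <- setdiff(seq_len(n), selected)
  min_d <- pmin(d[, selected[1]], d[, selected[2]])
  while (length(selected) < nc) {
    best <- candidates[which.max(min_d[candidates])]   # which.max: first (lowest index) on ties
    selected <- c(selected, best)
    candidates <- setdiff(candidates, best)
    min_d <- pmin(min_d, d[, best])
  }
  ids <- x$sample_id
  structure(
    list(
      calibration_ids = ids[sort(selected)],
      prediction_ids = ids[sort(setdiff(seq_len(n), selected))],
      order_selected = ids[selected]
    ),
    class = "ks_partition"
  )
}

#' @export
print.ks_partition <- function(x, ...) {
  cat("<ks_partition> calibration ", length(x$calibration_ids),
      " / prediction ", length(x$prediction_ids), "\n", sep = "")
  invisible(x)
}

#' Write or read a partition as structured text
#'
#' @param partition a `ks_partition`.
#' @param path file path (JSON).
#' @return the partition, invisibly (writer) or a `ks_partition` (reader).
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "ks_partition"))
  jsonlite::write_json(unclass(partition), path, pretty = TRUE)
  invisible(partition)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj[c("calibration_ids", "prediction_ids", "order_selected")],
            class = "ks_partition")
}

# subset a spectra table (and optionally reference) to a set of sample ids,
# preserving the table's own row order
filter_samples <- function(x, ids) {
  dplyr::filter(x, .data$sample_id %in% ids)
}
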