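# ---- matrix-level engine -----------------------------------------------
# NIPALS PLS1 with mean-centering only (no autoscaling), the dominant
# convention in NIR chemometrics. Returns cumulative regression coefficients
# for every component count 1..A so cross-validation over A costs one fit.

as_x_matrix <- function(x) {
  if (is.data.frame(x) && "sample_id" %in% names(x)) spectra_matrix(x) else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
}

pls1_engine <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- matrix(0, p, A); P <- matrix(0, p, A); q <- numeric(A)
  a_used <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break                      # no covariance left
    w <- w / nw
    t <- Xc %*% w
    tt <- sum(t^2)
    if (tt < 1e-28) break
    pa <- crossprod(Xc, t) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pa)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pa; q[a] <- qa
    a_used <- a
  }
  # beta for each component count: W_a (P_a' W_a)^-1 q_a; P'W is unit upper
  # triangular, so a backsolve per a
  B <- matrix(0, p, A)
  if (a_used > 0) {
    R <- crossprod(P[, seq_len(a_used), drop = FALSE],
                   W[, seq_len(a_used), drop = FALSE])
    for (a in seq_len(a_used)) {
      B[, a] <- W[, seq_len(a), drop = FALSE] %*%
        backsolve(R[seq_len(a), seq_len(a), drop = FALSE], q[seq_len(a)])
    }
  }
  if (a_used < A && a_used > 0) {
    for (a in (a_used + 1):A) B[, a] <- B[, a_used]
  }
  list(x_mean = x_mean, y_mean = y_mean, W = W, P = P, q = q,
       B = B, a_used = a_used)
}

# squared held-out errors for every component count 1..A_max; folds = "loo"
# or an integer k (folds assigned deterministically by sample order)
cv_sqerr <- function(X, y, A_max, folds = "loo") {
  n <- nrow(X)
  fold_id <- if (identical(folds, "loo")) seq_len(n) else {
    k <- as.integer(folds)
    stopifnot(k >= 2, k <= n)
    rep(seq_len(k), length.out = n)
  }
  err2 <- matrix(NA_real_, n, A_max)
  for (f in unique(fold_id)) {
    test <- which(fold_id == f)
    train <- which(fold_id != f)
    A_f <- min(A_max, length(train) - 1, ncol(X))
    fit <- pls1_engine(X[train, , drop = FALSE], y[train], A_f)
    Xc <- sweep(X[test, , drop = FALSE], 2, fit$x_mean)
    pred <- Xc %*% fit$B + fit$y_mean           # |test| x A_f
    e2 <- (pred - y[test])^2
    if (A_f < A_max) e2 <- cbind(e2, e2[, rep(A_f, A_max - A_f), drop = FALSE])
    err2[test, ] <- e2
  }
  err2
}

cv_engine <- function(X, y, A_max, folds = "loo") {
  rmsecv <- sqrt(colMeans(cv_sqerr(X, y, A_max, folds)))
  # near-ties (within a relative float tolerance of the minimum) resolve to
  # the smallest A, so noiseless data prefer the parsimonious model
  tol <- 1e-8 * (min(rmsecv) + max(rmsecv))
  list(rmsecv = rmsecv, optimal = which(rmsecv <= min(rmsecv) + tol)[1])
}

# ---- user-facing surface -----------------------------------------------

#' Fit a PLS1 regression model
#'
#' Mean-centered NIPALS PLS1 (no variance scaling) relating a spectra table
#' to one analyte's concentrations. The fitted object stores the regression
#' coefficient vector for every component count up to `ncomp`, so predictions
#' at fewer components need no refit.
#'
#' @param x spectra table (or plain numeric matrix).
#' @param y numeric vector of concentrations (g kg^-1), one per row of `x`.
#' @param ncomp number of latent variables A, `1 <= A <= min(n - 1, p)`.
#' @return an object of class `nir_pls` with elements `x_mean`, `y_mean`,
#'   `weights`, `x_loadings`, `y_loadings`, `coefficients` (length-p vector
#'   for `ncomp` components), `coef_by_ncomp` (p x A), `ncomp`, `wavelengths`.
#' @examples
#' d <- generate_nir(synthetic_config(n_samples = 20, n_channels = 60, seed = 3))
#' fit <- pls_fit(d$spectra, d$references$mannitol, ncomp = 4)
#' head(predict(fit, d$spectra))
#' @export
pls_fit <- function(x, y, ncomp) {
  X <- as_x_matrix(x)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("pls_fit: length(y) must equal nrow(x)", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("pls_fit: missing values not allowed", call. = FALSE)
  if (stats::var(y) == 0) stop("pls_fit: y has zero variance", call. = FALSE)
  A <- as.integer(ncomp)
  if (A < 1 || A > min(n - 1, p)) {
    stop("pls_fit: ncomp must be in [1, min(n - 1, p)] = [1, ", min(n - 1, p), "]",
         call. = FALSE)
  }
  eng <- pls1_engine(X, y, A)
  wl <- axis_of(x, X)
  structure(
    list(x_mean = eng$x_mean, y_mean = eng$y_mean,
         weights = eng$W, x_loadings = eng$P, y_loadings = eng$q,
         coefficients = eng$B[, A], coef_by_ncomp = eng$B,
         ncomp = A, ncomp_used = eng$a_used,
         wavelengths = wl, n = n, p = p),
    class = "nir_pls"
  )
}

#' Predict concentrations from a fitted PLS model
#'
#' @param object an `nir_pls` model.
#' @param newdata spectra table or matrix whose channels match the model's.
#' @param ncomp optionally predict with fewer components than the fit.
#' @param ... unused.
#' @return numeric vector of predicted concentrations (g kg^-1).
#' @export
predict.nir_pls <- function(object, newdata, ncomp = NULL, ...) {
  X <- as_x_matrix(newdata)
  if (ncol(X) != object$p) {
    stop("predict: newdata has ", ncol(X), " channels but the model was fit on ",
         object$p, call. = FALSE)
  }
  if (is.data.frame(newdata) && !is.null(object$wavelengths)) {
    wl <- spectra_wavelengths(newdata)
    if (!isTRUE(all.equal(wl, object$wavelengths))) {
      stop("predict: newdata wavelength axis does not match the model's", call. = FALSE)
    }
  }
  beta <- if (is.null(ncomp)) object$coefficients else {
    a <- as.integer(ncomp)
    if (a < 1 || a > ncol(object$coef_by_ncomp)) {
      stop("predict: ncomp out of range for this model", call. = FALSE)
    }
    object$coef_by_ncomp[, a]
  }
  as.numeric(sweep(X, 2, object$x_mean) %*% beta + object$y_mean)
}

#' @export
print.nir_pls <- function(x, ...) {
  cat("<nir_pls> ", x$ncomp, " latent variable(s), ", x$p, " channels, n = ",
      x$n, "\n", sep = "")
  invisible(x)
}

#' Cross-validated RMSECV over component counts
#'
#' Leave-one-out (default) or k-fold cross-validation of PLS1: each held-out
#' sample is predicted from a model refit without it, for every component
#' count `1..ncomp_max`, and `RMSECV(A)` is the root mean squared held-out
#' error. The optimal component count is the argmin; ties break toward the
#' smaller (more parsimonious) A. `ncomp_max` is capped at `min(n - 2, p)`.
#'
#' @param x spectra table or matrix.
#' @param y numeric concentrations.
#' @param ncomp_max largest component count to evaluate.
#' @param folds `"loo"` (default) or an integer number of folds; folds are
#'   assigned by sample order, so the result is deterministic.
#' @return an object of class `nir_cv`: list with `metrics`
#'   (tibble: `ncomp`, `rmsecv`), `optimal_ncomp`, `folds`.
#' @export
pls_cv <- function(x, y, ncomp_max = 18, folds = "loo") {
  X <- as_x_matrix(x)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("pls_cv: need at least 3 samples", call. = FALSE)
  A_max <- min(as.integer(ncomp_max), n - 2, ncol(X))
  cv <- cv_engine(X, y, A_max, folds)
  structure(
    list(metrics = tibble::tibble(ncomp = seq_len(A_max), rmsecv = cv$rmsecv),
         optimal_ncomp = cv$optimal,
         folds = folds),
    class = "nir_cv"
  )
}

#' @export
print.nir_cv <- function(x, ...) {
  cat("<nir_cv> optimal ncomp = ", x$optimal_ncomp, ", RMSECV = ",
      signif(x$metrics$rmsecv[x$optimal_ncomp], 4), "\n", sep = "")
  invisible(x)
}

#' Serialize a fitted PLS model as structured text
#'
#' Writes means, coefficient vector, component count and the wavelength axis
#' to JSON so models can be stored, diffed and reloaded.
#'
#' @param model an `nir_pls`.
#' @param path file path (JSON).
#' @return the model, invisibly (writer) or an `nir_pls` (reader).
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "nir_pls"))
  jsonlite::write_json(
    list(x_mean = model$x_mean, y_mean = model$y_mean,
         coefficients = model$coefficients, ncomp = model$ncomp,
         wavelengths = model$wavelengths, n = model$n, p = model$p),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(model)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coef_by_ncomp <- matrix(obj$coefficients, ncol = 1)
  structure(obj, class = "nir_pls")
}
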