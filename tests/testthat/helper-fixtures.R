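# shared fixture builders; all randomness is seeded at the call site

# spectra table straight from a matrix with a default 1..p nm axis
toy_spectra <- function(m, wl = NULL, ids = NULL) {
  m <- rbind(m)
  spectra_table(m, wl %||% seq(1000, by = 10, length.out = ncol(m)), ids)
}

# independent least-squares oracle: minimum-norm solution on centered data,
# via the pseudoinverse (SVD) -- deliberately not the NIPALS path
ols_oracle_predict <- function(X_train, y_train, X_test) {
  xm <- colMeans(X_train)
  ym <- mean(y_train)
  Xc <- sweep(X_train, 2, xm)
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-10
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y_train - ym)) / sv$d[pos])
  as.numeric(sweep(rbind(X_test), 2, xm) %*% beta + ym)
}

# a dataset where y depends on a known small set of channels, all other
# channels independent noise; returns list(X, y, truth)
planted_channels <- function(n, p, truth = c(10, 20), snr = 100, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    signal <- X[, truth, drop = FALSE] %*% rep(1, length(truth))
    noise_sd <- stats::sd(signal) / snr
    y <- as.numeric(signal + rnorm(n, sd = noise_sd))
    list(X = X, y = y, truth = truth)
  })
}

`%||%` <- rlang::`%||%`
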