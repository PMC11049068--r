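#' Uninformative variable elimination (UVE)
#'
#' Appends p artificial uniform-noise channels to the p real channels, runs
#' cross-validated PLS1 collecting the regression coefficient of every
#' channel in every fold, and scores each channel by its stability ratio
#' `h = mean(beta) / sd(beta)` across folds. Real channels whose |h| does not
#' exceed the largest |h| found among the noise channels carry no more
#' information than noise and are eliminated.
#'
#' @param x spectra table or matrix (calibration set only).
#' @param y numeric concentrations.
#' @param ncomp number of latent variables used in every fold's fit.
#' @param noise_amplitude scale of the appended uniform noise; default
#'   `1e-10 * max(abs(X))` — small enough not to perturb the fit, nonzero so
#'   noise-channel coefficients are defined.
#' @param folds `"loo"` (default) or an integer fold count; fold order is
#'   fixed by sample order.
#' @param seed integer seed for the noise draw.
#' @param threshold_type `"max"` (the largest noise |h|, default) or
#'   `"quantile"` (a quantile of the noise-block |h|).
#' @param threshold_quantile quantile used when `threshold_type = "quantile"`.
#' @return an object of class `uve_result`: list with `stability` (length 2p:
#'   real block then noise block), `threshold`, `selected_channels` (1-based
#'   indices into the real channels), `wavelengths`, `p`, `ncomp`.
#' @export
uve_select <- function(x, y, ncomp, noise_amplitude = NULL, folds = "loo",
                       seed = 1L, threshold_type = c("max", "quantile"),
                       threshold_quantile = 0.99) {
  threshold_type <- match.arg(threshold_type)
  X <- as_x_matrix(x)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (is.null(noise_amplitude)) noise_amplitude <- 1e-10 * max(abs(X))
  if (noise_amplitude <= 0) stop("uve_select: noise_amplitude must be > 0", call. = FALSE)
  noise <- withr::with_seed(as.integer(seed),
                            matrix(stats::runif(n * p), n, p) * noise_amplitude)
  Z <- cbind(X, noise)
  A <- as.integer(ncomp)
  fold_id <- if (identical(folds, "loo")) seq_len(n) else {
    rep(seq_len(as.integer(folds)), length.out = n)
  }
  ufolds <- unique(fold_id)
  betas <- matrix(NA_real_, length(ufolds), 2 * p)
  for (i in seq_along(ufolds)) {
    train <- which(fold_id != ufolds[i])
    A_f <- min(A, length(train) - 1, 2 * p)
    eng <- pls1_engine(Z[train, , drop = FALSE], y[train], A_f)
    betas[i, ] <- eng$B[, A_f]
  }
  mu <- colMeans(betas)
  s <- apply(betas, 2, stats::sd)
  h <- mu / s
  if (any(s == 0)) {
    warning("uve_select: zero coefficient spread for ", sum(s == 0),
            " channel(s); stability set to +/-Inf")
    h[s == 0] <- sign(mu[s == 0]) * Inf
    h[s == 0 & mu == 0] <- 0
  }
  noise_h <- abs(h[(p + 1):(2 * p)])
  threshold <- if (threshold_type == "max") max(noise_h) else {
    stats::quantile(noise_h, threshold_quantile, names = FALSE)
  }
  selected <- which(abs(h[seq_len(p)]) > threshold)
  wl <- axis_of(x, X)
  structure(
    list(stability = h, threshold = threshold,
         selected_channels = selected, wavelengths = wl, p = p,
         ncomp = A, noise_amplitude = noise_amplitude, folds = folds),
    class = "uve_result"
  )
}

#' @export
print.uve_result <- function(x, ...) {
  cat("<uve_result> ", length(x$selected_channels), "/", x$p,
      " channels retained (threshold ", signif(x$threshold, 4), ")\n", sep = "")
  invisible(x)
}

#' Exponentially decreasing retention schedule for CARS
#'
#' Run i of N retains a fraction `r_i = a * exp(-k * i)` of the p channels,
#' with `a` and `k` fixed by the boundary conditions that run 1 keeps all p
#' channels and run N keeps 2: `a = (p/2)^(1/(N-1))`, `k = log(p/2)/(N-1)`.
#'
#' @param p number of channels (>= 2).
#' @param n_runs number of sampling runs N (>= 2).
#' @return a tibble with columns `run`, `ratio`, `budget`
#'   (`ceiling(ratio * p)` channels retained).
#' @export
edf_schedule <- function(p, n_runs) {
  p <- as.integer(p); N <- as.integer(n_runs)
  if (p < 2) stop("edf_schedule: p must be >= 2", call. = FALSE)
  if (N < 2) stop("edf_schedule: n_runs must be >= 2", call. = FALSE)
  a <- (p / 2)^(1 / (N - 1))
  k <- log(p / 2) / (N - 1)
  i <- seq_len(N)
  ratio <- a * exp(-k * i)
  tibble::tibble(run = i, ratio = ratio, budget = as.integer(ceiling(ratio * p)))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Iterative wavelength selection over `n_runs` Monte-Carlo sampling runs.
#' Each run (1) draws `mc_fraction` of the calibration samples without
#' replacement, (2) fits PLS1 on the surviving channel subset, (3) turns the
#' absolute regression coefficients into normalized weights, (4) applies the
#' forced exponential retention: only the top `ceiling(r_i * p)` channels by
#' weight survive, (5) applies adaptive reweighted sampling: that many draws
#' with replacement, probability proportional to weight, keeping the distinct
#' channels drawn, and (6) records the subset and its cross-validated RMSECV
#' on the full calibration set (component count re-optimized up to
#' `ncomp_max`). The subset of the run with the lowest RMSECV is returned.
#' Channels eliminated at one run never reappear later.
#'
#' @param x spectra table or matrix (calibration set only).
#' @param y numeric concentrations.
#' @param ncomp_max largest component count considered.
#' @param n_runs number of Monte-Carlo sampling runs (default 100).
#' @param mc_fraction fraction of calibration samples drawn per run, in
#'   (0, 1] (default 0.8).
#' @param folds cross-validation scheme for the per-run RMSECV: `"loo"`
#'   (default) or an integer fold count.
#' @param seed integer seed governing all Monte-Carlo draws.
#' @return an object of class `cars_result`: list with `history` (tibble:
#'   `run`, `ratio`, `budget`, `n_channels`, `ncomp`, `rmsecv`),
#'   `subset_history` and `weight_history` (lists, one entry per run),
#'   `best_run`, `selected_channels` (1-based indices), `selected_wavelengths`,
#'   `wavelengths`, `p`.
#' @export
cars_select <- function(x, y, ncomp_max = 18, n_runs = 100, mc_fraction = 0.8,
                        folds = "loo", seed = 1L) {
  X <- as_x_matrix(x)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (p < 2) stop("cars_select: need at least 2 channels", call. = FALSE)
  if (!is.numeric(mc_fraction) || mc_fraction <= 0 || mc_fraction > 1) {
    stop("cars_select: mc_fraction must be in (0, 1]", call. = FALSE)
  }
  N <- as.integer(n_runs)
  sched <- edf_schedule(p, N)
  A_cap <- as.integer(ncomp_max)

  subset <- seq_len(p)
  sub_hist <- vector("list", N)
  w_hist <- vector("list", N)
  rmsecv <- rep(NA_real_, N)
  ncomp_opt <- rep(NA_integer_, N)
  n_chan <- rep(NA_integer_, N)
  last <- 0L

  withr::with_seed(as.integer(seed), {
    for (i in seq_len(N)) {
      n_mc <- max(2L, floor(mc_fraction * n))
      idx <- sample.int(n, n_mc)
      A_w <- min(A_cap, n_mc - 1, length(subset))
      eng <- pls1_engine(X[idx, subset, drop = FALSE], y[idx], A_w)
      w <- abs(eng$B[, A_w])
      if (sum(w) == 0) w <- rep(1, length(w))
      w <- w / sum(w)

      budget <- min(sched$budget[i], length(subset))
      keep_ord <- order(w, decreasing = TRUE)[seq_len(budget)]   # stable: lowest index on ties
      kept <- subset[keep_ord]
      w_kept <- w[keep_ord]

      drawn <- sample(kept, size = budget, replace = TRUE, prob = w_kept)
      new_subset <- sort(unique(drawn))
      if (length(new_subset) < 2) {
        warning("cars_select: channel subset collapsed below 2 at run ", i,
                "; stopping early at run ", i - 1L)
        break
      }
      cv <- cv_engine(X[, new_subset, drop = FALSE], y,
                      min(A_cap, n - 2, length(new_subset)), folds)
      sub_hist[[i]] <- new_subset
      w_hist[[i]] <- stats::setNames(w, as.character(subset))
      rmsecv[i] <- cv$rmsecv[cv$optimal]
      ncomp_opt[i] <- cv$optimal
      n_chan[i] <- length(new_subset)
      subset <- new_subset
      last <- i
    }
  })

  if (last == 0L) stop("cars_select: no valid sampling run completed", call. = FALSE)
  runs <- seq_len(last)
  best <- runs[which.min(rmsecv[runs])]
  wl <- axis_of(x, X)
  structure(
    list(
      history = tibble::tibble(run = runs, ratio = sched$ratio[runs],
                               budget = sched$budget[runs],
                               n_channels = n_chan[runs],
                               ncomp = ncomp_opt[runs], rmsecv = rmsecv[runs]),
      subset_history = sub_hist[runs],
      weight_history = w_hist[runs],
      best_run = best,
      selected_channels = sub_hist[[best]],
      selected_wavelengths = if (!is.null(wl)) wl[sub_hist[[best]]] else NULL,
      wavelengths = wl,
      p = p, n_runs = last, mc_fraction = mc_fraction, seed = as.integer(seed)
    ),
    class = "cars_result"
  )
}

#' @export
print.cars_result <- function(x, ...) {
  cat("<cars_result> best run ", x$best_run, "/", x$n_runs, ": ",
      length(x$selected_channels), "/", x$p, " channels, RMSECV ",
      signif(x$history$rmsecv[x$best_run], 4), "\n", sep = "")
  invisible(x)
}

#' Write a selection result as structured text
#'
#' Stores the retained channel indices, their wavelengths and the
#' algorithm's diagnostic traces (UVE stability curve or CARS run history)
#' as JSON.
#'
#' @param selection a `uve_result` or `cars_result`.
#' @param path file path (JSON).
#' @return the selection, invisibly.
#' @export
write_selection <- function(selection, path) {
  obj <- if (inherits(selection, "uve_result")) {
    list(method = "uve",
         selected_channels = selection$selected_channels,
         selected_wavelengths = selection$wavelengths[selection$selected_channels],
         threshold = selection$threshold,
         stability = selection$stability)
  } else if (inherits(selection, "cars_result")) {
    list(method = "cars",
         selected_channels = selection$selected_channels,
         selected_wavelengths = selection$selected_wavelengths,
         best_run = selection$best_run,
         history = selection$history)
  } else {
    stop("write_selection: expected a uve_result or cars_result", call. = FALSE)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(selection)
}
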