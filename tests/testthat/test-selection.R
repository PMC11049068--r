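test_that("edf schedule satisfies its boundary conditions and decreases", {
  s2 <- edf_schedule(2, 10)
  expect_equal(s2$ratio, rep(1, 10))
  for (case in list(c(40, 30), c(1557, 100))) {
    p <- case[1]; N <- case[2]
    s <- edf_schedule(p, N)
    expect_equal(round(s$ratio[1] * p), p)
    expect_equal(round(s$ratio[N] * p), 2)
    expect_true(all(diff(s$ratio) < 0))
    expect_true(all(s$budget >= 2))
  }
  expect_error(edf_schedule(1, 10), "p")
  expect_error(edf_schedule(10, 1), "n_runs")
})

test_that("uve gives identical stability to duplicated channels", {
  withr::local_seed(30)
  X <- matrix(rnorm(40 * 12), 40, 12)
  X[, 12] <- X[, 5]                        # duplicate channel
  y <- X[, 3] + rnorm(40, sd = 0.05)
  res <- uve_select(X, y, ncomp = 3, seed = 7)
  expect_equal(res$stability[5], res$stability[12], tolerance = 1e-10)
})

test_that("uve threshold is the maximum |h| over the noise block", {
  withr::local_seed(31)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- X[, 2] - X[, 7] + rnorm(30, sd = 0.1)
  res <- uve_select(X, y, ncomp = 2, seed = 3)
  expect_equal(res$threshold, max(abs(res$stability[11:20])))
  expect_true(all(abs(res$stability[res$selected_channels]) > res$threshold))
  q <- uve_select(X, y, ncomp = 2, seed = 3, threshold_type = "quantile",
                  threshold_quantile = 0.5)
  expect_lt(q$threshold, res$threshold)
  expect_true(all(res$selected_channels %in% q$selected_channels))
})

test_that("a fresh noise seed moves the threshold but not real-channel stabilities", {
  withr::local_seed(32)
  X <- matrix(rnorm(25 * 8), 25, 8)
  y <- X[, 1] + rnorm(25, sd = 0.1)
  r1 <- uve_select(X, y, ncomp = 2, seed = 1)
  r2 <- uve_select(X, y, ncomp = 2, seed = 99)
  expect_false(isTRUE(all.equal(r1$threshold, r2$threshold)))
  # the noise amplitude is ~1e-10 of the data, so real-channel h is unmoved
  expect_equal(r1$stability[1:8], r2$stability[1:8], tolerance = 1e-6)
})

test_that("uve recovers planted informative channels with few false positives", {
  pc <- planted_channels(n = 60, p = 50, truth = c(10, 20), snr = 100, seed = 41)
  res <- uve_select(pc$X, pc$y, ncomp = 2, seed = 5)
  expect_true(all(pc$truth %in% res$selected_channels))
  false_pos <- setdiff(res$selected_channels, pc$truth)
  expect_lte(length(false_pos), ceiling(0.05 * 50))
})

test_that("uve is deterministic given a seed", {
  pc <- planted_channels(n = 30, p = 20, truth = c(3, 9), seed = 42)
  r1 <- uve_select(pc$X, pc$y, ncomp = 2, seed = 11)
  r2 <- uve_select(pc$X, pc$y, ncomp = 2, seed = 11)
  expect_identical(r1, r2)
})

test_that("cars recovers planted channels and beats the full spectrum", {
  pc <- planted_channels(n = 60, p = 40, truth = c(5, 15), snr = 1e6, seed = 43)
  res <- cars_select(pc$X, pc$y, ncomp_max = 5, n_runs = 50, seed = 13)
  expect_true(all(pc$truth %in% res$selected_channels))
  cv_full <- pls_cv(pc$X, pc$y, ncomp_max = 5)
  expect_lte(res$history$rmsecv[res$best_run],
             min(cv_full$metrics$rmsecv))
})

test_that("cars is deterministic and respects the minimal schedule", {
  pc <- planted_channels(n = 20, p = 12, truth = c(2, 8), seed = 44)
  r1 <- cars_select(pc$X, pc$y, ncomp_max = 3, n_runs = 10, seed = 21)
  r2 <- cars_select(pc$X, pc$y, ncomp_max = 3, n_runs = 10, seed = 21)
  expect_identical(r1, r2)
  withr::local_seed(45)
  X <- matrix(rnorm(15 * 4), 15, 4)
  y <- rnorm(15)
  r <- cars_select(X, y, ncomp_max = 2, n_runs = 2, seed = 1)
  expect_equal(nrow(r$history), 2)
  expect_lte(r$history$n_channels[2], r$history$n_channels[1])
})

test_that("cars subsets respect the budget and never resurrect channels", {
  pc <- planted_channels(n = 40, p = 30, truth = c(4, 22), seed = 46)
  res <- suppressWarnings(cars_select(pc$X, pc$y, ncomp_max = 4, n_runs = 30,
                                      seed = 17))
  h <- res$history
  expect_true(all(h$n_channels <= h$budget))
  for (i in 2:length(res$subset_history)) {
    expect_true(all(res$subset_history[[i]] %in% res$subset_history[[i - 1]]))
  }
  expect_equal(res$selected_channels, res$subset_history[[res$best_run]])
  expect_equal(res$history$rmsecv[res$best_run], min(res$history$rmsecv))
})

test_that("cars validates mc_fraction", {
  withr::local_seed(47)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  expect_error(cars_select(X, y, 2, mc_fraction = 0), "mc_fraction")
  expect_error(cars_select(X, y, 2, mc_fraction = 1.2), "mc_fraction")
})

test_that("both selectors achieve high recall at high snr over replicates", {
  recall_uve <- recall_cars <- numeric(10)
  for (r in 1:10) {
    pc <- planted_channels(n = 60, p = 40, truth = c(7, 25), snr = 100,
                           seed = 600 + r)
    u <- uve_select(pc$X, pc$y, ncomp = 2, seed = 600 + r)
    # at this snr the subset can legitimately collapse to the truth set early
    cc <- suppressWarnings(cars_select(pc$X, pc$y, ncomp_max = 4, n_runs = 50,
                                       folds = 5, seed = 600 + r))
    recall_uve[r] <- mean(pc$truth %in% u$selected_channels)
    recall_cars[r] <- mean(pc$truth %in% cc$selected_channels)
  }
  expect_gte(mean(recall_uve), 0.9)
  expect_gte(mean(recall_cars), 0.9)
})

test_that("selection tidiers and writers expose the diagnostics", {
  pc <- planted_channels(n = 30, p = 15, truth = c(3, 12), seed = 48)
  u <- uve_select(pc$X, pc$y, ncomp = 2, seed = 2)
  td <- tidy(u)
  expect_equal(nrow(td), 30)
  expect_equal(sum(td$block == "noise"), 15)
  expect_equal(glance(u)$n_selected, length(u$selected_channels))
  cc <- suppressWarnings(cars_select(pc$X, pc$y, ncomp_max = 3, n_runs = 8, seed = 2))
  expect_identical(tidy(cc), cc$history)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection(cc, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$selected_channels, cc$selected_channels)
  expect_equal(back$method, "cars")
})

test_that("cars improves out-of-sample rmsep when most channels are uninformative", {
  # the regime where wavelength selection pays off: a few informative
  # channels among many pure-noise ones; on fully informative low-rank band
  # spectra the full-spectrum model is already near-optimal
  wins <- 0L
  for (r in 1:5) {
    pc <- planted_channels(n = 80, p = 50, truth = c(12, 33), snr = 100,
                           seed = 700 + r)
    tr <- 1:60; te <- 61:80
    Xtr <- pc$X[tr, ]; ytr <- pc$y[tr]
    cv_full <- pls_cv(Xtr, ytr, 5, folds = 5)
    fit_full <- pls_fit(Xtr, ytr, cv_full$optimal_ncomp)
    rmsep_full <- rmse(predict(fit_full, pc$X[te, ]), pc$y[te])
    cc <- suppressWarnings(cars_select(Xtr, ytr, ncomp_max = 5, n_runs = 50,
                                       folds = 5, seed = 700 + r))
    ch <- cc$selected_channels
    cv_sub <- pls_cv(Xtr[, ch, drop = FALSE], ytr, 5, folds = 5)
    fit_sub <- pls_fit(Xtr[, ch, drop = FALSE], ytr, cv_sub$optimal_ncomp)
    rmsep_sub <- rmse(predict(fit_sub, pc$X[te, ch, drop = FALSE]), pc$y[te])
    if (rmsep_sub <= rmsep_full) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
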