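test_that("uniform smoothing averages the window and preserves constants", {
  s <- toy_spectra(matrix(c(1, 2, 3), 1))
  out <- spectra_matrix(sg_smooth(s, w = 1))
  expect_equal(out[1, 2], 2)                      # (1+2+3)/3
  const <- toy_spectra(matrix(5, 1, 11))
  expect_equal(spectra_matrix(sg_smooth(const, w = 3)),
               spectra_matrix(const), tolerance = 1e-14)
})

test_that("edge channels use a symmetrically shrunk window", {
  s <- toy_spectra(matrix(c(1, 2, 3, 4, 5), 1))
  out <- spectra_matrix(sg_smooth(s, w = 2))
  expect_equal(out[1, 1], 1)                      # window shrinks to the point
  expect_equal(out[1, 2], 2)                      # mean(1:3)
  expect_equal(out[1, 3], 3)                      # mean(1:5)
})

test_that("smoothing a seeded white-noise spectrum reduces its variance", {
  x <- withr::with_seed(7, rnorm(101))
  s <- toy_spectra(matrix(x, 1))
  out <- spectra_matrix(sg_smooth(s, w = 5))
  expect_lt(var(out[1, ]), var(x))
})

test_that("smoothing is linear and rejects oversized windows", {
  a <- withr::with_seed(1, matrix(rnorm(40), 2, 20))
  b <- withr::with_seed(2, matrix(rnorm(40), 2, 20))
  sa <- toy_spectra(a); sb <- toy_spectra(b)
  lhs <- spectra_matrix(sg_smooth(toy_spectra(2 * a + 3 * b), w = 4))
  rhs <- 2 * spectra_matrix(sg_smooth(sa, w = 4)) +
    3 * spectra_matrix(sg_smooth(sb, w = 4))
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(sg_smooth(toy_spectra(matrix(1:5, 1)), w = 3), "wider")
})

test_that("custom window weights are honoured", {
  s <- toy_spectra(matrix(c(0, 6, 0), 1))
  out <- spectra_matrix(sg_smooth(s, w = 1, weights = c(1, 4, 1)))
  expect_equal(out[1, 2], 4)                      # 6*4/6
})

test_that("first gap derivative of a unit-slope ramp is constant 2", {
  s <- toy_spectra(matrix(1:10, 1))
  out <- spectra_matrix(gap_derivative(s, order = 1, gap = 1))
  expect_equal(unname(out[1, ]), rep(2, 8))       # (x[k+1]-x[k-1])/1
  conv <- spectra_matrix(gap_derivative(s, order = 1, gap = 1,
                                        divisor = "conventional"))
  expect_equal(unname(conv[1, ]), rep(1, 8))
})

test_that("second gap derivative annihilates affines and recovers quadratures", {
  aff <- toy_spectra(matrix(3 * (1:12) + 7, 1))
  out <- spectra_matrix(gap_derivative(aff, order = 2, gap = 3))
  expect_equal(unname(out[1, ]), rep(0, 6), tolerance = 1e-12)
  quad <- toy_spectra(matrix(c(0, 1, 4, 9, 16), 1))
  out2 <- spectra_matrix(gap_derivative(quad, order = 2, gap = 1))
  expect_equal(unname(out2[1, ]), c(2, 2, 2))
})

test_that("derivatives trim g channels per edge and the wavelength axis follows", {
  s <- toy_spectra(matrix(rnorm(30), 2, 15))
  out <- gap_derivative(s, order = 1, gap = 4)
  expect_equal(ncol(spectra_matrix(out)), 15 - 8)
  expect_equal(spectra_wavelengths(out), spectra_wavelengths(s)[5:11])
  expect_error(gap_derivative(s, gap = 8), "too large")
})

test_that("msc_fit is the column mean and stays frozen across new data", {
  cal <- toy_spectra(rbind(c(0, 2, 4), c(2, 0, 0)))
  ref <- msc_fit(cal)
  expect_equal(unname(ref), c(1, 1, 2))
  # applying a calibration reference to new data must not recompute the mean
  new <- toy_spectra(rbind(2 * c(1, 1, 2) + 3, c(5, 9, 13)))
  out <- spectra_matrix(msc_transform(new, ref))
  expect_equal(unname(out[1, ]), c(1, 1, 2), tolerance = 1e-12)
})

test_that("msc_fit on a noiseless rank-1 set is proportional to the pure spectrum", {
  cfg <- synthetic_config(n_samples = 10, n_channels = 40, seed = 4,
                          components = list(component_spec("a", 1500, 100, 0.2, 1, 5)),
                          baseline_amplitude = 0, scatter_slope_sd = 0,
                          scatter_offset_sd = 0, noise_sd = 0)
  d <- generate_nir(cfg)
  ref <- msc_fit(d$spectra)
  pure <- d$truth$pure[, "a"]
  cosine <- sum(ref * pure) / sqrt(sum(ref^2) * sum(pure^2))
  expect_equal(cosine, 1, tolerance = 1e-12)
})

test_that("msc_transform inverts exact affine distortions", {
  ref <- c(1, 2, 3, 5, 4)
  x <- toy_spectra(rbind(ref, 2 * ref + 3))
  out <- spectra_matrix(msc_transform(x, ref))
  expect_equal(unname(out[1, ]), ref, tolerance = 1e-12)   # m=1, b=0
  expect_equal(unname(out[2, ]), ref, tolerance = 1e-12)   # m=2, b=3
  expect_error(msc_transform(x, rep(1, 5)), "constant")
})

test_that("msc equalizes samples that differ only by scatter", {
  comps <- list(component_spec("a", 1400, 120, 0.1, 2, 2.0001))
  cfg <- synthetic_config(n_samples = 10, n_channels = 50, seed = 13,
                          components = comps, baseline_amplitude = 0,
                          scatter_slope_sd = 0.3, scatter_offset_sd = 0.2,
                          noise_sd = 0)
  d <- generate_nir(cfg)   # near-identical concentrations, scatter only
  out <- spectra_matrix(msc_transform(d$spectra, msc_fit(d$spectra)))
  for (i in 2:nrow(out)) {
    expect_equal(unname(out[i, ]), unname(out[1, ]), tolerance = 1e-8)
  }
})

test_that("snv output has row mean 0 and unit (n-1) sd, and is affine-invariant", {
  s <- toy_spectra(matrix(c(1, 2, 3), 1))
  expect_equal(unname(spectra_matrix(snv(s))[1, ]), c(-1, 0, 1))
  x <- withr::with_seed(3, matrix(rnorm(60), 3, 20))
  out <- spectra_matrix(snv(toy_spectra(x)))
  expect_equal(unname(rowMeans(out)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(out, 1, sd)), rep(1, 3), tolerance = 1e-12)
  shifted <- spectra_matrix(snv(toy_spectra(2.5 * x + 7)))
  expect_equal(shifted, out, tolerance = 1e-12)
  expect_error(snv(toy_spectra(matrix(1, 1, 5))), "constant")
})

test_that("operators are row-independent: permuting samples permutes outputs", {
  x <- withr::with_seed(5, matrix(rnorm(100), 5, 20))
  s <- toy_spectra(x, ids = paste0("s", 1:5))
  perm <- c(3, 1, 5, 2, 4)
  sp <- toy_spectra(x[perm, ], ids = paste0("s", 1:5)[perm])
  for (f in list(function(z) snv(z),
                 function(z) sg_smooth(z, w = 2),
                 function(z) gap_derivative(z, order = 2, gap = 2))) {
    expect_equal(unname(spectra_matrix(f(sp))),
                 unname(spectra_matrix(f(s))[perm, ]), tolerance = 1e-12)
  }
})

test_that("pretreat dispatcher composes smoothing with derivatives", {
  s <- toy_spectra(withr::with_seed(6, matrix(rnorm(60), 2, 30)))
  direct <- gap_derivative(sg_smooth(s, w = 3), order = 1, gap = 2)
  via <- pretreat(s, "d1_sg", window = 3, gap = 2)
  expect_equal(spectra_matrix(via), spectra_matrix(direct))
  expect_identical(spectra_matrix(pretreat(s, "raw")), spectra_matrix(s))
  expect_error(pretreat(s, "msc"), "reference")
})
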