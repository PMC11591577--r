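make_set <- function(wn, X) {
  spectra_set(wn, X, sprintf("s%02d", seq_len(nrow(X))),
              rep("HC", nrow(X)))
}

test_that("crop_region keeps the closed interval and errors when empty", {
  wn <- wavenumber_grid(1800, 900, 0.5)
  X <- matrix(seq_along(wn), nrow = 2, ncol = length(wn), byrow = TRUE)
  s <- make_set(wn, X)
  full <- crop_region(make_set(wavenumber_grid(), X[, 1:1001]), 1000, 1500)
  expect_equal(length(full$wavenumbers), 1001L)
  cr <- crop_region(s, 1000, 1500)
  expect_equal(length(cr$wavenumbers), 1001L)
  expect_true(all(cr$wavenumbers >= 1000 & cr$wavenumbers <= 1500))
  expect_error(crop_region(s, 2000, 2100), "no grid points")
})

test_that("normalization follows the closed forms", {
  expect_equal(normalize_spectrum(c(3, 4), "vector"), c(0.6, 0.8))
  set.seed(1)
  v <- rnorm(50)
  expect_equal(sqrt(sum(normalize_spectrum(v, "vector")^2)), 1,
               tolerance = 1e-12)
  expect_equal(normalize_spectrum(c(1, 2, 3), "snv"), c(-1, 0, 1))
  expect_error(normalize_spectrum(rep(0, 5), "vector", id = "S9"), "S9")
  expect_error(normalize_spectrum(rep(2, 5), "snv"), "zero-variance")
})

test_that("moving average: identity, constancy, and hand example", {
  expect_equal(moving_average(c(5, 1, 9), 1L), c(5, 1, 9))
  expect_equal(moving_average(rep(7, 10), 5L), rep(7, 10))
  expect_equal(moving_average(c(0, 0, 3, 0, 0), 3L), c(0, 1, 1, 1, 0))
  expect_error(moving_average(1:10, 4L), "odd")
})

test_that("S-G second derivative is exact for polynomials on the interior", {
  x <- seq(1000, 1050, by = 0.5)
  inner <- 6:(length(x) - 5)
  d2 <- sg_second_derivative(x^2, 11, 3, 0.5)
  expect_equal(d2[inner], rep(2, length(inner)), tolerance = 1e-9)
  dlin <- sg_second_derivative(3 * x - 7, 11, 3, 0.5)
  expect_equal(dlin[inner], rep(0, length(inner)), tolerance = 1e-9)
  d3 <- sg_second_derivative(x^3, 11, 3, 0.5)
  expect_equal(d3[inner], 6 * x[inner], tolerance = 1e-6)
  expect_error(sg_second_derivative(x, 10, 3), "odd")
  expect_error(sg_second_derivative(x, 11, 1), "polyorder")
})

test_that("preprocess errors on a non-uniform grid", {
  wn <- c(seq(1500, 1491, by = -1), seq(1489.5, 1480, by = -0.5))
  s <- make_set(wn, matrix(rnorm(2 * length(wn)), 2))
  expect_error(preprocess(s, preprocess_config(region = c(1400, 1500))),
               "uniform")
})

test_that("autoscaler centers and scales on train, never refits on test", {
  s <- generate_cohort(two_class_config(seed = 8))
  pp <- preprocess(s)
  sc <- fit_scaler(pp)
  z <- apply_scaler(sc, pp)
  expect_lt(max(abs(colMeans(z$absorbance))), 1e-10)
  expect_lt(max(abs(apply(z$absorbance, 2, sd) - 1)), 1e-10)

  # a "test" row equal to the training mean maps to all zeros
  mean_row <- spectra_set(pp$wavenumbers,
                          rbind(colMeans(pp$absorbance)), "m", "HC")
  expect_lt(max(abs(apply_scaler(sc, mean_row)$absorbance)), 1e-12)

  ident <- make_set(1:4, matrix(1, 3, 4))
  expect_warning(sc0 <- fit_scaler(ident), "zero-variance")
  expect_equal(length(sc0$zero_variance), 4L)
})

test_that("the chain removes multiplicative scatter and is order-equivariant", {
  wn <- wavenumber_grid()
  r <- band_profile(default_bands(), wn)
  s <- make_set(wn, rbind(r, 3.7 * r))
  out <- preprocess(s)
  expect_equal(out$absorbance[1, ], out$absorbance[2, ], tolerance = 1e-12)

  coh <- generate_cohort(cohort_config(seed = 12))
  perm <- sample(seq_len(nrow(coh$absorbance)))
  a <- preprocess(coh)
  b <- preprocess(subset_samples(coh, perm))
  expect_equal(b$absorbance, a$absorbance[perm, ], tolerance = 1e-14)
})

test_that("crop-only config is the identity beyond cropping; chain is pure", {
  s <- generate_cohort(cohort_config(seed = 9))
  cfg <- preprocess_config(normalization = "none", ma_window = 1L,
                           derivative_order = 0L)
  out <- preprocess(s, cfg)
  expect_equal(out$absorbance, s$absorbance)
  expect_identical(preprocess(s)$absorbance, preprocess(s)$absorbance)
})

test_that("group-mean second derivative dips at a planted marker", {
  cfg <- cohort_config(sizes = c(HC = 8, ALS_T0 = 8),
                       effects = list(HC = c(), ALS_T0 = c("1304" = 0.15)),
                       noise_sd = 1e-4)
  pp <- preprocess(generate_cohort(cfg, seed = 3))
  diffm <- colMeans(pp$absorbance[pp$group == "ALS_T0", ]) -
    colMeans(pp$absorbance[pp$group == "HC", ])
  j <- match(1304, pp$wavenumbers)
  # second derivative of an added positive Gaussian is negative at center
  expect_lt(diffm[j], 0)
  win <- abs(pp$wavenumbers - 1304) <= 4
  expect_equal(pp$wavenumbers[which.min(replace(diffm, !win, Inf))], 1304,
               tolerance = 2)
})

test_that("S-G filter reproduces random cubic derivatives exactly (property)", {
  x <- seq(0, 30, by = 0.5)
  inner <- 6:(length(x) - 5)
  set.seed(42)
  for (rep in 1:20) {
    cf <- rnorm(4)
    y <- cf[1] + cf[2] * x + cf[3] * x^2 + cf[4] * x^3
    d2 <- sg_second_derivative(y, 11, 3, 0.5)
    expect_equal(d2[inner], 2 * cf[3] + 6 * cf[4] * x[inner],
                 tolerance = 1e-9)
  }
})
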