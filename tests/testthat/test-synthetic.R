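test_that("band_profile matches the Gaussian closed form and is linear", {
  wn <- wavenumber_grid()
  one <- data.frame(center = 1300, width = 10, amplitude = 1)
  prof <- band_profile(one, wn)
  expect_equal(prof[match(1300, wn)], 1.0)
  expect_equal(prof[match(1310, wn)], exp(-0.5), tolerance = 1e-12)

  expect_identical(band_profile(one[0, ], wn), numeric(length(wn)))
  expect_equal(band_profile(rbind(one, one), wn), 2 * prof)
  expect_error(band_profile(one, numeric(0)), "empty")
  expect_error(band_profile(data.frame(center = 1, width = -1, amplitude = 1),
                            1:3), "width")
})

test_that("instrument effects reduce to identity and scale correctly", {
  wn <- wavenumber_grid()
  clean <- band_profile(default_bands(), wn)
  cfg0 <- cohort_config(noise_sd = 0, baseline_const = c(0, 0),
                        baseline_slope = c(0, 0), scatter = c(1, 1))
  expect_equal(apply_instrument_effects(clean, cfg0, wn), clean)

  cfg2 <- cohort_config(noise_sd = 0, baseline_const = c(0, 0),
                        baseline_slope = c(0, 0), scatter = c(2, 2))
  expect_equal(apply_instrument_effects(clean, cfg2, wn), 2 * clean)

  cfg <- cohort_config()
  set.seed(11); a <- apply_instrument_effects(clean, cfg, wn)
  set.seed(11); b <- apply_instrument_effects(clean, cfg, wn)
  expect_identical(a, b)
})

test_that("generate_cohort has the study-design shape and is deterministic", {
  s <- generate_cohort(cohort_config(seed = 5))
  expect_s3_class(s, "spectra_set")
  expect_equal(dim(s), c(57L, 1001L))
  expect_equal(sort(unique(s$group)), c("ALS_T0", "ALS_T6", "HC", "ON"))
  expect_equal(unname(table(s$group)[c("ALS_T0", "ALS_T6", "HC", "ON")]),
               c(19L, 16L, 15L, 7L), ignore_attr = TRUE)
  s2 <- generate_cohort(cohort_config(seed = 5))
  expect_identical(s, s2)
  expect_false(identical(s$absorbance,
                         generate_cohort(cohort_config(seed = 6))$absorbance))
})

test_that("degenerate config gives identical rows; unknown effect group errors", {
  cfg <- cohort_config(sizes = c(A = 3, B = 2),
                       effects = list(A = c(), B = c()),
                       band_cv = 0, effect_cv = 0,
                       noise_sd = 0, baseline_const = c(0, 0),
                       baseline_slope = c(0, 0), scatter = c(1, 1))
  s <- generate_cohort(cfg, seed = 1)
  expect_true(all(abs(sweep(s$absorbance, 2, s$absorbance[1, ])) < 1e-15))
  expect_error(
    cohort_config(sizes = c(A = 3), effects = list(ZZZ = c("1300" = 1))),
    "unknown group")
})

test_that("planted group delta appears as a Gaussian bump at the marker", {
  cfg <- cohort_config(sizes = c(HC = 5, ALS_T0 = 5),
                       effects = list(HC = c(), ALS_T0 = c("1335.5" = 0.2)),
                       band_cv = 0, effect_cv = 0,
                       noise_sd = 0, baseline_const = c(0, 0),
                       baseline_slope = c(0, 0), scatter = c(1, 1))
  s <- generate_cohort(cfg, seed = 2)
  diffm <- colMeans(s$absorbance[s$group == "ALS_T0", ]) -
    colMeans(s$absorbance[s$group == "HC", ])
  expected <- band_profile(
    data.frame(center = 1335.5, width = cfg$marker_width, amplitude = 0.2),
    s$wavenumbers)
  expect_equal(diffm, expected, tolerance = 1e-10)
  expect_equal(s$wavenumbers[which.max(diffm)], 1335.5)
})

test_that("triplicate averaging reduces noise by about sqrt(3)", {
  cfg <- cohort_config(sizes = c(HC = 1), effects = list(HC = c()),
                       noise_sd = 0.01, baseline_const = c(0, 0),
                       baseline_slope = c(0, 0), scatter = c(1, 1),
                       replicates = 3)
  wn <- wavenumber_grid()
  clean <- band_profile(cfg$bands, wn)
  set.seed(99)
  draws <- replicate(200, {
    reps <- replicate(3, apply_instrument_effects(clean, cfg, wn))
    rowMeans(reps)[1]
  })
  expect_equal(stats::sd(draws), 0.01 / sqrt(3), tolerance = 0.15)
})

test_that("group means recover planted deltas as noise vanishes", {
  cfg <- two_class_config(seed = 3)
  cfg$band_cv <- 0; cfg$effect_cv <- 0
  cfg$noise_sd <- 1e-5
  cfg$baseline_const <- c(0, 0); cfg$baseline_slope <- c(0, 0)
  cfg$scatter <- c(1, 1)
  s <- generate_cohort(cfg)
  diffm <- colMeans(s$absorbance[s$group == "ALS_T0", ]) -
    colMeans(s$absorbance[s$group == "HC", ])
  j <- match(1335.5, s$wavenumbers)
  expect_equal(diffm[j], unname(default_group_effects()$ALS_T0["1335.5"]),
               tolerance = 1e-2)
})

test_that("wide CSV round-trips a spectra_set with JSON sidecar", {
  s <- generate_cohort(cohort_config(sizes = c(HC = 3, ON = 2), seed = 4,
                                     effects = list()))
  f <- tempfile(fileext = ".csv")
  write_spectra(s, f, sidecar = list(seed = 4))
  expect_true(file.exists(sub("csv$", "json", f)))
  r <- read_spectra(f)
  expect_equal(r$wavenumbers, s$wavenumbers)
  expect_equal(r$absorbance, s$absorbance, tolerance = 1e-12)
  expect_identical(r$sample_id, s$sample_id)
  expect_identical(r$group, s$group)
  unlink(c(f, sub("csv$", "json", f)))
})
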