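test_that("simca_fit residual dispersions follow the stated formulas", {
  # data exactly on a 1-D subspace -> zero residual sd
  t_ <- seq(-2, 2, length.out = 6)
  X <- outer(t_, c(1, 2, -1)) + matrix(5, 6, 3)
  m <- simca_fit(X, 1)
  expect_lt(m$s0, 1e-12)

  # A = 0 collapses to the pooled variable sd about the class mean
  set.seed(4)
  X2 <- matrix(rnorm(40), 8, 5)
  m0 <- simca_fit(X2, 0)
  Xc <- scale(X2, scale = FALSE)
  expect_equal(m0$s0, sqrt(sum(Xc^2) / (5 * 7)), tolerance = 1e-12)
  expect_equal(m0$sd_var, sqrt(colSums(Xc^2) / 7), tolerance = 1e-12)

  # 5 x 3 matrix, A = 1: agree with an independent eigendecomposition
  set.seed(11)
  X3 <- matrix(rnorm(15), 5, 3)
  m1 <- simca_fit(X3, 1)
  Xc3 <- scale(X3, scale = FALSE)
  ev <- eigen(crossprod(Xc3))
  recon <- Xc3 %*% ev$vectors[, 1] %*% t(ev$vectors[, 1])
  E <- Xc3 - recon
  expect_equal(m1$s0, sqrt(sum(E^2) / ((3 - 1) * (5 - 1 - 1))),
               tolerance = 1e-10)
})

test_that("object_distance is zero in-plane and matches hand computation", {
  t_ <- seq(-2, 2, length.out = 6)
  X <- outer(t_, c(1, 2, -1))
  m <- simca_fit(X, 1)
  d <- object_distance(m, X[3, ])
  expect_lt(d$s, 1e-12)
  expect_identical(d$F, 0)
  expect_lt(object_distance(m, m$mean)$s, 1e-12)

  # hand case: model plane = span(e1) after centering at 0
  Xh <- rbind(c(-2, 0, 0), c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  mh <- simca_fit(Xh, 1)
  x <- c(0, 3, 4)             # residual (0, 3, 4), norm 5
  expect_equal(object_distance(mh, x)$s, 5 / sqrt(3 - 1), tolerance = 1e-12)
})

test_that("s0 decreases monotonically in the component count", {
  set.seed(5)
  X <- matrix(rnorm(20 * 6), 20, 6)
  s0s <- vapply(0:3, function(A) simca_fit(X, A)$s0, numeric(1))
  expect_true(all(diff(s0s) < 0))
})

test_that("open/forced classification has the expected geometry", {
  set.seed(6)
  XA <- cbind(rnorm(20, sd = 3), matrix(rnorm(20 * 4, sd = 0.3), 20, 4))
  XB <- cbind(matrix(rnorm(20 * 5, sd = 0.3), 20, 5))
  XB[, 3] <- XB[, 3] + 25
  mA <- simca_fit(XA, 1, "A"); mB <- simca_fit(XB, 1, "B")
  inA <- c(rnorm(1, sd = 3), rnorm(4, sd = 0.3))
  cl <- simca_classify(list(A = mA, B = mB), inA)
  expect_true(cl$open[1, "A"]); expect_false(cl$open[1, "B"])
  expect_identical(cl$forced, "A")

  far <- rep(1e3, 5)
  clf <- simca_classify(list(A = mA, B = mB), far)
  expect_false(any(clf$open))
  expect_identical(clf$forced,
                   c("A", "B")[which.min(clf$ratio[1, ])])

  # identical class models: forced tie resolved to the first label
  cl2 <- simca_classify(list(A = mA, A2 = mA), inA)
  expect_identical(cl2$forced, "A")
})

test_that("in-class open acceptance is close to 1 - alpha (quick check)", {
  set.seed(8)
  P <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:2]
  gen <- function(n) matrix(rnorm(n * 2, sd = 4), n, 2) %*% t(P) +
    matrix(rnorm(n * 10, sd = 0.5), n, 10)
  m <- simca_fit(gen(40), 2)
  acc <- mean(simca_classify(list(g = m), gen(200), alpha = 0.05)$open)
  expect_gt(acc, 0.88); expect_lte(acc, 1.0)
})

test_that("modelling power hits its closed-form extremes and bounds", {
  t_ <- seq(-3, 3, length.out = 10)
  X <- cbind(t_, 2 * t_, rnorm(10, sd = 0.1))
  m <- simca_fit(X, 1)
  mp <- modeling_power(m, X)
  expect_gt(mp[1], 0.99); expect_gt(mp[2], 0.99)

  m0 <- simca_fit(X, 0)
  expect_equal(modeling_power(m0, X), rep(0, 3))

  Xz <- cbind(t_, rep(1, 10))
  mz <- simca_fit(Xz, 1)
  expect_warning(mpz <- modeling_power(mz, Xz), "zero-variance")
  expect_true(is.na(mpz[2]))
  expect_true(all(is.na(mpz) | (mpz >= 0 & mpz <= 1)))
})

test_that("discriminant power separates shifted variables from null ones", {
  set.seed(9)
  null_in_band <- 0L
  shift_wins <- 0L
  for (r in 1:10) {
    XA <- matrix(rnorm(20 * 6), 20, 6)
    XB <- matrix(rnorm(20 * 6), 20, 6)
    mA <- simca_fit(XA, 1); mB <- simca_fit(XB, 1)
    dp_null <- discriminant_power(mA, mB, XA, XB)
    null_in_band <- null_in_band +
      (median(dp_null) >= 0.7 && median(dp_null) <= 1.4)

    XB2 <- XB; XB2[, 4] <- XB2[, 4] + 4
    mB2 <- simca_fit(XB2, 1)
    dp <- discriminant_power(mA, mB2, XA, XB2)
    shift_wins <- shift_wins + (which.max(dp) == 4)
  }
  expect_gte(null_in_band, 9L)
  expect_gte(shift_wins, 10L)
})

test_that("simca_analysis reports the full table layout on a cohort", {
  pp <- preprocess(generate_cohort(two_class_config(seed = 13)))
  z <- autoscale_self(pp)
  sel <- select_decorrelate(z$absorbance, z$group, 10, z$wavenumbers)
  zs <- subset_wavenumbers(z, sel$selected)
  rep_ <- simca_analysis(zs, alpha = 0.05)
  expect_s3_class(rep_, "simca_report")
  expect_setequal(rep_$rates$group, c("ALS_T0", "HC"))
  num <- unlist(rep_$rates[-1])
  expect_true(all(is.na(num) | (num >= 0 & num <= 100)))
  # power table: rows sorted by descending DP, MP columns per class in [0,1]
  expect_true(all(diff(rep_$power$DP) <= 1e-12))
  expect_true(all(rep_$power[["MP_ALS_T0"]] >= 0 &
                    rep_$power[["MP_ALS_T0"]] <= 1, na.rm = TRUE))
  expect_true(all(rep_$power[["MP_HC"]] >= 0 &
                    rep_$power[["MP_HC"]] <= 1, na.rm = TRUE))
  expect_equal(nrow(rep_$power), length(sel$selected))
})
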