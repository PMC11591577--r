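test_that("PLS-DA fits a perfectly aligned univariate predictor exactly", {
  y <- rep(c("A", "B"), each = 10)
  x <- scale(matrix(as.numeric(y == "B"), ncol = 1))
  m <- plsda_fit(x, y, 1)
  expect_equal(m$R2Y, 1, tolerance = 1e-10)
  expect_identical(predict(m, x)$labels, y)
})

test_that("first PLS weight is proportional to X'y for a single response", {
  set.seed(2)
  X <- scale(matrix(rnorm(30 * 10), 30, 10))
  y <- rep(c("A", "B"), each = 15)
  m <- plsda_fit(X, y, 1)
  yd <- scale(as.numeric(y == "B"), scale = FALSE)
  w_oracle <- as.numeric(crossprod(X, yd))
  w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  cosine <- abs(sum(m$W[, 1] * w_oracle))
  expect_gte(cosine, 0.999)
})

test_that("PLS internals satisfy their structural invariants", {
  set.seed(3)
  X <- scale(matrix(rnorm(30 * 10), 30, 10))
  y <- sample(rep(c("A", "B", "C"), each = 10))
  m <- plsda_fit(X, y, 3)
  expect_equal(colSums(m$W^2), rep(1, 3), tolerance = 1e-10)
  G <- crossprod(m$T)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_true(m$R2Y > 0 && m$R2Y < 1)
  acc <- mean(predict(m, X)$labels == y)
  expect_gte(acc, 1 / 3)
  expect_error(plsda_fit(X[1:4, ], y[1:4], 10), "rank")
})

test_that("PLS-DA with all components reproduces the OLS fit on full-rank X", {
  set.seed(4)
  X <- scale(matrix(rnorm(40 * 5), 40, 5))
  y <- rep(c("A", "B"), 20)
  m <- plsda_fit(X, y, 5)
  yd <- as.numeric(y == "B")
  ols <- stats::lm.fit(cbind(1, X), yd)
  yhat_ols <- cbind(1, X) %*% ols$coefficients
  expect_equal(unname(predict(m, X)$yhat[, "B"]), as.numeric(yhat_ols),
               tolerance = 1e-8)
})

test_that("VIP identities: equal weights, mean square one, dominant variable", {
  y <- rep(c("A", "B"), each = 10)
  set.seed(5)
  # one dominant variable: VIP ~ sqrt(p)
  X <- scale(cbind(as.numeric(y == "B") + rnorm(20, sd = 1e-4),
                   matrix(rnorm(20 * 9, sd = 1), 20, 9)))
  m <- plsda_fit(X, y, 1)
  v <- vip_scores(m)
  expect_equal(mean(v^2), 1, tolerance = 1e-10)
  expect_equal(v[1], sqrt(10), tolerance = 0.15)

  for (s in 1:10) {
    set.seed(s)
    Xr <- scale(matrix(rnorm(24 * 7), 24, 7))
    yr <- sample(rep(c("A", "B"), each = 12))
    mr <- plsda_fit(Xr, yr, 2)
    expect_equal(mean(vip_scores(mr)^2), 1, tolerance = 1e-10)
  }
})

test_that("Q2 is high for deterministic structure, non-positive under the null", {
  y <- rep(c("A", "B"), each = 30)
  set.seed(6)
  X <- cbind(as.numeric(y == "B") * 4 + rnorm(60, sd = 0.02),
             matrix(rnorm(60 * 4), 60, 4))
  q2 <- q2_crossval(X, y, n_comp = 1, folds = 5, seed = 1)
  expect_gte(q2$Q2Y, 0.95)

  null_q2 <- vapply(1:20, function(s) {
    set.seed(s)
    Xn <- matrix(rnorm(30 * 8), 30, 8)
    yn <- rep(c("A", "B"), each = 15)
    q2_crossval(Xn, yn, n_comp = 2, folds = 5, seed = s)$Q2Y
  }, numeric(1))
  expect_lte(median(null_q2), 0)

  a <- q2_crossval(X, y, n_comp = 1, folds = 5, seed = 9)
  b <- q2_crossval(X, y, n_comp = 1, folds = 5, seed = 9)
  expect_identical(a, b)
})

test_that("OPLS-DA reduces to PLS without orthogonal structure and is orthogonal", {
  set.seed(7)
  y <- rep(c("A", "B"), each = 15)
  X <- scale(matrix(rnorm(30 * 8), 30, 8))
  om <- oplsda_fit(X, y, n_orth = 1)
  pm <- plsda_fit(X, y, 1)
  if (om$n_orth > 0)
    expect_lt(abs(stats::cov(om$t_pred, om$T_orth[, 1])), 1e-8)

  # X-variance decomposition closes
  expect_equal(om$x_var_pred + om$x_var_orth + om$x_var_resid,
               om$x_var_total, tolerance = 1e-8)

  # no planted orthogonal structure: predictive scores track 1-comp PLS
  cosine <- abs(stats::cor(om$t_pred, pm$T[, 1]))
  expect_gte(cosine, 0.95)
  expect_error(oplsda_fit(X, rep(c("A", "B", "C"), each = 10)), "plsda")
})

test_that("a strong class-orthogonal direction hurts PLS Q2 more than OPLS Q2", {
  diffs <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 40
    y <- rep(c("A", "B"), each = n / 2)
    signal <- as.numeric(y == "B")
    conf <- rnorm(n, sd = 3)               # structured, class-orthogonal
    load_s <- runif(8, 0.5, 1); load_c <- runif(8, -1, 1)
    X <- outer(signal, load_s) + outer(conf, load_c) +
      matrix(rnorm(n * 8, sd = 0.3), n, 8)
    q_pls <- q2_crossval(X, y, n_comp = 1, folds = 5, seed = s,
                         fit_fun = "plsda")$Q2Y
    q_opls <- q2_crossval(X, y, folds = 5, seed = s,
                          fit_fun = "oplsda", n_orth = 1)$Q2Y
    q_opls - q_pls
  }, numeric(1))
  expect_gt(median(diffs), 0)
})

test_that("permutation test pins strong effects at the minimum p", {
  set.seed(8)
  y <- rep(c("A", "B"), each = 12)
  X <- cbind(as.numeric(y == "B") * 5 + rnorm(24, sd = 0.2),
             matrix(rnorm(24 * 5), 24, 5))
  pt <- permutation_test(X, y, n_perm = 39, seed = 1, fit_fun = "oplsda")
  expect_equal(pt$p_Q2Y, 1 / 40)
  expect_gte(pt$p_R2Y, 1 / 40)
  expect_warning(permutation_test(X, y, n_perm = 9, seed = 1), "resolution")
})

test_that("cv_anova follows its F-form arithmetic", {
  res <- cv_anova(press = 10, ss_tot = 10, n = 12, d1 = 2)
  expect_equal(res$F, 0); expect_equal(res$p, 1)

  res2 <- cv_anova(press = 1e-9, ss_tot = 10, n = 12, d1 = 2)
  expect_gt(res2$F, 1e8); expect_lt(res2$p, 1e-10)

  # worked fixture: n = 10, d1 = 1, PRESS 2, SS 10 -> F = 8/1 / (2/8) = 32
  res3 <- cv_anova(press = 2, ss_tot = 10, n = 10, d1 = 1)
  expect_equal(res3$F, 32)
  expect_equal(res3$p, stats::pf(32, 1, 8, lower.tail = FALSE))

  res4 <- cv_anova(press = 12, ss_tot = 10, n = 10, d1 = 1)
  expect_lte(res4$F, 0); expect_equal(res4$p, 1)
})
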