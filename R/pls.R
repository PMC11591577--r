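# Dummy-code class labels: one centered column per class.
dummy_code <- function(y) {
  y <- as.character(y)
  classes <- sort(unique(y))
  Y <- vapply(classes, function(g) as.numeric(y == g), numeric(length(y)))
  Y <- matrix(Y, ncol = length(classes), dimnames = list(NULL, classes))
  ymeans <- colMeans(Y)
  list(Y = sweep(Y, 2, ymeans), means = ymeans, classes = classes)
}

#' Fit a PLS-DA model (NIPALS)
#'
#' Partial least squares regression of centered class-membership dummies
#' on X, one dummy column per class, extracted component by component
#' with NIPALS: the X-weight is taken from the covariance with the
#' current Y residual, scores and loadings follow, then X and Y are
#' deflated. Weight vectors have unit norm; score vectors of successive
#' components are mutually orthogonal.
#'
#' @param X Numeric matrix (autoscaled upstream).
#' @param y Class labels (>= 2 classes).
#' @param n_comp Number of latent components, `< rank(X)`.
#' @return Object of class `plsda_model` with weights `W`, scores `T`,
#'   X-loadings `P`, Y-loadings `Q`, per-component explained Y-variance
#'   `ssy_explained`, and `R2Y`.
#' @export
plsda_fit <- function(X, y, n_comp = 2) {
  X <- as.matrix(X)
  dc <- dummy_code(y)
  Y <- dc$Y
  n <- nrow(X); p <- ncol(X)
  if (n_comp >= qr(X)$rank + 1) stop("n_comp >= rank(X)")
  ss_tot <- sum(Y^2)
  W <- matrix(0, p, n_comp); P <- matrix(0, p, n_comp)
  Tm <- matrix(0, n, n_comp); Q <- matrix(0, ncol(Y), n_comp)
  ssy <- numeric(n_comp)
  Xd <- X; Yd <- Y
  for (a in seq_len(n_comp)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    for (it in seq_len(500)) {
      w <- as.numeric(crossprod(Xd, u))
      w <- w / sqrt(sum(w^2))
      tt <- as.numeric(Xd %*% w)
      q <- as.numeric(crossprod(Yd, tt)) / sum(tt^2)
      u_new <- as.numeric(Yd %*% q) / sum(q^2)
      if (sum((u_new - u)^2) < 1e-12 * sum(u_new^2)) { u <- u_new; break }
      u <- u_new
    }
    pload <- as.numeric(crossprod(Xd, tt)) / sum(tt^2)
    ss_before <- sum(Yd^2)
    Xd <- Xd - tcrossprod(tt, pload)
    Yd <- Yd - tcrossprod(tt, q)
    ssy[a] <- ss_before - sum(Yd^2)
    W[, a] <- w; P[, a] <- pload; Tm[, a] <- tt; Q[, a] <- q
  }
  structure(list(W = W, P = P, T = Tm, Q = Q, n_comp = n_comp,
                 ssy_explained = ssy, ss_tot_y = ss_tot,
                 R2Y = 1 - sum(Yd^2) / ss_tot,
                 y_means = dc$means, classes = dc$classes,
                 x_var_total = sum(X^2), x_var_scores = colSums(Tm^2) *
                   colSums(P^2)),
            class = "plsda_model")
}

#' Predict from a PLS-DA model
#'
#' @param object A [plsda_fit()] result.
#' @param newdata Matrix on the same variables (same scaling).
#' @param ... Unused.
#' @return List with `labels` (argmax dummy estimate), `yhat` (estimated
#'   dummy values, uncentered) and `scores` (X-scores of `newdata`).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  # regression coefficients B = W (P'W)^-1 Q'
  B <- object$W %*% solve(crossprod(object$P, object$W), t(object$Q))
  Yhat <- sweep(X %*% B, 2, object$y_means, "+")
  colnames(Yhat) <- object$classes
  R <- object$W %*% solve(crossprod(object$P, object$W))
  list(labels = object$classes[apply(Yhat, 1, which.max)],
       yhat = Yhat, scores = X %*% R)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` with unit-norm
#' component weights `w_a` and `SSY_a` the Y-variance explained by
#' component a. Satisfies `mean(VIP^2) = 1` for every fitted model.
#'
#' @param model A [plsda_fit()] result.
#' @return Numeric vector of VIP scores, one per variable.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  p <- nrow(model$W)
  W2 <- sweep(model$W, 2, sqrt(colSums(model$W^2)), "/")^2
  ssy <- model$ssy_explained
  sqrt(p * as.numeric(W2 %*% ssy) / sum(ssy))
}

# Stratified fold assignment under a seed.
stratified_folds <- function(y, k, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  fold <- integer(length(y))
  for (g in unique(y)) {
    idx <- sample(which(y == g))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated predictive ability Q2Y
#'
#' Stratified k-fold cross-validation with a full refit per fold,
#' including the autoscaler: the scaler and the PLS (or OPLS) model are
#' learned on the training folds only and the held-out dummy responses
#' are predicted. `Q2Y = 1 - PRESS / SS_tot`.
#'
#' @param X Raw (pre-autoscaling) matrix.
#' @param y Class labels.
#' @param n_comp Components for the refits.
#' @param folds Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @param fit_fun Either `"plsda"` or `"oplsda"` (2 classes only).
#' @param n_orth Orthogonal components when `fit_fun = "oplsda"`.
#' @return List with `Q2Y`, `PRESS`, `ss_tot`, `fold` assignment.
#' @export
q2_crossval <- function(X, y, n_comp = 2, folds = 5, seed = 1,
                        fit_fun = c("plsda", "oplsda"), n_orth = 1) {
  fit_fun <- match.arg(fit_fun)
  X <- as.matrix(X); y <- as.character(y)
  fold <- stratified_folds(y, folds, seed)
  dc <- dummy_code(y)
  Yfull <- sweep(dc$Y, 2, dc$means, "+")   # uncentered dummies
  ss_tot <- sum(dc$Y^2)
  press <- 0
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    if (length(unique(y[tr])) < length(unique(y)))
      stop("fold ", f, " lacks a class in training")
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- col_sds(X[tr, , drop = FALSE])
    sdv[sdv == 0] <- 1
    scale_ <- function(M) sweep(sweep(M, 2, mu), 2, sdv, "/")
    m <- if (fit_fun == "plsda")
      plsda_fit(scale_(X[tr, , drop = FALSE]), y[tr], n_comp)
    else
      oplsda_fit(scale_(X[tr, , drop = FALSE]), y[tr], n_orth = n_orth)
    yh <- predict(m, scale_(X[te, , drop = FALSE]))$yhat
    yh <- yh[, dc$classes, drop = FALSE]
    press <- press + sum((Yfull[te, , drop = FALSE] - yh)^2)
  }
  list(Q2Y = 1 - press / ss_tot, PRESS = press, ss_tot = ss_tot, fold = fold)
}

#' Fit an OPLS-DA model (two classes)
#'
#' Orthogonal projections to latent structures: variation in X that is
#' orthogonal to the class response is split off into `n_orth` orthogonal
#' components (weights built from the part of the X-loading orthogonal to
#' the predictive weight); X is deflated by them and a single predictive
#' PLS component is fitted on the filtered matrix. With no structured
#' orthogonal variation the predictive component equals the 1-component
#' PLS solution.
#'
#' @param X Autoscaled matrix.
#' @param y Labels with exactly 2 classes (use [plsda_fit()] otherwise).
#' @param n_orth Number of orthogonal components (default 1).
#' @return Object of class `oplsda_model` (inherits `plsda_model`
#'   prediction machinery via its own `predict` method).
#' @export
oplsda_fit <- function(X, y, n_orth = 1) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2)
    stop("OPLS-DA requires exactly 2 classes; use plsda_fit for more")
  u <- as.numeric(y == classes[2])
  u_mean <- mean(u)
  uc <- u - u_mean
  ss_y <- sum(uc^2)
  Xd <- X
  Wo <- NULL; To <- NULL; Po <- NULL
  w <- as.numeric(crossprod(Xd, uc)); w <- w / sqrt(sum(w^2))
  for (a in seq_len(n_orth)) {
    tt <- as.numeric(Xd %*% w)
    pload <- as.numeric(crossprod(Xd, tt)) / sum(tt^2)
    w_o <- pload - as.numeric(crossprod(w, pload)) * w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) break   # no orthogonal variation left
    w_o <- w_o / nrm
    t_o <- as.numeric(Xd %*% w_o)
    p_o <- as.numeric(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    Wo <- cbind(Wo, w_o); To <- cbind(To, t_o); Po <- cbind(Po, p_o)
    w <- as.numeric(crossprod(Xd, uc)); w <- w / sqrt(sum(w^2))
  }
  t_p <- as.numeric(Xd %*% w)
  p_p <- as.numeric(crossprod(Xd, t_p)) / sum(t_p^2)
  q <- sum(uc * t_p) / sum(t_p^2)
  resid <- uc - t_p * q
  structure(list(
    classes = classes, w_pred = w, t_pred = t_p, p_pred = p_p, q = q,
    W_orth = Wo, T_orth = To, P_orth = Po,
    n_orth = if (is.null(To)) 0L else ncol(To),
    u_mean = u_mean, R2Y = 1 - sum(resid^2) / ss_y,
    x_var_total = sum(X^2),
    x_var_pred = sum(t_p^2) * sum(p_p^2),
    x_var_orth = if (is.null(To)) 0 else sum(colSums(To^2) * colSums(Po^2)),
    x_var_resid = sum((Xd - tcrossprod(t_p, p_p))^2)
  ), class = "oplsda_model")
}

#' Predict from an OPLS-DA model
#'
#' New spectra are first deflated by the orthogonal components, then
#' scored on the predictive component.
#'
#' @param object An [oplsda_fit()] result.
#' @param newdata Matrix on the same variables (same scaling).
#' @param ... Unused.
#' @return List with `labels`, `yhat` (two uncentered dummy columns, for
#'   symmetry with [predict.plsda_model()]), `t_pred` and `t_orth` scores.
#' @export
predict.oplsda_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  t_orth <- NULL
  if (object$n_orth > 0) {
    t_orth <- matrix(0, nrow(X), object$n_orth)
    for (a in seq_len(object$n_orth)) {
      t_orth[, a] <- X %*% object$W_orth[, a]
      X <- X - tcrossprod(t_orth[, a], object$P_orth[, a])
    }
  }
  t_p <- as.numeric(X %*% object$w_pred)
  uhat <- t_p * object$q + object$u_mean
  yhat <- cbind(1 - uhat, uhat)
  colnames(yhat) <- object$classes
  list(labels = object$classes[1 + (uhat >= 0.5)], yhat = yhat,
       t_pred = t_p, t_orth = t_orth)
}

#' Permutation test of PLS/OPLS class models
#'
#' The class labels are permuted `n_perm` times; for each permutation the
#' model is refitted and R2Y and cross-validated Q2Y recomputed. P-values
#' are `(1 + #{perm >= observed}) / (1 + n_perm)`.
#'
#' @param X Raw (pre-autoscaling) matrix.
#' @param y Class labels.
#' @param n_perm Number of permutations (default 999; < 19 draws a
#'   resolution warning).
#' @param seed Seed for permutations and fold assignment.
#' @param fit_fun `"plsda"` or `"oplsda"`.
#' @param n_comp,n_orth,folds Passed through to the fits.
#' @return List with observed `R2Y`, `Q2Y` and `p_R2Y`, `p_Q2Y`.
#' @export
permutation_test <- function(X, y, n_perm = 999, seed = 1,
                             fit_fun = c("oplsda", "plsda"),
                             n_comp = 2, n_orth = 1, folds = 5) {
  fit_fun <- match.arg(fit_fun)
  if (n_perm < 19) warning("n_perm < 19 gives poor p-value resolution")
  X <- as.matrix(X); y <- as.character(y)
  fit_r2 <- function(yy, s) {
    mu <- colMeans(X); sdv <- col_sds(X); sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    m <- if (fit_fun == "plsda") plsda_fit(Xs, yy, n_comp)
         else oplsda_fit(Xs, yy, n_orth)
    q2 <- q2_crossval(X, yy, n_comp = n_comp, folds = folds, seed = s,
                      fit_fun = fit_fun, n_orth = n_orth)$Q2Y
    c(m$R2Y, q2)
  }
  obs <- fit_r2(y, seed)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  perm <- matrix(0, n_perm, 2)
  for (b in seq_len(n_perm)) {
    yp <- sample(y)
    perm[b, ] <- fit_r2(yp, seed + b)
  }
  list(R2Y = obs[1], Q2Y = obs[2],
       p_R2Y = (1 + sum(perm[, 1] >= obs[1])) / (1 + n_perm),
       p_Q2Y = (1 + sum(perm[, 2] >= obs[2])) / (1 + n_perm))
}

#' Cross-validated-residual ANOVA (approximate)
#'
#' A simple F-form diagnostic comparing cross-validated residuals with
#' the total response variation:
#' `F = ((SS_tot - PRESS) / d1) / (PRESS / d2)` with `d1` = number of
#' model components and `d2 = n - d1 - 1` (a pragmatic degrees-of-freedom
#' convention; the p-value is labelled approximate). `PRESS >= SS_tot`
#' yields F <= 0 with p = 1.
#'
#' @param press Cross-validated PRESS.
#' @param ss_tot Total (centered) response sum of squares.
#' @param n Number of samples.
#' @param d1 Model degrees of freedom (component count).
#' @return List with `F`, `p`, `d1`, `d2`.
#' @export
cv_anova <- function(press, ss_tot, n, d1 = 1) {
  d2 <- n - d1 - 1
  if (d2 <= 0) stop("not enough samples for the residual dof")
  if (press >= ss_tot)
    return(list(F = (ss_tot - press) / d1 / (press / d2), p = 1,
                d1 = d1, d2 = d2))
  Fv <- ((ss_tot - press) / d1) / (press / d2)
  list(F = Fv, p = stats::pf(Fv, d1, d2, lower.tail = FALSE), d1 = d1, d2 = d2)
}
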