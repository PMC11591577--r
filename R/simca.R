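#' Fit a SIMCA class model
#'
#' Class-centered principal-component model of one class: the first `A`
#' PCA loadings plus residual dispersions. The per-variable residual sd
#' uses `n - A - 1` degrees of freedom, and the pooled class residual sd
#' is `s0 = sqrt(sum(E^2) / ((p - A) (n - A - 1)))`. With `A = 0` the
#' model collapses to the class centroid and `s0` to the pooled variable
#' sd about it.
#'
#' @param X_class Training matrix of one class (n x p).
#' @param A Number of principal components, `0 <= A`, `n > A + 1`,
#'   `A <= rank(X_centered)` when `A > 0`.
#' @param label Class label carried in reports.
#' @return Object of class `simca_model`.
#' @export
simca_fit <- function(X_class, A, label = "class") {
  X_class <- as.matrix(X_class)
  n <- nrow(X_class); p <- ncol(X_class)
  if (n <= A + 1) stop("need n_class > A + 1")
  mu <- colMeans(X_class)
  Xc <- sweep(X_class, 2, mu)
  if (A > 0) {
    sv <- svd(Xc)
    rank <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1])
    if (A > rank)
      stop("A = ", A, " > rank(", rank, ") of the centered class matrix")
    P <- sv$v[, seq_len(A), drop = FALSE]
    T <- Xc %*% P
    E <- Xc - T %*% t(P)
  } else {
    P <- matrix(0, p, 0)
    E <- Xc
  }
  sd_var <- sqrt(colSums(E^2) / (n - A - 1))
  s0 <- sqrt(sum(E^2) / ((p - A) * (n - A - 1)))
  structure(list(label = label, mean = mu, loadings = P, A = A,
                 n = n, p = p, s0 = s0, sd_var = sd_var,
                 residuals = E),
            class = "simca_model")
}

#' Distance of an object from a SIMCA class model
#'
#' Projects `x` onto the model plane and returns the residual standard
#' deviation `s_i = sqrt(sum(e^2) / (p - A))` and the variance ratio
#' `F_i = s_i^2 / s0^2` used for the membership F-test.
#'
#' @param model A [simca_fit()] result.
#' @param x Numeric vector (or matrix of rows) on the model's variables.
#' @return data.frame with columns `s` and `F`, one row per object.
#' @export
object_distance <- function(model, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != model$p) stop("variable count mismatch")
  Xc <- sweep(x, 2, model$mean)
  E <- if (model$A > 0) Xc - (Xc %*% model$loadings) %*% t(model$loadings) else Xc
  s <- sqrt(rowSums(E^2) / (model$p - model$A))
  # residuals at numerical-noise level count as in-plane (F = 0); a
  # degenerate model (s0 = 0) rejects everything else outright
  tiny <- s <= 1e-10 * sqrt(model$p)
  Fv <- if (model$s0 > 0) s^2 / model$s0^2 else ifelse(tiny, 0, Inf)
  Fv[tiny] <- 0
  data.frame(s = s, F = Fv)
}

# Critical F value of a class model at 1 - alpha, classic SIMCA dof.
simca_fcrit <- function(model, alpha = 0.05) {
  d1 <- model$p - model$A
  d2 <- (model$n - model$A - 1) * (model$p - model$A)
  stats::qf(1 - alpha, d1, d2)
}

#' SIMCA open and forced classification
#'
#' Open (soft) classification accepts object `x` in class `g` iff
#' `F_i < F_crit(p - A_g, (n_g - A_g - 1)(p - A_g))` at level `1 - alpha`;
#' an object may belong to several classes or to none. Forced
#' classification always assigns to the class minimizing `F_i / F_crit`
#' (exact ties to the first model in list order).
#'
#' @param models Named list of [simca_fit()] models (same variables).
#' @param X Matrix of objects to classify.
#' @param alpha Significance level of the membership F-test.
#' @return List: `open` (logical n x G membership matrix), `forced`
#'   (character labels), `ratio` (F/F_crit matrix).
#' @export
simca_classify <- function(models, X, alpha = 0.05) {
  if (!length(models)) stop("need at least one class model")
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  labs <- vapply(models, function(m) m$label, character(1))
  ratio <- vapply(models, function(m) {
    object_distance(m, X)$F / simca_fcrit(m, alpha)
  }, numeric(nrow(X)))
  ratio <- matrix(ratio, nrow = nrow(X), dimnames = list(NULL, labs))
  Fm <- vapply(models, function(m) object_distance(m, X)$F, numeric(nrow(X)))
  Fm <- matrix(Fm, nrow = nrow(X), dimnames = list(NULL, labs))
  crit <- vapply(models, simca_fcrit, numeric(1), alpha = alpha)
  open <- sweep(Fm, 2, crit, "<")
  forced <- unname(labs[apply(ratio, 1, which.min)])
  list(open = open, forced = forced, ratio = ratio, F = Fm, F_crit = crit)
}

#' Modelling power of each variable
#'
#' `MP_j = 1 - sd_resid_j / sd_raw_j` with `sd_raw_j` the class-centered
#' sd of variable j, clipped to [0, 1]. Values near 1 mean the variable
#' is well described by the class components; `A = 0` gives MP = 0.
#' Variables with zero raw sd are undefined (NA, with a warning).
#'
#' @param model A [simca_fit()] result.
#' @param X_class Its training block.
#' @return Numeric vector of MP values in [0, 1] (or NA).
#' @export
modeling_power <- function(model, X_class) {
  X_class <- as.matrix(X_class)
  Xc <- sweep(X_class, 2, model$mean)
  sd_raw <- sqrt(colSums(Xc^2) / (nrow(X_class) - 1))
  mp <- rep(NA_real_, model$p)
  bad <- sd_raw == 0
  if (any(bad)) warning(sum(bad), " zero-variance variable(s): MP undefined")
  mp[!bad] <- pmin(pmax(1 - model$sd_var[!bad] / sd_raw[!bad], 0), 1)
  mp
}

#' Discriminant power of each variable between two class models
#'
#' `DP_j = sqrt((S2_j(A->B) + S2_j(B->A)) / (S2_j(A->A) + S2_j(B->B)))`
#' where `S2_j(q->r)` is the mean squared residual of variable j when
#' class-q objects are projected onto the class-r model (mean over
#' objects, so unbalanced classes do not bias the ratio). DP near 1
#' means the variable does not discriminate; large DP means the classes
#' disagree strongly on it.
#'
#' @param mA,mB Fitted [simca_fit()] models.
#' @param XA,XB The corresponding training blocks.
#' @return Numeric vector of DP values (>= 0; `Inf` sentinel if both
#'   own-class residuals vanish while cross-class residuals do not).
#' @export
discriminant_power <- function(mA, mB, XA, XB) {
  msr <- function(model, X) {  # per-variable mean squared projection residual
    X <- as.matrix(X)
    Xc <- sweep(X, 2, model$mean)
    E <- if (model$A > 0) Xc - (Xc %*% model$loadings) %*% t(model$loadings) else Xc
    colMeans(E^2)
  }
  num <- msr(mB, XA) + msr(mA, XB)
  den <- msr(mA, XA) + msr(mB, XB)
  dp <- rep(Inf, length(num))
  ok <- den > 0
  if (!all(ok)) warning(sum(!ok), " variable(s) with zero own-class residual; DP sentinel Inf")
  dp[ok] <- sqrt(num[ok] / den[ok])
  dp
}

# Leave-one-out PRESS choice of the SIMCA component count for one class.
# For each candidate A, each object is projected onto the model fitted
# without it; A minimizing the total squared residual wins. Capped (3 by
# default) because small class sizes do not support deep models.
choose_simca_ncomp <- function(X_class, a_max = 3) {
  X_class <- as.matrix(X_class)
  n <- nrow(X_class); p <- ncol(X_class)
  a_max <- min(a_max, n - 3, p - 1)
  if (a_max < 1) return(0L)
  press <- vapply(0:a_max, function(A) {
    tot <- 0
    for (i in seq_len(n)) {
      m <- simca_fit(X_class[-i, , drop = FALSE], A)
      Xc <- X_class[i, ] - m$mean
      e <- if (A > 0) Xc - as.numeric((Xc %*% m$loadings) %*% t(m$loadings)) else Xc
      tot <- tot + sum(e^2)
    }
    tot
  }, numeric(1))
  as.integer(which.min(press) - 1L)
}

#' Full SIMCA analysis of a training/test pair
#'
#' Fits one class model per group (component count per class by
#' leave-one-out PRESS, capped), classifies the training set in
#' resubstitution and leave-one-out mode and the external test set, and
#' tabulates per-class rates, efficiencies, and the per-variable
#' modelling/discriminant power table.
#'
#' Reported columns: `classification` (% of class-g training objects
#' forced-assigned to g), `internal_prediction` (the same under LOO),
#' `external_prediction` (test objects), `efficiency` (geometric mean of
#' the class model's open-classification sensitivity and specificity on
#' the training set) and `efficiency_forced` (same under forced
#' assignment).
#'
#' @param train,test [spectra_set()]s on the selected variables (already
#'   autoscaled); `test` may be NULL.
#' @param alpha Membership F-test level.
#' @param a_max Cap on per-class component count.
#' @param A_override Optional named vector forcing component counts.
#' @return Object of class `simca_report` with `$rates`, `$power`
#'   (DP + per-class MP, sorted by descending DP), `$models`.
#' @export
simca_analysis <- function(train, test = NULL, alpha = 0.05, a_max = 3,
                           A_override = NULL) {
  stopifnot(inherits(train, "spectra_set"))
  X <- train$absorbance; y <- train$group
  classes <- sort(unique(y))
  models <- lapply(classes, function(g) {
    Xg <- X[y == g, , drop = FALSE]
    A <- if (!is.null(A_override) && g %in% names(A_override))
      A_override[[g]] else choose_simca_ncomp(Xg, a_max)
    simca_fit(Xg, A, label = g)
  })
  names(models) <- classes

  cls_resub <- simca_classify(models, X, alpha)
  # LOO: refit the left-out object's own class model without it
  forced_loo <- character(nrow(X))
  open_loo <- matrix(NA, nrow(X), length(classes), dimnames = list(NULL, classes))
  for (i in seq_len(nrow(X))) {
    g <- y[i]
    Xg <- X[y == g & seq_along(y) != i, , drop = FALSE]
    A <- min(models[[g]]$A, nrow(Xg) - 2)
    mods_i <- models
    mods_i[[g]] <- simca_fit(Xg, max(A, 0), label = g)
    ci <- simca_classify(mods_i, X[i, , drop = FALSE], alpha)
    forced_loo[i] <- ci$forced
    open_loo[i, ] <- ci$open
  }
  conf_resub <- table(true = factor(y, classes),
                      predicted = factor(cls_resub$forced, classes))
  conf_loo <- table(true = factor(y, classes),
                    predicted = factor(forced_loo, classes))
  conf_ext <- NULL
  if (!is.null(test)) {
    ce <- simca_classify(models, test$absorbance, alpha)
    conf_ext <- table(true = factor(test$group, classes),
                      predicted = factor(ce$forced, classes))
  }

  eff <- vapply(classes, function(g) {
    inx <- y == g
    sens_open <- mean(cls_resub$open[inx, g])
    spec_open <- mean(!cls_resub$open[!inx, g])
    sens_forc <- mean(cls_resub$forced[inx] == g)
    spec_forc <- mean(cls_resub$forced[!inx] != g)
    c(efficiency = 100 * sqrt(sens_open * spec_open),
      efficiency_forced = 100 * sqrt(sens_forc * spec_forc))
  }, numeric(2))

  rate <- function(conf) if (is.null(conf)) rep(NA_real_, length(classes)) else
    100 * diag(as.matrix(conf)) / pmax(rowSums(conf), 1)
  rates <- data.frame(
    group = classes,
    classification = rate(conf_resub),
    internal_prediction = rate(conf_loo),
    external_prediction = rate(conf_ext),
    efficiency = eff["efficiency", ],
    efficiency_forced = eff["efficiency_forced", ],
    row.names = NULL
  )

  mp <- vapply(classes, function(g)
    modeling_power(models[[g]], X[y == g, , drop = FALSE]),
    numeric(ncol(X)))
  mp <- matrix(mp, ncol = length(classes),
               dimnames = list(NULL, paste0("MP_", classes)))
  dp <- if (length(classes) == 2)
    discriminant_power(models[[1]], models[[2]],
                       X[y == classes[1], , drop = FALSE],
                       X[y == classes[2], , drop = FALSE])
  else rep(NA_real_, ncol(X))
  power <- data.frame(wavenumber = train$wavenumbers, DP = dp, mp,
                      check.names = FALSE)
  if (!all(is.na(dp))) power <- power[order(-power$DP), , drop = FALSE]
  rownames(power) <- NULL

  structure(list(rates = rates, power = power, models = models,
                 confusion = list(resub = conf_resub, loo = conf_loo,
                                  external = conf_ext),
                 alpha = alpha),
            class = "simca_report")
}

#' @export
print.simca_report <- function(x, ...) {
  cat("<simca_report> forced-assignment rates (%):\n")
  tab <- x$rates
  tab[-1] <- lapply(tab[-1], function(v) round(v, 2))
  print(tab, row.names = FALSE)
  cat("top variables by discriminant power:\n")
  print(utils::head(within(x$power, {
    DP <- signif(DP, 3)
  }), 5), row.names = FALSE)
  invisible(x)
}
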