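#' Linear discriminant analysis with pooled covariance and equal priors
#'
#' Classifies by minimum Mahalanobis distance to the class means under
#' the pooled within-class covariance, with equal class priors (the
#' symmetric per-class reporting convention of chemometric class
#' discrimination). Canonical variates (eigenvectors of W^-1 B) are kept
#' for score plots and histograms. If the pooled covariance is
#' numerically singular a ridge of `1e-8 * trace/p` is added and noted.
#'
#' @param X Numeric matrix on the selected variables (samples x p).
#' @param y Class labels.
#' @return An object of class `lda_model`.
#' @export
lda_fit <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  G <- length(classes)
  n <- nrow(X); p <- ncol(X)
  if (n <= G) stop("fewer samples than classes + 1")
  means <- matrix(0, G, p, dimnames = list(classes, NULL))
  for (g in classes) means[g, ] <- colMeans(X[y == g, , drop = FALSE])
  W <- matrix(0, p, p)
  for (g in classes) {
    Xg <- X[y == g, , drop = FALSE]
    Xc <- sweep(Xg, 2, colMeans(Xg))
    W <- W + crossprod(Xc)
  }
  W <- W / (n - G)
  ridged <- FALSE
  Winv <- tryCatch(solve(W), error = function(e) NULL)
  if (is.null(Winv) || !is.finite(rcond(W)) || rcond(W) < 1e-12) {
    W <- W + diag(1e-8 * sum(diag(W)) / p, p)
    Winv <- solve(W)
    ridged <- TRUE
  }
  grand <- colMeans(X)
  B <- matrix(0, p, p)
  for (g in classes) {
    d <- means[g, ] - grand
    B <- B + sum(y == g) * tcrossprod(d)
  }
  B <- B / max(G - 1, 1)
  ev <- eigen(Winv %*% B)
  ncv <- min(G - 1, p)
  basis <- Re(ev$vectors[, seq_len(ncv), drop = FALSE])
  structure(list(classes = classes, means = means, cov = W, cov_inv = Winv,
                 canonical = basis, ridged = ridged, p = p),
            class = "lda_model")
}

#' Predict class labels and canonical scores
#'
#' Assigns each row to the class minimizing Mahalanobis distance; exact
#' distance ties go to the first class in label order.
#'
#' @param model An [lda_fit()] result.
#' @param X Matrix on the same variables.
#' @return List with `labels` (character) and `scores`
#'   (canonical-variate projections, n x min(G-1, p)).
#' @export
lda_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$p) stop("variable count mismatch")
  D <- vapply(seq_along(model$classes), function(g) {
    d <- sweep(X, 2, model$means[g, ])
    rowSums((d %*% model$cov_inv) * d)
  }, numeric(nrow(X)))
  D <- matrix(D, nrow = nrow(X))
  labels <- model$classes[apply(D, 1, which.min)]  # which.min: first on ties
  list(labels = labels, scores = X %*% model$canonical, mahalanobis2 = D)
}

#' Leave-one-out cross-validation of LDA
#'
#' Each sample is predicted by an LDA model fitted on the remaining n-1
#' samples. Variable selection is NOT re-run inside the loop: the
#' cross-validation evaluates the discriminant rule on the fixed variable
#' subset, which matches the workflow sequence (SELECT first, LOO-LDA
#' after) and carries that procedure's optimistic selection bias.
#'
#' @param X Matrix on the selected variables.
#' @param y Class labels.
#' @return A confusion matrix (true x predicted).
#' @export
loo_crossval <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (nrow(X) < length(classes) + 1) stop("too few samples for LOO")
  pred <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    yi <- y[-i]
    if (length(unique(yi)) < length(classes))
      stop("leaving out sample ", i, " empties a class")
    m <- lda_fit(X[-i, , drop = FALSE], yi)
    pred[i] <- lda_predict(m, X[i, , drop = FALSE])$labels
  }
  table(true = factor(y, classes), predicted = factor(pred, classes))
}

#' Nested leave-one-out: selection re-run inside every fold
#'
#' The unbiased counterpart of [loo_crossval()]: for each held-out
#' sample, the autoscaler is refitted, SELECT is re-run and the LDA model
#' is fitted on the remaining n-1 samples only. This removes the
#' selection-induced optimism of the fixed-subset procedure (which on
#' pure-noise data with many variables can report near-perfect LOO rates)
#' and is the honest estimate of generalization error; on data with no
#' class structure it stays at chance level.
#'
#' @param X Raw or preprocessed (pre-autoscaling) matrix.
#' @param y Class labels.
#' @param k Variables retained by SELECT in each fold.
#' @param wavenumbers Optional column labels.
#' @return A confusion matrix (true x predicted).
#' @export
nested_loo_select_lda <- function(X, y, k, wavenumbers = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  pred <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    if (length(unique(yi)) < length(classes))
      stop("leaving out sample ", i, " empties a class")
    mu <- colMeans(Xi); sdv <- col_sds(Xi); sdv[sdv == 0] <- 1
    Zi <- sweep(sweep(Xi, 2, mu), 2, sdv, "/")
    sel <- select_decorrelate(Zi, yi, k, wavenumbers)
    m <- lda_fit(Zi[, sel$indices, drop = FALSE], yi)
    zi <- (X[i, ] - mu) / sdv
    pred[i] <- lda_predict(m, matrix(zi[sel$indices], 1))$labels
  }
  table(true = factor(y, classes), predicted = factor(pred, classes))
}

#' Build a classification report from confusion matrices
#'
#' Mirrors the standard chemometrics reporting table: per-class percent
#' correct and the total rate (sample-weighted mean of per-class rates,
#' i.e. overall accuracy) for resubstitution ("classification"), internal
#' cross-validation ("prediction"), and external test ("external"), as
#' available.
#'
#' @param resub,cv,external Confusion matrices (true x predicted); any
#'   may be NULL.
#' @return Object of class `classification_report` with `$table`
#'   (data.frame, rows = classes + "Total"), and the confusions.
#' @export
classification_report <- function(resub = NULL, cv = NULL, external = NULL) {
  mats <- list(classification = resub, prediction = cv, external = external)
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (!length(mats)) stop("at least one confusion matrix required")
  classes <- rownames(mats[[1]])
  per <- lapply(mats, function(m) {
    stopifnot(identical(rownames(m), classes))
    n <- rowSums(m)
    rate <- ifelse(n > 0, 100 * diag(as.matrix(m)) / n, NA_real_)
    total <- 100 * sum(diag(as.matrix(m))) / sum(m)
    # total rate must equal the sample-weighted mean of per-class rates
    stopifnot(isTRUE(all.equal(total,
      sum(rate * n, na.rm = TRUE) / sum(n[!is.na(rate)]))))
    c(rate, Total = total)
  })
  tab <- data.frame(group = c(classes, "Total"), per, check.names = FALSE)
  structure(list(table = tab, confusion = mats), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> (% correct)\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) round(v, 2))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Stratified train/test split
#'
#' Randomly withdraws the requested number of samples per class into an
#' external test set, deterministically under the seed.
#'
#' @param s A [spectra_set()].
#' @param per_class Named integer vector: test-set size per class. Classes
#'   absent from `per_class` contribute no test samples.
#' @param seed Integer seed.
#' @return List with `train` and `test` spectra_sets (disjoint).
#' @export
split_train_test <- function(s, per_class, seed) {
  stopifnot(inherits(s, "spectra_set"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  test_idx <- integer(0)
  for (g in names(per_class)) {
    idx <- which(s$group == g)
    if (per_class[[g]] > length(idx))
      stop("requested ", per_class[[g]], " test samples from class ", g,
           " which has only ", length(idx))
    test_idx <- c(test_idx, sort(sample(idx, per_class[[g]])))
  }
  train_idx <- setdiff(seq_along(s$sample_id), test_idx)
  list(train = subset_samples(s, train_idx),
       test  = subset_samples(s, sort(test_idx)))
}
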