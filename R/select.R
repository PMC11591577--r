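#' Per-variable Fisher weight
#'
#' Ratio of between-class to within-class variance per column:
#' between = sum_g n_g (mean_gj - mean_j)^2 / (G - 1); within = pooled
#' variance with n - G degrees of freedom. Columns separating the classes
#' perfectly (zero within-variance, nonzero between) map to a large
#' finite sentinel (`1e12`) so argmax stays well defined.
#'
#' @param X Numeric matrix (samples x variables), typically autoscaled.
#' @param y Class labels; at least 2 classes with >= 2 samples each.
#' @return Numeric vector of weights, one per column.
#' @export
fisher_weight <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- unique(y)
  G <- length(classes)
  if (G < 2) stop("need at least 2 classes")
  ng <- table(y)
  if (any(ng < 2)) stop("each class needs >= 2 samples")
  n <- nrow(X)
  grand <- colMeans(X)
  between <- numeric(ncol(X))
  within_ss <- numeric(ncol(X))
  for (g in classes) {
    Xg <- X[y == g, , drop = FALSE]
    mg <- colMeans(Xg)
    between <- between + nrow(Xg) * (mg - grand)^2
    within_ss <- within_ss + colSums(sweep(Xg, 2, mg)^2)
  }
  between <- between / (G - 1)
  within <- within_ss / (n - G)
  w <- ifelse(within > 0, between / within,
              ifelse(between > 0, 1e12, 0))
  as.numeric(w)
}

#' Cap on retained variables (3:1 sample/variable rule)
#'
#' The number of training samples should be at least three times the
#' number of variables retained by stepwise selection, i.e. at most
#' `floor(n_train / 3)` variables.
#'
#' @param n_train Number of training samples (>= 3).
#' @return Integer bound.
#' @export
max_variables_rule <- function(n_train) {
  if (n_train < 3) stop("need at least 3 training samples")
  as.integer(floor(n_train / 3))
}

#' SELECT: stepwise-orthogonalization variable selection
#'
#' Iteratively (1) scores every current column by [fisher_weight()],
#' (2) picks the argmax (ties broken toward the lower column index), and
#' (3) projects every remaining column onto the orthogonal complement of
#' the picked column, removing the information it shares with the pick.
#' Redundant copies of an already-selected variable are thereby never
#' re-selected. Stops early with a warning if the best remaining column
#' has (numerically) zero norm.
#'
#' @param X Autoscaled matrix (samples x variables).
#' @param y Class labels.
#' @param k Number of variables to retain; must respect
#'   [max_variables_rule()] for `nrow(X)`.
#' @param wavenumbers Optional column labels (cm-1); defaults to indices.
#' @return A list of class `selection_result`: `selected` (wavenumbers in
#'   pick order), `weights` (Fisher weight of each pick at pick time),
#'   `indices`, `deco_matrix` (the decorrelated design matrix), and
#'   `k_max_rule`.
#' @export
select_decorrelate <- function(X, y, k, wavenumbers = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  kmax <- max_variables_rule(n)
  if (k > kmax)
    stop("k = ", k, " violates the 3:1 sample/variable rule (max ", kmax, ")")
  if (k < 1 || k > p) stop("k must be in [1, ncol(X)]")
  if (is.null(wavenumbers)) wavenumbers <- seq_len(p)
  Z <- X
  picked <- integer(0)
  weights <- numeric(0)
  for (step in seq_len(k)) {
    w <- fisher_weight(Z, y)
    w[picked] <- -Inf
    # degenerate residual columns cannot be picked
    norms <- sqrt(colSums(Z^2))
    w[norms < 1e-10 * sqrt(n)] <- -Inf
    if (all(!is.finite(w) | w == -Inf)) {
      warning("SELECT stopped early after ", length(picked),
              " picks: remaining columns are degenerate")
      break
    }
    j <- which.max(w)   # which.max takes the first (lowest index) on ties
    picked <- c(picked, j)
    weights <- c(weights, w[j])
    zj <- Z[, j]
    denom <- sum(zj^2)
    if (denom < 1e-20) {
      warning("SELECT stopped early: picked column has zero norm")
      picked <- picked[-length(picked)]
      weights <- weights[-length(weights)]
      break
    }
    proj <- as.numeric(crossprod(Z, zj)) / denom
    Z <- Z - outer(zj, proj)
    Z[, picked] <- X[, picked]   # keep picked columns intact for reporting
  }
  structure(list(
    selected = wavenumbers[picked],
    indices = picked,
    weights = weights,
    deco_matrix = Z,
    k_max_rule = kmax
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", length(x$selected), " variables (cap ",
      x$k_max_rule, "):\n", sep = "")
  print(data.frame(wavenumber = x$selected, weight = signif(x$weights, 4)))
  invisible(x)
}
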