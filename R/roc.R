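#' Rank-based AUC with Mann-Whitney p-value
#'
#' `AUC = U / (n1 n2)` with ties counted one half: the probability that a
#' random positive scores above a random negative (plus half the tie
#' probability), for the "positive-if-high" orientation. The two-sided
#' p-value uses exact enumeration (via the Wilcoxon distribution) when
#' `n1 * n2 <= 400` and there are no ties, and the tie-corrected normal
#' approximation otherwise.
#'
#' @param values Numeric scores.
#' @param labels Logical or two-level vector; `positive` marks the
#'   positive class.
#' @param positive Value of `labels` treated as positive (default TRUE
#'   for logical labels, else the last sorted level).
#' @return List with `auc`, `p`, `n_pos`, `n_neg`.
#' @export
auc_mann_whitney <- function(values, labels, positive = NULL) {
  pos <- resolve_positive(labels, positive)
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) stop("both classes must be present")
  r <- rank(values)
  U <- sum(r[pos]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n2)
  ties <- table(values)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 * n2 <= 400) {
    p <- stats::wilcox.test(values[pos], values[!pos], exact = TRUE)$p.value
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(auc = auc, p = 1, n_pos = n1, n_neg = n2))
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc = auc, p = min(p, 1), n_pos = n1, n_neg = n2)
}

resolve_positive <- function(labels, positive) {
  if (is.logical(labels) && is.null(positive)) return(labels)
  if (is.null(positive)) {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2) stop("labels must have exactly 2 levels")
    positive <- lv[2]
  }
  as.character(labels) == as.character(positive)
}

#' ROC curve for a single-variable diagnostic
#'
#' Sweeps cut points placed at midpoints between adjacent sorted unique
#' values (plus -Inf/+Inf), computing sensitivity and specificity at each
#' cut. The direction is `"positive-if-low"` (test positive when value
#' <= cut; the natural reading for second-derivative band intensities,
#' where a stronger band is a more negative excursion) or
#' `"positive-if-high"`; `"auto"` picks the orientation with AUC >= 0.5
#' and reports it explicitly.
#'
#' @param values Per-sample scalar (e.g. one wavenumber's intensity).
#' @param labels Binary class labels.
#' @param positive Which label is the positive (diseased) class.
#' @param direction `"auto"`, `"positive-if-low"` or `"positive-if-high"`.
#' @return Object of class `roc_result`: `$curve` (data.frame cut /
#'   sensitivity / specificity), `$auc`, `$p`, `$direction`, and the
#'   Youden fields `$youden_cut`, `$sensitivity`, `$specificity`, `$J`.
#' @export
roc_curve <- function(values, labels, positive = NULL,
                      direction = c("auto", "positive-if-low",
                                    "positive-if-high")) {
  direction <- match.arg(direction)
  pos <- resolve_positive(labels, positive)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  mw_high <- auc_mann_whitney(values, pos)
  if (direction == "auto")
    direction <- if (mw_high$auc >= 0.5) "positive-if-high" else "positive-if-low"
  auc <- if (direction == "positive-if-high") mw_high$auc else 1 - mw_high$auc
  uv <- sort(unique(values))
  cuts <- c(-Inf, if (length(uv) > 1) (uv[-1] + uv[-length(uv)]) / 2, Inf)
  sens <- spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    test_pos <- if (direction == "positive-if-low") values <= cuts[i]
                else values >= cuts[i]
    sens[i] <- mean(test_pos[pos])
    spec[i] <- mean(!test_pos[!pos])
  }
  curve <- data.frame(cut = cuts, sensitivity = sens, specificity = spec)
  res <- structure(list(curve = curve, auc = auc, p = mw_high$p,
                        direction = direction,
                        n_pos = mw_high$n_pos, n_neg = mw_high$n_neg),
                   class = "roc_result")
  yj <- youden_cut(res)
  res$youden_cut <- yj$cut
  res$sensitivity <- yj$sensitivity
  res$specificity <- yj$specificity
  res$J <- yj$J
  res
}

#' Youden-index optimal cut point
#'
#' Maximizes `J = sensitivity + specificity - 1` over the computed cuts.
#' Ties are broken toward the cut with higher sensitivity, then the lower
#' cut value.
#'
#' @param r A [roc_curve()] result (the Youden fields need not be set).
#' @return List with `cut`, `sensitivity`, `specificity`, `J` and the
#'   rule direction.
#' @export
youden_cut <- function(r) {
  stopifnot(inherits(r, "roc_result"))
  cv <- r$curve
  J <- cv$sensitivity + cv$specificity - 1
  best <- which(J >= max(J) - 1e-12)
  if (length(best) > 1) {
    best <- best[order(-cv$sensitivity[best], cv$cut[best])]
  }
  b <- best[1]
  list(cut = cv$cut[b], sensitivity = cv$sensitivity[b],
       specificity = cv$specificity[b], J = J[b], direction = r$direction)
}

#' @export
print.roc_result <- function(x, ...) {
  rule <- if (x$direction == "positive-if-low") "<=" else ">="
  cat(sprintf("<roc_result> AUC = %.3f (p = %.2g), n = %d/%d\n",
              x$auc, x$p, x$n_pos, x$n_neg))
  cat(sprintf("Youden cut: %s %.4g  (sens %.1f%%, spec %.1f%%, J = %.3f)\n",
              rule, x$youden_cut, 100 * x$sensitivity,
              100 * x$specificity, x$J))
  invisible(x)
}
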