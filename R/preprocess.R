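#' Preprocessing configuration
#'
#' Parameters of the spectral conditioning chain applied before any
#' multivariate modelling: crop to the fingerprint region, per-spectrum
#' normalization, moving-average smoothing, and an 11-point
#' Savitzky-Golay second derivative. Autoscaling is handled separately
#' (fitted on training data only, see [fit_scaler()]).
#'
#' @param region `c(lo, hi)` in cm-1, closed interval (default 1000-1500).
#' @param normalization One of `"vector"` (unit Euclidean norm, default),
#'   `"snv"` (standard normal variate) or `"none"`.
#' @param ma_window Odd moving-average window in points (default 5; 1 = off).
#' @param sg_window Odd Savitzky-Golay window in points (default 11).
#' @param sg_polyorder Polynomial order of the S-G fit (default 3).
#' @param derivative_order Derivative order (default 2; 0 skips the filter).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(region = c(1000, 1500),
                              normalization = c("vector", "snv", "none"),
                              ma_window = 5L,
                              sg_window = 11L,
                              sg_polyorder = 3L,
                              derivative_order = 2L) {
  normalization <- match.arg(normalization)
  if (region[1] >= region[2]) stop("region must satisfy lo < hi")
  if (ma_window %% 2 == 0) stop("ma_window must be odd")
  if (sg_window %% 2 == 0) stop("sg_window must be odd")
  if (derivative_order > 0 && sg_window <= sg_polyorder)
    stop("sg_window must exceed sg_polyorder")
  structure(list(region = region, normalization = normalization,
                 ma_window = as.integer(ma_window),
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 derivative_order = as.integer(derivative_order)),
            class = "preprocess_config")
}

#' Crop a spectra_set to a wavenumber region
#'
#' @param s A [spectra_set()].
#' @param lo,hi Closed-interval limits in cm-1.
#' @return A cropped `spectra_set`; errors if no grid point falls inside.
#' @export
crop_region <- function(s, lo, hi) {
  stopifnot(inherits(s, "spectra_set"), lo < hi)
  keep <- s$wavenumbers >= lo & s$wavenumbers <= hi
  if (!any(keep)) stop("crop [", lo, ", ", hi, "] leaves no grid points")
  structure(list(
    wavenumbers = s$wavenumbers[keep],
    absorbance  = s$absorbance[, keep, drop = FALSE],
    sample_id   = s$sample_id,
    group       = s$group,
    provenance  = c(s$provenance, paste0("crop_region(", lo, ",", hi, ")"))
  ), class = "spectra_set")
}

#' Normalize a single spectrum
#'
#' `"vector"` divides by the Euclidean norm (removes multiplicative
#' scatter); `"snv"` centers and divides by the sd (n-1 denominator);
#' `"none"` is the identity.
#'
#' @param row Numeric spectrum.
#' @param mode `"vector"`, `"snv"` or `"none"`.
#' @param id Sample label used in error messages.
#' @return Normalized numeric vector.
#' @export
normalize_spectrum <- function(row, mode = c("vector", "snv", "none"),
                               id = "<row>") {
  mode <- match.arg(mode)
  if (mode == "none") return(row)
  if (mode == "vector") {
    nrm <- sqrt(sum(row^2))
    if (nrm == 0) stop("zero spectrum, cannot vector-normalize sample ", id)
    return(row / nrm)
  }
  sdv <- stats::sd(row)
  if (sdv == 0) stop("zero-variance spectrum, cannot SNV-normalize sample ", id)
  (row - mean(row)) / sdv
}

#' Centered moving average with shrinking edges
#'
#' Mean filter of odd width; near the edges the window shrinks
#' symmetrically (at position i it spans `min(h, i-1, n-i)` points each
#' side), so a window-1 call and a constant input are exact identities.
#'
#' @param row Numeric vector.
#' @param window Odd window width in points, `<= length(row)`.
#' @return Smoothed vector, same length.
#' @export
moving_average <- function(row, window) {
  n <- length(row)
  if (window %% 2 == 0) stop("moving-average window must be odd")
  if (window > n) stop("window exceeds spectrum length")
  if (window == 1L) return(row)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, row))
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(h, i - 1L, n - i)
    out[i] <- (cs[i + k + 1L] - cs[i - k]) / (2L * k + 1L)
  }
  out
}

#' Savitzky-Golay second derivative
#'
#' Least-squares polynomial convolution filter returning d2A/dnu2 in
#' AU * cm^2 (scaled by the grid step so results are step-invariant).
#' Interior points are exact for polynomials up to `polyorder`; edge
#' points come from the one-sided window fits. Requires a uniform grid.
#'
#' @param row Numeric spectrum sampled on a uniform grid.
#' @param window Odd window in points (default 11).
#' @param polyorder Polynomial order (default 3), `>= 2`, `< window`.
#' @param step Grid spacing in cm-1.
#' @return Second-derivative vector, same length as `row`.
#' @export
sg_second_derivative <- function(row, window = 11L, polyorder = 3L, step = 0.5) {
  if (window %% 2 == 0) stop("S-G window must be odd")
  if (polyorder < 2 || polyorder >= window)
    stop("need 2 <= polyorder < window")
  if (length(step) > 1 || !is.finite(step) || step <= 0)
    stop("step must be a positive scalar")
  signal::sgolayfilt(row, p = polyorder, n = window, m = 2, ts = step)
}

# Guard used by preprocess(): the derivative assumes uniform spacing.
assert_uniform_grid <- function(wn, tol = 1e-8) {
  d <- abs(diff(wn))
  if (length(d) && (max(d) - min(d)) > tol * mean(d))
    stop("wavenumber grid is not uniform; Savitzky-Golay derivative undefined")
  invisible(mean(d))
}

#' Fit a training-set autoscaler
#'
#' Learns per-column means and standard deviations (n-1 denominator) on a
#' training set. Columns with zero variance get sd 1 with a warning: after
#' centering they carry no information. Test data must be scaled with the
#' training parameters via [apply_scaler()], never refit.
#'
#' @param train A [spectra_set()] with at least 2 samples.
#' @return An object of class `scaler`.
#' @export
fit_scaler <- function(train) {
  stopifnot(inherits(train, "spectra_set"))
  if (nrow(train$absorbance) < 2) stop("need >= 2 training samples")
  mu <- colMeans(train$absorbance)
  sdv <- col_sds(train$absorbance)
  zero <- sdv == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance column(s); sd set to 1")
    sdv[zero] <- 1
  }
  structure(list(mean = mu, sd = sdv, wavenumbers = train$wavenumbers,
                 zero_variance = which(zero)),
            class = "scaler")
}

#' Apply a fitted autoscaler
#'
#' @param scaler A [fit_scaler()] result.
#' @param s A [spectra_set()] on the same grid.
#' @return Autoscaled `spectra_set`.
#' @export
apply_scaler <- function(scaler, s) {
  stopifnot(inherits(scaler, "scaler"), inherits(s, "spectra_set"))
  if (!isTRUE(all.equal(scaler$wavenumbers, s$wavenumbers)))
    stop("scaler grid does not match spectra grid")
  X <- sweep(sweep(s$absorbance, 2, scaler$mean), 2, scaler$sd, "/")
  structure(list(wavenumbers = s$wavenumbers, absorbance = X,
                 sample_id = s$sample_id, group = s$group,
                 provenance = c(s$provenance, "autoscale(train-fitted)")),
            class = "spectra_set")
}

#' Full preprocessing chain
#'
#' Applies, in order: crop to `cfg$region`, per-spectrum normalization,
#' moving-average smoothing, Savitzky-Golay second derivative. All steps
#' are per-spectrum, so the chain is split-independent; autoscaling is
#' deliberately left to the model-fitting stage (train-fitted).
#'
#' @param s A [spectra_set()].
#' @param cfg A [preprocess_config()].
#' @return Preprocessed `spectra_set` with provenance appended.
#' @export
preprocess <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "spectra_set"), inherits(cfg, "preprocess_config"))
  out <- crop_region(s, cfg$region[1], cfg$region[2])
  X <- out$absorbance
  if (cfg$normalization != "none") {
    for (i in seq_len(nrow(X)))
      X[i, ] <- normalize_spectrum(X[i, ], cfg$normalization, out$sample_id[i])
  }
  if (cfg$ma_window > 1L) {
    for (i in seq_len(nrow(X))) X[i, ] <- moving_average(X[i, ], cfg$ma_window)
  }
  if (cfg$derivative_order > 0L) {
    if (cfg$derivative_order != 2L)
      stop("only the second derivative is implemented")
    step <- assert_uniform_grid(out$wavenumbers)
    for (i in seq_len(nrow(X)))
      X[i, ] <- sg_second_derivative(X[i, ], cfg$sg_window, cfg$sg_polyorder, step)
  }
  structure(list(
    wavenumbers = out$wavenumbers, absorbance = X,
    sample_id = out$sample_id, group = out$group,
    provenance = c(out$provenance, sprintf(
      "normalize(%s) + moving_average(%d) + sg_derivative(order=%d,window=%d,poly=%d)",
      cfg$normalization, cfg$ma_window, cfg$derivative_order,
      cfg$sg_window, cfg$sg_polyorder))
  ), class = "spectra_set")
}
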