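#' Default fingerprint-region band set
#'
#' A plausible set of Gaussian absorbance bands for blood-derived
#' biofluid spectra in the 1500-1000 cm-1 window: carbohydrate C-O and
#' phosphate stretches towards low wavenumbers, amide III / protein bands
#' around 1300-1350, and CH2/CH3 deformation bands near 1400-1475 cm-1.
#' Every spectrum generated by [generate_cohort()] starts from this profile.
#'
#' @return A data.frame with columns `center` (cm-1), `width` (Gaussian
#'   sigma, cm-1) and `amplitude` (absorbance units).
#' @export
default_bands <- function() {
  data.frame(
    center    = c(1045, 1080, 1120, 1170, 1240, 1304, 1335.5, 1400, 1449.5, 1475),
    width     = c(  12,   14,   10,   12,   13,    9,      8,   11,     10,    8),
    amplitude = c(0.45, 0.55, 0.30, 0.35, 0.50, 0.40,   0.35, 0.55,   0.60, 0.25)
  )
}

#' Default group-specific marker effects
#'
#' Absorbance shifts planted at three marker wavenumbers (1335.5, 1304
#' and 1449.5 cm-1) that give each clinical group a distinct fingerprint:
#' healthy controls (HC) carry the base profile; the disease groups
#' (ALS at diagnosis `ALS_T0`, after six months `ALS_T6`, and other
#' neuromuscular disorders `ON`) deviate at the markers with patterns
#' that separate all four groups.
#'
#' @return Named list mapping group label to a named numeric vector of
#'   amplitude shifts (AU) keyed by marker center (cm-1).
#' @export
default_group_effects <- function() {
  list(
    HC     = c(),
    ALS_T0 = c("1335.5" = -0.035, "1304" =  0.030, "1449.5" =  0.035),
    ALS_T6 = c("1335.5" = -0.020, "1304" =  0.060, "1449.5" =  0.012),
    ON     = c("1335.5" =  0.015, "1304" = -0.035, "1449.5" = -0.025)
  )
}

#' Synthetic cohort configuration
#'
#' Describes the simulated study: group sizes (default 19/16/15/7 for
#' ALS_T0/ALS_T6/HC/ON), the shared band profile, group-specific marker
#' effects, instrument artifact magnitudes (additive Gaussian noise,
#' linear baseline drift, multiplicative scatter), and triplicate
#' acquisition with averaging.
#'
#' @param sizes Named integer vector of samples per group.
#' @param bands Base band table as from [default_bands()].
#' @param effects Group effects as from [default_group_effects()].
#' @param marker_width Gaussian sigma (cm-1) of the planted marker bumps.
#' @param band_cv Relative per-sample variability of every base band
#'   amplitude (biological heterogeneity; default 0.05).
#' @param effect_cv Relative per-sample variability of the planted marker
#'   effects (disease heterogeneity; default 0.4).
#' @param noise_sd Additive noise sd per grid point per replicate (AU).
#' @param baseline_const Range of the constant baseline offset (AU).
#' @param baseline_slope Range of the baseline slope (AU per cm-1).
#' @param scatter Range of the multiplicative scatter factor (around 1;
#'   must exclude 0).
#' @param replicates Replicate measurements averaged per sample (default 3).
#' @param grid_from,grid_to,grid_step Wavenumber grid, see [wavenumber_grid()].
#' @param seed Default seed used by [generate_cohort()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(sizes = c(ALS_T0 = 19, ALS_T6 = 16, HC = 15, ON = 7),
                          bands = default_bands(),
                          effects = default_group_effects(),
                          marker_width = 4,
                          band_cv = 0.05,
                          effect_cv = 0.4,
                          noise_sd = 0.004,
                          baseline_const = c(-0.02, 0.02),
                          baseline_slope = c(-2e-5, 2e-5),
                          scatter = c(0.97, 1.03),
                          replicates = 3,
                          grid_from = 1500, grid_to = 1000, grid_step = 0.5,
                          seed = 1L) {
  if (any(sizes < 0)) stop("group sizes must be >= 0")
  if (replicates < 1) stop("replicates must be >= 1")
  if (noise_sd < 0) stop("noise sd must be non-negative")
  if (min(scatter) <= 0 && max(scatter) >= 0)
    stop("scatter range must exclude 0")
  if (!all(names(effects) %in% names(sizes)))
    stop("unknown group in effects: ",
         paste(setdiff(names(effects), names(sizes)), collapse = ", "))
  if (band_cv < 0 || effect_cv < 0) stop("variability CVs must be >= 0")
  structure(list(
    sizes = sizes, bands = bands, effects = effects,
    marker_width = marker_width, band_cv = band_cv, effect_cv = effect_cv,
    noise_sd = noise_sd,
    baseline_const = baseline_const, baseline_slope = baseline_slope,
    scatter = scatter, replicates = replicates,
    grid_from = grid_from, grid_to = grid_to, grid_step = grid_step,
    seed = seed
  ), class = "cohort_config")
}

#' Sum-of-Gaussians absorbance profile
#'
#' Evaluates `sum_b amplitude_b * exp(-(nu - center_b)^2 / (2 width_b^2))`
#' on a wavenumber grid.
#'
#' @param bands data.frame with `center`, `width`, `amplitude` columns;
#'   may have zero rows.
#' @param wavenumbers Numeric grid (non-empty).
#' @return Numeric vector of absorbances, one per grid point.
#' @export
band_profile <- function(bands, wavenumbers) {
  if (length(wavenumbers) == 0L) stop("empty wavenumber grid")
  out <- numeric(length(wavenumbers))
  if (NROW(bands) == 0L) return(out)
  if (any(bands$width <= 0)) stop("band widths must be positive")
  if (any(bands$amplitude < 0)) stop("band amplitudes must be non-negative")
  for (b in seq_len(nrow(bands))) {
    out <- out + bands$amplitude[b] *
      exp(-(wavenumbers - bands$center[b])^2 / (2 * bands$width[b]^2))
  }
  out
}

#' Apply instrument artifacts to a clean spectrum
#'
#' Returns `scatter * clean + (a + b * nu) + eps` with the scatter factor
#' and baseline coefficients drawn uniformly from the configured ranges
#' and `eps` i.i.d. Gaussian(0, `noise_sd`) per grid point. Consumes the
#' current RNG state; seed the session (or use [generate_cohort()]) for
#' reproducibility.
#'
#' @param clean Numeric spectrum.
#' @param config A [cohort_config()].
#' @param wavenumbers Grid matching `clean`.
#' @return Numeric vector, same length as `clean`.
#' @export
apply_instrument_effects <- function(clean, config, wavenumbers) {
  if (config$noise_sd < 0) stop("noise sd must be non-negative")
  scatter <- stats::runif(1, min(config$scatter), max(config$scatter))
  a <- stats::runif(1, min(config$baseline_const), max(config$baseline_const))
  b <- stats::runif(1, min(config$baseline_slope), max(config$baseline_slope))
  eps <- if (config$noise_sd > 0)
    stats::rnorm(length(clean), 0, config$noise_sd) else 0
  scatter * clean + (a + b * wavenumbers) + eps
}

#' Generate a synthetic ATR-FTIR cohort
#'
#' For each sample the group profile (base bands plus that group's marker
#' shifts) is measured `replicates` times with independent instrument
#' artifacts and the replicates are averaged, emulating triplicate
#' acquisition. Rows are then shuffled deterministically under the seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`. The same
#'   config + seed always yields a byte-identical [spectra_set()].
#' @return A [spectra_set()] with `sum(config$sizes)` spectra.
#' @export
#' @examples
#' s <- generate_cohort(cohort_config(seed = 7))
#' dim(s)   # 57 samples x 1001 points
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  wn <- wavenumber_grid(config$grid_from, config$grid_to, config$grid_step)
  for (g in names(config$effects)) {
    cent <- as.numeric(names(config$effects[[g]]))
    if (length(cent) && !all(cent %in% wn))
      stop("marker centers off grid for group ", g)
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  n <- sum(config$sizes)
  X <- matrix(0, n, length(wn))
  groups <- character(n)
  i <- 0L
  for (g in names(config$sizes)) {
    eff <- config$effects[[g]]
    for (s in seq_len(config$sizes[[g]])) {
      i <- i + 1L
      # per-sample biological variability of the shared band profile
      bands_i <- config$bands
      if (config$band_cv > 0)
        bands_i$amplitude <- pmax(bands_i$amplitude *
          (1 + stats::rnorm(nrow(bands_i), 0, config$band_cv)), 0)
      profile <- band_profile(bands_i, wn)
      if (!is.null(eff) && length(eff) > 0L) {
        # per-sample heterogeneity of the planted group effect
        amp <- unname(eff)
        if (config$effect_cv > 0)
          amp <- amp * (1 + stats::rnorm(length(amp), 0, config$effect_cv))
        delta <- data.frame(center = as.numeric(names(eff)),
                            width = config$marker_width,
                            amplitude = abs(amp))
        profile <- profile + band_profile_signed(delta, sign(amp), wn)
      }
      reps <- vapply(seq_len(config$replicates), function(r)
        apply_instrument_effects(profile, config, wn),
        numeric(length(wn)))
      X[i, ] <- rowMeans(reps)
      groups[i] <- g
    }
  }
  ids <- sprintf("%s_%02d", groups, stats::ave(seq_len(n), groups, FUN = seq_along))
  ord <- sample.int(n)
  spectra_set(wn, X[ord, , drop = FALSE], ids[ord], groups[ord],
              provenance = paste0("generate_cohort(seed=", seed,
                                  ", config=", config_hash(unclass(config)), ")"))
}

# Signed sum of Gaussians: like band_profile but each band may subtract.
band_profile_signed <- function(bands, signs, wavenumbers) {
  out <- numeric(length(wavenumbers))
  for (b in seq_len(NROW(bands))) {
    out <- out + signs[b] * bands$amplitude[b] *
      exp(-(wavenumbers - bands$center[b])^2 / (2 * bands$width[b]^2))
  }
  out
}
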