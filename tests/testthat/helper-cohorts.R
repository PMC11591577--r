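# Shared fixtures, all built in code.

# Two-class study (ALS at diagnosis vs controls) with effects scaled by
# `effect_scale`; scale 1 is the strong default regime, 0 a null cohort,
# and ~0.30 the moderate regime with a ~1.2 within-class-sd marker shift.
two_class_config <- function(seed, effect_scale = 1) {
  eff <- lapply(default_group_effects(), function(e) e * effect_scale)
  cohort_config(sizes = c(ALS_T0 = 19, HC = 15),
                effects = eff[c("HC", "ALS_T0")], seed = seed)
}

# Planted marker centers and the recovery tolerance: a hit is a reported
# band within the planted bump's 2-sigma support (8 cm-1).
marker_centers <- c(1335.5, 1304, 1449.5)
marker_tol <- 2 * cohort_config()$marker_width

markers_recovered <- function(wn_list, centers = marker_centers,
                              tol = marker_tol) {
  vapply(centers, function(cc) any(abs(wn_list - cc) <= tol), logical(1))
}

# Autoscale a preprocessed spectra_set in place (fit on itself).
autoscale_self <- function(s) apply_scaler(fit_scaler(s), s)

# A small light-weight pipeline config for orchestration tests.
light_pipeline_config <- function(seed = 1, n_perm = 25) {
  cmps <- default_comparisons()
  for (i in seq_along(cmps)) cmps[[i]]$n_perm <- n_perm
  pipeline_config(comparisons = cmps, seed = seed)
}
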