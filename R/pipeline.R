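#' PCA overview with advisory outlier flags
#'
#' Principal component analysis of an autoscaled spectra set for an
#' initial look at the data. Samples beyond the 99% Hotelling T2 limit
#' (F-based) or the 99% residual Q limit (moment-matched chi-square
#' approximation) are flagged. Flags are ADVISORY only: no sample is ever
#' removed automatically, since no objective removal rule is assumed.
#'
#' @param s A [spectra_set()] (preprocessed).
#' @param n_comp Components to keep; default: smallest number explaining
#'   >= 90% of the variance, capped at 10.
#' @return List with `scores`, `explained` (% per component,
#'   non-increasing), `t2`, `q_resid`, their 99% limits and logical
#'   `flagged`.
#' @export
pca_overview <- function(s, n_comp = NULL) {
  stopifnot(inherits(s, "spectra_set"))
  X <- s$absorbance
  n <- nrow(X)
  mu <- colMeans(X); sdv <- col_sds(X); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  sv <- svd(Xs)
  lambda <- sv$d^2 / (n - 1)
  explained <- 100 * lambda / sum(lambda)
  if (is.null(n_comp))
    n_comp <- min(which(cumsum(explained) >= 90), 10, n - 2)
  n_comp <- max(1L, min(n_comp, length(lambda)))
  Tsc <- sv$u[, seq_len(n_comp), drop = FALSE] %*%
    diag(sv$d[seq_len(n_comp)], n_comp)
  t2 <- rowSums(sweep(Tsc^2, 2, lambda[seq_len(n_comp)], "/"))
  t2_lim <- n_comp * (n - 1) * (n + 1) / (n * (n - n_comp)) *
    stats::qf(0.99, n_comp, n - n_comp)
  E <- Xs - Tsc %*% t(sv$v[, seq_len(n_comp), drop = FALSE])
  q <- rowSums(E^2)
  m <- mean(q); v <- stats::var(q)
  q_lim <- if (v > 0) (v / (2 * m)) * stats::qchisq(0.99, 2 * m^2 / v) else Inf
  list(scores = Tsc, explained = explained[seq_len(n_comp)],
       n_comp = n_comp, t2 = t2, t2_limit = t2_lim,
       q_resid = q, q_limit = q_lim,
       flagged = t2 > t2_lim | q > q_lim,
       sample_id = s$sample_id, group = s$group)
}

#' Top distinct bands of an importance profile
#'
#' Greedy band picking on a per-wavenumber importance profile (e.g. VIP
#' scores): wavenumbers are visited in decreasing order of importance and
#' kept only if at least `min_sep` cm-1 away from every band already
#' kept. On a 0.5 cm-1 grid the raw top-n grid points of a smooth
#' profile all sit inside one or two bands; this returns band-level
#' maxima instead, the way a spectroscopist reads a VIP plot.
#'
#' @param values Importance per wavenumber (higher = more important).
#' @param wavenumbers Matching wavenumber vector (cm-1).
#' @param n Number of bands to return.
#' @param min_sep Minimum separation between reported bands (cm-1).
#' @return Numeric vector of up to `n` band positions, by importance.
#' @export
top_bands <- function(values, wavenumbers, n = 10, min_sep = 4) {
  stopifnot(length(values) == length(wavenumbers), min_sep >= 0)
  ord <- order(-values)
  taken <- numeric(0)
  for (j in ord) {
    if (all(abs(wavenumbers[j] - taken) >= min_sep))
      taken <- c(taken, wavenumbers[j])
    if (length(taken) == n) break
  }
  taken
}

#' Bands selected by every strategy (consensus)
#'
#' Intersects two or more ordered wavenumber lists (e.g. the SELECT list
#' and the top-VIP list). Two entries match when they differ by at most
#' `tolerance` cm-1; a merged band is reported at the first list's value.
#' Output is ordered by best combined (summed) rank.
#'
#' @param lists List of >= 2 numeric vectors, each ordered by importance.
#' @param tolerance Matching tolerance in cm-1 (default 0, exact).
#' @return data.frame with `band` and one rank column per list; zero rows
#'   when the intersection is empty.
#' @export
consensus_bands <- function(lists, tolerance = 0) {
  stopifnot(length(lists) >= 2, all(lengths(lists) > 0))
  ref <- lists[[1]]
  nm <- names(lists) %||% paste0("list", seq_along(lists))
  rows <- list()
  for (i in seq_along(ref)) {
    ranks <- integer(length(lists))
    ranks[1] <- i
    ok <- TRUE
    for (l in 2:length(lists)) {
      d <- abs(lists[[l]] - ref[i])
      j <- which(d <= tolerance + 1e-9)
      if (!length(j)) { ok <- FALSE; break }
      ranks[l] <- j[which.min(d[j])]
    }
    if (ok) rows[[length(rows) + 1L]] <- c(band = ref[i], ranks)
  }
  if (!length(rows)) {
    out <- as.data.frame(matrix(numeric(0), 0, 1 + length(lists)))
    names(out) <- c("band", paste0("rank_", nm))
    return(out)
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("band", paste0("rank_", nm))
  out[order(rowSums(out[-1])), , drop = FALSE]
}

#' Pipeline configuration
#'
#' Bundles the cohort source, preprocessing parameters, and the list of
#' group comparisons to run. The default mirrors the two published-style
#' analyses: a two-class comparison (ALS at diagnosis vs healthy
#' controls; 5 + 5 external test samples, OPLS-DA route) and a
#' three-class comparison (ALS_T0 vs ALS_T6 vs ON; 2 test samples per
#' class, PLS-DA route).
#'
#' @param simulate A [cohort_config()] used when `input` is NULL.
#' @param input Optional CSV path of an existing cohort
#'   (see [read_spectra()]); overrides `simulate`.
#' @param preprocess A [preprocess_config()].
#' @param comparisons List of comparison specs; each a list with `name`,
#'   `classes`, `test_per_class` (named), `k` (SELECT variables, clamped
#'   to the 3:1 rule), `n_comp`, `n_orth`, `folds`, `n_perm`, `alpha`,
#'   `band_tolerance`, and `roc` (list with `positive`, `negative` class
#'   subsets).
#' @param seed Root seed; all stage randomness derives from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = cohort_config(),
                            input = NULL,
                            preprocess = preprocess_config(),
                            comparisons = default_comparisons(),
                            seed = 1L) {
  structure(list(simulate = simulate, input = input,
                 preprocess = preprocess, comparisons = comparisons,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
default_comparisons <- function() {
  list(
    list(name = "ALS_T0_vs_HC",
         classes = c("ALS_T0", "HC"),
         test_per_class = c(ALS_T0 = 5, HC = 5),
         k = 10, n_comp = 2, n_orth = 1, folds = 5, n_perm = 199,
         alpha = 0.05, band_tolerance = 1.0,
         roc = list(positive = "ALS_T0", negative = "HC")),
    list(name = "ALS_T0_vs_T6_vs_ON",
         classes = c("ALS_T0", "ALS_T6", "ON"),
         test_per_class = c(ALS_T0 = 2, ALS_T6 = 2, ON = 2),
         k = 10, n_comp = 2, n_orth = 1, folds = 5, n_perm = 199,
         alpha = 0.05, band_tolerance = 1.0,
         roc = list(positive = c("ALS_T0", "ALS_T6"), negative = "ON"))
  )
}

#' Run the full chemometric workflow
#'
#' For every configured comparison: stratified train/test split,
#' preprocessing, train-fitted autoscaling, PCA overview (advisory
#' outlier flags), SELECT variable selection, LDA with resubstitution /
#' leave-one-out / external reporting, SIMCA on the selected variables,
#' PLS-DA (3+ classes) or OPLS-DA (2 classes) with 5-fold Q2Y,
#' permutation test and CV-ANOVA, top-10 VIP ranking, consensus bands
#' across the SELECT and VIP lists, and a ROC analysis per consensus
#' band. All fitted parameters (scaler, selection, models) are learned on
#' the training split only.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory; when given, TSV tables and a JSON
#'   run manifest are written there.
#' @return A `report_bundle`: list with `cohort`, per-comparison results,
#'   and `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  cohort <- if (!is.null(cfg$input)) read_spectra(cfg$input)
            else generate_cohort(cfg$simulate,
                                 seed = seed_stream(cfg$seed, "simulate"))
  pp <- preprocess(cohort, cfg$preprocess)

  comparisons <- lapply(cfg$comparisons, function(cmp) {
    run_comparison(pp, cmp, cfg$seed)
  })
  names(comparisons) <- vapply(cfg$comparisons, `[[`, character(1), "name")

  manifest <- list(
    seed = cfg$seed,
    config_hash = config_hash(list(simulate = unclass(cfg$simulate),
                                   preprocess = unclass(cfg$preprocess),
                                   comparisons = cfg$comparisons)),
    n_samples = nrow(cohort$absorbance),
    groups = as.list(table(cohort$group)),
    r_version = as.character(getRversion()),
    comparisons = names(comparisons)
  )
  bundle <- structure(list(cohort = cohort, preprocessed = pp,
                           comparisons = comparisons, manifest = manifest),
                      class = "report_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

run_comparison <- function(pp, cmp, root_seed) {
  wrap_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed for comparison '",
           cmp$name, "' (seed ", root_seed, "): ", conditionMessage(e),
           call. = FALSE))
  }
  sub <- subset_samples(pp, pp$group %in% cmp$classes)
  split <- wrap_stage("split", split_train_test(
    sub, cmp$test_per_class, seed_stream(root_seed, paste0("split:", cmp$name))))
  train <- split$train; test <- split$test
  n_train <- nrow(train$absorbance)

  scaler <- wrap_stage("autoscale", fit_scaler(train))
  tr_s <- apply_scaler(scaler, train)
  te_s <- apply_scaler(scaler, test)

  pca <- wrap_stage("pca_overview", pca_overview(train))

  k <- min(cmp$k, max_variables_rule(n_train))
  if (k < cmp$k)
    message("SELECT k clamped from ", cmp$k, " to ", k,
            " by the 3:1 sample/variable rule (n_train = ", n_train, ")")
  sel <- wrap_stage("select", select_decorrelate(
    tr_s$absorbance, tr_s$group, k, tr_s$wavenumbers))

  Xtr <- tr_s$absorbance[, sel$indices, drop = FALSE]
  Xte <- te_s$absorbance[, sel$indices, drop = FALSE]
  lda_m <- wrap_stage("lda", lda_fit(Xtr, tr_s$group))
  resub <- table(true = factor(tr_s$group), predicted =
                   factor(lda_predict(lda_m, Xtr)$labels, sort(unique(tr_s$group))))
  loo <- wrap_stage("loo", loo_crossval(Xtr, tr_s$group))
  ext <- table(true = factor(te_s$group, sort(unique(tr_s$group))),
               predicted = factor(lda_predict(lda_m, Xte)$labels,
                                  sort(unique(tr_s$group))))
  lda_report <- classification_report(resub, loo, ext)

  tr_sel <- subset_wavenumbers(tr_s, sel$selected)
  te_sel <- subset_wavenumbers(te_s, sel$selected)
  simca <- wrap_stage("simca", simca_analysis(tr_sel, te_sel,
                                              alpha = cmp$alpha))

  two_class <- length(cmp$classes) == 2
  fit_fun <- if (two_class) "oplsda" else "plsda"
  Xraw_tr <- train$absorbance   # pre-autoscale; q2/permutation refit scaler
  pls_m <- wrap_stage("pls", if (two_class)
    oplsda_fit(tr_s$absorbance, tr_s$group, n_orth = cmp$n_orth)
  else plsda_fit(tr_s$absorbance, tr_s$group, n_comp = cmp$n_comp))
  # VIP needs a PLS weight structure; for OPLS-DA rank variables by the
  # predictive component of a plain PLS-DA fit with the same data
  vip_model <- if (two_class)
    plsda_fit(tr_s$absorbance, tr_s$group, n_comp = cmp$n_comp)
  else pls_m
  vip <- vip_scores(vip_model)
  vip_top <- top_bands(vip, tr_s$wavenumbers, n = 10)

  q2 <- wrap_stage("q2", q2_crossval(
    Xraw_tr, train$group, n_comp = cmp$n_comp, folds = cmp$folds,
    seed = seed_stream(root_seed, paste0("q2:", cmp$name)),
    fit_fun = fit_fun, n_orth = cmp$n_orth))
  perm <- wrap_stage("permutation", permutation_test(
    Xraw_tr, train$group, n_perm = cmp$n_perm,
    seed = seed_stream(root_seed, paste0("perm:", cmp$name)),
    fit_fun = fit_fun, n_comp = cmp$n_comp, n_orth = cmp$n_orth,
    folds = cmp$folds))
  d1 <- if (two_class) 1 + cmp$n_orth else cmp$n_comp
  cva <- cv_anova(q2$PRESS, q2$ss_tot, n_train, d1 = d1)

  cons <- consensus_bands(list(SELECT = sel$selected, VIP = vip_top),
                          tolerance = cmp$band_tolerance)

  roc <- list()
  roc_pos <- cmp$roc$positive; roc_neg <- cmp$roc$negative
  roc_set <- subset_samples(pp, pp$group %in% c(roc_pos, roc_neg))
  roc_lab <- roc_set$group %in% roc_pos
  # with an empty consensus set, still report the leading VIP band
  roc_bands <- if (nrow(cons)) cons$band else vip_top[1]
  for (b in roc_bands) {
    vals <- roc_set$absorbance[, match(b, roc_set$wavenumbers)]
    roc[[format(b)]] <- roc_curve(vals, roc_lab, positive = TRUE,
                                  direction = "auto")
  }

  list(name = cmp$name,
       split = list(train_id = train$sample_id, test_id = test$sample_id),
       n_train = n_train, k = k,
       pca = pca, selection = sel, lda = lda_report,
       simca = simca,
       pls = list(model = pls_m, R2Y = pls_m$R2Y, Q2Y = q2$Q2Y,
                  vip = data.frame(wavenumber = tr_s$wavenumbers, VIP = vip),
                  vip_top = vip_top,
                  permutation = perm, cv_anova = cva, route = fit_fun),
       consensus = cons, roc = roc)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(bundle$comparisons)) {
    cm <- bundle$comparisons[[nm]]
    pre <- file.path(out_dir, nm)
    utils::write.table(cm$lda$table, paste0(pre, "_lda.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(cm$simca$rates, paste0(pre, "_simca.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(cm$simca$power, paste0(pre, "_power.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(cm$consensus, paste0(pre, "_consensus.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    val <- c(list(R2Y = cm$pls$R2Y, Q2Y = cm$pls$Q2Y,
                  p_R2Y = cm$pls$permutation$p_R2Y,
                  p_Q2Y = cm$pls$permutation$p_Q2Y,
                  cv_anova_F = cm$pls$cv_anova$F,
                  cv_anova_p = cm$pls$cv_anova$p),
             lapply(cm$roc, function(r)
               list(auc = r$auc, p = r$p, cut = r$youden_cut,
                    direction = r$direction,
                    sensitivity = r$sensitivity,
                    specificity = r$specificity)))
    names(val)[-(1:6)] <- paste0("roc_", names(cm$roc))
    jsonlite::write_json(val, paste0(pre, "_validation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> seed", x$manifest$seed, "| cohort:",
      x$manifest$n_samples, "samples\n")
  for (nm in names(x$comparisons)) {
    cm <- x$comparisons[[nm]]
    tot <- cm$lda$table[cm$lda$table$group == "Total", ]
    cat(sprintf(
      "%s: LDA total %% (resub/LOO/ext) = %.1f/%.1f/%.1f | Q2Y = %.2f | %d consensus band(s)\n",
      nm, tot$classification, tot$prediction, tot$external,
      cm$pls$Q2Y, nrow(cm$consensus)))
  }
  invisible(x)
}
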