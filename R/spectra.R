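#' Wavenumber grid for the mid-IR fingerprint region
#'
#' Builds the descending wavenumber axis on which all spectra in a
#' [spectra_set()] live. The default spans the biochemical fingerprint
#' region, 1500 down to 1000 cm-1, at a 0.5 cm-1 data interval (1001
#' points), so that marker bands reported at half-wavenumber precision
#' (e.g. 1335.5 or 1449.5 cm-1) are addressable exactly.
#'
#' @param from,to Region limits in cm-1; `from` > `to` (descending axis).
#' @param step Grid spacing in cm-1 (default 0.5).
#' @return Numeric vector of wavenumbers, strictly decreasing.
#' @export
#' @examples
#' wn <- wavenumber_grid()
#' length(wn)   # 1001
#' 1335.5 %in% wn
wavenumber_grid <- function(from = 1500, to = 1000, step = 0.5) {
  stopifnot(step > 0, from > to)
  seq(from, to, by = -step)
}

#' Spectra collection with sample metadata
#'
#' The container consumed and produced by every stage of the workflow:
#' a samples x wavenumbers absorbance matrix, the wavenumber axis, sample
#' identifiers, group labels, and a provenance trail recording the
#' transformations applied so far.
#'
#' @param wavenumbers Numeric vector, strictly monotone (conventionally
#'   descending, as spectrometers export).
#' @param absorbance Numeric matrix, one row per sample, `length(wavenumbers)`
#'   columns; absorbance units (or derivative units after preprocessing).
#' @param sample_id Character vector of unique sample identifiers.
#' @param group Character or factor group labels, one per sample.
#' @param provenance Character vector of transformation descriptions.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumbers, absorbance, sample_id, group,
                        provenance = character()) {
  absorbance <- as.matrix(absorbance)
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) < 1L) stop("empty wavenumber grid")
  d <- diff(wavenumbers)
  if (!(all(d > 0) || all(d < 0))) stop("wavenumbers must be strictly monotone")
  if (ncol(absorbance) != length(wavenumbers))
    stop("absorbance has ", ncol(absorbance), " columns but grid has ",
         length(wavenumbers), " points")
  if (nrow(absorbance) != length(sample_id) || length(sample_id) != length(group))
    stop("sample_id / group length must match the number of spectra")
  if (anyNA(absorbance)) stop("absorbance contains missing values")
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  structure(list(
    wavenumbers = wavenumbers,
    absorbance  = unname(absorbance),
    sample_id   = as.character(sample_id),
    group       = as.character(group),
    provenance  = as.character(provenance)
  ), class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$absorbance), " spectra x ",
      length(x$wavenumbers), " wavenumbers [",
      max(x$wavenumbers), " .. ", min(x$wavenumbers), " cm-1]\n", sep = "")
  tab <- table(x$group)
  cat("groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  if (length(x$provenance))
    cat("provenance:\n", paste(" -", x$provenance, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset a spectra_set by sample
#'
#' @param s A [spectra_set()].
#' @param i Row index (logical, integer or sample-id character vector).
#' @return A `spectra_set` with the selected samples.
#' @export
subset_samples <- function(s, i) {
  stopifnot(inherits(s, "spectra_set"))
  if (is.character(i)) i <- match(i, s$sample_id)
  spectra_set(s$wavenumbers, s$absorbance[i, , drop = FALSE],
              s$sample_id[i], s$group[i], s$provenance)
}

#' Subset a spectra_set to given wavenumbers
#'
#' @param s A [spectra_set()].
#' @param wn Wavenumbers to retain (must all be on the grid).
#' @return A `spectra_set` restricted to those columns, in the order given.
#' @export
subset_wavenumbers <- function(s, wn) {
  stopifnot(inherits(s, "spectra_set"))
  j <- match(wn, s$wavenumbers)
  if (anyNA(j)) stop("wavenumbers not on grid: ",
                     paste(wn[is.na(j)], collapse = ", "))
  # single columns break monotonicity checks nowhere: grid of length >= 1
  structure(list(
    wavenumbers = s$wavenumbers[j],
    absorbance  = s$absorbance[, j, drop = FALSE],
    sample_id   = s$sample_id,
    group       = s$group,
    provenance  = c(s$provenance, paste0("subset_wavenumbers(k=", length(j), ")"))
  ), class = "spectra_set")
}

#' Write a spectra_set to wide CSV
#'
#' Header `sample_id,group,<wn1>,<wn2>,...` with wavenumbers as numeric
#' column labels in grid order; one data row per sample. An optional JSON
#' sidecar (same path with extension `.json`) stores generating metadata.
#'
#' @param s A [spectra_set()].
#' @param path Output CSV path.
#' @param sidecar Optional list written as a JSON sidecar next to `path`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path, sidecar = NULL) {
  stopifnot(inherits(s, "spectra_set"))
  df <- data.frame(sample_id = s$sample_id, group = s$group,
                   s$absorbance, check.names = FALSE)
  names(df)[-(1:2)] <- format(s$wavenumbers, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path), ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a spectra_set from wide CSV
#'
#' @param path CSV path in the dialect written by [write_spectra()].
#' @return A [spectra_set()].
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("CSV must have sample_id and group columns")
  wn <- as.numeric(setdiff(names(df), c("sample_id", "group")))
  X <- as.matrix(df[, setdiff(names(df), c("sample_id", "group"))])
  spectra_set(wn, X, df$sample_id, df$group,
              provenance = paste0("read_spectra(", basename(path), ")"))
}
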