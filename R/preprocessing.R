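# Preprocessing: raw recordings -> characteristic-value matrices.
#
# Spectra are corrected per sample by the standard normal variate (SNV);
# e-nose recordings are reduced to the maximum response of each gas sensor
# over the sampling window. Both characteristic matrices are then column
# z-scored with statistics from the training rows only.

#' Standard normal variate transform
#'
#' Centers and scales each spectrum to zero mean and unit standard deviation
#' (n-1 denominator), removing additive offsets and multiplicative scatter:
#' `snv(a*x + b) = snv(x)` for any `a > 0`.
#'
#' @param x a numeric vector (one spectrum), a samples-by-wavenumber matrix
#'   (transformed row-wise), or a `spectrum` object.
#' @param denominator `"n-1"` (chemometrics convention, default) or `"n"`.
#' @return the transformed object, same shape as the input.
#' @export
snv_transform <- function(x, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  snv1 <- function(v) {
    s <- sd(v)
    if (denominator == "n") s <- s * sqrt((length(v) - 1) / length(v))
    if (!is.finite(s) || s == 0)
      stop("degenerate input: constant spectrum has zero standard deviation")
    (v - mean(v)) / s
  }
  if (inherits(x, "spectrum")) {
    x$absorbance <- snv1(x$absorbance)
    return(x)
  }
  if (is.matrix(x)) return(t(apply(x, 1, snv1)))
  snv1(x)
}

#' Maximum sensor response of an e-nose recording
#'
#' Extracts the per-sensor maximum over the sampling window, the
#' characteristic value of the raw e-nose signal. For the noiseless
#' first-order rise model this is the response at the end of the window.
#'
#' @param recording an `enose_recording` (11 x T response matrix) or a bare
#'   numeric matrix with 11 sensor rows.
#' @return named numeric vector of 11 maxima, in sensor order.
#' @export
max_response <- function(recording) {
  m <- if (inherits(recording, "enose_recording")) recording$response else recording
  if (!is.matrix(m) || nrow(m) != 11)
    stop("recording must have exactly 11 sensor rows")
  if (ncol(m) < 1) stop("recording must have at least one time point")
  apply(m, 1, max)
}

#' Characteristic-value matrix from a list of e-nose recordings
#'
#' @param recordings list of `enose_recording` objects.
#' @return samples x 11 matrix of maximum responses; rownames are sample ids.
#' @export
enose_features <- function(recordings) {
  m <- t(vapply(recordings, max_response, numeric(11)))
  rownames(m) <- vapply(recordings, function(r) as.character(r$sample_id), "")
  m
}

#' Column standardization fitted on training rows
#'
#' Z-scores every column using the mean and standard deviation (n-1
#' denominator by default) of `fit_rows` only; all rows -- including held-out
#' validation rows -- are transformed with those training statistics, so no
#' information leaks from validation into the fitted scaling.
#'
#' @param x samples x features numeric matrix.
#' @param fit_rows row indices (or rownames) used to fit means and scales;
#'   default all rows.
#' @param denominator `"n-1"` (default) or `"n"`.
#' @return an object of class `standardized_features`: list with `x` (the
#'   transformed full matrix), `center`, `scale`, `fit_rows`.
#' @export
standardize <- function(x, fit_rows = seq_len(nrow(x)),
                        denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  stopifnot(is.matrix(x), length(fit_rows) >= 1)
  if (anyNA(x)) stop("feature matrix contains missing values")
  xf <- x[fit_rows, , drop = FALSE]
  center <- colMeans(xf)
  scale <- apply(xf, 2, sd)
  if (denominator == "n")
    scale <- scale * sqrt((nrow(xf) - 1) / nrow(xf))
  bad <- which(!is.finite(scale) | scale == 0)
  if (length(bad)) {
    nm <- colnames(x)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("zero-variance column within fit rows: ", paste(nm, collapse = ", "))
  }
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  structure(list(x = z, center = center, scale = scale, fit_rows = fit_rows),
            class = "standardized_features")
}

#' Apply a fitted standardization to new data
#'
#' @param stats a `standardized_features` object (or any list with `center`
#'   and `scale`).
#' @param newdata matrix with the same columns as the fitted data.
#' @return the transformed matrix.
#' @export
apply_standardization <- function(stats, newdata) {
  if (ncol(newdata) != length(stats$center)) stop("column count mismatch")
  sweep(sweep(newdata, 2, stats$center), 2, stats$scale, "/")
}

#' Write a feature matrix with a sidecar of fitted statistics
#'
#' @param features a `standardized_features` object.
#' @param path CSV path for the matrix; the fitted center/scale are written
#'   alongside as `<path>.stats.json`.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "standardized_features"))
  df <- data.frame(sample_id = rownames(features$x), features$x,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(center = features$center, scale = features$scale),
                       paste0(path, ".stats.json"), digits = NA)
  invisible(path)
}
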