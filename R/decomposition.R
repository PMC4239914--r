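# Feature extraction and fusion: per-modality PCA, then feature-level fusion
# of the concatenated PC scores by independent component analysis.
#
# ICA assumes the observed feature vector x is a linear mixture x = A s of
# statistically independent non-Gaussian sources s, and estimates an
# unmixing matrix W such that y = W' x recovers the sources up to
# permutation, sign and scale. Here it decorrelates and de-duplicates the
# information shared between the e-nose and NIRS principal components before
# classification (intermediate-level fusion).

#' Fit a PCA feature-extraction model
#'
#' Mean-centered principal component analysis. Components are ordered by
#' explained variance; signs are fixed so each loading vector's
#' largest-magnitude element is positive, making refits on identical data
#' reproducible.
#'
#' @param x samples x features matrix (typically standardized training rows).
#' @param k number of components to retain; `k <= min(rows - 1, cols)`.
#' @return an object of class `pca_model`: `center`, `loadings`
#'   (features x k, orthonormal), `explained_var` (variance fractions for all
#'   principal components of the fit data), `k`.
#' @export
fit_pca <- function(x, k) {
  stopifnot(is.matrix(x))
  if (k < 1 || k > min(nrow(x) - 1, ncol(x)))
    stop("k must be between 1 and min(rows - 1, columns)")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  colnames(load) <- paste0("PC", seq_len(k))
  structure(list(center = pc$center, loadings = load,
                 explained_var = ev, k = k),
            class = "pca_model")
}

#' Project data onto a fitted PCA model
#'
#' Centers with the fit-time means and projects onto the stored loadings;
#' applies unchanged to held-out rows.
#'
#' @param model a `pca_model`.
#' @param x matrix with the same feature columns as the fit data.
#' @return samples x k score matrix.
#' @export
project_pca <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  if (ncol(x) != nrow(model$loadings)) stop("feature count does not match model")
  sweep(x, 2, model$center) %*% model$loadings
}

#' Concatenate per-modality score matrices (feature-level fusion input)
#'
#' Column-binds the e-nose scores and the NIRS scores (e-nose first) after
#' checking that both matrices describe the same samples in the same order.
#'
#' @param enose_scores,nirs_scores score matrices with matching rownames
#'   (sample ids) in identical order. Either may have zero columns.
#' @return combined matrix with provenance column names.
#' @export
concat_features <- function(enose_scores, nirs_scores) {
  if (nrow(enose_scores) != nrow(nirs_scores) ||
      !identical(rownames(enose_scores), rownames(nirs_scores)))
    stop("sample ids of the two score matrices do not match")
  ne <- ncol(enose_scores)
  nn <- ncol(nirs_scores)
  out <- cbind(enose_scores, nirs_scores)
  colnames(out) <- c(if (ne) paste0("enose_PC", seq_len(ne)),
                     if (nn) paste0("nirs_PC", seq_len(nn)))
  out
}

logcosh_negentropy <- function(y) {
  # negentropy proxy: (E[log cosh y] - E[log cosh g])^2 for standard normal g
  (colMeans(log(cosh(y))) - 0.3745672)^2
}

#' Fit a fixed-point ICA model (logcosh contrast, symmetric decorrelation)
#'
#' Whitens the centered data to `n_ics` dimensions, then runs fixed-point
#' iteration with the logcosh nonlinearity and symmetric decorrelation.
#' Components are ordered by decreasing non-Gaussianity (a negentropy proxy)
#' and sign-fixed so the largest-magnitude element of each unmixing row is
#' positive; with a fixed seed the fit is fully deterministic.
#'
#' @param x samples x features matrix; `rows >= cols`, `n_ics <= cols`.
#' @param n_ics number of independent components.
#' @param seed seed for the random orthogonal initialization.
#' @param max_iter,tol fixed-point iteration controls.
#' @return an object of class `ica_model`: `center`, `whitening`
#'   (features x n_ics, maps centered data to whitened scores), `W`
#'   (n_ics x n_ics rotation), `unmixing` (features x n_ics; scores =
#'   centered x \%*\% unmixing), `mixing` (the pseudo-inverse mixing matrix),
#'   `converged`, `iterations`.
#' @export
fit_ica <- function(x, n_ics, seed = 1L, max_iter = 500L, tol = 1e-8) {
  stopifnot(is.matrix(x))
  m <- ncol(x)
  if (n_ics < 1 || n_ics > m) stop("n_ics must be between 1 and ncol(x)")
  if (nrow(x) < m) stop("need at least as many rows as columns")
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  eg <- eigen(cov(xc), symmetric = TRUE)
  d <- eg$values[seq_len(n_ics)]
  if (any(d < 1e-12)) stop("rank-deficient data: cannot whiten to n_ics dimensions")
  K <- eg$vectors[, seq_len(n_ics), drop = FALSE] %*% diag(1 / sqrt(d), n_ics)
  z <- xc %*% K                      # whitened: cov(z) = I (n-1 denominator)
  if (max(abs(colMeans(z^4)) - 3) < 0.05 && n_ics > 1)
    warning("sources look close to Gaussian; ICA may be unidentifiable")

  sym_decorr <- function(W) {
    s <- eigen(W %*% t(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(pmax(s$values, 1e-300)), n_ics) %*%
      t(s$vectors) %*% W
  }
  W <- with_seed(substream_seed(seed, "ica-init"),
                 matrix(rnorm(n_ics * n_ics), n_ics, n_ics))
  W <- sym_decorr(W)
  n <- nrow(z)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    y <- z %*% t(W)                  # samples x n_ics
    g <- tanh(y)
    gp <- colMeans(1 - g^2)
    W_new <- sym_decorr(crossprod(g, z) / n - diag(gp, n_ics) %*% W)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("ICA fixed-point iteration did not converge; returning best iterate")

  # order by non-Gaussianity, then fix signs on the feature-space unmixing
  y <- z %*% t(W)
  ord <- order(logcosh_negentropy(y), decreasing = TRUE)
  W <- W[ord, , drop = FALSE]
  unmixing <- K %*% t(W)             # features x n_ics
  for (j in seq_len(n_ics)) {
    i <- which.max(abs(unmixing[, j]))
    if (unmixing[i, j] < 0) {
      unmixing[, j] <- -unmixing[, j]
      W[j, ] <- -W[j, ]
    }
  }
  mixing <- t(MASS_ginv(unmixing))   # features x n_ics: xc ~ y %*% t(mixing)
  structure(list(center = center, whitening = K, W = W, unmixing = unmixing,
                 mixing = mixing, n_ics = n_ics,
                 converged = converged, iterations = it),
            class = "ica_model")
}

# Moore-Penrose pseudo-inverse (small dense case).
MASS_ginv <- function(a, tol = 1e-10) {
  s <- svd(a)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*%
    t(s$u[, pos, drop = FALSE])
}

#' Transform data with a fitted ICA model
#'
#' `y = W' K' (x - center)`: applies the training whitening and unmixing to
#' new rows, yielding independent-component scores (near unit variance on
#' the training rows).
#'
#' @param model an `ica_model`.
#' @param x matrix with the same feature columns as the fit data.
#' @return samples x n_ics matrix of class `fused_features` with an
#'   `ic_provenance` attribute naming the input columns.
#' @export
transform_ica <- function(model, x) {
  stopifnot(inherits(model, "ica_model"))
  if (ncol(x) != length(model$center)) stop("feature count does not match model")
  y <- sweep(x, 2, model$center) %*% model$unmixing
  colnames(y) <- paste0("IC", seq_len(model$n_ics))
  attr(y, "ic_provenance") <- names(model$center)
  class(y) <- c("fused_features", class(y))
  y
}

#' Serialize a PCA or ICA model to JSON
#'
#' @param model a `pca_model` or `ica_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- lapply(unclass(model), function(v) if (is.matrix(v)) unclass(v) else v)
  obj$.class <- class(model)[1]
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
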