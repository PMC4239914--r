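# BP_AdaBoost: an AdaBoost ensemble whose weak predictors are small 3-layer
# backpropagation networks.
#
# Per boosting round t: draw m training rows by weighted resampling from the
# distribution D_t, train a BP network, flag every training sample whose
# prediction deviates from its dummy-coded target by more than the error
# threshold, sum the flagged samples' distribution weights into the round
# error e_t, give the round the vote weight a_t = 0.5 * ln((1 - e_t) / e_t),
# multiply the flagged samples' weights by the adjustment factor k and
# renormalize. The strong predictor averages the weak networks' outputs with
# weights a_t; a sample whose winning class score does not exceed the cutoff
# stays unassigned.

#' Weak-learner and boosting configuration
#'
#' Defaults follow the calibrated monitoring model: 10 hidden neurons,
#' learning rate 0.1, momentum 0.1, initial weights uniform on
#' \[-0.3, 0.3\], sigmoid activations, permitted training MSE 0.01, at most
#' 50 training epochs; boosting uses error threshold 0.2, adjustment factor
#' k = 1.1 and (by default) 10 rounds.
#'
#' @param hidden hidden-layer size.
#' @param lr learning-rate factor in (0, 1].
#' @param momentum momentum factor in (0, 1].
#' @param init_bound initial weights drawn uniformly from
#'   `[-init_bound, init_bound]`.
#' @param target_mse permitted training error (MSE); training stops early
#'   when reached.
#' @param max_epochs maximum training epochs (>= 1).
#' @param err_threshold per-sample deviation above which a sample counts as
#'   mispredicted in a round.
#' @param k distribution-weight adjustment factor for mispredicted samples.
#' @param err_rule how the per-sample deviation is judged: `"max"` (largest
#'   absolute output deviation, default), `"mean"`, or `"argmax"`
#'   (class mismatch).
#' @param update_rule `"multiplicative"` (bump flagged weights by `k`, then
#'   renormalize; default) or `"exponential"` (classic
#'   `D * exp(-a_t * agreement) / B_t` with agreement +1/-1 from the flag).
#' @param eps clamp for the round error: `e_t` is forced into
#'   `[eps, 0.5 - eps]` before the vote weight.
#' @return an object of class `bp_config`.
#' @export
bp_config <- function(hidden = 10L, lr = 0.1, momentum = 0.1,
                      init_bound = 0.3, target_mse = 0.01, max_epochs = 50L,
                      err_threshold = 0.2, k = 1.1,
                      err_rule = c("max", "mean", "argmax"),
                      update_rule = c("multiplicative", "exponential"),
                      eps = 1e-10) {
  err_rule <- match.arg(err_rule)
  update_rule <- match.arg(update_rule)
  if (lr <= 0 || lr > 1 || momentum <= 0 || momentum > 1)
    stop("learning rate and momentum must be in (0, 1]")
  if (max_epochs < 1) stop("max_epochs must be at least 1")
  if (hidden < 1) stop("hidden must be at least 1")
  structure(list(hidden = as.integer(hidden), lr = lr, momentum = momentum,
                 init_bound = init_bound, target_mse = target_mse,
                 max_epochs = as.integer(max_epochs),
                 err_threshold = err_threshold, k = k, err_rule = err_rule,
                 update_rule = update_rule, eps = eps),
            class = "bp_config")
}

#' One-of-c dummy coding of day labels
#'
#' @param days integer day labels.
#' @param levels the full ordered label set (default `0:6`).
#' @return samples x length(levels) 0/1 target matrix.
#' @export
encode_labels <- function(days, levels = 0:6) {
  if (!all(days %in% levels)) stop("unseen label: ", paste(setdiff(days, levels), collapse = ", "))
  y <- matrix(0, length(days), length(levels),
              dimnames = list(NULL, paste0("day", levels)))
  y[cbind(seq_along(days), match(days, levels))] <- 1
  y
}

#' Decode a dummy-coded (or real-valued score) matrix back to labels
#'
#' @param y matrix of per-class targets or scores.
#' @param levels ordered label set (default `0:6`).
#' @return vector of labels (argmax per row; ties to the lowest class index).
#' @export
decode_labels <- function(y, levels = 0:6) {
  levels[max.col(y, ties.method = "first")]
}

#' Train one weak BP network
#'
#' A 3-layer sigmoid network trained by sequential gradient descent with
#' momentum (sigmoid delta rule at the output), stopping when the full-set
#' training MSE reaches `cfg$target_mse` or after `cfg$max_epochs` epochs.
#' Initial weights are uniform on `[-init_bound, init_bound]` from `seed`.
#' If `row_weights` is given, the network is trained on `m` rows resampled
#' with replacement with those probabilities (AdaBoost's "select m group
#' training samples"); the stopping MSE is measured on the resampled set.
#'
#' @param x samples x features input matrix.
#' @param y samples x classes target matrix.
#' @param cfg a [bp_config()].
#' @param row_weights optional resampling distribution over rows (sums to 1).
#' @param seed integer seed (initial weights, presentation order, resampling).
#' @return an object of class `bp_net` with weight matrices `W1`, `b1`,
#'   `W2`, `b2`, final `mse` and `epochs` used.
#' @export
train_bp <- function(x, y, cfg = bp_config(), row_weights = NULL, seed = 1L) {
  stopifnot(is.matrix(x), is.matrix(y), nrow(x) == nrow(y))
  if (anyNA(x) || anyNA(y)) stop("NaN/NA in training data")
  m <- nrow(x)
  if (!is.null(row_weights)) {
    if (length(row_weights) != m) stop("row_weights length mismatch")
    if (abs(sum(row_weights) - 1) > 1e-8) stop("row_weights must sum to 1")
    idx <- with_seed(substream_seed(seed, "resample"),
                     sample.int(m, m, replace = TRUE, prob = row_weights))
    x <- x[idx, , drop = FALSE]
    y <- y[idx, , drop = FALSE]
  }
  p <- ncol(x); q <- ncol(y); h <- cfg$hidden
  init <- with_seed(substream_seed(seed, "init"), {
    list(W1 = matrix(runif(p * h, -cfg$init_bound, cfg$init_bound), p, h),
         b1 = runif(h, -cfg$init_bound, cfg$init_bound),
         W2 = matrix(runif(h * q, -cfg$init_bound, cfg$init_bound), h, q),
         b2 = runif(q, -cfg$init_bound, cfg$init_bound))
  })
  order <- with_seed(substream_seed(seed, "order"), {
    t(vapply(seq_len(cfg$max_epochs), function(e) sample.int(m), integer(m)))
  })
  fit <- bp_train_cpp(x, y, init$W1, init$b1, init$W2, init$b2, order,
                      cfg$lr, cfg$momentum, cfg$target_mse, cfg$max_epochs)
  structure(c(fit, list(p = p, q = q)), class = "bp_net")
}

#' Forward pass of a weak BP network
#'
#' @param object a `bp_net`.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @return samples x classes matrix of sigmoid outputs in (0, 1).
#' @export
predict.bp_net <- function(object, newdata, ...) {
  if (ncol(newdata) != object$p) stop("feature dimension mismatch")
  bp_predict_cpp(newdata, object$W1, object$b1, object$W2, object$b2)
}

#' Round error of a weak predictor under the current distribution
#'
#' Flags sample `i` when its prediction deviates from the dummy-coded target
#' by more than `threshold` (by default the maximum absolute output
#' deviation); the round error is the sum of the flagged samples'
#' distribution weights.
#'
#' @param d distribution over training samples (sums to 1).
#' @param y targets matrix.
#' @param yhat predicted outputs matrix.
#' @param threshold deviation threshold (default 0.2).
#' @param rule `"max"`, `"mean"` or `"argmax"` deviation rule.
#' @return list with `e` (round error) and `flags` (logical vector).
#' @export
weak_error <- function(d, y, yhat, threshold = 0.2,
                       rule = c("max", "mean", "argmax")) {
  rule <- match.arg(rule)
  stopifnot(length(d) == nrow(y), all(dim(y) == dim(yhat)))
  flags <- switch(rule,
    max    = apply(abs(y - yhat), 1, max) > threshold,
    mean   = rowMeans(abs(y - yhat)) > threshold,
    argmax = max.col(y, ties.method = "first") !=
             max.col(yhat, ties.method = "first"))
  list(e = sum(d[flags]), flags = flags)
}

#' Vote weight of a boosting round
#'
#' `a_t = 0.5 * ln((1 - e_t) / e_t)`, with `e_t` clamped into
#' `[eps, 1 - eps]` so the weight stays finite at the endpoints. The sign
#' follows the round error: positive iff `e < 0.5`. The boosting loop
#' additionally caps `e_t` at `0.5 - eps` before calling, so a failed round
#' enters the ensemble with a vote of (approximately) zero rather than a
#' negative one.
#'
#' @param e round error in \[0, 1\].
#' @param eps clamp width (default 1e-10).
#' @return the vote weight `a_t` (finite; positive iff `e < 0.5`).
#' @export
vote_weight <- function(e, eps = 1e-10) {
  # allow float drift when e is a sum of distribution weights
  if (e < -1e-9 || e > 1 + 1e-9) stop("round error must be in [0, 1]")
  e <- min(max(e, eps), 1 - eps)
  0.5 * log((1 - e) / e)
}

#' Update the sample-weight distribution
#'
#' Multiplies flagged (mispredicted) samples' weights by the adjustment
#' factor `k`, then divides by the normalization factor `B_t` so the
#' distribution sums to 1 again.
#'
#' @param d current distribution (sums to 1).
#' @param flags logical misprediction flags.
#' @param k adjustment factor (default 1.1).
#' @return the updated distribution.
#' @export
update_distribution <- function(d, flags, k = 1.1) {
  if (length(d) == 0) stop("empty distribution")
  stopifnot(length(flags) == length(d))
  d2 <- ifelse(flags, k * d, d)
  d2 / sum(d2)
}

# exponential alternative (classic AdaBoost form): agreement coded +1/-1
update_distribution_exp <- function(d, flags, a) {
  d2 <- d * exp(-a * ifelse(flags, -1, 1))
  d2 / sum(d2)
}

#' Train the BP_AdaBoost strong predictor
#'
#' Runs the boosting loop for `rounds` rounds: weighted resampling by the
#' current distribution, weak BP training, round-error and vote-weight
#' computation, distribution update. The full distribution trace and all
#' round errors and vote weights are retained.
#'
#' @param x samples x features matrix.
#' @param days integer day labels.
#' @param cfg a [bp_config()].
#' @param rounds number of boosting rounds T (default 10).
#' @param seed master seed; per-round seeds are derived substreams.
#' @param levels ordered label set (default `0:6`).
#' @return an object of class `strong_predictor`: weak `nets`, vote weights
#'   `a`, round errors `e`, distribution trace `d_trace`
#'   ((rounds + 1) x m), `levels`, `cutoff`.
#' @export
train_ensemble <- function(x, days, cfg = bp_config(), rounds = 10L,
                           seed = 1L, levels = 0:6) {
  stopifnot(is.matrix(x))
  if (length(unique(days)) < 2) stop("need at least 2 classes to boost")
  y <- encode_labels(days, levels)
  m <- nrow(x)
  d <- rep(1 / m, m)
  nets <- vector("list", rounds)
  a <- e <- numeric(rounds)
  d_trace <- matrix(NA_real_, rounds + 1, m)
  d_trace[1, ] <- d
  for (t in seq_len(rounds)) {
    nets[[t]] <- train_bp(x, y, cfg, row_weights = d,
                          seed = substream_seed(seed, "round", t))
    yhat <- predict(nets[[t]], x)
    we <- weak_error(d, y, yhat, cfg$err_threshold, cfg$err_rule)
    e[t] <- we$e
    if (we$e >= 0.5 - cfg$eps)
      warning(sprintf("round %d: error %.3f clamps at 0.5; vote weight ~ 0", t, we$e))
    a[t] <- vote_weight(min(we$e, 0.5 - cfg$eps), cfg$eps)
    d <- if (cfg$update_rule == "exponential")
      update_distribution_exp(d, we$flags, a[t])
    else
      update_distribution(d, we$flags, cfg$k)
    d_trace[t + 1, ] <- d
  }
  structure(list(nets = nets, a = a, e = e, d_trace = d_trace,
                 levels = levels, cutoff = 0.5, cfg = cfg, rounds = rounds),
            class = "strong_predictor")
}

#' Predict fermentation day with the strong predictor
#'
#' Per-class score is the vote-weight-normalized average of the weak
#' networks' outputs, `sum_t a_t yhat_t(x) / sum_t a_t`. The predicted class
#' is the argmax (ties broken toward the lower class index); when the
#' winning score does not exceed the cutoff (0.5) the sample is left
#' unassigned (`NA`), which evaluation counts as misclassified.
#'
#' @param object a `strong_predictor`.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @return list with `label` (day labels, `NA` = unassigned) and `scores`
#'   (samples x classes matrix).
#' @export
predict.strong_predictor <- function(object, newdata, ...) {
  if (length(object$nets) == 0) stop("empty ensemble")
  if (sum(object$a) <= 0) stop("ensemble has no positive total vote weight")
  scores <- 0
  for (t in seq_along(object$nets))
    scores <- scores + object$a[t] * predict(object$nets[[t]], newdata)
  scores <- scores / sum(object$a)
  win <- max.col(scores, ties.method = "first")
  label <- object$levels[win]
  label[scores[cbind(seq_len(nrow(scores)), win)] <= object$cutoff] <- NA
  list(label = label, scores = scores)
}

#' @export
print.strong_predictor <- function(x, ...) {
  cat(sprintf("BP_AdaBoost strong predictor: %d weak BP networks (%d hidden units)\n",
              length(x$nets), x$cfg$hidden))
  cat("  round errors e_t:  ", paste(sprintf("%.3f", x$e), collapse = " "), "\n")
  cat("  vote weights a_t:  ", paste(sprintf("%.3f", x$a), collapse = " "), "\n")
  invisible(x)
}

#' Serialize a strong predictor to JSON
#'
#' @param strong a `strong_predictor`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(strong, path) {
  obj <- list(a = strong$a, e = strong$e, levels = strong$levels,
              cutoff = strong$cutoff, cfg = unclass(strong$cfg),
              nets = lapply(strong$nets, function(n)
                list(W1 = unclass(n$W1), b1 = n$b1,
                     W2 = unclass(n$W2), b2 = n$b2)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Per-round training log as a data frame
#'
#' @param strong a `strong_predictor`.
#' @return data frame with columns `round`, `e_t`, `a_t`.
#' @export
training_log <- function(strong) {
  data.frame(round = seq_along(strong$e), e_t = strong$e, a_t = strong$a)
}
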