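# End-to-end orchestration: run-based train/validation split, leave-one-out
# cross-validated selection of component counts by the first-local-maximum
# rule, and the three-way model comparison (e-nose only, NIRS only, fusion).

#' Split samples into training and validation sets by fermentation run
#'
#' The model is calibrated on whole runs and validated on a held-out run, so
#' validation stresses between-run variation. Under the default 4-run design
#' the first three runs give 105 training samples and the last run the 35
#' validation samples.
#'
#' @param manifest data frame with columns `sample_id`, `run`, `day`.
#' @param train_runs run ids forming the training set (default `1:3`).
#' @return list with `train` and `validation` sample-id vectors (disjoint).
#' @export
split_by_run <- function(manifest, train_runs = 1:3) {
  stopifnot(all(c("sample_id", "run") %in% names(manifest)))
  if (!all(train_runs %in% manifest$run))
    stop("unknown run id in train_runs: ",
         paste(setdiff(train_runs, manifest$run), collapse = ", "))
  tr <- manifest$sample_id[manifest$run %in% train_runs]
  va <- manifest$sample_id[!manifest$run %in% train_runs]
  if (length(va) == 0) warning("validation set is empty: all runs are training runs")
  list(train = tr, validation = va)
}

#' Leave-one-out cross-validated identification rate
#'
#' For each training sample: hold it out, train a BP_AdaBoost ensemble on
#' the remaining samples, and identify the held-out sample; the rate is
#' `100 * correct / m`. Feature extraction is not refit per fold -- the
#' cross-validation selects the classifier's input dimensionality on
#' already-extracted scores. An unassigned prediction counts as an error; a
#' fold whose remainder loses all but one class is counted as an error with
#' a warning.
#'
#' @param x samples x features score matrix (training rows).
#' @param days integer day labels.
#' @param cfg a [bp_config()].
#' @param rounds boosting rounds per fold.
#' @param seed master seed; per-fold seeds are derived substreams.
#' @param levels ordered label set (default `0:6`).
#' @return identification rate in percent (full precision).
#' @export
loocv_rate <- function(x, days, cfg = bp_config(), rounds = 10L, seed = 1L,
                       levels = 0:6) {
  stopifnot(is.matrix(x), nrow(x) == length(days))
  m <- nrow(x)
  if (m < 2) stop("need at least 2 samples for leave-one-out")
  correct <- 0L
  for (i in seq_len(m)) {
    rest_days <- days[-i]
    if (length(unique(rest_days)) < 2) {
      warning(sprintf("fold %d: fewer than 2 classes remain; counted as error", i))
      next
    }
    fit <- train_ensemble(x[-i, , drop = FALSE], rest_days, cfg, rounds,
                          seed = substream_seed(seed, "fold", i),
                          levels = levels)
    pred <- predict(fit, x[i, , drop = FALSE])$label
    if (!is.na(pred) && pred == days[i]) correct <- correct + 1L
  }
  100 * correct / m
}

#' Select a component count at the first local maximum of a rate curve
#'
#' The chosen count is the smallest candidate whose rate strictly exceeds
#' its predecessor's and is at least its successor's (rates before the first
#' and after the last candidate are taken as -Inf, so a plateau's first
#' point qualifies). If no local maximum exists the global maximum is the
#' fallback.
#'
#' @param rates identification rates (percent), one per candidate.
#' @param candidates ascending candidate component counts.
#' @return an object of class `selection_curve`: `candidates`, `rates`,
#'   `chosen`.
#' @export
select_components <- function(rates, candidates = seq_along(rates)) {
  if (length(candidates) == 0) stop("empty candidate list")
  stopifnot(length(rates) == length(candidates), !is.unsorted(candidates))
  n <- length(rates)
  prev <- c(-Inf, rates[-n])
  nxt <- c(rates[-1], -Inf)
  local <- which(rates > prev & rates >= nxt)
  chosen <- if (length(local)) candidates[local[1]] else candidates[which.max(rates)]
  structure(list(candidates = candidates, rates = rates, chosen = chosen),
            class = "selection_curve")
}

#' @export
print.selection_curve <- function(x, ...) {
  cat("Component selection (first local maximum rule):\n")
  print(data.frame(n = x$candidates, rate = round_half_up(x$rates, 2)))
  cat("chosen:", x$chosen, "\n")
  invisible(x)
}

#' Evaluate predictions against true day labels
#'
#' @param pred predicted day labels (`NA` = unassigned).
#' @param truth true day labels.
#' @param levels ordered label set (default `0:6`).
#' @param model optional model descriptor string.
#' @return an `evaluation_report`: `confusion` (classes x classes + an
#'   `unassigned` column), `per_class` rates (%), `overall` rate (%),
#'   `correct`, `total`.
#' @export
evaluate_predictions <- function(pred, truth, levels = 0:6, model = NULL) {
  stopifnot(length(pred) == length(truth))
  nl <- length(levels)
  conf <- matrix(0L, nl, nl + 1,
                 dimnames = list(paste0("day", levels),
                                 c(paste0("day", levels), "unassigned")))
  for (i in seq_along(truth)) {
    r <- match(truth[i], levels)
    c <- if (is.na(pred[i])) nl + 1 else match(pred[i], levels)
    conf[r, c] <- conf[r, c] + 1L
  }
  correct <- sum(diag(conf[, seq_len(nl)]))
  per_class_n <- rowSums(conf)
  per_class <- ifelse(per_class_n > 0,
                      round_half_up(100 * diag(conf[, seq_len(nl)]) / per_class_n, 2),
                      NA_real_)
  structure(list(confusion = conf, per_class = per_class,
                 overall = identification_rate(correct, length(truth)),
                 correct = correct, total = length(truth), model = model),
            class = "evaluation_report")
}

#' Evaluate a fitted strong predictor on labelled data
#'
#' @param strong a `strong_predictor`.
#' @param x samples x features matrix.
#' @param days true day labels.
#' @param model optional model descriptor string.
#' @return an `evaluation_report` (see [evaluate_predictions()]).
#' @export
evaluate <- function(strong, x, days, model = NULL) {
  pred <- predict(strong, x)$label
  evaluate_predictions(pred, days, levels = strong$levels, model = model)
}

#' @export
print.evaluation_report <- function(x, ...) {
  if (!is.null(x$model)) cat("Model:", x$model, "\n")
  cat(sprintf("Identification rate: %d/%d = %.2f%%\n", x$correct, x$total, x$overall))
  print(x$confusion)
  invisible(x)
}

#' Run the full monitoring study: single-technique and fusion models
#'
#' Executes the complete architecture on a synthetic fermentation study:
#' per-modality preprocessing (maximum sensor response; SNV), column
#' standardization fitted on training rows, per-modality PCA with the PC
#' count selected by leave-one-out cross-validation (first local maximum),
#' concatenation of the selected PC scores, ICA fusion with the IC count
#' selected the same way, and BP_AdaBoost ensembles for the e-nose-only,
#' NIRS-only and fused feature sets, each evaluated on the training and the
#' held-out-run validation sets.
#'
#' @param seed master seed driving data generation, cross-validation folds
#'   and ensemble training.
#' @param design,trajectories,sensors,spectra generator settings
#'   (see [generate_study()]).
#' @param modality_split split analyte visibility across modalities
#'   (default `TRUE`).
#' @param cfg a [bp_config()].
#' @param rounds boosting rounds (default 10).
#' @param pc_candidates candidate PC counts per modality (default `1:10`).
#' @param input_scale standard deviation given to each classifier input
#'   column (default 3): the sigmoid networks resolve the 7 classes packed
#'   along a component axis better when the axis spans a few units.
#' @param ic_candidates candidate IC counts; default 1 up to the total
#'   number of concatenated selected PCs.
#' @param train_runs run ids for the training set (default `1:3`).
#' @param study optionally, a pre-generated `ssf_study` to analyse instead
#'   of generating one from `seed`.
#' @param verbose print stage progress (default `FALSE`).
#' @return an object of class `study_report`: `report` (one row per model:
#'   latent-vector count, training and validation ratios and rates),
#'   `curves` (selection curves), `reports` (full `evaluation_report`s),
#'   `models`, `split`, `seed`.
#' @export
run_study <- function(seed = 1L,
                      design = study_design(),
                      trajectories = analyte_trajectories(),
                      sensors = sensor_model(),
                      spectra = spectrum_model(),
                      modality_split = TRUE,
                      cfg = bp_config(), rounds = 10L,
                      pc_candidates = 1:10, ic_candidates = NULL,
                      input_scale = 3,
                      train_runs = 1:3, study = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(study)) {
    say("generating synthetic study (seed %d)", seed)
    study <- generate_study(design, trajectories, sensors, spectra,
                            seed = substream_seed(seed, "study"),
                            modality_split = modality_split)
  }
  manifest <- study$manifest
  levels <- sort(unique(manifest$day))
  split <- split_by_run(manifest, train_runs)
  tr <- match(split$train, manifest$sample_id)
  va <- match(split$validation, manifest$sample_id)
  days_tr <- manifest$day[tr]
  days_va <- manifest$day[va]

  # characteristic values
  feat_e <- enose_features(study$enose)
  feat_n <- snv_transform(study$spectra)
  std_e <- standardize(feat_e, fit_rows = tr)
  std_n <- standardize(feat_n, fit_rows = tr)

  modality <- function(name, z) {
    kmax <- min(max(pc_candidates), ncol(z), length(tr) - 1)
    cands <- pc_candidates[pc_candidates <= kmax]
    pca <- fit_pca(z[tr, , drop = FALSE], k = kmax)
    scores <- project_pca(pca, z)
    # classifier inputs are the normalized PC scores: z-scored per column
    # with training-row statistics (the sigmoid network needs roughly
    # unit-scale inputs); the LOOCV count selection guards against pulling
    # amplified noise components into the model
    scores_std <- standardize(scores, fit_rows = tr)$x * input_scale
    rates <- vapply(cands, function(k) {
      say("  %s: LOOCV with %d PCs", name, k)
      # one fold-seed stream shared by all candidate counts, so the
      # selection curve is a paired comparison rather than seed noise
      loocv_rate(scores_std[tr, seq_len(k), drop = FALSE], days_tr, cfg, rounds,
                 seed = substream_seed(seed, paste0("cv-", name)),
                 levels = levels)
    }, numeric(1))
    sel <- select_components(rates, cands)
    say("%s: selected %d PCs", name, sel$chosen)
    list(pca = pca, scores = scores, scores_std = scores_std, sel = sel)
  }
  say("e-nose branch")
  br_e <- modality("enose", std_e$x)
  say("NIRS branch")
  br_n <- modality("nirs", std_n$x)

  fit_and_eval <- function(name, xs, n_latent) {
    fit <- train_ensemble(xs[tr, , drop = FALSE], days_tr, cfg, rounds,
                          seed = substream_seed(seed, paste0("final-", name)),
                          levels = levels)
    list(fit = fit,
         train = evaluate(fit, xs[tr, , drop = FALSE], days_tr,
                          model = sprintf("%s (%d latent vectors), training set", name, n_latent)),
         valid = evaluate(fit, xs[va, , drop = FALSE], days_va,
                          model = sprintf("%s (%d latent vectors), validation set", name, n_latent)))
  }
  say("final single-technique models")
  mod_e <- fit_and_eval("electronic nose",
                        br_e$scores_std[, seq_len(br_e$sel$chosen), drop = FALSE],
                        br_e$sel$chosen)
  mod_n <- fit_and_eval("NIRS",
                        br_n$scores_std[, seq_len(br_n$sel$chosen), drop = FALSE],
                        br_n$sel$chosen)

  # fusion branch: ICA on the concatenated selected PC scores. The
  # normalized scores are fused: the raw NIRS scores carry an order of
  # magnitude more variance than the e-nose scores (1557 vs 11 input
  # features), and unnormalized concatenation would make the whitening
  # step discard the e-nose directions wholesale.
  concat <- concat_features(br_e$scores_std[, seq_len(br_e$sel$chosen), drop = FALSE],
                            br_n$scores_std[, seq_len(br_n$sel$chosen), drop = FALSE])
  p_tot <- ncol(concat)
  if (is.null(ic_candidates)) ic_candidates <- seq_len(p_tot)
  ic_candidates <- ic_candidates[ic_candidates <= p_tot]
  ica_fits <- list()
  ic_rates <- vapply(ic_candidates, function(n) {
    say("  fusion: LOOCV with %d ICs", n)
    ica <- fit_ica(concat[tr, , drop = FALSE], n,
                   seed = substream_seed(seed, "ica", n))
    ica_fits[[as.character(n)]] <<- ica
    y <- unclass(transform_ica(ica, concat[tr, , drop = FALSE])) * input_scale
    loocv_rate(y, days_tr, cfg, rounds,
               seed = substream_seed(seed, "cv-fusion"), levels = levels)
  }, numeric(1))
  sel_ic <- select_components(ic_rates, ic_candidates)
  say("fusion: selected %d ICs", sel_ic$chosen)
  ica <- ica_fits[[as.character(sel_ic$chosen)]]
  fused <- unclass(transform_ica(ica, concat)) * input_scale
  mod_f <- fit_and_eval("fusion", fused, sel_ic$chosen)

  report <- data.frame(
    model = c("NIRS", "Electronic nose", "Fusion"),
    latent_vectors = c(br_n$sel$chosen, br_e$sel$chosen, sel_ic$chosen),
    train_correct = c(mod_n$train$correct, mod_e$train$correct, mod_f$train$correct),
    train_total = rep(length(tr), 3),
    train_rate = c(mod_n$train$overall, mod_e$train$overall, mod_f$train$overall),
    valid_correct = c(mod_n$valid$correct, mod_e$valid$correct, mod_f$valid$correct),
    valid_total = rep(length(va), 3),
    valid_rate = c(mod_n$valid$overall, mod_e$valid$overall, mod_f$valid$overall)
  )
  structure(list(report = report,
                 curves = list(enose = br_e$sel, nirs = br_n$sel, fusion = sel_ic),
                 reports = list(enose = mod_e[c("train", "valid")],
                                nirs = mod_n[c("train", "valid")],
                                fusion = mod_f[c("train", "valid")]),
                 models = list(enose = mod_e$fit, nirs = mod_n$fit,
                               fusion = mod_f$fit, ica = ica,
                               pca_enose = br_e$pca, pca_nirs = br_n$pca),
                 split = split, seed = seed),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("SSF monitoring study: model comparison\n")
  df <- x$report
  df$train <- sprintf("%d/%d (%.2f%%)", df$train_correct, df$train_total, df$train_rate)
  df$valid <- sprintf("%d/%d (%.2f%%)", df$valid_correct, df$valid_total, df$valid_rate)
  print(df[, c("model", "latent_vectors", "train", "valid")], row.names = FALSE)
  invisible(x)
}

#' Write a study report as CSV and JSON
#'
#' @param x a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(x$report, file.path(dir, "comparison.csv"), row.names = FALSE)
  for (nm in names(x$curves)) {
    cv <- x$curves[[nm]]
    write.csv(data.frame(n = cv$candidates, rate = cv$rates, chosen = cv$chosen),
              file.path(dir, sprintf("selection_%s.csv", nm)), row.names = FALSE)
  }
  jsonlite::write_json(
    list(report = x$report, seed = x$seed,
         confusion_fusion_train = unclass(x$reports$fusion$train$confusion),
         confusion_fusion_valid = unclass(x$reports$fusion$valid$confusion)),
    file.path(dir, "report.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
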