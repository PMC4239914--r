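test_that("dummy coding is a one-of-seven bijection", {
  y <- encode_labels(c(3, 0, 6))
  expect_equal(y[1, ], c(0, 0, 0, 1, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(rowSums(y), rep(1, 3), ignore_attr = TRUE)
  days <- sample(0:6, 30, replace = TRUE)
  expect_equal(decode_labels(encode_labels(days)), days)
  expect_error(encode_labels(c(1, 7)), "unseen label")
})

test_that("configuration enforces the weak-learner parameter ranges", {
  cfg <- bp_config()
  expect_equal(cfg$hidden, 10L)
  expect_equal(cfg$lr, 0.1)
  expect_equal(cfg$max_epochs, 50L)
  expect_error(bp_config(max_epochs = 0), "max_epochs")
  expect_error(bp_config(lr = 0), "learning rate")
})

test_that("weak BP nets reach the permitted training error on a wide-margin toy", {
  toy <- toy_two_class()
  ok <- 0
  for (s in 1:10) {
    net <- train_bp(toy$x, toy$y, seed = s)
    if (net$mse <= 0.01) ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("weak BP training is deterministic and rejects bad input", {
  toy <- toy_two_class()
  n1 <- train_bp(toy$x, toy$y, seed = 7)
  n2 <- train_bp(toy$x, toy$y, seed = 7)
  expect_identical(n1$W1, n2$W1)
  expect_identical(n1$W2, n2$W2)
  n3 <- train_bp(toy$x, toy$y, seed = 8)
  expect_false(identical(n1$W1, n3$W1))
  bad <- toy$x; bad[1, 1] <- NA
  expect_error(train_bp(bad, toy$y), "NaN/NA")
  expect_error(train_bp(toy$x, toy$y, row_weights = c(1, 1, 1, 1)), "sum to 1")
})

test_that("round error sums distribution weights over flagged samples", {
  y <- diag(4)
  yhat <- y
  yhat[1, 1] <- 0.5                       # deviation 0.5 > 0.2 for sample 1
  d <- rep(0.25, 4)
  we <- weak_error(d, y, yhat)
  expect_equal(we$e, 0.25)
  expect_equal(we$flags, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(weak_error(d, y, y)$e, 0)
  expect_equal(weak_error(d, y, 1 - y)$e, 1)
  # argmax rule flags only class mismatches
  soft <- y * 0.6 + 0.1
  expect_equal(weak_error(d, y, soft, rule = "argmax")$e, 0)
  expect_equal(weak_error(d, y, soft, rule = "max")$e, 1)
})

test_that("vote weight follows a = log((1 - e) / e) / 2 with clamping", {
  expect_equal(vote_weight(0.5), 0, tolerance = 1e-9)
  expect_equal(vote_weight(0.1), 0.5 * log(9))
  expect_true(is.finite(vote_weight(0)))
  expect_gt(vote_weight(0), 10)
  expect_error(vote_weight(1.5), "round error")
  # sign: positive iff e < 0.5
  expect_gt(vote_weight(0.3), 0)
  expect_lt(vote_weight(0.7), 0)
})

test_that("distribution update bumps flagged weights by k and renormalizes", {
  d <- rep(0.25, 4)
  d2 <- update_distribution(d, c(TRUE, FALSE, FALSE, FALSE), k = 1.1)
  expect_equal(d2, c(0.2683, 0.2439, 0.2439, 0.2439), tolerance = 1e-4)
  expect_equal(sum(d2), 1, tolerance = 1e-12)
  expect_equal(update_distribution(d, rep(FALSE, 4)), d)
  expect_error(update_distribution(numeric(0), logical(0)), "empty")
})

test_that("the ensemble conserves its distribution and ranks flagged samples up", {
  study <- small_study(seed = 17)
  fe <- standardize(enose_features(study$enose))$x
  days <- study$manifest$day
  fit <- suppressWarnings(train_ensemble(fe, days, rounds = 5, seed = 2))
  expect_equal(rowSums(fit$d_trace), rep(1, 6), tolerance = 1e-12)
  # within a round the per-sample ratio D'/D takes two levels, k/B for
  # flagged and 1/B for unflagged, so flagged weights never fall behind
  for (t in 1:5) {
    ratio <- fit$d_trace[t + 1, ] / fit$d_trace[t, ]
    two_level <- abs(ratio - max(ratio)) < 1e-9 | abs(ratio - min(ratio)) < 1e-9
    expect_true(all(two_level))
    expect_lte(max(ratio) / min(ratio), 1.1 + 1e-9)
  }
  # full reproducibility from (data, config, seed)
  fit2 <- suppressWarnings(train_ensemble(fe, days, rounds = 5, seed = 2))
  expect_identical(fit$a, fit2$a)
  expect_identical(fit$nets[[3]]$W1, fit2$nets[[3]]$W1)
  expect_error(train_ensemble(fe, rep(1, nrow(fe))), "2 classes")
})

test_that("a single-round ensemble decides exactly like its weak predictor", {
  study <- small_study(seed = 23)
  fe <- standardize(enose_features(study$enose))$x
  days <- study$manifest$day
  fit <- suppressWarnings(train_ensemble(fe, days, rounds = 1, seed = 9))
  pred <- predict(fit, fe)
  weak_out <- predict(fit$nets[[1]], fe)
  expect_equal(pred$scores, weak_out, ignore_attr = TRUE)
  expect_equal(max.col(pred$scores, ties.method = "first"),
               max.col(weak_out, ties.method = "first"))
})

test_that("strong prediction averages weak votes with cutoff and tie rules", {
  net1 <- constant_net(c(0.9, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1))
  s1 <- crafted_strong(list(net1), a = 1)
  x <- matrix(0, 2, 2)
  p <- predict(s1, x)
  expect_equal(p$label, c(0, 0))
  expect_equal(p$scores[1, 1], 0.9)
  # two equal-weight nets voting for different classes tie at 0.5 -> unassigned
  net_a <- constant_net(c(0.9999999, rep(1e-7, 6)))
  net_b <- constant_net(c(1e-7, 0.9999999, rep(1e-7, 5)))
  tie <- crafted_strong(list(net_a, net_b), a = c(1, 1))
  expect_true(all(is.na(predict(tie, x)$label)))
  # scores invariant to rescaling all vote weights
  scaled <- crafted_strong(list(net_a, net_b), a = c(10, 10))
  expect_equal(predict(scaled, x)$scores, predict(tie, x)$scores)
  expect_error(predict(crafted_strong(list(), numeric(0)), x), "empty ensemble")
})

test_that("boosting keeps or improves the training fit from 1 to 10 rounds", {
  study <- generate_study(design = study_design(3, 7, 3),
                          trajectories = analyte_trajectories(rep_noise_sd = 0.15),
                          seed = 300)
  z <- standardize(enose_features(study$enose))$x
  sc <- standardize(project_pca(fit_pca(z, 3), z))$x * 3
  days <- study$manifest$day
  r1 <- r10 <- numeric(6)
  for (s in 1:6) {
    f1 <- suppressWarnings(train_ensemble(sc, days, rounds = 1, seed = s))
    f10 <- suppressWarnings(train_ensemble(sc, days, rounds = 10, seed = s))
    r1[s] <- evaluate(f1, sc, days)$overall
    r10[s] <- evaluate(f10, sc, days)$overall
  }
  expect_gte(median(r10), median(r1))
})

test_that("ensembles serialize with their training log", {
  toy <- toy_two_class()
  fit <- suppressWarnings(
    train_ensemble(toy$x, toy$days, rounds = 2, seed = 1, levels = 0:1))
  log <- training_log(fit)
  expect_equal(names(log), c("round", "e_t", "a_t"))
  expect_equal(nrow(log), 2)
  path <- file.path(withr::local_tempdir(), "model.json")
  write_ensemble(fit, path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_equal(unlist(obj$a), fit$a, tolerance = 1e-12)
  expect_equal(length(obj$nets), 2)
})
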