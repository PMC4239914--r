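test_that("study design validates counts and yields the full factorial", {
  d <- study_design()
  expect_equal(d$n_runs * d$n_days * d$n_reps, 140)
  expect_error(study_design(0, 7, 5), "invalid design")
  expect_error(study_design(4, 7, 1.5), "invalid design")

  study <- generate_study(design = study_design(1, 1, 1), seed = 3)
  expect_equal(nrow(study$manifest), 1)
  expect_equal(study$manifest$day, 0)
  expect_equal(study$manifest$run, 1)
})

test_that("default study has 140 samples, one recording and spectrum each", {
  study <- small_study()
  n <- nrow(study$manifest)
  expect_equal(length(study$enose), n)
  expect_equal(nrow(study$spectra), n)
  expect_equal(ncol(study$spectra), 1557)
  expect_true(all(study$manifest$run %in% 1:3))
  expect_true(all(study$manifest$day %in% 0:6))
  expect_false(any(duplicated(study$manifest$sample_id)))
})

test_that("generation is bitwise deterministic for a fixed seed", {
  a <- small_study(seed = 99)
  b <- small_study(seed = 99)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$enose, b$enose)
  expect_identical(a$manifest, b$manifest)
  c <- small_study(seed = 100)
  expect_false(identical(a$spectra, c$spectra))
})

test_that("trajectories are monotone with the stationary-phase plateau", {
  traj <- analyte_trajectories()
  vals <- sapply(0:6, function(d) trajectory_value(traj, d))  # analytes x days
  gaps <- abs(vals[, -1] - vals[, -7])                        # analytes x 6
  # monotone in day for each analyte
  expect_true(all(vals[, -1] - vals[, -7] > 0))
  # day-5 -> day-6 change is strictly the smallest adjacent-day change
  for (a in seq_len(nrow(gaps)))
    expect_true(all(gaps[a, 6] < gaps[a, 1:5]))
  # plateau: day 5 and day 6 differ by < 5% of each analyte's range
  range <- traj$params$ceiling - traj$params$floor
  expect_true(all(gaps[, 6] / range < 0.05))
})

test_that("analyte concentrations follow logistic + run effect + noise, floored", {
  traj <- analyte_trajectories(run_effect_sd = 0, rep_noise_sd = 0)
  # at the midpoint day the noiseless value is (floor + ceiling) / 2
  mid <- traj$params$midpoint[1]
  v <- logistic_mid <- trajectory_value(traj, mid)[1]
  expect_equal(v, (traj$params$floor[1] + traj$params$ceiling[1]) / 2)
  expect_error(analyte_concentrations(traj, day = 9, run = 1, seed = 1),
               "day out of range")
  # huge negative noise is clamped at zero
  noisy <- analyte_trajectories(run_effect_sd = 0, rep_noise_sd = 1e4)
  conc <- analyte_concentrations(noisy, day = 0, run = 1, seed = 7)
  expect_true(all(conc >= 0))
})

test_that("e-nose rendering follows first-order rise kinetics", {
  sens <- sensor_model(noise_sd = 0, drift = 0)
  flat <- render_enose(rep(0, 4), sens, seed = 1)
  expect_equal(dim(flat$response), c(11, 121))
  expect_equal(flat$response, matrix(sens$baseline, 11, 121),
               ignore_attr = TRUE)
  # noiseless monotone rise: max over the window is the value at t = 120 s
  r1 <- render_enose(c(1, 2, 0.5, 1), sens, seed = 1)
  expect_equal(max_response(r1), r1$response[, ncol(r1$response)])
  # doubling concentrations doubles (max - baseline)
  r2 <- render_enose(2 * c(1, 2, 0.5, 1), sens, seed = 1)
  expect_equal(max_response(r2) - sens$baseline,
               2 * (max_response(r1) - sens$baseline), tolerance = 1e-12)
  expect_error(sensor_model(tau = c(-1, rep(10, 10))), "tau")
  expect_error(render_enose(c(-1, 0, 0, 0), sens), "non-negative")
})

test_that("spectrum rendering is additive with exact SNV-removable scatter", {
  sm <- spectrum_model(noise_sd = 0, alpha_spread = 0, beta_spread = 0)
  base_only <- render_spectrum(rep(0, 4), sm, seed = 1, alpha = 1, beta = 0)
  baseline <- sm$baseline_offset + sm$baseline_slope * (sm$wavenumber - 4000)
  expect_equal(base_only$absorbance, baseline)
  expect_equal(length(base_only$absorbance), 1557)
  # wavenumber grid: descending, |step| ~ 3.856
  expect_true(all(diff(sm$wavenumber) < 0))
  expect_equal(abs(diff(sm$wavenumber)[1]), 3.856)
  # Beer-Lambert additivity across analytes
  s13 <- render_spectrum(c(2, 0, 1, 0), sm, seed = 1, alpha = 1, beta = 0)
  s1 <- render_spectrum(c(2, 0, 0, 0), sm, seed = 1, alpha = 1, beta = 0)
  s3 <- render_spectrum(c(0, 0, 1, 0), sm, seed = 1, alpha = 1, beta = 0)
  expect_equal(s13$absorbance,
               s1$absorbance + s3$absorbance - baseline, tolerance = 1e-12)
  # multiplicative/additive scatter removed exactly by SNV
  plain <- render_spectrum(c(1, 1, 1, 1), sm, seed = 1, alpha = 1, beta = 0)
  scat <- render_spectrum(c(1, 1, 1, 1), sm, seed = 1, alpha = 1.3, beta = 0.2)
  expect_equal(snv_transform(scat$absorbance), snv_transform(plain$absorbance),
               tolerance = 1e-6)
})

test_that("modality split hides early analytes from spectra and late from sensors", {
  study <- noiseless_study()
  expect_true(all(study$sensors$sensitivity[, 3:4] == 0))
  expect_true(all(study$sensors$sensitivity[, 1:2] >= 0))
  b <- study$spectrum_model$bands
  expect_true(all(b$height[b$analyte <= 2] == 0))
  expect_true(any(b$height[b$analyte >= 3] > 0))
  full <- noiseless_study(modality_split = FALSE)
  expect_true(any(full$sensors$sensitivity[, 3:4] > 0))
})

test_that("day-5/6 class means are the closest adjacent pair in both modalities", {
  study <- noiseless_study()
  fe <- enose_features(study$enose)           # 7 x 11, one row per day
  fn <- snv_transform(study$spectra)          # 7 x 1557
  for (f in list(fe, fn)) {
    d <- sqrt(rowSums((f[-1, ] - f[-7, ])^2))
    expect_true(all(d[6] < d[1:5]))
  }
})

test_that("with replicate noise near zero the days separate in concatenated features", {
  study <- generate_study(
    design = study_design(2, 7, 3),
    trajectories = analyte_trajectories(run_effect_sd = 0, rep_noise_sd = 1e-4),
    sensors = sensor_model(noise_sd = 1e-5, drift = 0),
    spectra = spectrum_model(alpha_spread = 0, beta_spread = 0, noise_sd = 1e-6),
    seed = 5)
  f <- cbind(scale(enose_features(study$enose)), snv_transform(study$spectra))
  day <- study$manifest$day
  centers <- t(sapply(0:6, function(d) colMeans(f[day == d, , drop = FALSE])))
  spread <- max(sapply(0:6, function(d) {
    rows <- f[day == d, , drop = FALSE]
    max(sqrt(rowSums(sweep(rows, 2, colMeans(rows))^2)))
  }))
  between <- as.matrix(dist(centers))
  min_gap <- min(between[upper.tri(between)])
  expect_gt(min_gap, 2 * spread)
})

test_that("studies round-trip through the CSV writers", {
  study <- generate_study(design = study_design(2, 2, 1), seed = 8)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_true(all(file.exists(file.path(dir,
    c("manifest.csv", "enose.csv", "spectra.csv", "config.yaml")))))
  back <- read_study(dir)
  expect_equal(back$manifest$sample_id, study$manifest$sample_id)
  expect_equal(unname(back$spectra), unname(study$spectra), tolerance = 1e-12)
  expect_equal(back$enose[[1]]$response, study$enose[[1]]$response,
               ignore_attr = TRUE, tolerance = 1e-12)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg$design$n_runs, 2)
})
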