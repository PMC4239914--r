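# Synthetic fermentation study generator.
#
# Emulates a multi-run solid-state fermentation trial monitored by an 11-sensor
# electronic nose and an FT-NIR spectrometer: a small set of latent volatile /
# chemical analytes follows logistic growth trajectories over fermentation days
# (lag -> exponential -> stationary phase), sensors respond with first-order
# rise kinetics over a 120 s sampling window, and spectra are sums of Gaussian
# absorbance bands under Beer-Lambert additivity with multiplicative scatter.

#' Study design: runs, days and replicates
#'
#' Defaults describe a trial of 4 fermentation runs, sampled at 7 time points
#' (day 0 to day 6) with 5 replicate samples per run and day: 140 samples.
#'
#' @param n_runs number of fermentation runs (default 4).
#' @param n_days number of sampling days; labels are `0:(n_days - 1)` (default 7).
#' @param n_reps replicate samples per run and day (default 5).
#' @return an object of class `study_design`.
#' @export
study_design <- function(n_runs = 4, n_days = 7, n_reps = 5) {
  if (any(c(n_runs, n_days, n_reps) < 1) ||
      any(c(n_runs, n_days, n_reps) != round(c(n_runs, n_days, n_reps)))) {
    stop("invalid design: n_runs, n_days and n_reps must be positive integers")
  }
  structure(list(n_runs = as.integer(n_runs), n_days = as.integer(n_days),
                 n_reps = as.integer(n_reps)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design: %d runs x %d days x %d replicates = %d samples\n",
              x$n_runs, x$n_days, x$n_reps, x$n_runs * x$n_days * x$n_reps))
  invisible(x)
}

#' Latent analyte trajectories over fermentation time
#'
#' Each latent analyte follows a logistic curve in fermentation day, which
#' encodes the lag, exponential and stationary phases in one parametric
#' family. Midpoints sit at days 2--3 and steepness is such that the day-5 to
#' day-6 change is the smallest adjacent-day change for every analyte (the
#' stationary-phase plateau that makes day 5 and day 6 nearly
#' indistinguishable). Run-to-run variation is an additive shift on
#' concentrations drawn once per run; replicate noise is drawn per sample.
#'
#' @param params data frame with one row per analyte and columns `floor`,
#'   `ceiling`, `midpoint`, `steepness`.
#' @param run_effect_sd standard deviation of the per-run additive shift, in
#'   concentration units (default 0.03).
#' @param rep_noise_sd standard deviation of per-sample replicate noise, in
#'   concentration units (default 0.1).
#' @return an object of class `analyte_trajectory`.
#' @export
analyte_trajectories <- function(params = NULL, run_effect_sd = 0.03,
                                 rep_noise_sd = 0.1) {
  if (is.null(params)) {
    # Within each modality pair the two analytes rise with different timing
    # and steepness (early/steep vs late/gradual), so each modality's
    # feature space is genuinely two-dimensional; steepness keeps the
    # day-5 -> day-6 change the smallest adjacent-day change everywhere.
    params <- data.frame(
      floor     = c(0.0, 0.0, 0.0, 1.0),
      ceiling   = c(10.0, 6.0, 8.0, 9.0),
      midpoint  = c(1.2, 2.5, 1.8, 2.6),
      steepness = c(1.8, 1.15, 1.5, 1.35)
    )
  }
  stopifnot(is.data.frame(params),
            all(c("floor", "ceiling", "midpoint", "steepness") %in% names(params)))
  if (run_effect_sd < 0 || rep_noise_sd < 0) stop("noise scales must be non-negative")
  structure(list(params = params, run_effect_sd = run_effect_sd,
                 rep_noise_sd = rep_noise_sd),
            class = "analyte_trajectory")
}

#' Noise-free trajectory value per analyte
#'
#' @param trajectories an [analyte_trajectories()] object.
#' @param day fermentation day (may be fractional for curve inspection).
#' @return vector of one concentration per analyte.
#' @export
trajectory_value <- function(trajectories, day) {
  p <- trajectories$params
  logistic_curve(day, p$floor, p$ceiling, p$midpoint, p$steepness)
}

#' Analyte concentrations for one sample
#'
#' Logistic trajectory value at `day`, plus the run's additive effect (drawn
#' once per run from the `run` substream of `seed`) and per-sample replicate
#' noise, floored at zero.
#'
#' @param trajectories an [analyte_trajectories()] object.
#' @param day integer day label, `0 <= day <= n_days - 1`.
#' @param run run id (positive integer).
#' @param seed master seed for the study's randomness.
#' @param rep replicate index within run and day (default 1); together with
#'   `run` and `day` it identifies the per-sample noise draw.
#' @param n_days number of days in the design (bound check; default 7).
#' @return non-negative concentration vector, one entry per analyte.
#' @export
analyte_concentrations <- function(trajectories, day, run, seed, rep = 1L,
                                   n_days = 7L) {
  if (day < 0 || day > n_days - 1) stop("day out of range")
  n_a <- nrow(trajectories$params)
  base <- trajectory_value(trajectories, day)
  run_eff <- with_seed(substream_seed(seed, "run", run),
                       rnorm(n_a, 0, trajectories$run_effect_sd))
  noise <- with_seed(substream_seed(seed, "rep", ((run * 997L + day) * 101L + rep)),
                     rnorm(n_a, 0, trajectories$rep_noise_sd))
  pmax(base + run_eff + noise, 0)
}

#' Electronic-nose sensor array model
#'
#' Eleven cross-sensitive gas sensors. Sensor `s` responds to a headspace
#' concentration vector `conc` with a first-order rise over the sampling
#' window: `r_s(t) = baseline_s + (S conc)_s (1 - exp(-t / tau_s)) + drift t
#' + noise`, in ppm.
#'
#' @param sensitivity non-negative matrix, 11 sensors x n_analytes.
#' @param tau per-sensor rise time constants in seconds (positive).
#' @param baseline per-sensor baseline response, ppm.
#' @param drift linear drift, ppm per second (default 0.002).
#' @param noise_sd additive measurement noise sd, ppm (default 0.02).
#' @param time_s sampling time grid in seconds (default 1 Hz over 120 s).
#' @return an object of class `sensor_model`.
#' @export
sensor_model <- function(sensitivity = NULL, tau = NULL, baseline = NULL,
                         drift = 0.002, noise_sd = 0.02, time_s = 0:120) {
  if (is.null(sensitivity)) {
    # Cross-sensitivity pattern: every sensor sees every analyte a little,
    # each analyte has a few preferentially tuned sensors.
    sensitivity <- matrix(c(
      1.20, 0.30, 0.15, 0.10,
      0.90, 0.55, 0.20, 0.15,
      0.40, 1.10, 0.25, 0.10,
      0.25, 0.95, 0.35, 0.20,
      0.15, 0.30, 1.15, 0.25,
      0.20, 0.25, 0.85, 0.45,
      0.10, 0.15, 0.40, 1.05,
      0.15, 0.20, 0.30, 0.90,
      0.60, 0.60, 0.20, 0.20,
      0.20, 0.20, 0.60, 0.60,
      0.45, 0.35, 0.45, 0.35), nrow = 11, byrow = TRUE)
  }
  if (is.null(tau)) tau <- c(18, 22, 25, 30, 16, 20, 28, 35, 24, 32, 26)
  if (is.null(baseline)) baseline <- c(1.5, 2.0, 1.2, 1.8, 2.5, 1.0, 1.4, 2.2, 1.6, 1.9, 1.3)
  if (nrow(sensitivity) != 11) stop("sensor array must have 11 sensors")
  if (any(sensitivity < 0)) stop("sensitivities must be non-negative")
  if (any(tau <= 0)) stop("rise time constants tau must be positive")
  structure(list(sensitivity = sensitivity, tau = tau, baseline = baseline,
                 drift = drift, noise_sd = noise_sd, time_s = time_s),
            class = "sensor_model")
}

#' Render an e-nose recording from analyte concentrations
#'
#' @param conc non-negative analyte concentration vector.
#' @param sensors a [sensor_model()].
#' @param seed seed for the measurement-noise draw.
#' @param sample_id optional id attached to the recording.
#' @return an `enose_recording`: list with `sample_id`, `response`
#'   (11 x T matrix, ppm) and `time_s`.
#' @export
render_enose <- function(conc, sensors, seed = 0L, sample_id = NA_character_) {
  stopifnot(inherits(sensors, "sensor_model"))
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (length(conc) != ncol(sensors$sensitivity))
    stop("concentration length does not match sensor sensitivity matrix")
  t <- sensors$time_s
  amp <- drop(sensors$sensitivity %*% conc)
  rise <- 1 - exp(-outer(1 / sensors$tau, t))     # 11 x T
  resp <- sensors$baseline + amp * rise +
    matrix(sensors$drift * t, nrow = 11, ncol = length(t), byrow = TRUE)
  if (sensors$noise_sd > 0) {
    resp <- resp + with_seed(substream_seed(seed, "enose-noise"),
                             matrix(rnorm(length(resp), 0, sensors$noise_sd),
                                    nrow = 11))
  }
  rownames(resp) <- paste0("sensor", 1:11)
  structure(list(sample_id = sample_id, response = resp, time_s = t),
            class = "enose_recording")
}

#' Near-infrared spectrum model
#'
#' Spectra live on a fixed 1557-point wavenumber grid descending from
#' 10,000 cm-1 in steps of 3.856 cm-1 (instrument convention). A sample's
#' absorbance (log 1/R) is the Beer-Lambert sum of per-analyte Gaussian
#' bands plus a linear baseline, the whole signal scaled by a multiplicative
#' scatter factor `alpha ~ 1` and offset by `beta ~ 0`.
#'
#' @param bands data frame with columns `analyte`, `center` (cm-1), `width`
#'   (cm-1) and `height` (absorbance per unit concentration, non-negative).
#' @param baseline_offset,baseline_slope linear baseline in absorbance units;
#'   slope is per cm-1 relative to 4000 cm-1.
#' @param alpha_spread sd of the multiplicative scatter factor around 1.
#' @param beta_spread sd of the additive scatter offset around 0.
#' @param noise_sd spectral noise sd, absorbance units.
#' @param n_points number of grid points (default 1557).
#' @param wn_max,wn_step grid start (cm-1) and descending step (cm-1).
#' @return an object of class `spectrum_model`.
#' @export
spectrum_model <- function(bands = NULL, baseline_offset = 0.25,
                           baseline_slope = 1e-5, alpha_spread = 0.08,
                           beta_spread = 0.03, noise_sd = 0.001,
                           n_points = 1557, wn_max = 10000, wn_step = 3.856) {
  if (is.null(bands)) {
    bands <- data.frame(
      analyte = c(1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L),
      center  = c(8400, 5200, 6900, 4800, 8700, 5600, 4350, 7500, 5000, 6200),
      width   = c(120, 90, 100, 80, 110, 85, 70, 95, 75, 130),
      height  = c(0.020, 0.015, 0.018, 0.022, 0.025, 0.020, 0.015,
                  0.022, 0.018, 0.012)
    )
  }
  stopifnot(all(c("analyte", "center", "width", "height") %in% names(bands)))
  if (any(bands$height < 0)) stop("band responses must be non-negative")
  wavenumber <- wn_max - wn_step * (seq_len(n_points) - 1)
  structure(list(bands = bands, wavenumber = wavenumber,
                 baseline_offset = baseline_offset,
                 baseline_slope = baseline_slope,
                 alpha_spread = alpha_spread, beta_spread = beta_spread,
                 noise_sd = noise_sd),
            class = "spectrum_model")
}

#' Render a NIR spectrum from analyte concentrations
#'
#' `x(nu) = alpha * (sum_a conc_a * bands_a(nu) + baseline(nu)) + beta +
#' noise`. The multiplicative scatter `alpha` scales the whole deterministic
#' signal (as scatter acts on a measured reflectance spectrum), so SNV removes
#' the `alpha`/`beta` scatter exactly.
#'
#' @param conc non-negative analyte concentration vector.
#' @param model a [spectrum_model()].
#' @param seed seed for scatter and noise draws.
#' @param sample_id optional id attached to the spectrum.
#' @param alpha,beta optional explicit scatter parameters; when `NULL`
#'   (default) they are drawn from the seed's substream.
#' @return a `spectrum`: list with `sample_id`, `absorbance` (length-1557
#'   vector) and `wavenumber`.
#' @export
render_spectrum <- function(conc, model, seed = 0L, sample_id = NA_character_,
                            alpha = NULL, beta = NULL) {
  stopifnot(inherits(model, "spectrum_model"))
  if (any(conc < 0)) stop("concentrations must be non-negative")
  wn <- model$wavenumber
  if (length(wn) != 1557) stop("wavenumber grid must have exactly 1557 points")
  chem <- numeric(length(wn))
  b <- model$bands
  for (i in seq_len(nrow(b))) {
    a <- b$analyte[i]
    if (a > length(conc) || conc[a] == 0 || b$height[i] == 0) next
    chem <- chem + conc[a] * b$height[i] * exp(-0.5 * ((wn - b$center[i]) / b$width[i])^2)
  }
  baseline <- model$baseline_offset + model$baseline_slope * (wn - 4000)
  draws <- with_seed(substream_seed(seed, "nirs-scatter"), rnorm(2))
  if (is.null(alpha)) alpha <- 1 + draws[1] * model$alpha_spread
  if (is.null(beta)) beta <- draws[2] * model$beta_spread
  x <- alpha * (chem + baseline) + beta
  if (model$noise_sd > 0) {
    x <- x + with_seed(substream_seed(seed, "nirs-noise"),
                       rnorm(length(wn), 0, model$noise_sd))
  }
  structure(list(sample_id = sample_id, absorbance = x, wavenumber = wn),
            class = "spectrum")
}

#' Generate a complete labelled fermentation study
#'
#' Produces one e-nose recording and one NIR spectrum per manifest row. All
#' randomness flows from `seed` through named substreams (run effects drawn
#' once per run, replicate noise per sample, measurement noise per modality),
#' so a fixed seed gives a bitwise-identical study.
#'
#' With `modality_split = TRUE` (the default study condition) the first half
#' of the analytes is visible only to the gas sensors and the second half
#' only to the spectra, so neither modality alone carries all the
#' class-discriminating information but their fusion does.
#'
#' @param design a [study_design()].
#' @param trajectories an [analyte_trajectories()].
#' @param sensors a [sensor_model()].
#' @param spectra a [spectrum_model()].
#' @param seed master integer seed.
#' @param modality_split logical; split analyte visibility across modalities
#'   (default `TRUE`).
#' @return an `ssf_study`: list with `manifest` (data.frame: sample_id, run,
#'   day), `enose` (list of `enose_recording`), `spectra` (samples x 1557
#'   absorbance matrix, rownames = sample ids), `wavenumber`, and the model
#'   objects used.
#' @export
generate_study <- function(design = study_design(),
                           trajectories = analyte_trajectories(),
                           sensors = sensor_model(),
                           spectra = spectrum_model(),
                           seed = 1L, modality_split = TRUE) {
  stopifnot(inherits(design, "study_design"))
  n_a <- nrow(trajectories$params)
  sens <- sensors
  spec <- spectra
  if (modality_split) {
    # analytes 1..k visible only to the gas sensors, k+1..n only to spectra
    k <- floor(n_a / 2)
    sens$sensitivity[, (k + 1):n_a] <- 0
    spec$bands$height[spec$bands$analyte <= k] <- 0
  }
  manifest <- expand.grid(rep = seq_len(design$n_reps),
                          day = 0:(design$n_days - 1),
                          run = seq_len(design$n_runs))
  manifest <- manifest[, c("run", "day", "rep")]
  manifest$sample_id <- sprintf("R%dD%dS%d", manifest$run, manifest$day, manifest$rep)
  manifest <- manifest[, c("sample_id", "run", "day", "rep")]
  rownames(manifest) <- NULL

  enose <- vector("list", nrow(manifest))
  spectra_mat <- matrix(NA_real_, nrow(manifest), length(spec$wavenumber),
                        dimnames = list(manifest$sample_id,
                                        sprintf("wn_%.3f", spec$wavenumber)))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    conc <- analyte_concentrations(trajectories, row$day, row$run, seed,
                                   rep = row$rep, n_days = design$n_days)
    enose[[i]] <- render_enose(conc, sens,
                               seed = substream_seed(seed, "enose", i),
                               sample_id = row$sample_id)
    spectra_mat[i, ] <- render_spectrum(conc, spec,
                                        seed = substream_seed(seed, "nirs", i),
                                        sample_id = row$sample_id)$absorbance
  }
  names(enose) <- manifest$sample_id
  structure(list(manifest = manifest[, c("sample_id", "run", "day")],
                 enose = enose, spectra = spectra_mat,
                 wavenumber = spec$wavenumber,
                 design = design, trajectories = trajectories,
                 sensors = sens, spectrum_model = spec,
                 modality_split = modality_split, seed = seed),
            class = "ssf_study")
}

#' @export
print.ssf_study <- function(x, ...) {
  cat(sprintf("Synthetic SSF study: %d samples (%d runs x %d days x %d reps), seed %d\n",
              nrow(x$manifest), x$design$n_runs, x$design$n_days,
              x$design$n_reps, x$seed))
  cat(sprintf("  e-nose: 11 sensors x %d time points; NIRS: %d wavenumbers\n",
              length(x$enose[[1]]$time_s), ncol(x$spectra)))
  invisible(x)
}

#' Write a study to disk as plain-text files
#'
#' Writes `manifest.csv` (sample_id, run, day), `enose.csv` in long format
#' (sample_id, sensor_id, time_s, response_ppm), `spectra.csv` in wide format
#' (sample_id, one column per wavenumber), and `config.yaml` describing the
#' generator settings.
#'
#' @param study an `ssf_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "ssf_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(study$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  long <- do.call(rbind, lapply(study$enose, function(r) {
    data.frame(sample_id = r$sample_id,
               sensor_id = rep(1:11, times = length(r$time_s)),
               time_s = rep(r$time_s, each = 11),
               response_ppm = as.vector(r$response))
  }))
  write.csv(long, file.path(dir, "enose.csv"), row.names = FALSE)
  wide <- data.frame(sample_id = rownames(study$spectra), study$spectra,
                     check.names = FALSE)
  write.csv(wide, file.path(dir, "spectra.csv"), row.names = FALSE)
  cfg <- list(
    design = unclass(study$design),
    trajectories = list(params = as.list(study$trajectories$params),
                        run_effect_sd = study$trajectories$run_effect_sd,
                        rep_noise_sd = study$trajectories$rep_noise_sd),
    sensors = list(tau = study$sensors$tau, baseline = study$sensors$baseline,
                   drift = study$sensors$drift, noise_sd = study$sensors$noise_sd),
    spectra = list(baseline_offset = study$spectrum_model$baseline_offset,
                   baseline_slope = study$spectrum_model$baseline_slope,
                   alpha_spread = study$spectrum_model$alpha_spread,
                   beta_spread = study$spectrum_model$beta_spread,
                   noise_sd = study$spectrum_model$noise_sd),
    modality_split = study$modality_split,
    seed = study$seed
  )
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir directory containing `manifest.csv`, `enose.csv`, `spectra.csv`.
#' @return a list with `manifest`, `enose` (list of `enose_recording`) and
#'   `spectra` (matrix).
#' @export
read_study <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  long <- read.csv(file.path(dir, "enose.csv"))
  enose <- lapply(split(long, long$sample_id), function(d) {
    t <- sort(unique(d$time_s))
    resp <- matrix(d$response_ppm[order(d$time_s, d$sensor_id)],
                   nrow = 11, dimnames = list(paste0("sensor", 1:11), NULL))
    structure(list(sample_id = d$sample_id[1], response = resp, time_s = t),
              class = "enose_recording")
  })
  enose <- enose[manifest$sample_id]
  wide <- read.csv(file.path(dir, "spectra.csv"), check.names = FALSE)
  spectra <- as.matrix(wide[, -1])
  rownames(spectra) <- wide$sample_id
  list(manifest = manifest, enose = enose, spectra = spectra)
}
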