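# Shared small fixtures, built in code.

# A small study for fast end-to-end tests: 3 runs x 7 days x 2 replicates.
small_study <- function(seed = 42, ...) {
  generate_study(design = study_design(3, 7, 2), seed = seed, ...)
}

# Noiseless single-replicate study: one sample per day = the class means.
noiseless_study <- function(seed = 1, modality_split = TRUE) {
  generate_study(
    design = study_design(1, 7, 1),
    trajectories = analyte_trajectories(run_effect_sd = 0, rep_noise_sd = 0),
    sensors = sensor_model(noise_sd = 0, drift = 0),
    spectra = spectrum_model(alpha_spread = 0, beta_spread = 0, noise_sd = 0),
    seed = seed, modality_split = modality_split)
}

# Linearly separable 2-class toy with a wide margin: class = sign of x1.
toy_two_class <- function() {
  x <- matrix(c(-2, -1, -2, 1, 2, -1, 2, 1), 4, 2, byrow = TRUE)
  y <- matrix(c(1, 0, 1, 0, 0, 1, 0, 1), 4, 2, byrow = TRUE)
  list(x = x, y = y, days = c(0, 0, 1, 1))
}

# Crafted constant-output weak net: ignores its input and returns sigmoid(b2).
constant_net <- function(outputs, p = 2) {
  h <- 3
  q <- length(outputs)
  structure(list(W1 = matrix(0, p, h), b1 = rep(0, h),
                 W2 = matrix(0, h, q), b2 = log(outputs / (1 - outputs)),
                 mse = 0, epochs = 1, p = p, q = q),
            class = "bp_net")
}

# Strong predictor assembled from crafted weak nets.
crafted_strong <- function(nets, a, levels = 0:6) {
  structure(list(nets = nets, a = a, e = rep(0.1, length(nets)),
                 d_trace = NULL, levels = levels, cutoff = 0.5,
                 cfg = bp_config(), rounds = length(nets)),
            class = "strong_predictor")
}
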