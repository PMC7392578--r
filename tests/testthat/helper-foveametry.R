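# Shared fixtures, all built in code.

# A dog_fit object with chosen parameters, bypassing the optimizer, for
# testing the analytic morphometry operations in isolation.
make_fit <- function(baseline = 0,
                     nasal = list(a_pit = 100, sigma_pit = 500,
                                  a_para = 0, sigma_para = 1500),
                     temporal = nasal, d_max = 3000) {
  structure(
    list(baseline = baseline, nasal = nasal, temporal = temporal,
         lambda = 10, rss = c(nasal = 0, temporal = 0), objective = 0,
         converged = TRUE, degenerate = FALSE, sigma_order_ok = TRUE,
         n_points = c(nasal = 250, temporal = 250),
         d_max = c(nasal = d_max, temporal = d_max),
         pit_height_obs = NA_real_, optim_info = 1,
         optim_message = "synthetic", config = dog_fit_config()),
    class = "dog_fit"
  )
}

# Independent re-implementation of the contour model used by the generator
# and the fit, written directly from the closed form (baseline + wide
# Gaussian - narrow inverted Gaussian); oracles compare against this.
contour_oracle <- function(baseline, a_pit, s_pit, a_para, s_para, d) {
  baseline + a_para * exp(-d^2 / (2 * s_para^2)) -
    a_pit * exp(-d^2 / (2 * s_pit^2))
}

# Random valid single-side parameter draws for property tests.
random_side <- function() {
  s_pit <- runif(1, 200, 700)
  list(a_pit = runif(1, 40, 150), sigma_pit = s_pit,
       a_para = runif(1, -60, 60), sigma_para = s_pit * runif(1, 2, 5))
}

# An asymmetric truth used across fitting tests. Both sides meet at the
# pit bottom (B + A_para - A_pit = 140 µm), as a continuous contour must;
# the temporal parafovea is inverted.
asym_truth <- function(noise_sd = 0, n_points = 500, seed = 1) {
  profile_truth(
    baseline_height = 200,
    nasal = list(pit_amplitude = 90, pit_sigma = 400,
                 para_amplitude = 30, para_sigma = 1400),
    temporal = list(pit_amplitude = 35, pit_sigma = 350,
                    para_amplitude = -25, para_sigma = 1200),
    noise_sd = noise_sd, n_points = n_points, seed = seed
  )
}
asym_truth_values <- list(nasal = c(90, 400, 30, 1400),
                          temporal = c(35, 350, -25, 1200))

# Small, fast scan geometry for image tests.
small_geometry <- function(bruch_row = 120, ...) {
  scan_geometry(n_cols = 120, n_rows = 160, lateral_um_per_px = 25,
                axial_um_per_px = 2.5, bruch_row = bruch_row, ...)
}

# Truth that fits comfortably inside small_geometry (3000 µm wide view,
# 400 µm axial depth above Bruch at most).
small_truth <- function(...) {
  profile_truth(
    baseline_height = 200,
    nasal = list(pit_amplitude = 90, pit_sigma = 350,
                 para_amplitude = 20, para_sigma = 900),
    temporal = list(pit_amplitude = 90, pit_sigma = 350,
                    para_amplitude = 20, para_sigma = 900),
    lateral_extent = 3000, ...
  )
}
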