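#' Ground-truth parameters for a synthetic ILM profile
#'
#' Describes the generating foveal contour used by [gen_ilm_profile()] and
#' [gen_bscan()]: on each side of the pit, a narrow inverted Gaussian (the
#' pit) and a wide Gaussian of either sign (the parafovea) over a shared
#' baseline — the same functional family the fitting stage estimates, so
#' recovery is exactly testable.
#'
#' Default magnitudes emulate a preterm foveal contour: retinal thickness
#' around 200 µm, a shallow pit (~90 µm amplitude, ~400 µm width) and a
#' modest parafoveal mound.
#'
#' @param baseline_height baseline retinal height above Bruch, µm.
#' @param nasal,temporal named lists with `pit_amplitude` (µm, > 0),
#'   `pit_sigma` (µm, > 0), `para_amplitude` (µm, signed; negative means an
#'   inverted parafoveal Gaussian), `para_sigma` (µm, > `pit_sigma`).
#' @param noise_sd additive Gaussian noise SD on heights, µm (>= 0).
#' @param n_points number of lateral samples (>= 50).
#' @param lateral_extent total lateral span, µm (> 0).
#' @param seed integer seed for the profile noise stream.
#' @return A `profile_truth` list.
#' @export
#' @examples
#' tr <- profile_truth(noise_sd = 0)
#' p <- gen_ilm_profile(tr)
profile_truth <- function(baseline_height = 200,
                          nasal = list(pit_amplitude = 90, pit_sigma = 400,
                                       para_amplitude = 30, para_sigma = 1400),
                          temporal = nasal,
                          noise_sd = 2, n_points = 500,
                          lateral_extent = 10000, seed = 1) {
  side_ok <- function(s, nm) {
    req <- c("pit_amplitude", "pit_sigma", "para_amplitude", "para_sigma")
    if (!all(req %in% names(s))) {
      stop(sprintf("side '%s' must provide %s", nm, paste(req, collapse = ", ")),
           call. = FALSE)
    }
    if (s$pit_amplitude <= 0 || s$pit_sigma <= 0 || s$para_sigma <= 0) {
      stop(sprintf("side '%s': amplitudes/sigmas must be positive", nm),
           call. = FALSE)
    }
    if (s$pit_sigma >= s$para_sigma) {
      stop(sprintf("side '%s': pit_sigma must be smaller than para_sigma", nm),
           call. = FALSE)
    }
    s[req]
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_points < 50) stop("n_points must be >= 50", call. = FALSE)
  if (lateral_extent <= 0) stop("lateral_extent must be > 0", call. = FALSE)
  structure(
    list(baseline_height = baseline_height,
         nasal = side_ok(nasal, "nasal"),
         temporal = side_ok(temporal, "temporal"),
         noise_sd = noise_sd, n_points = as.integer(n_points),
         lateral_extent = lateral_extent, seed = as.integer(seed)),
    class = "profile_truth"
  )
}

# Noise-free contour height of a truth at pit-centered positions x (µm).
truth_height <- function(truth, x) {
  h <- numeric(length(x))
  for (side in c("nasal", "temporal")) {
    sel <- if (side == "nasal") x >= 0 else x < 0
    s <- truth[[side]]
    h[sel] <- dog_side_value(truth$baseline_height, s$pit_amplitude,
                             s$pit_sigma, s$para_amplitude, s$para_sigma,
                             abs(x[sel]))
  }
  h
}

#' Generate a synthetic ILM profile
#'
#' Samples the two-sided difference-of-Gaussians contour of `truth` on a
#' regular lateral grid and adds Gaussian height noise. With `noise_sd = 0`
#' the samples equal the model exactly; the same truth (including its seed)
#' always yields bit-identical output.
#'
#' @param truth a [profile_truth()].
#' @return An [ilm_profile()] in micrometre units. The lateral grid has
#'   spacing `lateral_extent / n_points` and contains a sample exactly at
#'   the pit center x = 0.
#' @export
gen_ilm_profile <- function(truth) {
  stopifnot(inherits(truth, "profile_truth"))
  n <- truth$n_points
  dx <- truth$lateral_extent / n
  x <- (seq_len(n) - (floor(n / 2) + 1)) * dx
  h <- truth_height(truth, x)
  if (truth$noise_sd > 0) {
    h <- h + withr::with_seed(
      substream_seed(truth$seed, "ilm_profile"),
      rnorm(n, 0, truth$noise_sd)
    )
  }
  ilm_profile(x, h, units = "um",
              metadata = list(source = "synthetic", seed = truth$seed))
}
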