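#' Locate the foveal rim edge on one side
#'
#' The rim edge is defined as the maximum of the third derivative of the
#' fitted contour over distances d in (0, d_max]: the earliest indication
#' of the ILM falling away to form the pit. This definition applies
#' identically whether the parafoveal Gaussian is inverted or not (the
#' classic zero-slope rim does not exist when the contour keeps rising
#' beyond the rim, as is common in preterm eyes). The maximum is bracketed
#' on a 1 µm grid and refined by golden-section search.
#'
#' For a pure single-pit contour (no parafoveal component) the rim distance
#' has the closed form \eqn{d^* = \sigma_{pit}\sqrt{3+\sqrt 6}}.
#'
#' @param fit a [fit_dog()] result.
#' @param side `"nasal"` or `"temporal"`.
#' @param d_max search limit, µm; defaults to the maximum fitted distance
#'   on that side.
#' @param grid_step bracketing grid step, µm.
#' @return List with `d` (rim distance, µm) and `h` (contour height at the
#'   rim, µm).
#' @export
locate_rim_edge <- function(fit, side = c("nasal", "temporal"),
                            d_max = NULL, grid_step = 1) {
  stopifnot(inherits(fit, "dog_fit"))
  side <- match.arg(side)
  if (is.null(d_max)) d_max <- fit$d_max[[side]]
  grid <- seq(grid_step, d_max, by = grid_step)
  v <- dog_eval(fit, side, grid, order = 3)
  if (!any(is.finite(v))) {
    stop("rim-not-found: third derivative not finite on the search grid",
         call. = FALSE)
  }
  i <- which.max(v)
  if (i == length(grid)) {
    stop("rim-not-found: third derivative has no interior maximum in (0, d_max]",
         call. = FALSE)
  }
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  opt <- optimize(function(d) dog_eval(fit, side, d, order = 3),
                  interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  d_star <- opt$maximum
  list(d = d_star, h = dog_eval(fit, side, d_star, order = 0))
}

#' Steepest slope of the foveal wall on one side
#'
#' Maximum absolute first derivative of the fitted contour over
#' d in (0, rim_d], found on a fine grid with golden-section refinement.
#' For a pure single-pit contour the maximum sits at d = sigma_pit with
#' value A_pit / (sigma_pit * sqrt(e)).
#'
#' @param fit a [fit_dog()] result.
#' @param side `"nasal"` or `"temporal"`.
#' @param rim_d rim distance bounding the search, µm (> 0); defaults to
#'   [locate_rim_edge()] on the same side.
#' @param grid_step bracketing grid step, µm.
#' @return List with `gradient` (µm/µm), `degrees` (atan of the gradient),
#'   and `d` (location of the maximum, µm).
#' @export
steepest_slope <- function(fit, side = c("nasal", "temporal"), rim_d = NULL,
                           grid_step = 0.5) {
  stopifnot(inherits(fit, "dog_fit"))
  side <- match.arg(side)
  if (is.null(rim_d)) rim_d <- locate_rim_edge(fit, side)$d
  if (rim_d <= 0) stop("rim_d must be > 0", call. = FALSE)
  grid <- seq(grid_step, rim_d, by = grid_step)
  if (tail(grid, 1) < rim_d) grid <- c(grid, rim_d)
  v <- abs(dog_eval(fit, side, grid, order = 1))
  i <- which.max(v)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  opt <- optimize(function(d) abs(dog_eval(fit, side, d, order = 1)),
                  interval = c(lo, hi), maximum = TRUE, tol = 1e-10)
  g <- opt$objective
  list(gradient = g, degrees = atan(g) * 180 / pi, d = opt$maximum)
}

#' Classify the parafoveal Gaussian as inverted or non-inverted
#'
#' The parafovea is *inverted* when the fitted wide Gaussian has negative
#' amplitude — the parafoveal contour slopes inward toward the fovea
#' rather than mounding outward. Amplitudes within `dead_zone` of zero are
#' labelled indeterminate.
#'
#' @param fit a [fit_dog()] result.
#' @param side `"nasal"` or `"temporal"`.
#' @param dead_zone half-width of the indeterminate band, µm.
#' @return `"inverted"`, `"noninverted"` or `"indeterminate"`.
#' @export
classify_parafovea <- function(fit, side = c("nasal", "temporal"),
                               dead_zone = 1) {
  stopifnot(inherits(fit, "dog_fit"))
  side <- match.arg(side)
  a <- fit[[side]]$a_para
  if (abs(a) <= dead_zone) "indeterminate"
  else if (a < 0) "inverted"
  else "noninverted"
}

#' Compute the six foveal parameters from a fitted contour
#'
#' Derives, from a converged DoG fit (and the raw profile for extent
#' checks):
#' * `width` — sum of the nasal and temporal rim distances (third-derivative
#'   rim rule, [locate_rim_edge()]);
#' * `cft` — central foveal thickness: fitted height at d = 0, averaged
#'   over the two sides (the pit-bottom penalty keeps them consistent);
#' * `depth` — mean rim height minus CFT (per-side depths also returned);
#' * `area` — area between the chord joining the two rim points and the
#'   fitted contour, computed from the closed-form Gaussian integral;
#' * `slope_nasal`, `slope_temporal` — steepest wall slope per side
#'   ([steepest_slope()]), in µm/µm and degrees;
#' * `prt_nasal`, `prt_temporal` — parafoveal retinal thickness: fitted
#'   height at d = `prt_d` (default 1000 µm); heights are measured above
#'   Bruch, so height equals retinal thickness. Flagged missing when the
#'   profile does not extend to `prt_d` on that side.
#'
#' @param fit a [fit_dog()] result.
#' @param profile the fitted [ilm_profile()]; used to check lateral extent
#'   and, with `prt_fitted = FALSE`, to read pRT off the nearest raw
#'   sample.
#' @param prt_d parafoveal sampling distance, µm.
#' @param prt_fitted use the fitted contour (default) or the nearest raw
#'   sample for pRT.
#' @return A `foveal_metrics` list; see [as.data.frame.foveal_metrics()]
#'   for the flat form.
#' @export
compute_metrics <- function(fit, profile = NULL, prt_d = 1000,
                            prt_fitted = TRUE) {
  stopifnot(inherits(fit, "dog_fit"))
  if (!fit$converged) {
    warning("computing metrics from a non-converged fit", call. = FALSE)
  }
  rim_n <- locate_rim_edge(fit, "nasal")
  rim_t <- locate_rim_edge(fit, "temporal")
  sl_n <- steepest_slope(fit, "nasal", rim_n$d)
  sl_t <- steepest_slope(fit, "temporal", rim_t$d)
  cft_n <- dog_eval(fit, "nasal", 0)
  cft_t <- dog_eval(fit, "temporal", 0)
  cft <- (cft_n + cft_t) / 2
  depth_n <- rim_n$h - cft
  depth_t <- rim_t$h - cft
  depth <- (rim_n$h + rim_t$h) / 2 - cft
  width <- rim_n$d + rim_t$d

  # chord-to-contour area between the rim points (µm^2)
  chord_area <- (rim_n$h + rim_t$h) / 2 * width
  under_n <- with(fit$nasal,
                  dog_side_integral(fit$baseline, a_pit, sigma_pit, a_para,
                                    sigma_para, rim_n$d))
  under_t <- with(fit$temporal,
                  dog_side_integral(fit$baseline, a_pit, sigma_pit, a_para,
                                    sigma_para, rim_t$d))
  area <- chord_area - (under_n + under_t)

  prt_missing <- c(nasal = FALSE, temporal = FALSE)
  prt <- c(nasal = NA_real_, temporal = NA_real_)
  for (side in c("nasal", "temporal")) {
    extent <- if (!is.null(profile)) {
      if (side == "nasal") max(profile$x) else -min(profile$x)
    } else fit$d_max[[side]]
    if (extent < prt_d) {
      prt_missing[[side]] <- TRUE
      next
    }
    if (prt_fitted || is.null(profile)) {
      prt[[side]] <- dog_eval(fit, side, prt_d)
    } else {
      target <- if (side == "nasal") prt_d else -prt_d
      prt[[side]] <- profile$h[which.min(abs(profile$x - target))]
    }
  }

  structure(
    list(width = width, depth = depth, area = area, cft = cft,
         cft_raw = if (!is.null(profile)) profile$h[which.min(abs(profile$x))] else NA_real_,
         slope_nasal = sl_n$gradient, slope_temporal = sl_t$gradient,
         slope_nasal_deg = sl_n$degrees, slope_temporal_deg = sl_t$degrees,
         prt_nasal = prt[["nasal"]], prt_temporal = prt[["temporal"]],
         prt_missing = prt_missing,
         rim_d_nasal = rim_n$d, rim_d_temporal = rim_t$d,
         rim_h_nasal = rim_n$h, rim_h_temporal = rim_t$h,
         depth_nasal = depth_n, depth_temporal = depth_t,
         parafovea_nasal = classify_parafovea(fit, "nasal"),
         parafovea_temporal = classify_parafovea(fit, "temporal")),
    class = "foveal_metrics"
  )
}

#' @exportS3Method base::print
print.foveal_metrics <- function(x, ...) {
  cat("<foveal_metrics>\n")
  cat(sprintf("  width %.1f um   depth %.1f um   area %.0f um^2   CFT %.1f um\n",
              x$width, x$depth, x$area, x$cft))
  cat(sprintf("  slope  nasal %.4f um/um (%.2f deg)   temporal %.4f um/um (%.2f deg)\n",
              x$slope_nasal, x$slope_nasal_deg,
              x$slope_temporal, x$slope_temporal_deg))
  cat(sprintf("  pRT    nasal %.1f um   temporal %.1f um\n",
              x$prt_nasal, x$prt_temporal))
  cat(sprintf("  parafovea: nasal %s, temporal %s\n",
              x$parafovea_nasal, x$parafovea_temporal))
  invisible(x)
}

#' Flatten foveal metrics to a one-row data frame
#'
#' @param x a `foveal_metrics` object.
#' @param ... unused.
#' @return One-row data frame with all scalar metrics.
#' @export
as.data.frame.foveal_metrics <- function(x, ...) {
  data.frame(
    width = x$width, depth = x$depth, area = x$area, cft = x$cft,
    slope_nasal = x$slope_nasal, slope_temporal = x$slope_temporal,
    slope_nasal_deg = x$slope_nasal_deg,
    slope_temporal_deg = x$slope_temporal_deg,
    prt_nasal = x$prt_nasal, prt_temporal = x$prt_temporal,
    rim_d_nasal = x$rim_d_nasal, rim_d_temporal = x$rim_d_temporal,
    rim_h_nasal = x$rim_h_nasal, rim_h_temporal = x$rim_h_temporal,
    parafovea_nasal = x$parafovea_nasal,
    parafovea_temporal = x$parafovea_temporal,
    stringsAsFactors = FALSE
  )
}
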