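#' Configuration for the DoG contour fit
#'
#' @param lambda weight of the pit-bottom penalty term that ties the fitted
#'   height at d = 0 on each side to the observed pit-bottom height
#'   (dimensionless; 0 disables).
#' @param multistart number of jittered restarts; the best
#'   root-sum-of-squares fit is kept.
#' @param jitter relative jitter (fraction) applied to the data-driven
#'   starting values for the restarts.
#' @param seed seed for the jitter stream.
#' @param maxiter maximum Levenberg–Marquardt iterations per start.
#' @param ftol,ptol cost and parameter convergence tolerances.
#' @param bounds list with elements `baseline`, `a_pit`, `a_para`,
#'   `sigma_pit`, `sigma_para`: each a `c(lower, upper)` box in µm. The pit
#'   amplitude is constrained non-negative (the pit Gaussian is inverted by
#'   construction); the parafoveal amplitude is free in sign so an inverted
#'   parafovea is representable. The parafoveal width is bounded below at
#'   500 µm — it models the millimetre-scale parafoveal mound, and without
#'   that floor the optimizer can repurpose it as a narrow spike that
#'   corrupts the derivative-based landmarks.
#' @param degenerate_a_pit pit amplitudes below this (µm) flag the fit as
#'   degenerate (no discernible pit).
#' @return A `dog_fit_config` list.
#' @export
dog_fit_config <- function(lambda = 10, multistart = 5, jitter = 0.3,
                           seed = 1, maxiter = 1000,
                           ftol = 1e-10, ptol = 1e-10,
                           bounds = list(baseline = c(0, 2000),
                                         a_pit = c(0, 1000),
                                         a_para = c(-1000, 1000),
                                         sigma_pit = c(20, 2000),
                                         sigma_para = c(500, 5000)),
                           degenerate_a_pit = 1) {
  structure(
    list(lambda = lambda, multistart = as.integer(multistart),
         jitter = jitter, seed = as.integer(seed),
         maxiter = as.integer(maxiter), ftol = ftol, ptol = ptol,
         bounds = bounds, degenerate_a_pit = degenerate_a_pit),
    class = "dog_fit_config"
  )
}

# Parameter vector layout used by the optimizer:
# (B, a_pit_N, s_pit_N, a_para_N, s_para_N, a_pit_T, s_pit_T, a_para_T, s_para_T)
.p_unpack <- function(p) {
  list(baseline = p[1],
       nasal = list(a_pit = p[2], sigma_pit = p[3],
                    a_para = p[4], sigma_para = p[5]),
       temporal = list(a_pit = p[6], sigma_pit = p[7],
                       a_para = p[8], sigma_para = p[9]))
}

# Residual vector: per-side model-minus-data residuals followed by the two
# sqrt(lambda)-weighted pit-bottom residuals (model at d = 0 vs observed
# pit-bottom height). nls.lm minimizes its sum of squares.
.dog_residuals <- function(p, sides, lambda) {
  u <- .p_unpack(p)
  rn <- with(u$nasal, dog_side_value(u$baseline, a_pit, sigma_pit, a_para,
                                     sigma_para, sides$nasal$d)) - sides$nasal$h
  rt <- with(u$temporal, dog_side_value(u$baseline, a_pit, sigma_pit, a_para,
                                        sigma_para, sides$temporal$d)) - sides$temporal$h
  pen <- sqrt(lambda) * c(
    u$baseline + u$nasal$a_para - u$nasal$a_pit - sides$pit_h,
    u$baseline + u$temporal$a_para - u$temporal$a_pit - sides$pit_h
  )
  c(rn, rt, pen)
}

# Analytic Jacobian of .dog_residuals. For g(d; s) = exp(-d^2/2s^2):
# dg/ds = g * d^2 / s^3.
.dog_jacobian <- function(p, sides, lambda) {
  u <- .p_unpack(p)
  nN <- length(sides$nasal$d)
  nT <- length(sides$temporal$d)
  J <- matrix(0, nN + nT + 2, 9)
  fill <- function(rows, d, s, off) {
    g_pit <- exp(-d^2 / (2 * s$sigma_pit^2))
    g_para <- exp(-d^2 / (2 * s$sigma_para^2))
    J[rows, 1] <<- 1
    J[rows, off + 0] <<- -g_pit
    J[rows, off + 1] <<- -s$a_pit * g_pit * d^2 / s$sigma_pit^3
    J[rows, off + 2] <<- g_para
    J[rows, off + 3] <<- s$a_para * g_para * d^2 / s$sigma_para^3
  }
  fill(seq_len(nN), sides$nasal$d, u$nasal, 2)
  fill(nN + seq_len(nT), sides$temporal$d, u$temporal, 6)
  sl <- sqrt(lambda)
  J[nN + nT + 1, c(1, 2, 4)] <- sl * c(1, -1, 1)
  J[nN + nT + 2, c(1, 6, 8)] <- sl * c(1, -1, 1)
  J
}

# Data-driven starting values: pit-bottom height and an outer-plateau
# estimate give the amplitudes; the half-depth crossing gives the pit width.
.dog_init <- function(sides, bounds) {
  h_all <- c(sides$nasal$h, sides$temporal$h)
  d_all <- c(sides$nasal$d, sides$temporal$d)
  d_max <- max(d_all)
  outer <- h_all[d_all > 0.6 * d_max]
  B0 <- if (length(outer)) median(outer) else median(h_all)
  h0 <- sides$pit_h
  a_pit0 <- max(B0 - h0, 5)
  half <- h0 + 0.5 * a_pit0
  s_pit0 <- 400
  ord <- order(d_all)
  cross <- d_all[ord][which(h_all[ord] >= half)[1]]
  if (is.finite(cross) && !is.na(cross) && cross > 0) {
    s_pit0 <- cross / sqrt(2 * log(2))  # half-maximum of a Gaussian
  }
  s_pit0 <- min(max(s_pit0, bounds$sigma_pit[1] * 1.5), d_max / 2)
  a_para0 <- max(max(h_all) - B0, 5)
  s_para0 <- min(max(3 * s_pit0, 800), bounds$sigma_para[2] * 0.8)
  c(B0, a_pit0, s_pit0, a_para0, s_para0, a_pit0, s_pit0, a_para0, s_para0)
}

#' Fit the asymmetric difference-of-Gaussians foveal contour model
#'
#' Models the nasal and temporal halves of a pit-centered ILM profile
#' separately as
#' \deqn{h_s(d) = B + A_{para,s} e^{-d^2/2\sigma_{para,s}^2}
#'                 - A_{pit,s} e^{-d^2/2\sigma_{pit,s}^2}, \quad d = |x|,}
#' with the baseline \eqn{B} shared between sides. Parameters are estimated
#' by bounded Levenberg–Marquardt least squares
#' ([minpack.lm::nls.lm()]) with an analytic Jacobian, minimizing the sum
#' of squared residuals plus a penalty \eqn{\lambda (h_s(0) - h_{obs}(0))^2}
#' per side that ties both fitted contours to the observed pit-bottom
#' height. Starting values follow a typical foveal profile — a narrower
#' inverted Gaussian for the pit, a wider non-inverted Gaussian for the
#' parafovea — and `multistart` jittered restarts guard against local
#' minima; the best fit by total root sum of squares is returned.
#'
#' @param profile a pit-centered [ilm_profile()] in µm with at least 20
#'   samples on each side.
#' @param config a [dog_fit_config()].
#' @return An object of class `dog_fit`: baseline, per-side parameters,
#'   `rss` (root sum of squares of the data residuals per side), total
#'   `objective`, `converged` and `degenerate` flags, per-side sample
#'   counts and maximum fitted distances, the observed pit-bottom height
#'   and the configuration.
#' @export
fit_dog <- function(profile, config = dog_fit_config()) {
  stopifnot(inherits(profile, "ilm_profile"))
  if (profile$units != "um") {
    stop("profile must be in micrometre units (see to_micrometers)", call. = FALSE)
  }
  sides <- split_profile_sides(profile)
  if (length(sides$nasal$d) < 20 || length(sides$temporal$d) < 20) {
    stop("insufficient data: need at least 20 samples on each side of the pit",
         call. = FALSE)
  }
  b <- config$bounds
  lower <- c(b$baseline[1],
             rep(c(b$a_pit[1], b$sigma_pit[1], b$a_para[1], b$sigma_para[1]), 2))
  upper <- c(b$baseline[2],
             rep(c(b$a_pit[2], b$sigma_pit[2], b$a_para[2], b$sigma_para[2]), 2))
  p0 <- .dog_init(sides, b)
  clamp <- function(p) pmin(pmax(p, lower * 1.0 + 1e-9), upper - 1e-9)

  starts <- list(p0)
  if (config$multistart > 1) {
    jit <- withr::with_seed(
      substream_seed(config$seed, "dog_multistart"),
      lapply(seq_len(config$multistart - 1), function(i) {
        f <- 1 + runif(9, -config$jitter, config$jitter)
        p <- p0 * f
        # keep the pit Gaussian narrower than the parafoveal one
        p[5] <- max(p[5], 1.5 * p[3])
        p[9] <- max(p[9], 1.5 * p[7])
        p
      })
    )
    starts <- c(starts, jit)
  }
  starts <- lapply(starts, clamp)

  best <- NULL
  best_obj <- Inf
  for (p_start in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = p_start, lower = lower, upper = upper,
        fn = .dog_residuals, jac = .dog_jacobian,
        sides = sides, lambda = config$lambda,
        control = minpack.lm::nls.lm.control(
          maxiter = config$maxiter, ftol = config$ftol, ptol = config$ptol)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    obj <- sum(res$fvec^2)
    if (is.finite(obj) && obj < best_obj) {
      best_obj <- obj
      best <- res
    }
  }
  if (is.null(best)) {
    stop("convergence error: no finite-residual DoG fit found", call. = FALSE)
  }
  u <- .p_unpack(best$par)
  nN <- length(sides$nasal$d)
  nT <- length(sides$temporal$d)
  fv <- .dog_residuals(best$par, sides, config$lambda)
  rss <- c(nasal = sqrt(sum(fv[seq_len(nN)]^2)),
           temporal = sqrt(sum(fv[nN + seq_len(nT)]^2)))
  sigma_order_ok <- u$nasal$sigma_pit < u$nasal$sigma_para &&
    u$temporal$sigma_pit < u$temporal$sigma_para
  structure(
    list(baseline = u$baseline, nasal = u$nasal, temporal = u$temporal,
         lambda = config$lambda, rss = rss, objective = best_obj,
         converged = best$info %in% 1:4 && all(is.finite(best$par)),
         degenerate = min(u$nasal$a_pit, u$temporal$a_pit) < config$degenerate_a_pit,
         sigma_order_ok = sigma_order_ok,
         n_points = c(nasal = nN, temporal = nT),
         d_max = c(nasal = max(sides$nasal$d), temporal = max(sides$temporal$d)),
         pit_height_obs = sides$pit_h,
         optim_info = best$info, optim_message = best$message,
         config = config),
    class = "dog_fit"
  )
}

#' @exportS3Method base::print
print.dog_fit <- function(x, ...) {
  cat("<dog_fit>\n")
  cat(sprintf("  baseline B: %.2f um (shared)\n", x$baseline))
  for (s in c("nasal", "temporal")) {
    p <- x[[s]]
    cat(sprintf("  %-8s A_pit %.2f um (sigma %.1f), A_para %+.2f um (sigma %.1f), rss %.2f\n",
                s, p$a_pit, p$sigma_pit, p$a_para, p$sigma_para, x$rss[[s]]))
  }
  cat(sprintf("  converged: %s%s%s\n", x$converged,
              if (x$degenerate) ", degenerate (no pit)" else "",
              if (!x$sigma_order_ok) ", sigma ordering violated" else ""))
  invisible(x)
}

#' Evaluate a fitted DoG contour or its derivatives
#'
#' Closed-form evaluation of the fitted half-profile \eqn{h_s(d)} or its
#' first, second or third derivative with respect to the pit distance
#' \eqn{d \ge 0}, using the analytic Gaussian derivative formulas.
#'
#' @param fit a [fit_dog()] result.
#' @param side `"nasal"` or `"temporal"`.
#' @param d distances from the pit center, µm (>= 0); vectorized.
#' @param order derivative order 0, 1, 2 or 3.
#' @return Numeric vector: µm for order 0, µm per µm^order otherwise.
#' @export
dog_eval <- function(fit, side = c("nasal", "temporal"), d, order = 0) {
  stopifnot(inherits(fit, "dog_fit"))
  side <- match.arg(side)
  if (!order %in% 0:3) stop("order must be 0, 1, 2 or 3", call. = FALSE)
  if (any(d < 0)) stop("d must be >= 0", call. = FALSE)
  s <- fit[[side]]
  dog_side_value(fit$baseline, s$a_pit, s$sigma_pit, s$a_para, s$sigma_para,
                 d, order)
}
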