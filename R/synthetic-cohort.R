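#' Specification of a synthetic longitudinal cohort
#'
#' Defines the generating model for a preterm imaging cohort: infants are
#' imaged every 1–2 weeks between 31 and 44 weeks postmenstrual age (PMA);
#' foveal width follows a group-specific linear PMA trend (decreasing
#' without ROP, increasing with ROP) around group intercepts at 32 weeks,
#' with a per-infant random intercept and visit-level residual noise.
#' Depth, central foveal thickness and slope follow quadratic PMA trends;
#' all secondary parameters carry gestational-age (GA) and birthweight (BW)
#' effects.
#'
#' The default width slopes and 32-week intercepts are the published effect
#' sizes for this population (-11.18 µm/week without ROP, +24.96 µm/week
#' with ROP; 1,584.9 vs 1,203.6 µm at 32 weeks). Variance components are
#' not published; the defaults (between-infant SD 150 µm, residual SD
#' 100 µm for width, other parameters scaled proportionally) are chosen to
#' give visible but recoverable effects.
#'
#' @param n_infants number of infants.
#' @param pma_range PMA window in weeks, within \[31, 44\].
#' @param visit_interval range of between-visit gaps in weeks, from \{1, 2\}.
#' @param prop_rop proportion of infants with ROP.
#' @param width_slope_rop_absent,width_slope_rop_present width change,
#'   µm/week, by visit-level ROP status.
#' @param width_intercepts_at_32wk named vector `c(absent=, present=)`,
#'   mean width in µm at 32 weeks PMA.
#' @param ga_range,bw_range GA (weeks) and BW (g) ranges.
#' @param between_infant_sd,residual_sd width variance components, µm. The
#'   other parameters' variance components are scaled by
#'   `residual_sd / 100` and `between_infant_sd / 150`, so a noiseless
#'   cohort (`0, 0`) is noiseless in every parameter.
#' @param param_effects per-parameter generating coefficients; see
#'   [default_param_effects()].
#' @param rop_transition_prob per-visit probability that an infant's ROP
#'   status toggles (default 0: status is persistent).
#' @param eyes `"both"` or `"right"`.
#' @param prop_poor_quality,prop_cystic per-visit exclusion probabilities;
#'   excluded rows carry no metric values.
#' @param seed integer seed for the cohort stream.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_infants = 80,
                        pma_range = c(31, 44),
                        visit_interval = c(1, 2),
                        prop_rop = 0.35,
                        width_slope_rop_absent = -11.18,
                        width_slope_rop_present = 24.96,
                        width_intercepts_at_32wk = c(absent = 1584.9,
                                                     present = 1203.6),
                        ga_range = c(24, 30),
                        bw_range = c(600, 1500),
                        between_infant_sd = 150,
                        residual_sd = 100,
                        param_effects = default_param_effects(),
                        rop_transition_prob = 0,
                        eyes = c("both", "right"),
                        prop_poor_quality = 0,
                        prop_cystic = 0,
                        seed = 1) {
  eyes <- match.arg(eyes)
  if (pma_range[1] < 31 || pma_range[2] > 44 || diff(pma_range) < 0) {
    stop("pma_range must lie within [31, 44]", call. = FALSE)
  }
  if (!all(visit_interval %in% 1:2)) {
    stop("visit_interval entries must be 1 or 2", call. = FALSE)
  }
  if (prop_rop < 0 || prop_rop > 1) stop("prop_rop must be in [0, 1]", call. = FALSE)
  if (between_infant_sd < 0 || residual_sd < 0) {
    stop("variance components must be >= 0", call. = FALSE)
  }
  if (diff(pma_range) < min(visit_interval)) {
    stop("configuration error: pma_range too narrow for two visits", call. = FALSE)
  }
  structure(
    list(n_infants = as.integer(n_infants), pma_range = pma_range,
         visit_interval = visit_interval, prop_rop = prop_rop,
         width_slope_rop_absent = width_slope_rop_absent,
         width_slope_rop_present = width_slope_rop_present,
         width_intercepts_at_32wk = width_intercepts_at_32wk,
         ga_range = ga_range, bw_range = bw_range,
         between_infant_sd = between_infant_sd, residual_sd = residual_sd,
         param_effects = param_effects,
         rop_transition_prob = rop_transition_prob, eyes = eyes,
         prop_poor_quality = prop_poor_quality, prop_cystic = prop_cystic,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Default generating coefficients for the secondary foveal parameters
#'
#' Each parameter is generated as
#' `intercept + pma * (PMA - 32) + pma2 * (PMA - 32)^2 + ga * (GA - 27) +
#'  bw * (BW - 1000) + infant effect + residual`,
#' with variance components `between_sd` / `resid_sd` (scaled globally by
#' the cohort spec). Units: µm for depth, CFT and pRT; µm² for area;
#' µm/µm for slope. `side_offset` is added on the nasal side and
#' subtracted on the temporal side for the per-side parameters (nasal
#' steeper and thicker).
#'
#' @return A named list of per-parameter coefficient lists.
#' @export
default_param_effects <- function() {
  list(
    area  = list(intercept = 35000, pma = 800, pma2 = 0, ga = 1500, bw = 8,
                 between_sd = 5000, resid_sd = 4000, side_offset = 0),
    depth = list(intercept = 45, pma = 3, pma2 = -0.12, ga = 2.5, bw = 0.01,
                 between_sd = 8, resid_sd = 6, side_offset = 0),
    cft   = list(intercept = 180, pma = -2.5, pma2 = 0.10, ga = -8, bw = -0.01,
                 between_sd = 12, resid_sd = 8, side_offset = 0),
    slope = list(intercept = 0.105, pma = 0.005, pma2 = -2e-4, ga = 0.004,
                 bw = 2e-5, between_sd = 0.012, resid_sd = 0.010,
                 side_offset = 0.008),
    prt   = list(intercept = 310, pma = 2, pma2 = 0, ga = 5, bw = 0.02,
                 between_sd = 20, resid_sd = 12, side_offset = 10)
  )
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws infants, assigns ROP status, schedules 1–2-weekly visits across
#' the PMA window, and generates the six foveal parameters from the
#' spec's linear/quadratic trends plus per-infant and residual noise.
#' Identical spec (including seed) gives a bit-identical table.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `table` (one row per infant x eye x visit; columns
#'   `infant_id, eye, visit, pma, ga, bw, rop, sex, ethnicity, birth,
#'   poor_quality, cystic, width, area, depth, cft, slope_nasal,
#'   slope_temporal, prt_nasal, prt_temporal`) and `truth` (the generating
#'   quantities: the spec, per-infant random intercepts and the group
#'   width slopes/intercepts).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(substream_seed(spec$seed, "cohort"), {
    n <- spec$n_infants
    noise_scale <- spec$residual_sd / 100
    between_scale <- spec$between_infant_sd / 150

    ga <- runif(n, spec$ga_range[1], spec$ga_range[2])
    bw_mid <- mean(spec$bw_range)
    bw <- bw_mid + (ga - mean(spec$ga_range)) *
      diff(spec$bw_range) / max(diff(spec$ga_range), 1e-9) * 0.4 +
      rnorm(n, 0, 0.08 * diff(spec$bw_range)) * noise_scale
    bw <- pmin(pmax(bw, spec$bw_range[1]), spec$bw_range[2])
    rop0 <- runif(n) < spec$prop_rop
    sex <- sample(c("male", "female"), n, replace = TRUE)
    ethnicity <- sample(c("caucasian", "non_caucasian"), n, replace = TRUE,
                        prob = c(0.7, 0.3))
    birth <- sample(c("single", "multiple"), n, replace = TRUE,
                    prob = c(0.8, 0.2))
    b_width <- rnorm(n, 0, spec$between_infant_sd)
    b_param <- lapply(spec$param_effects, function(pe)
      rnorm(n, 0, pe$between_sd * between_scale))

    eyes <- if (spec$eyes == "both") c("right", "left") else "right"
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      pma <- spec$pma_range[1]
      pmas <- pma
      repeat {
        step <- if (length(spec$visit_interval) == 1) spec$visit_interval else
          sample(seq(spec$visit_interval[1], spec$visit_interval[2]), 1)
        pma <- pma + step
        if (pma > spec$pma_range[2]) break
        pmas <- c(pmas, pma)
      }
      rop_path <- logical(length(pmas))
      rop_path[1] <- rop0[i]
      if (length(pmas) > 1) {
        for (v in 2:length(pmas)) {
          flip <- runif(1) < spec$rop_transition_prob
          rop_path[v] <- if (flip) !rop_path[v - 1] else rop_path[v - 1]
        }
      }
      inf <- lapply(seq_along(eyes), function(e) {
        nv <- length(pmas)
        pma_c <- pmas - 32
        grp <- ifelse(rop_path, "present", "absent")
        width <- ifelse(rop_path,
                        spec$width_intercepts_at_32wk[["present"]] +
                          spec$width_slope_rop_present * pma_c,
                        spec$width_intercepts_at_32wk[["absent"]] +
                          spec$width_slope_rop_absent * pma_c) +
          b_width[i] + rnorm(nv, 0, spec$residual_sd)
        gen_param <- function(name, side_sign = 0) {
          pe <- spec$param_effects[[name]]
          pe$intercept + pe$pma * pma_c + pe$pma2 * pma_c^2 +
            pe$ga * (ga[i] - 27) + pe$bw * (bw[i] - 1000) +
            side_sign * pe$side_offset +
            b_param[[name]][i] + rnorm(nv, 0, pe$resid_sd * noise_scale)
        }
        data.frame(
          infant_id = sprintf("I%03d", i), eye = eyes[e],
          visit = seq_len(nv), pma = pmas, ga = ga[i], bw = bw[i],
          rop = grp, sex = sex[i], ethnicity = ethnicity[i],
          birth = birth[i],
          poor_quality = runif(nv) < spec$prop_poor_quality,
          cystic = runif(nv) < spec$prop_cystic,
          width = pmax(width, 1),
          area = pmax(gen_param("area"), 1),
          depth = pmax(gen_param("depth"), 0.5),
          cft = pmax(gen_param("cft"), 1),
          slope_nasal = pmax(gen_param("slope", +1), 1e-4),
          slope_temporal = pmax(gen_param("slope", -1), 1e-4),
          prt_nasal = pmax(gen_param("prt", +1), 1),
          prt_temporal = pmax(gen_param("prt", -1), 1),
          stringsAsFactors = FALSE
        )
      })
      rows[[i]] <- do.call(rbind, inf)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    metric_cols <- c("width", "area", "depth", "cft", "slope_nasal",
                     "slope_temporal", "prt_nasal", "prt_temporal")
    excl <- tab$poor_quality | tab$cystic
    tab[excl, metric_cols] <- NA_real_

    list(
      table = tab,
      truth = list(
        spec = spec,
        slopes = c(absent = spec$width_slope_rop_absent,
                   present = spec$width_slope_rop_present),
        intercepts_32wk = spec$width_intercepts_at_32wk,
        random_intercepts_width = b_width
      )
    )
  })
}
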