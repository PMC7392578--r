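#' Cohort exclusion and subgroup accounting
#'
#' Tabulates the recruitment-level exclusions (unanalyzable image quality,
#' cystic central-retinal changes) over the recruited denominator, and the
#' ROP-pattern subgroups (never / always / sometimes ROP) over the analyzed
#' denominator. Each family of percentages is rounded by the
#' largest-remainder method so that a full partition sums to exactly 100%,
#' matching how clinical cohort tables are reported.
#'
#' @param recruited number of infants recruited.
#' @param unanalyzable infants excluded for poor image quality.
#' @param cystic infants excluded for cystic foveal changes.
#' @param analyzed infants analyzed.
#' @param never_rop,always_rop,mixed_rop ROP-pattern subgroup counts among
#'   the analyzed infants.
#' @return Data frame with columns `group`, `count`, `denominator`,
#'   `percent` (integer).
#' @export
#' @examples
#' cohort_accounting(174, 62, 25, 87, 57, 19, 11)
cohort_accounting <- function(recruited, unanalyzable, cystic, analyzed,
                              never_rop, always_rop, mixed_rop) {
  counts <- c(recruited, unanalyzable, cystic, analyzed,
              never_rop, always_rop, mixed_rop)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (recruited <= 0) stop("recruited must be positive", call. = FALSE)
  if (unanalyzable + cystic + analyzed != recruited) {
    stop(sprintf(
      "accounting error: unanalyzable + cystic + analyzed = %d, but recruited = %d",
      unanalyzable + cystic + analyzed, recruited), call. = FALSE)
  }
  if (never_rop + always_rop + mixed_rop != analyzed) {
    stop(sprintf(
      "accounting error: never_rop + always_rop + mixed_rop = %d, but analyzed = %d",
      never_rop + always_rop + mixed_rop, analyzed), call. = FALSE)
  }
  excl_pct <- largest_remainder_pct(c(unanalyzable, cystic, analyzed), recruited)
  rop_pct <- if (analyzed > 0) {
    largest_remainder_pct(c(never_rop, always_rop, mixed_rop), analyzed)
  } else c(NA_integer_, NA_integer_, NA_integer_)
  data.frame(
    group = c("unanalyzable", "cystic", "analyzed",
              "never_rop", "always_rop", "mixed_rop"),
    count = c(unanalyzable, cystic, analyzed, never_rop, always_rop, mixed_rop),
    denominator = c(recruited, recruited, recruited,
                    analyzed, analyzed, analyzed),
    percent = c(excl_pct, rop_pct),
    stringsAsFactors = FALSE
  )
}

# columns a cohort table must carry for modelling
.cohort_required <- c("infant_id", "eye", "pma", "ga", "bw", "rop",
                      "sex", "ethnicity", "birth")

#' Fit a longitudinal mixed model for one foveal parameter
#'
#' Linear mixed-effects model of a foveal parameter against PMA with a
#' random intercept per infant:
#' `value ~ pma_c * rop + [pma_c^2] + (ga | bw) + sex + ethnicity + birth +
#'  eye [+ side] + (1 | infant_id)`,
#' where `pma_c` is PMA centered at 32 weeks, so the ROP main effect is the
#' 32-week group contrast. GA and BW are *separate predictor models* — the
#' adjustment uses one or the other, never both. Factor terms with fewer
#' than two observed levels are dropped automatically. Fitting is by
#' restricted maximum likelihood ([lmerTest::lmer()]); per-term tests are
#' Wald-type t-tests with Satterthwaite degrees of freedom.
#'
#' @param table cohort data frame (see [gen_cohort()] for the column
#'   dictionary). Rows flagged `poor_quality` or `cystic`, and rows with a
#'   missing response, are dropped.
#' @param response one of `"width"`, `"area"`, `"depth"`, `"cft"`, or —
#'   with `sided = TRUE` — `"slope"` or `"prt"` (modelled long with a
#'   `side` factor from the `_nasal` / `_temporal` columns).
#' @param adjustment `"ga"` or `"bw"`.
#' @param quadratic_pma add a quadratic PMA term (used for depth, CFT and
#'   steepest slope, which change nonlinearly with PMA).
#' @param sided model the nasal/temporal measurements jointly with a side
#'   factor.
#' @param center_pma centering constant for PMA, weeks.
#' @return A `mixed_model_result`: fixed-effect table (estimate, SE, df, t,
#'   p per term), random-intercept and residual variances, ROP-group PMA
#'   slopes with SEs, sample sizes, convergence flag, and the fitted
#'   `lmerMod` object.
#' @export
fit_mixed_model <- function(table, response, adjustment = c("ga", "bw"),
                            quadratic_pma = FALSE, sided = FALSE,
                            center_pma = 32) {
  adjustment <- match.arg(adjustment)
  missing_cols <- setdiff(.cohort_required, names(table))
  if (length(missing_cols)) {
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- table
  for (fl in c("poor_quality", "cystic")) {
    if (fl %in% names(dat)) dat <- dat[!isTRUE_vec(dat[[fl]]), , drop = FALSE]
  }
  if (sided) {
    cn <- paste0(response, c("_nasal", "_temporal"))
    if (!all(cn %in% names(dat))) {
      stop("sided response needs columns ", paste(cn, collapse = " and "),
           call. = FALSE)
    }
    long_n <- dat
    long_n$value <- dat[[cn[1]]]
    long_n$side <- "nasal"
    long_t <- dat
    long_t$value <- dat[[cn[2]]]
    long_t$side <- "temporal"
    dat <- rbind(long_n, long_t)
  } else {
    if (!response %in% names(dat)) {
      stop("response column not found: ", response, call. = FALSE)
    }
    dat$value <- dat[[response]]
  }
  dat <- dat[!is.na(dat$value), , drop = FALSE]
  nv <- table(dat$infant_id)
  if (mean(nv >= 2) < 0.5) {
    stop("need at least 2 visits for at least half of the infants", call. = FALSE)
  }
  dat$pma_c <- dat$pma - center_pma
  dat$rop <- factor(dat$rop, levels = c("absent", "present"))
  for (f in c("sex", "ethnicity", "birth", "eye", if (sided) "side")) {
    if (f %in% names(dat)) dat[[f]] <- factor(dat[[f]])
  }

  has2 <- function(f) f %in% names(dat) && nlevels(droplevels(dat[[f]])) >= 2
  terms <- "pma_c"
  if (quadratic_pma) terms <- c(terms, "I(pma_c^2)")
  if (has2("rop")) terms <- c(terms, "rop", "pma_c:rop")
  terms <- c(terms, adjustment)
  for (f in c("sex", "ethnicity", "birth", "eye", if (sided) "side")) {
    if (has2(f)) terms <- c(terms, f)
  }
  form <- stats::as.formula(
    paste("value ~", paste(terms, collapse = " + "), "+ (1 | infant_id)"))

  converged <- TRUE
  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = dat, REML = TRUE),
    warning = function(w) {
      if (grepl("converge|singular", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )

  sm <- summary(fit)$coefficients
  fixed <- data.frame(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    df = sm[, "df"],
    t = sm[, "t value"],
    p = sm[, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_infant <- vc$vcov[vc$grp == "infant_id"][1]
  var_resid <- vc$vcov[vc$grp == "Residual"][1]

  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  slopes <- NULL
  int_term <- grep("^pma_c:rop", names(beta), value = TRUE)
  if ("pma_c" %in% names(beta)) {
    k_abs <- as.numeric(names(beta) == "pma_c")
    sl_abs <- c(sum(k_abs * beta), sqrt(drop(t(k_abs) %*% V %*% k_abs)))
    slopes <- data.frame(group = "absent", estimate = sl_abs[1], se = sl_abs[2],
                         stringsAsFactors = FALSE)
    if (length(int_term)) {
      k_pre <- as.numeric(names(beta) %in% c("pma_c", int_term))
      sl_pre <- c(sum(k_pre * beta), sqrt(drop(t(k_pre) %*% V %*% k_pre)))
      slopes <- rbind(slopes,
                      data.frame(group = "present", estimate = sl_pre[1],
                                 se = sl_pre[2], stringsAsFactors = FALSE))
    }
  }

  structure(
    list(response = response, adjustment = adjustment,
         quadratic_pma = quadratic_pma, sided = sided,
         center_pma = center_pma,
         fixed = fixed,
         random = list(var_infant = var_infant, sd_infant = sqrt(var_infant),
                       var_resid = var_resid, sd_resid = sqrt(var_resid)),
         slopes = slopes,
         n_obs = nrow(dat), n_infants = length(unique(dat$infant_id)),
         converged = converged,
         formula = form, model = fit,
         data_ranges = list(pma = range(dat$pma),
                            ga = range(dat$ga), bw = range(dat$bw)),
         xlevels = lapply(Filter(function(f) f %in% names(dat),
                                 c("rop", "sex", "ethnicity", "birth", "eye",
                                   if (sided) "side")),
                          function(f) levels(dat[[f]])) |>
           setNames(Filter(function(f) f %in% names(dat),
                           c("rop", "sex", "ethnicity", "birth", "eye",
                             if (sided) "side")))),
    class = "mixed_model_result"
  )
}

# treat NA flags as FALSE
isTRUE_vec <- function(x) !is.na(x) & x

#' @exportS3Method base::print
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("<mixed_model_result: %s ~ PMA x ROP, %s-adjusted%s>\n",
              x$response, toupper(x$adjustment),
              if (x$quadratic_pma) ", quadratic PMA" else ""))
  cat(sprintf("  n_obs %d, n_infants %d, converged %s\n",
              x$n_obs, x$n_infants, x$converged))
  print(transform(x$fixed, estimate = signif(estimate, 5),
                  se = signif(se, 4), df = round(df, 1),
                  t = round(t, 2), p = signif(p, 3)), row.names = FALSE)
  cat(sprintf("  random intercept SD %.3f, residual SD %.3f\n",
              x$random$sd_infant, x$random$sd_resid))
  if (!is.null(x$slopes)) {
    for (i in seq_len(nrow(x$slopes))) {
      cat(sprintf("  PMA slope (ROP %s): %.3f +- %.3f per week\n",
                  x$slopes$group[i], x$slopes$estimate[i], x$slopes$se[i]))
    }
  }
  invisible(x)
}

#' Predicted means with 95% confidence intervals
#'
#' Evaluates the fixed-effect linear predictor at one or more covariate
#' profiles and returns Wald confidence intervals; with exactly two
#' profiles the ratio of the first to the second predicted mean is also
#' reported as a rounded percentage. Unspecified numeric covariates
#' default to their sample means, unspecified factors to their reference
#' level. Profiles outside the observed PMA range are flagged as
#' extrapolated.
#'
#' @param result a [fit_mixed_model()] result.
#' @param profiles a list of named lists, e.g.
#'   `list(list(pma = 32, rop = "present"), list(pma = 32, rop = "absent"))`.
#' @param level confidence level.
#' @return Data frame with `estimate`, `se`, `lower`, `upper`,
#'   `extrapolated` per profile; attribute `ratio_pct` when two profiles
#'   are given.
#' @export
predict_means <- function(result, profiles, level = 0.95) {
  stopifnot(inherits(result, "mixed_model_result"))
  if (!is.null(names(profiles)) && !is.list(profiles[[1]])) {
    profiles <- list(profiles)
  }
  fit <- result$model
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  mf <- stats::model.frame(fit)
  Terms <- delete.response(terms(lme4::nobars(formula(fit, fixed.only = TRUE))))

  build_row <- function(pr) {
    nd <- list()
    if (is.null(pr$pma)) stop("each profile must give pma", call. = FALSE)
    nd$pma_c <- pr$pma - result$center_pma
    nd[[result$adjustment]] <-
      pr[[result$adjustment]] %||% mean(mf[[result$adjustment]])
    for (f in names(result$xlevels)) {
      lv <- result$xlevels[[f]]
      nd[[f]] <- factor(pr[[f]] %||% lv[1], levels = lv)
    }
    as.data.frame(nd, stringsAsFactors = FALSE)
  }
  nd <- do.call(rbind, lapply(profiles, build_row))
  X <- model.matrix(Terms, nd)
  est <- drop(X %*% beta)
  se <- sqrt(diag(X %*% V %*% t(X)))
  z <- qnorm(1 - (1 - level) / 2)
  pma_in <- vapply(profiles, function(pr) {
    pr$pma >= result$data_ranges$pma[1] && pr$pma <= result$data_ranges$pma[2]
  }, logical(1))
  if (any(!pma_in)) {
    warning("profile PMA outside the observed range; prediction is an extrapolation",
            call. = FALSE)
  }
  out <- data.frame(estimate = est, se = se,
                    lower = est - z * se, upper = est + z * se,
                    extrapolated = !pma_in)
  if (nrow(out) == 2) {
    attr(out, "ratio_pct") <- percent_ratio(est[1], est[2])
  }
  out
}

#' Ratio of two means as a rounded percentage
#'
#' @param numerator,denominator positive scalars on the same scale.
#' @return `100 * numerator / denominator`, rounded half-up to an integer.
#' @export
#' @examples
#' percent_ratio(1203.6, 1584.9)  # 76
percent_ratio <- function(numerator, denominator) {
  if (denominator == 0) stop("denominator must be nonzero", call. = FALSE)
  as.integer(round_half_up(100 * numerator / denominator))
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' Association between parafoveal inversion (inverted / non-inverted fit)
#' and ROP group. Continuity correction is off by default (Pearson's
#' statistic as usually reported for image-level counts).
#'
#' @param table 2 x 2 matrix of counts.
#' @param correct apply the Yates continuity correction.
#' @return List with `statistic`, `p_value`, `df` (= 1), `expected`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2 x 2", call. = FALSE)
  if (any(table < 0) || sum(table) == 0) {
    stop("cells must be non-negative with a positive total", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("undefined test: a row or column margin is zero", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter), expected = ct$expected)
}

#' Empirical type-I error of the ROP-by-PMA interaction test
#'
#' Simulates cohorts with no ROP effect (equal width slopes and intercepts
#' in both groups), fits the width mixed model to each, and reports the
#' proportion of replicates in which the ROP x PMA interaction is rejected
#' at `alpha`. With a calibrated test this proportion should sit near
#' `alpha`.
#'
#' @param n_reps number of replicate cohorts.
#' @param n_infants infants per replicate (reduced n keeps the study fast).
#' @param alpha nominal level.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param spec optional base [cohort_spec()] to modify; the ROP effect is
#'   nulled out regardless.
#' @return List with `rejection_rate`, `n_reps`, `alpha`, and the vector of
#'   interaction p-values.
#' @export
estimate_type1_error <- function(n_reps = 500, n_infants = 25, alpha = 0.05,
                                 seed = 1, spec = NULL) {
  pvals <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    sp <- spec %||% cohort_spec(eyes = "right")
    sp$n_infants <- as.integer(n_infants)
    sp$width_slope_rop_present <- sp$width_slope_rop_absent
    sp$width_intercepts_at_32wk[["present"]] <-
      sp$width_intercepts_at_32wk[["absent"]]
    sp$seed <- as.integer((seed + r) %% 2147483647)
    cohort <- gen_cohort(sp)
    res <- tryCatch(
      fit_mixed_model(cohort$table, "width", adjustment = "ga"),
      error = function(e) NULL
    )
    if (is.null(res)) next
    row <- grep("^pma_c:rop", res$fixed$term)
    if (length(row)) pvals[r] <- res$fixed$p[row[1]]
  }
  ok <- !is.na(pvals)
  list(rejection_rate = mean(pvals[ok] < alpha), n_reps = sum(ok),
       alpha = alpha, p_values = pvals)
}
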