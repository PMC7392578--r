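# --- Readers and writers. CSV: UTF-8, comma separated, header row, '.' ---
# --- decimal, '#' comment lines; numbers written with 17 significant   ---
# --- digits so write-then-read is an exact round trip. JSON for nested ---
# --- results. Units are µm / weeks / grams throughout.                 ---

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

write_csv_precise <- function(df, path, comment = NULL) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  })
  lines <- c(
    comment,
    paste(names(df), collapse = ","),
    do.call(paste, c(cols, sep = ","))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write / read an ILM profile as CSV
#'
#' The profile is written as a two-column CSV (`x_um`, `h_um`) with full
#' float precision, plus a JSON metadata sidecar (`<path>.json`) carrying
#' units and acquisition metadata. `read_profile_csv()` validates the
#' schema and invariants and reports the offending row on failure.
#'
#' @param profile an [ilm_profile()] in micrometres.
#' @param path CSV file path.
#' @return `write_profile_csv()`: the path, invisibly.
#'   `read_profile_csv()`: an [ilm_profile()].
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "ilm_profile"))
  write_csv_precise(data.frame(x_um = profile$x, h_um = profile$h), path)
  meta <- list(units = profile$units, metadata = profile$metadata,
               quality_flags = profile$quality_flags)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("x_um", "h_um")) {
    if (!col %in% names(df)) {
      stop(sprintf("profile CSV is missing column '%s'", col), call. = FALSE)
    }
  }
  bad <- which(!is.finite(df$x_um) | !is.finite(df$h_um))
  if (length(bad)) {
    stop(sprintf("profile CSV row %d: non-numeric value", bad[1]), call. = FALSE)
  }
  inc <- which(diff(df$x_um) <= 0)
  if (length(inc)) {
    stop(sprintf("profile CSV row %d: x_um not strictly increasing", inc[1] + 1),
         call. = FALSE)
  }
  neg <- which(df$h_um < 0)
  if (length(neg)) {
    stop(sprintf("profile CSV row %d: negative height h_um", neg[1]),
         call. = FALSE)
  }
  meta <- list()
  flags <- character()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    js <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta <- as.list(js$metadata %||% list())
    flags <- as.character(js$quality_flags %||% character())
  }
  ilm_profile(df$x_um, df$h_um, units = "um", metadata = meta,
              quality_flags = flags)
}

.cohort_metric_cols <- c("width", "area", "depth", "cft", "slope_nasal",
                         "slope_temporal", "prt_nasal", "prt_temporal")

validate_cohort_table <- function(df) {
  need <- c(.cohort_required, "poor_quality", "cystic")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check <- function(bad, msg) {
    i <- which(bad)
    if (length(i)) stop(sprintf("cohort row %d: %s", i[1], msg), call. = FALSE)
  }
  check(df$pma < 31 | df$pma > 44, "pma outside [31, 44] weeks")
  check(df$ga >= df$pma, "ga must be smaller than pma")
  check(df$bw <= 0, "bw must be positive")
  excl <- isTRUE_vec(df$poor_quality) | isTRUE_vec(df$cystic)
  for (mc in intersect(.cohort_metric_cols, names(df))) {
    check(excl & !is.na(df[[mc]]),
          sprintf("excluded row carries a value in '%s'", mc))
  }
  invisible(df)
}

#' Write / read a longitudinal cohort table as CSV
#'
#' Column dictionary: `infant_id`; `eye` (right/left); `visit` (index);
#' `pma` (weeks, 31–44); `ga` (weeks, < pma); `bw` (g); `rop`
#' (absent/present at the visit); `sex`; `ethnicity`
#' (caucasian/non_caucasian); `birth` (single/multiple); `poor_quality`,
#' `cystic` (exclusion flags — excluded rows carry no metric values);
#' metrics `width, area, depth, cft` (µm / µm²) and per-side
#' `slope_nasal, slope_temporal` (µm/µm), `prt_nasal, prt_temporal` (µm).
#' Both functions validate the invariants and name the offending row and
#' column on failure.
#'
#' @param table cohort data frame.
#' @param path CSV file path.
#' @param comment optional comment lines (prefixed `#`) written above the
#'   header.
#' @return `write_cohort_csv()`: the path, invisibly. `read_cohort_csv()`:
#'   a validated data frame.
#' @export
write_cohort_csv <- function(table, path, comment = NULL) {
  validate_cohort_table(table)
  if (!is.null(comment)) comment <- paste0("# ", comment)
  write_csv_precise(table, path, comment = comment)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 na.strings = c("NA", ""))
  for (fl in c("poor_quality", "cystic")) {
    if (fl %in% names(df)) df[[fl]] <- as.logical(df[[fl]])
  }
  validate_cohort_table(df)
  df
}

.fit_json_required <- c("a_pit", "sigma_pit", "a_para", "sigma_para")

#' Write / read a DoG fit as JSON
#'
#' Serializes all fitted parameters, residuals, convergence diagnostics and
#' the fitting configuration. `read_fit_json()` checks the schema and names
#' the first missing field.
#'
#' @param fit a [fit_dog()] result.
#' @param path JSON file path.
#' @return `write_fit_json()`: the path, invisibly. `read_fit_json()`: a
#'   `dog_fit` object.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "dog_fit"))
  payload <- list(
    baseline = fit$baseline,
    nasal = fit$nasal, temporal = fit$temporal,
    lambda = fit$lambda,
    rss = as.list(fit$rss), objective = fit$objective,
    converged = fit$converged, degenerate = fit$degenerate,
    sigma_order_ok = fit$sigma_order_ok,
    n_points = as.list(fit$n_points), d_max = as.list(fit$d_max),
    pit_height_obs = fit$pit_height_obs,
    optim_info = fit$optim_info,
    config = fit$config[c("lambda", "multistart", "jitter", "seed",
                          "maxiter", "ftol", "ptol", "degenerate_a_pit")]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(js$baseline)) {
    stop("fit JSON missing field 'baseline'", call. = FALSE)
  }
  for (side in c("nasal", "temporal")) {
    if (is.null(js[[side]])) {
      stop(sprintf("fit JSON missing field '%s'", side), call. = FALSE)
    }
    for (f in .fit_json_required) {
      if (is.null(js[[side]][[f]])) {
        stop(sprintf("fit JSON missing field '%s.%s'", side, f), call. = FALSE)
      }
    }
  }
  cfg <- dog_fit_config()
  for (nm in names(js$config %||% list())) cfg[[nm]] <- js$config[[nm]]
  structure(
    list(baseline = js$baseline,
         nasal = as.list(js$nasal), temporal = as.list(js$temporal),
         lambda = js$lambda %||% cfg$lambda,
         rss = unlist(js$rss %||% c(nasal = NA_real_, temporal = NA_real_)),
         objective = js$objective %||% NA_real_,
         converged = isTRUE(js$converged),
         degenerate = isTRUE(js$degenerate),
         sigma_order_ok = isTRUE(js$sigma_order_ok %||% TRUE),
         n_points = unlist(js$n_points %||% c(nasal = NA, temporal = NA)),
         d_max = unlist(js$d_max %||% c(nasal = 5000, temporal = 5000)),
         pit_height_obs = js$pit_height_obs %||% NA_real_,
         optim_info = js$optim_info %||% NA_integer_,
         optim_message = "restored from JSON",
         config = cfg),
    class = "dog_fit"
  )
}
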