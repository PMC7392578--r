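#' ILM profile container
#'
#' An `ilm_profile` holds the inner-retinal contour of one flattened B-scan:
#' lateral positions `x` and heights `h` of the internal limiting membrane
#' above the Bruch membrane. In micrometre units `x` is pit-centered (0 at
#' the foveal pit center, temporal negative, nasal positive); in pixel units
#' `x` is the image column index.
#'
#' @param x numeric, strictly increasing lateral positions.
#' @param h numeric, heights above Bruch; must be non-negative (small
#'   negative values from noise are clamped to 0 and flagged).
#' @param units `"um"` or `"px"`.
#' @param metadata named list of acquisition metadata (e.g. `pma`, `ga`,
#'   `eye`, `infant_id`).
#' @param quality_flags character vector of quality annotations.
#' @return An object of class `ilm_profile`: a list with elements `x`, `h`,
#'   `units`, `metadata`, `quality_flags`.
#' @export
ilm_profile <- function(x, h, units = c("um", "px"), metadata = list(),
                        quality_flags = character()) {
  units <- match.arg(units)
  x <- as.numeric(x)
  h <- as.numeric(h)
  if (length(x) != length(h)) {
    stop("x and h must have equal length", call. = FALSE)
  }
  if (any(diff(x) <= 0)) {
    stop("x must be strictly increasing", call. = FALSE)
  }
  if (any(h < 0)) {
    if (min(h) < -1e-6) quality_flags <- c(quality_flags, "clamped_negative_h")
    h <- pmax(h, 0)
  }
  structure(
    list(x = x, h = h, units = units, metadata = metadata,
         quality_flags = quality_flags),
    class = "ilm_profile"
  )
}

#' @exportS3Method base::print
print.ilm_profile <- function(x, ...) {
  cat(sprintf("<ilm_profile: %d samples, x in [%.1f, %.1f] %s, h in [%.1f, %.1f] %s>\n",
              length(x$x), min(x$x), max(x$x), x$units,
              min(x$h), max(x$h), x$units))
  if (length(x$quality_flags)) {
    cat(" flags:", paste(x$quality_flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.ilm_profile <- function(x, ...) {
  data.frame(x = x$x, h = x$h)
}

# Split a pit-centered profile into per-side (distance, height) data.
# The sample nearest x = 0 serves as the observed pit-bottom height.
split_profile_sides <- function(profile) {
  x <- profile$x
  h <- profile$h
  i0 <- which.min(abs(x))
  list(
    nasal = list(d = x[x >= 0], h = h[x >= 0]),
    temporal = list(d = -x[x < 0], h = h[x < 0]),
    pit_h = h[i0]
  )
}
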