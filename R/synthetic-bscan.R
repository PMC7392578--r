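#' B-scan image container
#'
#' A grayscale OCT cross-section with its pixel scales. Rows run down the
#' image (increasing depth), columns run laterally; intensities are in
#' \[0, 1\].
#'
#' @param intensity numeric matrix (rows x columns), at least 16 x 16.
#' @param axial_um_per_px axial scale, µm per pixel (> 0).
#' @param lateral_um_per_px lateral scale, µm per pixel (> 0).
#' @param index optional slice index within a volume.
#' @return An object of class `bscan`.
#' @export
bscan <- function(intensity, axial_um_per_px, lateral_um_per_px, index = NA) {
  if (!is.matrix(intensity) || nrow(intensity) < 16 || ncol(intensity) < 16) {
    stop("intensity must be a matrix with at least 16 rows and columns",
         call. = FALSE)
  }
  if (axial_um_per_px <= 0 || lateral_um_per_px <= 0) {
    stop("pixel scales must be positive", call. = FALSE)
  }
  structure(
    list(intensity = intensity, axial_um_per_px = axial_um_per_px,
         lateral_um_per_px = lateral_um_per_px, index = index),
    class = "bscan"
  )
}

#' @exportS3Method base::print
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan: %d x %d px, %.3f um/px axial, %.3f um/px lateral>\n",
              nrow(x$intensity), ncol(x$intensity),
              x$axial_um_per_px, x$lateral_um_per_px))
  invisible(x)
}

#' Scan geometry for the synthetic B-scan renderer
#'
#' Defaults follow a hand-held OCT macular volume of 500 A-scans over 10 mm
#' laterally (20 µm/px) and a 2 mm axial window rendered over 512 rows
#' (3.906 µm/px). `bruch_row` places the Bruch membrane; `bruch_tilt_px`
#' adds a linear ramp (0 at the first column up to the stated pixels at the
#' last) emulating an un-flattened acquisition.
#'
#' @param n_cols,n_rows image size in pixels.
#' @param lateral_um_per_px,axial_um_per_px pixel scales, µm.
#' @param bruch_row Bruch membrane row at the first column.
#' @param bruch_tilt_px total linear Bruch tilt across the image, pixels.
#' @param band_px thickness of the bright ILM/Bruch bands, pixels.
#' @return A `scan_geometry` list.
#' @export
scan_geometry <- function(n_cols = 500, n_rows = 512,
                          lateral_um_per_px = 10000 / 500,
                          axial_um_per_px = 2000 / 512,
                          bruch_row = 400, bruch_tilt_px = 0, band_px = 3) {
  stopifnot(n_cols >= 16, n_rows >= 16,
            lateral_um_per_px > 0, axial_um_per_px > 0, band_px >= 1)
  structure(
    list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
         lateral_um_per_px = lateral_um_per_px,
         axial_um_per_px = axial_um_per_px,
         bruch_row = bruch_row, bruch_tilt_px = bruch_tilt_px,
         band_px = as.integer(band_px)),
    class = "scan_geometry"
  )
}

# Band intensities of the three-zone piecewise-constant renderer.
.bands <- list(vitreous = 0.05, ilm = 0.85, tissue = 0.45,
               bruch = 1.0, below = 0.10)

#' Render a synthetic B-scan with known boundaries
#'
#' Draws a three-band piecewise-constant image from a ground-truth contour:
#' dark vitreous above a bright ILM band, mid-gray tissue down to a bright
#' Bruch band, dark choroid below. Optional Gaussian blur and multiplicative
#' log-normal speckle. The renderer guarantees that the returned per-column
#' ILM/Bruch rows are exactly the band boundaries drawn; pixel statistics
#' are otherwise nominal.
#'
#' @param truth a [profile_truth()] for the ILM contour.
#' @param geometry a [scan_geometry()].
#' @param blur_sigma Gaussian blur SD in pixels (0 disables).
#' @param speckle_sd log-normal speckle SD (0 disables).
#' @param seed seed for the speckle stream; defaults to the truth seed.
#' @return A list with `image` (a [bscan()]), `ilm_rows` and `bruch_rows`
#'   (integer ground-truth boundary row per column), `truth`, `geometry`.
#' @export
gen_bscan <- function(truth, geometry = scan_geometry(),
                      blur_sigma = 1, speckle_sd = 0.08, seed = truth$seed) {
  stopifnot(inherits(truth, "profile_truth"), inherits(geometry, "scan_geometry"))
  nc <- geometry$n_cols
  nr <- geometry$n_rows
  x <- (seq_len(nc) - (floor(nc / 2) + 1)) * geometry$lateral_um_per_px
  h_um <- truth_height(truth, x)
  bruch_rows <- as.integer(round(
    geometry$bruch_row +
      geometry$bruch_tilt_px * (seq_len(nc) - 1) / (nc - 1)
  ))
  ilm_rows <- as.integer(bruch_rows - round(h_um / geometry$axial_um_per_px))
  bp <- geometry$band_px
  if (any(ilm_rows < 1) || any(bruch_rows + bp - 1 > nr) ||
      any(ilm_rows >= bruch_rows)) {
    stop("contour leaves image bounds for this geometry", call. = FALSE)
  }
  img <- matrix(.bands$vitreous, nr, nc)
  for (j in seq_len(nc)) {
    ir <- ilm_rows[j]
    br <- bruch_rows[j]
    img[ir:min(ir + bp - 1, nr), j] <- .bands$ilm
    if (br > ir + bp) img[(ir + bp):(br - 1), j] <- .bands$tissue
    img[br:min(br + bp - 1, nr), j] <- .bands$bruch
    if (br + bp <= nr) img[(br + bp):nr, j] <- .bands$below
  }
  if (blur_sigma > 0) {
    img <- EBImage::gblur(img, sigma = blur_sigma)
  }
  if (speckle_sd > 0) {
    img <- img * withr::with_seed(
      substream_seed(seed, "bscan_speckle"),
      matrix(exp(rnorm(nr * nc, 0, speckle_sd)), nr, nc)
    )
  }
  img <- pmin(pmax(img, 0), 1)
  list(
    image = bscan(img, geometry$axial_um_per_px, geometry$lateral_um_per_px),
    ilm_rows = ilm_rows, bruch_rows = bruch_rows,
    truth = truth, geometry = geometry
  )
}

#' Render a synthetic B-scan volume with a known foveal slice
#'
#' Stacks `n_slices` B-scans whose pit amplitude is modulated by a Gaussian
#' across slices and peaks at `pit_slice`, so the deepest foveal depression
#' sits at a known slice.
#'
#' @inheritParams gen_bscan
#' @param n_slices number of B-scans in the volume.
#' @param pit_slice slice index at which the pit is deepest.
#' @param slice_sigma Gaussian width (in slices) of the pit modulation.
#' @return A list with `slices` (list of [bscan()]), `ilm_rows`/`bruch_rows`
#'   (matrices, slice x column), `pit_slice`, `geometry`.
#' @export
gen_bscan_volume <- function(truth, geometry = scan_geometry(),
                             n_slices = 100, pit_slice = 50,
                             slice_sigma = n_slices / 4,
                             blur_sigma = 1, speckle_sd = 0.08,
                             seed = truth$seed) {
  stopifnot(n_slices >= 1, pit_slice >= 1, pit_slice <= n_slices)
  slices <- vector("list", n_slices)
  ilm <- matrix(NA_integer_, n_slices, geometry$n_cols)
  brm <- matrix(NA_integer_, n_slices, geometry$n_cols)
  for (s in seq_len(n_slices)) {
    fac <- exp(-(s - pit_slice)^2 / (2 * slice_sigma^2))
    tr_s <- truth
    tr_s$nasal$pit_amplitude <- truth$nasal$pit_amplitude * fac
    tr_s$temporal$pit_amplitude <- truth$temporal$pit_amplitude * fac
    # keep the truth valid for arbitrarily small modulated amplitudes
    tr_s$nasal$pit_amplitude <- max(tr_s$nasal$pit_amplitude, 1e-6)
    tr_s$temporal$pit_amplitude <- max(tr_s$temporal$pit_amplitude, 1e-6)
    b <- gen_bscan(tr_s, geometry, blur_sigma = blur_sigma,
                   speckle_sd = speckle_sd,
                   seed = substream_seed(seed, paste0("slice", s)))
    b$image$index <- s
    slices[[s]] <- b$image
    ilm[s, ] <- b$ilm_rows
    brm[s, ] <- b$bruch_rows
  }
  list(slices = slices, ilm_rows = ilm, bruch_rows = brm,
       pit_slice = as.integer(pit_slice), geometry = geometry)
}

#' Write a B-scan volume as a multi-page TIFF
#'
#' @param volume result of [gen_bscan_volume()], or a list of [bscan()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bscan_tiff <- function(volume, path) {
  slices <- if (!is.null(volume$slices)) volume$slices else volume
  pages <- lapply(slices, function(s) s$intensity)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a single B-scan from a PNG file
#'
#' @param path PNG file path (grayscale or RGB; RGB is reduced to its first
#'   channel).
#' @param axial_um_per_px,lateral_um_per_px pixel scales to attach.
#' @return A [bscan()].
#' @export
read_bscan_png <- function(path, axial_um_per_px, lateral_um_per_px) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading PNG requires the 'png' package", call. = FALSE)
  }
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  bscan(m, axial_um_per_px, lateral_um_per_px)
}

#' Read a (multi-page) TIFF as a list of B-scans
#'
#' @param path TIFF file path.
#' @param axial_um_per_px,lateral_um_per_px pixel scales to attach.
#' @return A list of [bscan()] objects.
#' @export
read_bscan_tiff <- function(path, axial_um_per_px, lateral_um_per_px) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(seq_along(pages), function(i) {
    m <- pages[[i]]
    if (length(dim(m)) == 3) m <- m[, , 1]
    bscan(m, axial_um_per_px, lateral_um_per_px, index = i)
  })
}
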