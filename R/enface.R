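#' Construct an en-face OCTA image object
#'
#' Bundles an 8-bit pixel grid with the physical scan geometry and the
#' acquisition metadata the quantification pipeline needs. The nominal study
#' geometry is a 586 x 585 px scan covering 3 x 3 mm around the fovea, but
#' any positive geometry is accepted.
#'
#' @param pixels Numeric or integer matrix of intensities; every value must
#'   be an integer in \[0, 255\]. Rows index the vertical (height) axis.
#' @param extent_mm Length-2 numeric, physical scan size in mm as
#'   `c(height_mm, width_mm)`. A single value is recycled to both axes.
#' @param plexus `"SCP"` (superficial) or `"DCP"` (deep capillary plexus).
#' @param quality_score Device quality index in \[0, 100\], or `NA` if absent.
#' @param eye_id,visit Free-form identifiers carried through to output rows.
#'
#' @return An object of class `enface_image`: a list with elements `pixels`
#'   (integer matrix), `extent_mm`, `plexus`, `quality_score`, `eye_id`,
#'   `visit`.
#' @seealso [load_enface()], [to_8bit()], [pixel_scale_um()]
#' @export
enface_image <- function(pixels, extent_mm = c(3, 3), plexus = c("SCP", "DCP"),
                         quality_score = NA, eye_id = NA_character_,
                         visit = NA_character_) {
  if (!is.matrix(pixels)) {
    stop("`pixels` must be a 2D matrix; got ", paste(class(pixels), collapse = "/"))
  }
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255) ||
      any(pixels != round(pixels))) {
    stop("`pixels` must contain integers in [0, 255]; use to_8bit() to convert raw data")
  }
  plexus <- match.arg(plexus)
  extent_mm <- as.numeric(extent_mm)
  if (length(extent_mm) == 1L) extent_mm <- rep(extent_mm, 2L)
  if (length(extent_mm) != 2L || anyNA(extent_mm) || any(extent_mm <= 0)) {
    stop("`extent_mm` must be two positive values (height_mm, width_mm)")
  }
  if (!is.na(quality_score) &&
      (quality_score < 0 || quality_score > 100)) {
    stop("`quality_score` must be in [0, 100] or NA")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, extent_mm = extent_mm, plexus = plexus,
         quality_score = quality_score, eye_id = eye_id, visit = visit),
    class = "enface_image"
  )
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image> %d x %d px, %.2f x %.2f mm, plexus %s\n",
              nrow(x$pixels), ncol(x$pixels), x$extent_mm[1], x$extent_mm[2],
              x$plexus))
  cat(sprintf("  pitch: %.2f x %.2f um/px; quality: %s; eye: %s; visit: %s\n",
              pixel_scale_um(x$extent_mm[1], nrow(x$pixels)),
              pixel_scale_um(x$extent_mm[2], ncol(x$pixels)),
              ifelse(is.na(x$quality_score), "absent", x$quality_score),
              x$eye_id, x$visit))
  invisible(x)
}

#' Dimensions of an en-face image
#' @param x An `enface_image`.
#' @return `c(height_px, width_px)`.
#' @export
dim.enface_image <- function(x) dim(x$pixels)

#' Load an en-face OCTA image with sidecar metadata
#'
#' Reads a single-channel 8-bit PNG or TIFF and attaches the acquisition
#' metadata (scan extent, plexus, quality score, identifiers). Pixels are
#' taken as stored: 8-bit input is not rescaled. Higher bit depths must be
#' converted explicitly with [to_8bit()] so the rescaling is a recorded,
#' deliberate step.
#'
#' @param image_path Path to a PNG or TIFF file (extension decides the reader).
#' @param metadata Either a path to a JSON sidecar or a named list. Must
#'   supply `extent_mm` (scalar or length 2, mm) and `plexus`; may supply
#'   `quality_score`, `eye_id`, `visit`.
#' @return An [enface_image()].
#' @export
load_enface <- function(image_path, metadata) {
  if (!file.exists(image_path)) stop("image file not found: ", image_path)
  ext <- tolower(tools::file_ext(image_path))
  raw <- switch(ext,
    png = png::readPNG(image_path),
    tif = ,
    tiff = tiff::readTIFF(image_path, as.is = TRUE),
    stop("unsupported image format '.", ext, "' (use PNG or TIFF)")
  )
  if (length(dim(raw)) != 2L) {
    stop("expected a single-channel 2D image; got an array with dims ",
         paste(dim(raw), collapse = " x "),
         " (multi-channel input is not an en-face angiogram)")
  }
  if (ext == "png") {
    # readPNG normalizes to [0,1]; an 8-bit file maps back onto exact
    # integers, higher bit depths do not.
    px <- raw * 255
    if (max(abs(px - round(px))) > 1e-6) {
      stop("image is not 8-bit; convert with to_8bit() before quantification")
    }
    raw <- round(px)
  } else if (max(raw) > 255) {
    stop("image is not 8-bit; convert with to_8bit() before quantification")
  }
  meta <- if (is.character(metadata)) jsonlite::read_json(metadata, simplifyVector = TRUE) else metadata
  if (is.null(meta$extent_mm)) {
    if (!is.null(meta$extent_mm_h) && !is.null(meta$extent_mm_w)) {
      meta$extent_mm <- c(meta$extent_mm_h, meta$extent_mm_w)
    } else {
      stop("metadata must supply `extent_mm` (or `extent_mm_h`/`extent_mm_w`)")
    }
  }
  if (is.null(meta$plexus)) stop("metadata must supply `plexus` (SCP or DCP)")
  enface_image(
    pixels = raw,
    extent_mm = unlist(meta$extent_mm),
    plexus = meta$plexus,
    quality_score = if (is.null(meta$quality_score)) NA else meta$quality_score,
    eye_id = if (is.null(meta$eye_id)) NA_character_ else meta$eye_id,
    visit = if (is.null(meta$visit)) NA_character_ else meta$visit
  )
}

#' Linear 8-bit conversion of a raw intensity grid
#'
#' Min-max rescales a grid of finite non-negative intensities at any bit
#' depth to integers in \[0, 255\]. A constant grid carries no contrast and
#' maps to 0 everywhere (documented degenerate rule).
#'
#' @param raw_grid Numeric matrix of finite, non-negative intensities.
#' @return Integer matrix in \[0, 255\] with the same dimensions.
#' @export
to_8bit <- function(raw_grid) {
  if (!is.matrix(raw_grid)) stop("`raw_grid` must be a matrix")
  if (anyNA(raw_grid) || any(!is.finite(raw_grid))) {
    stop("`raw_grid` contains NA/NaN/Inf intensities")
  }
  if (any(raw_grid < 0)) stop("`raw_grid` contains negative intensities")
  lo <- min(raw_grid); hi <- max(raw_grid)
  if (hi == lo) {
    out <- array(0L, dim(raw_grid))
  } else {
    out <- round(255 * (raw_grid - lo) / (hi - lo))
    storage.mode(out) <- "integer"
  }
  out
}

#' Physical pixel pitch in micrometres
#'
#' For the nominal study geometry (3 mm over 585 px) the pitch is 5.13 um.
#'
#' @param extent_mm Physical extent along one axis, in mm (> 0).
#' @param n_pixels Number of pixels along that axis (>= 1).
#' @return Micrometres per pixel, `1000 * extent_mm / n_pixels`.
#' @export
pixel_scale_um <- function(extent_mm, n_pixels) {
  if (any(extent_mm <= 0)) stop("`extent_mm` must be > 0")
  if (any(n_pixels < 1)) stop("`n_pixels` must be >= 1")
  1000 * extent_mm / n_pixels
}

#' Filter visit records on device image quality
#'
#' Drops records whose quality score falls below the study cut-off (Topcon
#' Quality Index; the study excluded scans scoring below 45). Records with a
#' missing score cannot be vouched for and are excluded with a logged reason.
#'
#' @param records Data frame with a `quality_score` column (NA = absent).
#' @param min_quality Minimum acceptable score (default 45); retention is
#'   `quality_score >= min_quality`.
#' @return The retained rows. The dropped rows, with an `exclusion_reason`
#'   column (`"low quality"` or `"missing quality"`), are attached as
#'   attribute `"excluded"`.
#' @export
quality_filter <- function(records, min_quality = 45) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) return(records)
  if (is.null(records$quality_score)) stop("records lack a `quality_score` column")
  q <- records$quality_score
  keep <- !is.na(q) & q >= min_quality
  excluded <- records[!keep, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$exclusion_reason <- ifelse(is.na(excluded$quality_score),
                                        "missing quality", "low quality")
    message(nrow(excluded), " record(s) excluded by quality filter (cut-off ",
            min_quality, ")")
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}
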