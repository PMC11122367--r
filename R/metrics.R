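.as_mask <- function(x) {
  if (inherits(x, "binary_vessel_map") || inherits(x, "skeleton_map") ||
      inherits(x, "roi_mask")) x <- x$mask
  if (!is.matrix(x)) stop("expected a logical matrix or mask object")
  x
}

.check_roi <- function(mask, roi) {
  if (!identical(dim(mask), dim(roi))) stop("mask and ROI differ in shape")
  if (!any(roi)) stop("empty ROI")
}

#' Vessel area density (VAD)
#'
#' The proportion of the region of interest that exhibits observable
#' perfusion: vessel pixels in the ROI divided by ROI pixels.
#'
#' @param vessel_map Binary vessel map ([binarize_enface()] result or logical
#'   matrix).
#' @param roi_mask ROI ([make_region_mask()] result or logical matrix).
#' @return Fraction in \[0, 1\].
#' @export
compute_vad <- function(vessel_map, roi_mask) {
  m <- .as_mask(vessel_map); roi <- .as_mask(roi_mask)
  .check_roi(m, roi)
  sum(m & roi) / sum(roi)
}

#' Vessel skeleton density (VSD)
#'
#' Skeleton pixels in the ROI divided by ROI pixels: a caliber-independent
#' measure of the total length of the vascular network. Length is counted in
#' skeleton pixels (set `euclidean = TRUE` to weight diagonal skeleton steps
#' by sqrt(2) instead).
#'
#' @param skeleton A `skeleton_map` or logical matrix.
#' @param roi_mask ROI mask.
#' @param euclidean If `TRUE`, report Euclidean centerline length (diagonal
#'   8-neighbour steps contribute sqrt(2)/2 per endpoint pixel) instead of
#'   the pixel count. Default `FALSE`.
#' @return Fraction (length per ROI pixel).
#' @export
compute_vsd <- function(skeleton, roi_mask, euclidean = FALSE) {
  s <- .as_mask(skeleton); roi <- .as_mask(roi_mask)
  .check_roi(s, roi)
  if (!euclidean) return(sum(s & roi) / sum(roi))
  sum(.euclidean_length(s & roi)) / sum(roi)
}

# Per-pixel Euclidean length contribution: half the distance to each
# 8-neighbour on the skeleton (isolated pixels count 1).
.euclidean_length <- function(s) {
  h <- nrow(s); w <- ncol(s)
  p <- matrix(FALSE, h + 2L, w + 2L); p[2:(h + 1), 2:(w + 1)] <- s
  orth <- p[1:h, 2:(w + 1)] + p[3:(h + 2), 2:(w + 1)] +
          p[2:(h + 1), 1:w] + p[2:(h + 1), 3:(w + 2)]
  diago <- p[1:h, 1:w] + p[1:h, 3:(w + 2)] +
           p[3:(h + 2), 1:w] + p[3:(h + 2), 3:(w + 2)]
  len <- (orth + sqrt(2) * diago) / 2
  len[!s] <- 0
  len[s & orth + diago == 0] <- 1
  len
}

#' Vessel diameter index (VDI)
#'
#' Mean vascular caliber: vessel pixels divided by skeleton pixels within
#' the ROI, reported both in pixels and micrometres.
#'
#' @param vessel_map Binary vessel map.
#' @param skeleton Its skeleton.
#' @param roi_mask ROI mask.
#' @param pixel_um Physical pixel pitch in um (default 1: pixel units only).
#' @return Named list `vdi_px`, `vdi_um`. An empty skeleton inside the ROI
#'   makes the metric undefined and raises an error (reporting 0 would bias
#'   cohort means).
#' @export
compute_vdi <- function(vessel_map, skeleton, roi_mask, pixel_um = 1) {
  m <- .as_mask(vessel_map); s <- .as_mask(skeleton); roi <- .as_mask(roi_mask)
  .check_roi(m, roi)
  if (!identical(dim(s), dim(m))) stop("mask and skeleton differ in shape")
  n_skel <- sum(s & roi)
  if (n_skel == 0L) stop("empty skeleton within ROI: VDI is undefined")
  vdi_px <- sum(m & roi) / n_skel
  list(vdi_px = vdi_px, vdi_um = vdi_px * pixel_um)
}

#' Foveal avascular zone area from a traced contour
#'
#' Shoelace (Gauss) area of the manually traced FAZ polygon, in mm^2. The
#' closing edge is implied and the result is independent of vertex
#' orientation. Self-intersecting contours are rejected.
#'
#' @param contour n x 2 numeric matrix of polygon vertices in mm (n >= 3).
#' @return Area in mm^2 (non-negative).
#' @export
faz_area <- function(contour) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3L || ncol(contour) != 2L || anyNA(contour)) {
    stop("contour must be an n x 2 numeric matrix with n >= 3 vertices")
  }
  if (.polygon_self_intersects(contour)) {
    stop("contour is self-intersecting; trace a simple polygon")
  }
  x <- contour[, 1]; y <- contour[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  a1 <- v; a2 <- v[c(2:n, 1), , drop = FALSE]
  cross <- function(o, p, q) {
    (p[1] - o[1]) * (q[2] - o[2]) - (p[2] - o[2]) * (q[1] - o[1])
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the closing edge
      d1 <- cross(a1[i, ], a2[i, ], a1[j, ])
      d2 <- cross(a1[i, ], a2[i, ], a2[j, ])
      d3 <- cross(a1[j, ], a2[j, ], a1[i, ])
      d4 <- cross(a1[j, ], a2[j, ], a2[i, ])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Quantify an en-face angiogram
#'
#' Runs the full pipeline — three-way binarization, skeletonization, and
#' per-region VAD/VSD/VDI — and returns one tidy row per region of interest,
#' with the parameter hash recorded for provenance. The FAZ area is computed
#' from an optionally supplied traced contour.
#'
#' @param image An [enface_image()].
#' @param vparams,tparams,rule Passed to [binarize_enface()].
#' @param regions Character vector among `"foveal"`, `"parafoveal"`,
#'   `"whole"`.
#' @param faz_contour Optional n x 2 vertex matrix of the traced FAZ contour.
#' @param faz_units `"mm"` (default) or `"px"`; pixel vertices are given as
#'   (row, col) and converted to mm via the per-axis pitch.
#' @param center_px Optional 0-based fovea center override for decentered
#'   scans.
#' @return `data.frame` with columns `eye_id, visit, plexus, region, vad,
#'   vsd, vdi_px, vdi_um, vdi_defined, faz_mm2, params_hash`. Regions where
#'   the skeleton is empty get `vdi_defined = FALSE` and `NA` VDI.
#' @export
quantify <- function(image, vparams = vesselness_params(),
                     tparams = threshold_params(), rule = "vesselness_and_any",
                     regions = c("foveal", "parafoveal", "whole"),
                     faz_contour = NULL, faz_units = c("mm", "px"),
                     center_px = NULL) {
  stopifnot(inherits(image, "enface_image"))
  regions <- match.arg(regions, several.ok = TRUE)
  faz_units <- match.arg(faz_units)
  bvm <- binarize_enface(image, vparams, tparams, rule)
  skel <- skeletonize(bvm)
  pitch <- pixel_scale_um(image$extent_mm, dim(image$pixels))
  pixel_um <- mean(pitch)   # per-axis pitches differ in the 3rd decimal
  faz_mm2 <- NA_real_
  if (!is.null(faz_contour)) {
    cont <- as.matrix(faz_contour)
    if (faz_units == "px") {
      cont <- cbind(cont[, 1] * pitch[1] / 1000, cont[, 2] * pitch[2] / 1000)
    }
    faz_mm2 <- faz_area(cont)
  }
  rows <- lapply(regions, function(reg) {
    roi <- make_region_mask(image, region_spec(reg, center_px = center_px))
    vad <- compute_vad(bvm, roi)
    vsd <- compute_vsd(skel, roi)
    vdi <- tryCatch(compute_vdi(bvm, skel, roi, pixel_um),
                    error = function(e) NULL)
    data.frame(
      eye_id = image$eye_id, visit = image$visit, plexus = image$plexus,
      region = reg, vad = vad, vsd = vsd,
      vdi_px = if (is.null(vdi)) NA_real_ else vdi$vdi_px,
      vdi_um = if (is.null(vdi)) NA_real_ else vdi$vdi_um,
      vdi_defined = !is.null(vdi),
      faz_mm2 = faz_mm2,
      params_hash = bvm$provenance$params_hash,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask Logical matrix, or a `binary_vessel_map`/`skeleton_map`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- .as_mask(mask)
  png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  invisible(path)
}
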