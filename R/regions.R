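#' Region-of-interest specification (ETDRS-style)
#'
#' The study separates each angiogram into foveal, parafoveal and whole
#' areas. Diameters follow the ETDRS convention: foveal = central disc of
#' 1 mm diameter, parafoveal = annulus between 1 mm and 3 mm diameters,
#' whole = the full scan.
#'
#' @param region `"foveal"`, `"parafoveal"` or `"whole"`.
#' @param center_px Fovea center as 0-based `(row, col)` pixel coordinates,
#'   or `NULL` for the image center (scans are fovea-centered).
#' @param inner_diameter_mm,outer_diameter_mm Disc/annulus diameters in mm.
#' @return A list of class `region_spec`.
#' @export
region_spec <- function(region = c("foveal", "parafoveal", "whole"),
                        center_px = NULL,
                        inner_diameter_mm = 1.0, outer_diameter_mm = 3.0) {
  region <- match.arg(region)
  if (inner_diameter_mm >= outer_diameter_mm) {
    stop("inner diameter must be smaller than outer diameter")
  }
  structure(list(region = region, center_px = center_px,
                 inner_diameter_mm = inner_diameter_mm,
                 outer_diameter_mm = outer_diameter_mm),
            class = "region_spec")
}

#' Build a boolean region mask in physical coordinates
#'
#' Converts the mm-diameter region definition into a pixel mask congruent
#' with the image, using the per-axis pixel pitch (the nominal 586 x 585 px
#' / 3 x 3 mm geometry is slightly anisotropic). Distances are measured
#' between pixel centers. Foveal and parafoveal masks are disjoint by
#' construction: foveal is `r <= inner radius`, parafoveal is
#' `inner < r <= outer`.
#'
#' @param image An [enface_image()].
#' @param spec A [region_spec()], or a region name passed to `region_spec()`.
#' @return A list of class `roi_mask` with elements `mask` (logical matrix)
#'   and `region`.
#' @export
make_region_mask <- function(image, spec) {
  stopifnot(inherits(image, "enface_image"))
  if (is.character(spec)) spec <- region_spec(spec)
  stopifnot(inherits(spec, "region_spec"))
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  if (spec$region == "whole") {
    return(structure(list(mask = matrix(TRUE, h, w), region = "whole"),
                     class = "roi_mask"))
  }
  ctr <- spec$center_px
  if (is.null(ctr)) ctr <- c((h - 1) / 2, (w - 1) / 2)
  if (ctr[1] < 0 || ctr[1] > h - 1 || ctr[2] < 0 || ctr[2] > w - 1) {
    stop("`center_px` lies outside the image")
  }
  pitch_mm <- image$extent_mm / c(h, w)             # mm per pixel, per axis
  dr <- (seq_len(h) - 1 - ctr[1]) * pitch_mm[1]
  dc <- (seq_len(w) - 1 - ctr[2]) * pitch_mm[2]
  r_mm <- sqrt(outer(dr^2, dc^2, `+`))
  r_in <- spec$inner_diameter_mm / 2
  r_out <- spec$outer_diameter_mm / 2
  lim <- if (spec$region == "foveal") r_in else r_out
  edge_mm <- min(ctr[1], h - 1 - ctr[1]) * pitch_mm[1]
  edge_mm <- min(edge_mm, min(ctr[2], w - 1 - ctr[2]) * pitch_mm[2])
  if (lim > edge_mm + max(pitch_mm)) {  # one-pixel tolerance: pixel centers
                                        # stop half a pitch short of the edge
    warning("region circle (radius ", lim, " mm) exceeds the image bounds; ",
            "mask clipped to the image")
  }
  mask <- if (spec$region == "foveal") {
    r_mm <= r_in
  } else {
    r_mm > r_in & r_mm <= r_out
  }
  structure(list(mask = mask, region = spec$region), class = "roi_mask")
}
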