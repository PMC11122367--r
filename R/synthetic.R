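#' Parameters of the synthetic angiogram generator
#'
#' Defaults emulate a superficial-plexus 3 x 3 mm en-face scan at the study
#' geometry: 586 x 585 px, a vessel area fraction around 0.43, capillary
#' calibers of 2-5 px (about 10-26 um at 5.13 um/px) and a vessel-free
#' central disc whose radius (0.276 mm) corresponds to the cohort-typical
#' FAZ area of 0.24 mm^2.
#'
#' @param height_px,width_px Image size in pixels.
#' @param extent_mm Physical extent `c(height_mm, width_mm)`.
#' @param target_vad Vessel area fraction at which tree growth stops
#'   (0 = empty scene). Each tree adds a small increment, so the realized
#'   fraction lands just above the target.
#' @param caliber_range_px Range the root caliber of each tree is drawn
#'   from, in pixels (>= 1).
#' @param caliber_decay Multiplicative caliber reduction at each branching
#'   (clamped at 1 px and at the range minimum).
#' @param faz_radius_mm Radius of the central avascular disc (0 = none).
#' @param noise `"none"`, `"gaussian"` (additive, `noise_sigma` in 8-bit
#'   counts) or `"speckle"` (multiplicative, `noise_sigma` relative).
#' @param noise_sigma Noise scale; see `noise`.
#' @param vessel_intensity,background Rendered 8-bit levels.
#' @param background_ramp Additive linear illumination gradient across the
#'   width, in 8-bit counts (left edge `background`, right edge
#'   `background + background_ramp`). Emulates the slow decorrelation/
#'   illumination drift that defeats a single global threshold; 0 = flat.
#' @param blur_sigma Gaussian blur (px) applied after rendering, giving
#'   vessels a smooth profile.
#' @param branch_prob Per-step (per px) probability that a branch forks off.
#' @param curvature_sd SD of the per-step heading jitter (radians); the walk
#'   keeps momentum between steps.
#' @param max_trees,max_steps Growth caps.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(height_px = 586L, width_px = 585L, extent_mm = c(3, 3),
                         target_vad = 0.43, caliber_range_px = c(2, 5),
                         caliber_decay = 0.9, faz_radius_mm = 0.276,
                         noise = c("none", "gaussian", "speckle"),
                         noise_sigma = 10, vessel_intensity = 200,
                         background = 20, background_ramp = 0,
                         blur_sigma = 0.6,
                         branch_prob = 0.02, curvature_sd = 0.15,
                         max_trees = 4000L, max_steps = 500L) {
  noise <- match.arg(noise)
  extent_mm <- as.numeric(extent_mm)
  if (length(extent_mm) == 1L) extent_mm <- rep(extent_mm, 2L)
  if (any(caliber_range_px < 1)) stop("calibers must be >= 1 px")
  if (max(caliber_range_px) >= min(height_px, width_px)) {
    stop("caliber exceeds the image: infeasible scene")
  }
  if (target_vad < 0 || target_vad > 0.7) stop("`target_vad` must be in [0, 0.7]")
  structure(
    list(height_px = as.integer(height_px), width_px = as.integer(width_px),
         extent_mm = extent_mm, target_vad = target_vad,
         caliber_range_px = sort(as.numeric(caliber_range_px)),
         caliber_decay = caliber_decay, faz_radius_mm = faz_radius_mm,
         noise = noise, noise_sigma = noise_sigma,
         vessel_intensity = vessel_intensity, background = background,
         background_ramp = background_ramp,
         blur_sigma = blur_sigma, branch_prob = branch_prob,
         curvature_sd = curvature_sd, max_trees = as.integer(max_trees),
         max_steps = as.integer(max_steps)),
    class = "scene_params"
  )
}

# Random walk with momentum: unit steps, heading jitter curvature_sd.
# Returns float (row, col) positions including the start, plus headings.
.walk_path <- function(pt, theta0, n_steps, curvature_sd) {
  theta <- theta0 + cumsum(rnorm(n_steps, 0, curvature_sd))
  r <- pt[1] + cumsum(cos(theta))
  c <- pt[2] + cumsum(sin(theta))
  list(path = cbind(c(pt[1], r), c(pt[2], c)), theta = theta)
}

# Pixels covered by a tube of width `caliber` around a float polyline,
# sampled every 0.5 px. Pixel centers at integer coordinates; a pixel is set
# when its center lies within caliber/2 of a sample point. Returns linear
# indices of tube and centerline pixels. The centerline is digitized at 1 px
# spacing so successive pixels are 8-adjacent and the chain is minimal —
# the same length convention a thinned skeleton produces.
.segment_pixels <- function(polyline, caliber, h, w) {
  pts <- .densify(polyline, 0.5)
  cpts <- .densify(polyline, 1.0)
  rad <- caliber / 2
  reach <- ceiling(rad) + 1L
  off <- expand.grid(dr = -reach:reach, dc = -reach:reach)
  ri <- round(pts[, 1]); ci <- round(pts[, 2])
  fr <- pts[, 1] - ri;   fc <- pts[, 2] - ci
  keep_any <- sqrt(off$dr^2 + off$dc^2) <= rad + 0.8  # coarse prefilter
  off <- off[keep_any, , drop = FALSE]
  # distance from each candidate pixel center to its sample point
  dr <- outer(-fr, off$dr, `+`)
  dc <- outer(-fc, off$dc, `+`)
  hit <- dr * dr + dc * dc <= rad * rad
  rr <- outer(ri, off$dr, `+`)[hit]
  cc <- outer(ci, off$dc, `+`)[hit]
  ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
  idx <- unique((cc[ok] - 1) * h + rr[ok])
  cri <- round(cpts[, 1]); cci <- round(cpts[, 2])
  okc <- cri >= 1 & cri <= h & cci >= 1 & cci <= w
  center_idx <- unique((cci[okc] - 1) * h + cri[okc])
  list(idx = as.integer(idx), center_idx = as.integer(center_idx))
}

.densify <- function(polyline, spacing) {
  if (nrow(polyline) == 1L) return(polyline)
  out <- vector("list", nrow(polyline) - 1L)
  for (i in seq_len(nrow(polyline) - 1L)) {
    a <- polyline[i, ]; b <- polyline[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(1L, ceiling(len / spacing))
    t <- seq(0, 1, length.out = n + 1L)
    seg <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    out[[i]] <- if (i < nrow(polyline) - 1L) seg[-nrow(seg), , drop = FALSE] else seg
  }
  do.call(rbind, out)
}

#' Rasterize one vessel segment
#'
#' Sets all pixels whose centers lie within `caliber_px / 2` of the
#' (sub-pixel) polyline. A degenerate polyline of two equal points yields a
#' disc of diameter `caliber_px`.
#'
#' @param segment List with `polyline` (n x 2 float (row, col) matrix,
#'   n >= 2) and `caliber_px` (>= 1).
#' @param dim Target grid size `c(height, width)`.
#' @return Logical matrix; the number of centerline pixels is attached as
#'   attribute `"centerline_px"`.
#' @export
rasterize_segment <- function(segment, dim) {
  stopifnot(is.list(segment), !is.null(segment$polyline),
            nrow(segment$polyline) >= 2L, segment$caliber_px >= 1)
  h <- dim[1]; w <- dim[2]
  px <- .segment_pixels(segment$polyline, segment$caliber_px, h, w)
  m <- matrix(FALSE, h, w)
  m[px$idx] <- TRUE
  attr(m, "centerline_px") <- length(px$center_idx)
  m
}

#' Generate a synthetic en-face angiogram with exact ground truth
#'
#' Grows random branching vessel trees from the image border toward the
#' center — random walks with momentum, per-step branching, calibers drawn
#' from `caliber_range_px` — while avoiding a central avascular disc. The
#' trees are rasterized into a ground-truth vessel mask and centerline map,
#' then rendered on a dark background with a smooth profile and optional
#' noise. Fully deterministic per seed (one RNG stream; the caller's RNG
#' state is restored on exit).
#'
#' @param params A [scene_params()].
#' @param seed Integer seed determining the whole scene.
#' @param plexus Label stored in the image metadata.
#' @return List with `image` (an [enface_image()]), `truth` (class
#'   `synthetic_ground_truth`: `truth_mask`, `centerline_mask`,
#'   `truth_skeleton_px`, `truth_vad`, `truth_vsd`, `truth_mean_caliber_px`
#'   — total vessel area over total centerline length, the construction VDI
#'   estimates — and `truth_mean_caliber_area_weighted_px`), and `segments`
#'   (polylines with calibers).
#' @export
generate_scene <- function(params = scene_params(), seed = 1L, plexus = "SCP") {
  stopifnot(inherits(params, "scene_params"))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  h <- params$height_px; w <- params$width_px
  n_px <- h * w
  truth <- logical(n_px)
  center <- logical(n_px)
  n_truth <- 0L
  pitch_mm <- params$extent_mm / c(h, w)
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  segments <- list()
  seg_len <- numeric(0); seg_cal <- numeric(0)
  min_cal <- params$caliber_range_px[1]

  tree <- 0L
  while (tree < params$max_trees && n_truth / n_px < params$target_vad) {
    tree <- tree + 1L
    # uniform seeding keeps the mesh density roughly homogeneous
    start <- c(runif(1, 1, h), runif(1, 1, w))
    # heading convention matches .walk_path: row step = cos, col step = sin
    theta <- runif(1, 0, 2 * pi)
    start_idx <- (round(start[2]) - 1L) * h + round(start[1])
    if (truth[start_idx]) next              # don't seed inside a vessel
    cal <- runif(1, params$caliber_range_px[1], params$caliber_range_px[2])
    stack <- list(list(pt = start, theta = theta, cal = cal))
    n_branches <- 0L
    while (length(stack) > 0L && n_branches < 64L &&
           n_truth / n_px < params$target_vad) {
      n_branches <- n_branches + 1L
      br <- stack[[1L]]; stack <- stack[-1L]
      wp <- .walk_path(br$pt, br$theta, params$max_steps, params$curvature_sd)
      path <- wp$path
      din <- sqrt(((path[, 1] - ctr[1]) * pitch_mm[1])^2 +
                  ((path[, 2] - ctr[2]) * pitch_mm[2])^2)
      bad <- path[, 1] < 1 | path[, 1] > h | path[, 2] < 1 | path[, 2] > w |
             din <= params$faz_radius_mm
      cut <- which(bad)[1L]
      if (!is.na(cut)) path <- path[seq_len(cut - 1L), , drop = FALSE]
      if (nrow(path) < 2L) next
      # anastomose: stop shortly after meeting an existing vessel, so
      # branches join the mesh instead of running through it
      ri <- pmin(h, pmax(1L, round(path[, 1])))
      ci <- pmin(w, pmax(1L, round(path[, 2])))
      hit <- truth[(ci - 1L) * h + ri]
      grace <- ceiling(br$cal) + 2L         # ignore the exit from the parent
      hit[seq_len(min(grace, length(hit)))] <- FALSE
      first_hit <- which(hit)[1L]
      if (!is.na(first_hit)) {
        keep <- min(nrow(path), first_hit + ceiling(br$cal / 2) + 1L)
        path <- path[seq_len(keep), , drop = FALSE]
      }
      if (nrow(path) < 2L) next
      seg <- list(polyline = path, caliber_px = br$cal,
                  intensity = params$vessel_intensity)
      segments[[length(segments) + 1L]] <- seg
      seg_len <- c(seg_len, nrow(path) - 1)
      seg_cal <- c(seg_cal, br$cal)
      px <- .segment_pixels(path, br$cal, h, w)
      # centerline pixels buried inside pre-existing vessels (fork exits,
      # anastomosis joins) merge into the mesh and are not counted twice
      center[px$center_idx[!truth[px$center_idx]]] <- TRUE
      new <- px$idx[!truth[px$idx]]
      truth[new] <- TRUE
      n_truth <- n_truth + length(new)
      # fork children off the surviving part of this branch
      child_cal <- max(1, min_cal, br$cal * params$caliber_decay)
      forks <- which(runif(nrow(path) - 1L) < params$branch_prob)
      for (f in forks) {
        if (length(stack) >= 32L) break
        stack[[length(stack) + 1L]] <- list(
          pt = path[f + 1L, ],
          theta = wp$theta[f] + sample(c(-1, 1), 1L) * runif(1, 0.4, 1.1),
          cal = child_cal)
      }
    }
  }

  truth_mask <- matrix(truth, h, w)
  centerline_mask <- matrix(center, h, w)
  bg <- params$background +
    params$background_ramp * (col(matrix(0, h, w)) - 1) / max(1, w - 1)
  img <- bg
  # vessels keep constant contrast above the (possibly ramped) background
  img[truth_mask] <- bg[truth_mask] +
    (params$vessel_intensity - params$background)
  if (params$blur_sigma > 0) {
    k <- .gauss_kernel(params$blur_sigma, 0L)
    img <- .conv_sep(img, k, k)
  }
  if (params$noise == "gaussian") {
    img <- img + rnorm(n_px, 0, params$noise_sigma)
  } else if (params$noise == "speckle") {
    img <- img * (1 + rnorm(n_px, 0, params$noise_sigma))
  }
  img <- matrix(pmin(255, pmax(0, round(img))), h, w)

  n_center <- sum(center)
  area <- seg_len * seg_cal
  truth <- structure(
    list(
      truth_mask = truth_mask,
      centerline_mask = centerline_mask,
      truth_skeleton_px = n_center,
      truth_vad = n_truth / n_px,
      truth_vsd = n_center / n_px,
      truth_mean_caliber_px = if (n_center > 0) n_truth / n_center else NA_real_,
      truth_mean_caliber_area_weighted_px =
        if (length(area)) sum(area * seg_cal) / sum(area) else NA_real_,
      faz_radius_mm = params$faz_radius_mm,
      seed = seed
    ),
    class = "synthetic_ground_truth"
  )
  list(
    image = enface_image(img, extent_mm = params$extent_mm, plexus = plexus,
                         quality_score = 90,
                         eye_id = sprintf("synthetic-seed%d", seed),
                         visit = "synthetic"),
    truth = truth,
    segments = segments
  )
}

#' Ground-truth perfusion metrics of a synthetic scene
#'
#' Computes VAD/VSD/VDI directly from the ground-truth vessel mask and
#' centerline map (no image processing), for comparison against the
#' measurement pipeline.
#'
#' @param ground_truth A `synthetic_ground_truth` from [generate_scene()].
#' @param roi ROI mask congruent with the scene ([make_region_mask()] result
#'   or logical matrix).
#' @param pixel_um Pixel pitch for the um-scaled VDI (default 1).
#' @return List `vad`, `vsd`, `vdi_px`, `vdi_um` (VDI is `NA` when the ROI
#'   holds no centerline pixels).
#' @export
truth_metrics <- function(ground_truth, roi, pixel_um = 1) {
  stopifnot(inherits(ground_truth, "synthetic_ground_truth"))
  roi <- .as_mask(roi)
  .check_roi(ground_truth$truth_mask, roi)
  n_roi <- sum(roi)
  n_v <- sum(ground_truth$truth_mask & roi)
  n_s <- sum(ground_truth$centerline_mask & roi)
  list(vad = n_v / n_roi, vsd = n_s / n_roi,
       vdi_px = if (n_s > 0) n_v / n_s else NA_real_,
       vdi_um = if (n_s > 0) n_v / n_s * pixel_um else NA_real_)
}
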