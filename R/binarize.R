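#' Otsu threshold of an 8-bit intensity grid
#'
#' Exhaustively maximizes the between-class variance over the 255 possible
#' cut points of the 8-bit histogram. Pixels strictly above the returned
#' threshold are foreground. Ties are broken toward the lowest threshold.
#'
#' @param pixels Integer matrix/vector with values in \[0, 255\].
#' @return The threshold (integer in \[0, 254\]), or `NA` for a constant
#'   input, where no foreground is separable.
#' @export
otsu_threshold <- function(pixels) {
  v <- as.integer(pixels)
  if (anyNA(v) || any(v < 0L) || any(v > 255L)) {
    stop("`pixels` must be 8-bit integers in [0, 255]")
  }
  if (min(v) == max(v)) return(NA_integer_)
  p <- tabulate(v + 1L, 256L) / length(v)
  omega <- cumsum(p)                      # P(class 0) for threshold t = 0..255
  mu <- cumsum(p * (0:255))
  mu_total <- mu[256L]
  o <- omega[1:255]
  m <- mu[1:255]
  sigma_b <- (mu_total * o - m)^2 / (o * (1 - o))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  which.max(sigma_b) - 1L
}

#' Global threshold mask
#'
#' First leg of the three-way binarization: one intensity cut for the whole
#' image. Default method is Otsu; `mean_offset` thresholds at the global
#' mean plus `offset`.
#'
#' @param image An [enface_image()] or an 8-bit integer matrix.
#' @param method `"otsu"` or `"mean_offset"`.
#' @param offset Offset added to the global mean for `method = "mean_offset"`.
#' @return Logical matrix; `TRUE` where intensity exceeds the threshold. The
#'   threshold used is attached as attribute `"threshold"`. A constant image
#'   has no separable foreground: the mask is empty and a warning is raised.
#' @export
global_mask <- function(image, method = c("otsu", "mean_offset"), offset = 0) {
  px <- if (inherits(image, "enface_image")) image$pixels else image
  method <- match.arg(method)
  if (min(px) == max(px)) {
    warning("constant image: no foreground separable, returning an empty mask")
    return(structure(array(FALSE, dim(px)), threshold = NA_real_))
  }
  thr <- switch(method,
    otsu = otsu_threshold(px),
    mean_offset = mean(px) + offset
  )
  structure(px > thr, threshold = as.numeric(thr))
}

#' Parameters of the multiscale Hessian vesselness filter
#'
#' Defaults target capillary calibers of roughly 5-40 um at the study's
#' 5.13 um/px pitch: Gaussian scales 1-4 px (the tube response peaks near
#' sigma = caliber/2, so 40 um vessels need sigma around 4), blob-suppression
#' `beta` 0.5, structureness constant `c` set automatically per scale to
#' half the maximum Hessian norm.
#'
#' @param scales_px Gaussian scales sigma, in pixels (all > 0).
#' @param beta Blob-suppression constant (> 0).
#' @param c Structureness constant, or `"auto"`.
#' @param bright_on_dark `TRUE` for bright vessels on a dark background
#'   (en-face OCTA); the eigenvalue sign test is flipped when `FALSE`.
#' @return A list of class `vesselness_params`.
#' @export
vesselness_params <- function(scales_px = c(1, 1.5, 2, 2.5, 3, 4), beta = 0.5,
                              c = "auto", bright_on_dark = TRUE) {
  if (length(scales_px) == 0L || any(scales_px <= 0)) {
    stop("`scales_px` must be a non-empty vector of positive scales")
  }
  if (beta <= 0) stop("`beta` must be > 0")
  if (!identical(c, "auto") && (!is.numeric(c) || c <= 0)) {
    stop("`c` must be a positive number or \"auto\"")
  }
  structure(list(scales_px = sort(scales_px), beta = beta, c = c,
                 bright_on_dark = isTRUE(bright_on_dark)),
            class = "vesselness_params")
}

#' Multiscale Hessian (Frangi) vesselness response
#'
#' Second leg of the three-way binarization. At each scale sigma the image is
#' convolved with scale-normalized (sigma^2) Gaussian second derivatives; the
#' Hessian eigenvalues `lambda1, lambda2` (`|lambda1| <= |lambda2|`) give the
#' tubularity response
#' `exp(-R_B^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))`
#' with `R_B = lambda1/lambda2` (blobness) and `S = sqrt(lambda1^2 +
#' lambda2^2)` (structureness). Pixels failing the bright-on-dark sign test
#' (`lambda2 >= 0`) respond zero. The per-pixel maximum over scales is
#' rescaled to \[0, 1\].
#'
#' @param image An [enface_image()] or numeric matrix.
#' @param params A [vesselness_params()].
#' @return Numeric matrix in \[0, 1\], congruent with the image, with
#'   attribute `"best_scale"`: the scale (px) at which each pixel attained
#'   its maximal response (`NA` where the response is zero).
#' @export
vesselness <- function(image, params = vesselness_params()) {
  px <- if (inherits(image, "enface_image")) image$pixels else image
  stopifnot(inherits(params, "vesselness_params"))
  px <- matrix(as.numeric(px), nrow(px), ncol(px))
  if (max(params$scales_px) > min(dim(px)) / 4) {
    stop("largest scale exceeds min(image dims)/4")
  }
  beta2 <- 2 * params$beta^2
  out <- array(0, dim(px))
  best <- array(NA_real_, dim(px))
  for (sigma in params$scales_px) {
    k0 <- .gauss_kernel(sigma, 0L)
    k1 <- .gauss_kernel(sigma, 1L)
    k2 <- .gauss_kernel(sigma, 2L)
    s2 <- sigma^2
    drr <- s2 * .conv_sep(px, k2, k0)
    dcc <- s2 * .conv_sep(px, k0, k2)
    drc <- s2 * .conv_sep(px, k1, k1)
    disc <- sqrt(((drr - dcc) / 2)^2 + drc^2)
    mid <- (drr + dcc) / 2
    e_a <- mid + disc
    e_b <- mid - disc
    swap <- abs(e_a) > abs(e_b)               # lambda2 carries the larger |.|
    lam2 <- ifelse(swap, e_a, e_b)
    lam1 <- ifelse(swap, e_b, e_a)
    s_sq <- lam1^2 + lam2^2
    if (max(s_sq) < 1e-10) next   # flat image: numerical residue only
    rb_sq <- ifelse(lam2 != 0, (lam1 / lam2)^2, 0)
    c_val <- if (identical(params$c, "auto")) sqrt(max(s_sq)) / 2 else params$c
    v <- if (c_val > 0) {
      exp(-rb_sq / beta2) * (1 - exp(-s_sq / (2 * c_val^2)))
    } else {
      array(0, dim(px))
    }
    fails_sign <- if (params$bright_on_dark) lam2 >= 0 else lam2 <= 0
    v[fails_sign] <- 0
    improved <- v > out
    best[improved] <- sigma
    out <- pmax(out, v)
  }
  top <- max(out)
  if (top > 0) out <- out / top
  attr(out, "best_scale") <- best
  out
}

#' Adaptive local-mean threshold mask
#'
#' Third leg of the three-way binarization: a pixel is vessel if its
#' intensity exceeds the mean over a square window centered on it, plus an
#' offset. Borders are handled by reflective padding. The adaptive leg keeps
#' vessels visible through the slow illumination/decorrelation gradients
#' that defeat a single global cut.
#'
#' @param image An [enface_image()] or numeric matrix.
#' @param window_px Odd window side length in pixels (>= 3); the default
#'   51 px spans about 261 um at the study pitch.
#' @param offset Value added to the local mean before comparison.
#' @return Logical matrix congruent with the image.
#' @export
adaptive_mask <- function(image, window_px = 51L, offset = 0) {
  px <- if (inherits(image, "enface_image")) image$pixels else image
  if (window_px < 3L || window_px %% 2L == 0L) {
    stop("`window_px` must be an odd integer >= 3")
  }
  px <- matrix(as.numeric(px), nrow(px), ncol(px))
  local_mean <- .box_mean(px, window_px)
  px > local_mean + offset
}

#' Fuse the three component masks into a binary vessel map
#'
#' Default rule `"vesselness_and_any"`: a pixel is vessel iff it passes the
#' vesselness mask AND (global OR adaptive) — the Hessian filter gates shape,
#' the thresholds gate intensity. Alternatives: `"majority"` (2 of 3),
#' `"intersection"`, `"union"`. Every rule yields a subset of the union of
#' the components; the rule id and components are recorded in the result.
#'
#' @param global_m,vessel_m,adaptive_m Congruent logical matrices
#'   (`vessel_m` is the vesselness response already thresholded).
#' @param rule Fusion rule id.
#' @return A list of class `binary_vessel_map`: `mask` plus `provenance`
#'   (component masks and rule id).
#' @export
fuse_masks <- function(global_m, vessel_m, adaptive_m,
                       rule = c("vesselness_and_any", "majority",
                                "intersection", "union")) {
  rule <- match.arg(rule)
  if (!identical(dim(global_m), dim(vessel_m)) ||
      !identical(dim(global_m), dim(adaptive_m))) {
    stop("component masks differ in shape")
  }
  mask <- switch(rule,
    vesselness_and_any = vessel_m & (global_m | adaptive_m),
    majority = (global_m + vessel_m + adaptive_m) >= 2,
    intersection = global_m & vessel_m & adaptive_m,
    union = global_m | vessel_m | adaptive_m
  )
  structure(
    list(mask = mask,
         provenance = list(global = global_m, vesselness = vessel_m,
                           adaptive = adaptive_m, rule = rule)),
    class = "binary_vessel_map"
  )
}

#' Threshold parameters of the three-way binarization
#'
#' @param global_method `"otsu"` (default) or `"mean_offset"`.
#' @param adaptive_window_px Odd window (default 51 px).
#' @param adaptive_offset Offset added to the local mean (default 0).
#' @param vesselness_threshold Cut on the \[0, 1\] vesselness response: a
#'   number in (0, 1), or `"otsu_nonzero"` for an Otsu cut on the
#'   8-bit-quantized nonzero response histogram. The default 0.05 is
#'   deliberately permissive: the vesselness mask acts as a shape gate in
#'   the fusion rule and must cover whole vessel bodies (the Frangi response
#'   falls off at junctions and tube cores), while the intensity thresholds
#'   do the foreground/background separation. An Otsu cut on the response
#'   lands mid-vessel and erodes the map, so it is offered only as an
#'   alternative.
#' @return A list of class `threshold_params`.
#' @export
threshold_params <- function(global_method = "otsu", adaptive_window_px = 51L,
                             adaptive_offset = 0,
                             vesselness_threshold = 0.05) {
  if (!identical(vesselness_threshold, "otsu_nonzero") &&
      (!is.numeric(vesselness_threshold) || vesselness_threshold <= 0 ||
       vesselness_threshold >= 1)) {
    stop("`vesselness_threshold` must be in (0, 1) or \"otsu_nonzero\"")
  }
  structure(list(global_method = global_method,
                 adaptive_window_px = as.integer(adaptive_window_px),
                 adaptive_offset = adaptive_offset,
                 vesselness_threshold = vesselness_threshold),
            class = "threshold_params")
}

#' Three-way binarization of an en-face angiogram
#'
#' End-to-end segmentation of the vessel network: global threshold,
#' multiscale Hessian vesselness and adaptive local threshold, fused by
#' [fuse_masks()]. Deterministic for fixed inputs and parameters.
#'
#' @param image An [enface_image()].
#' @param vparams A [vesselness_params()].
#' @param tparams A [threshold_params()].
#' @param rule Fusion rule passed to [fuse_masks()].
#' @return A `binary_vessel_map` whose provenance also records the
#'   parameters and their hash.
#' @export
binarize_enface <- function(image, vparams = vesselness_params(),
                            tparams = threshold_params(),
                            rule = "vesselness_and_any") {
  stopifnot(inherits(image, "enface_image"))
  stopifnot(inherits(tparams, "threshold_params"))
  g <- suppressWarnings(
    global_mask(image, method = tparams$global_method)
  )
  resp <- vesselness(image, vparams)
  vth <- tparams$vesselness_threshold
  if (identical(vth, "otsu_nonzero")) {
    q <- round(resp * 255)
    nz <- q[q > 0]
    vmask <- if (length(nz) == 0L || min(nz) == max(nz)) {
      resp > 0   # degenerate: single-valued response, keep anything nonzero
    } else {
      q > otsu_threshold(nz)
    }
  } else {
    vmask <- resp > vth
  }
  a <- adaptive_mask(image, tparams$adaptive_window_px, tparams$adaptive_offset)
  out <- fuse_masks(g, vmask, a, rule = rule)
  out$provenance$vparams <- vparams
  out$provenance$tparams <- tparams
  out$provenance$params_hash <- .params_hash(list(vparams, tparams, rule))
  out
}

# Deterministic short hash of a parameter list (for provenance columns).
.params_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
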