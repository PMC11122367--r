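# Independent oracles and scene builders shared across tests.

# Exhaustive Otsu: maximize between-class variance over all 255 cut points
# by explicitly splitting the sample (no cumulative-sum shortcuts).
brute_force_otsu <- function(values) {
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 0:254) {
    lo <- values[values <= t]
    hi <- values[values > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(values)
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# 8-connected component count via igraph (independent of the package's
# thinning code).
count_components <- function(m) {
  idx <- which(m)
  if (length(idx) == 0L) return(0L)
  h <- nrow(m); w <- ncol(m)
  ri <- ((idx - 1L) %% h) + 1L
  ci <- ((idx - 1L) %/% h) + 1L
  edges <- NULL
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nr <- ri + d[1]; nc <- ci + d[2]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nb <- match((nc[ok] - 1L) * h + nr[ok], idx)
    src <- which(ok)[!is.na(nb)]
    nb <- nb[!is.na(nb)]
    if (length(nb)) edges <- rbind(edges, cbind(src, nb))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$no
}

# Any fully-set 2x2 block?
has_2x2_block <- function(m) {
  any(m[-nrow(m), -ncol(m)] & m[-1, -ncol(m)] & m[-nrow(m), -1] & m[-1, -1])
}

# 8-connected binary dilation by one pixel.
dilate8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1), 2:(w + 1)] <- m
  out <- matrix(FALSE, h, w)
  for (dr in 0:2) for (dc in 0:2) {
    out <- out | p[(1 + dr):(h + dr), (1 + dc):(w + dc)]
  }
  out
}

# Brute-force polygon area: count unit-spaced sample points inside the
# polygon (even-odd ray casting), scaled by the sampling cell area.
pixel_polygon_area <- function(contour, step = 0.005) {
  xr <- range(contour[, 1]); yr <- range(contour[, 2])
  xs <- seq(xr[1] - step, xr[2] + step, by = step)
  ys <- seq(yr[1] - step, yr[2] + step, by = step)
  pts_x <- rep(xs, times = length(ys))
  pts_y <- rep(ys, each = length(xs))
  n <- nrow(contour)
  inside <- rep(FALSE, length(pts_x))
  j <- n
  for (i in seq_len(n)) {
    xi <- contour[i, 1]; yi <- contour[i, 2]
    xj <- contour[j, 1]; yj <- contour[j, 2]
    crosses <- ((yi > pts_y) != (yj > pts_y)) &
      (pts_x < (xj - xi) * (pts_y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  sum(inside) * step^2
}

# Random convex polygon: convex hull of random points in a disc.
random_convex_polygon <- function(n = 12, radius = 0.4) {
  th <- runif(n, 0, 2 * pi)
  r <- radius * sqrt(runif(n, 0.4, 1))
  pts <- cbind(r * cos(th), r * sin(th))
  hull <- chull(pts)
  pts[hull, , drop = FALSE]
}

# Bright ridge of given width/angle on a dark background (binary levels).
render_line_image <- function(angle_deg, size = 101, width = 3,
                              bg = 20, fg = 200) {
  ctr <- (size + 1) / 2
  th <- angle_deg * pi / 180
  rr <- row(matrix(0, size, size)) - ctr
  cc <- col(matrix(0, size, size)) - ctr
  perp <- abs(cos(th) * rr - sin(th) * cc)
  along <- abs(sin(th) * rr + cos(th) * cc)
  m <- matrix(bg, size, size)
  m[perp <= width / 2] <- fg
  structure(m, perp = perp, along = along)
}

# Small noise-free synthetic scene for pipeline tests.
small_scene <- function(seed, size = 192, vad = 0.3, calibers = c(3, 6),
                        noise = "none", ...) {
  generate_scene(
    scene_params(height_px = size, width_px = size, extent_mm = c(1, 1),
                 target_vad = vad, caliber_range_px = calibers,
                 faz_radius_mm = 0.1, noise = noise, ...),
    seed = seed
  )
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
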