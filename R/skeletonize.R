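#' Skeletonize a binary vessel map
#'
#' Iteratively removes pixels from the outer perimeter of the vessel area
#' map until only one pixel remains in the width direction, preserving the
#' 8-connectivity of every vessel component (Zhang-Suen parallel thinning,
#' followed by a deterministic removal of residual 2 x 2 staircase pixels
#' using a simple-point test). The result is the centerline map from which
#' vessel skeleton density and the vessel diameter index are computed.
#'
#' @param vessel_map A `binary_vessel_map` (from [binarize_enface()]) or a
#'   logical matrix.
#' @return A list of class `skeleton_map` with element `mask`, a logical
#'   matrix congruent with the input and a subset of it.
#' @export
skeletonize <- function(vessel_map) {
  m <- if (inherits(vessel_map, "binary_vessel_map")) vessel_map$mask else vessel_map
  if (!is.matrix(m)) stop("`vessel_map` must be a matrix or binary_vessel_map")
  h <- nrow(m); w <- ncol(m)
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1), 2:(w + 1)] <- as.logical(m)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      del <- .zs_deletable(p, step)
      # parallel deletion may wipe out a small component wholesale; only
      # delete pixels that keep at least one surviving neighbour, so every
      # vessel component leaves a remnant (cleanup thins the rest)
      del <- del & .dilate8(p & !del)
      if (any(del)) {
        p[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p <- .thin_cleanup(p)
  structure(list(mask = p[2:(h + 1), 2:(w + 1), drop = FALSE]),
            class = "skeleton_map")
}

# 8-neighbour dilation (input already carries a FALSE border).
.dilate8 <- function(p) {
  h <- nrow(p); w <- ncol(p)
  out <- matrix(FALSE, h, w)
  out[2:(h - 1), 2:(w - 1)] <-
    p[1:(h - 2), 1:(w - 2)] | p[1:(h - 2), 2:(w - 1)] | p[1:(h - 2), 3:w] |
    p[2:(h - 1), 1:(w - 2)] |                           p[2:(h - 1), 3:w] |
    p[3:h,       1:(w - 2)] | p[3:h,       2:(w - 1)] | p[3:h,       3:w]
  out
}

# One Zhang-Suen sub-iteration on a FALSE-padded image: marks deletable
# pixels. Neighbours P2..P9 start north of the centre and run clockwise.
.zs_deletable <- function(p, step) {
  h2 <- nrow(p); w2 <- ncol(p)
  ctr <- p[2:(h2 - 1), 2:(w2 - 1)]
  n  <- p[1:(h2 - 2), 2:(w2 - 1)]
  ne <- p[1:(h2 - 2), 3:w2]
  e  <- p[2:(h2 - 1), 3:w2]
  se <- p[3:h2,       3:w2]
  s  <- p[3:h2,       2:(w2 - 1)]
  sw <- p[3:h2,       1:(w2 - 2)]
  wv <- p[2:(h2 - 1), 1:(w2 - 2)]
  nw <- p[1:(h2 - 2), 1:(w2 - 2)]
  b <- n + ne + e + se + s + sw + wv + nw
  a <- (!n & ne) + (!ne & e) + (!e & se) + (!se & s) +
       (!s & sw) + (!sw & wv) + (!wv & nw) + (!nw & n)
  cond <- ctr & b >= 2 & b <= 6 & a == 1
  cond <- if (step == 1L) {
    cond & !(n & e & s) & !(e & s & wv)
  } else {
    cond & !(n & e & wv) & !(n & s & wv)
  }
  full <- matrix(FALSE, h2, w2)
  full[2:(h2 - 1), 2:(w2 - 1)] <- cond
  full
}

# Remove residual fully-set 2x2 blocks left by parallel thinning. A pixel is
# removed only if it is a simple point (its deletion cannot split or delete
# a component), scanning blocks in row-major order — deterministic.
.thin_cleanup <- function(p) {
  repeat {
    blk <- p[-nrow(p), -ncol(p)] & p[-1, -ncol(p)] &
           p[-nrow(p), -1] & p[-1, -1]
    if (!any(blk)) break
    idx <- which(blk, arr.ind = TRUE)
    removed <- FALSE
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      for (off in list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))) {
        r <- i + off[1]; cc <- j + off[2]
        if (p[r, cc] && .is_simple_point(p, r, cc)) {
          p[r, cc] <- FALSE
          removed <- TRUE
          break
        }
      }
    }
    if (!removed) break
  }
  p
}

# 8-connectivity simple-point test (Guo-Hall connectivity count C == 1):
# deleting the pixel leaves its foreground neighbourhood in one 8-connected
# piece, so neither component count nor connectivity can change.
.is_simple_point <- function(p, r, c) {
  n1 <- p[r - 1, c];     n2 <- p[r - 1, c + 1]
  n3 <- p[r, c + 1];     n4 <- p[r + 1, c + 1]
  n5 <- p[r + 1, c];     n6 <- p[r + 1, c - 1]
  n7 <- p[r, c - 1];     n8 <- p[r - 1, c - 1]
  b <- n1 + n2 + n3 + n4 + n5 + n6 + n7 + n8
  cc <- (!n1 & (n2 | n3)) + (!n3 & (n4 | n5)) +
        (!n5 & (n6 | n7)) + (!n7 & (n8 | n1))
  cc == 1L && b >= 1L && b <= 7L
}
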