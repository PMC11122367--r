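test_that("Otsu threshold equals exhaustive between-class-variance search", {
  set.seed(41)
  for (i in 1:30) {
    # random histograms of varying shape, including sparse toy ones
    n_levels <- sample(c(3, 8, 32, 256), 1)
    levels <- sort(sample(0:255, n_levels))
    v <- sample(levels, 500, replace = TRUE,
                prob = runif(n_levels)^sample(1:3, 1))
    expect_identical(otsu_threshold(matrix(v, 20)), brute_force_otsu(v))
  }
})

test_that("global mask separates a two-level image and flags constant input", {
  m <- matrix(c(rep(50L, 200), rep(200L, 200)), 20)
  g <- global_mask(m)
  expect_identical(which(g), which(m == 200L))
  expect_warning(ge <- global_mask(matrix(7L, 10, 10)), "constant")
  expect_false(any(ge))
  gm <- global_mask(m, method = "mean_offset", offset = 10)
  expect_identical(sum(gm), 200L)
})

test_that("vesselness responds on tubes, is rotation-invariant and contrast-monotone", {
  img0 <- render_line_image(0)
  v0 <- vesselness(img0)
  expect_true(all(v0 >= 0 & v0 <= 1))
  # response maximal on the centerline of the ridge
  expect_identical(which.max(v0[, 51]), 51L)
  # a 3-px tube is matched by the small end of the scale ladder
  expect_lte(attr(v0, "best_scale")[51, 51], 2)
  # rotation invariance of the mean on-line response (<= 5%)
  img37 <- render_line_image(37)
  v37 <- vesselness(img37)
  on0 <- attr(img0, "perp") <= 0.3 & attr(img0, "along") <= 35
  on37 <- attr(img37, "perp") <= 0.3 & attr(img37, "along") <= 35
  expect_lt(abs(mean(v37[on37]) - mean(v0[on0])) / mean(v0[on0]), 0.05)
  # monotone non-decreasing in contrast (mean on-line response)
  v_dim <- vesselness(render_line_image(0, fg = 120))
  expect_lte(mean(v_dim[on0]), mean(v0[on0]))
  # degenerate and invalid inputs
  expect_true(all(vesselness(matrix(40L, 50, 50)) == 0))
  expect_error(vesselness(matrix(0L, 20, 20),
                          vesselness_params(scales_px = 10)),
               "scale")
  expect_error(vesselness_params(scales_px = numeric(0)))
  expect_error(vesselness_params(beta = -1))
})

test_that("adaptive threshold tracks local background", {
  expect_false(any(adaptive_mask(matrix(9L, 30, 30), 5, offset = 1)))
  expect_error(adaptive_mask(matrix(0L, 10, 10), window_px = 4), "odd")
  # bright line on a linear ramp: retained end-to-end where global loses it
  ramp <- matrix(rep(seq(0, 180, length.out = 120), each = 20), 20, 120)
  ramp[10, ] <- ramp[10, ] + 60
  ri <- matrix(as.integer(round(pmin(255, ramp))), 20, 120)
  aa <- adaptive_mask(ri, 15, 0)
  ga <- global_mask(ri)
  expect_true(all(aa[10, ]))
  expect_lt(mean(ga[10, ]), 1)
  # window spanning the whole (reflect-padded) image = global mean threshold
  toy <- matrix(30L, 16, 16); toy[5:12, 5:12] <- 200L
  expect_identical(adaptive_mask(toy, window_px = 33, offset = 0),
                   toy > mean(toy))
})

test_that("mask fusion follows the selected rule and stays within the union", {
  g <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2)
  h <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
  a <- matrix(c(FALSE, FALSE, TRUE, FALSE), 2)
  fused <- fuse_masks(g, h, a)
  expect_identical(fused$mask, matrix(c(TRUE, FALSE, TRUE, FALSE), 2))
  expect_identical(fused$provenance$rule, "vesselness_and_any")
  # vesselness all-true reduces the default rule to global | adaptive
  all_on <- matrix(TRUE, 2, 2)
  expect_identical(fuse_masks(g, all_on, a)$mask, g | a)
  expect_false(any(fuse_masks(g, !all_on, a)$mask))
  expect_error(fuse_masks(g, matrix(TRUE, 3, 3), a), "shape")
  # every rule yields a subset of the union of components
  set.seed(5)
  for (i in 1:20) {
    ms <- replicate(3, matrix(runif(64) > 0.5, 8), simplify = FALSE)
    uni <- ms[[1]] | ms[[2]] | ms[[3]]
    for (rule in c("vesselness_and_any", "majority", "intersection", "union")) {
      f <- fuse_masks(ms[[1]], ms[[2]], ms[[3]], rule = rule)
      expect_false(any(f$mask & !uni))
    }
  }
})

test_that("end-to-end binarization recovers synthetic trees and is deterministic", {
  sc <- small_scene(seed = 21)
  b1 <- binarize_enface(sc$image)
  b2 <- binarize_enface(sc$image)
  expect_identical(b1$mask, b2$mask)           # bit-identical rerun
  expect_gte(dice(b1$mask, sc$truth$truth_mask), 0.9)
  # fused mask never exceeds the union of its components
  prov <- b1$provenance
  expect_false(any(b1$mask & !(prov$global | prov$vesselness | prov$adaptive)))
  # all-dark image gives an empty map
  dark <- enface_image(matrix(0L, 64, 64))
  expect_false(any(suppressWarnings(binarize_enface(dark))$mask))
})

test_that("fusion beats a lone global threshold under an illumination drift", {
  sc <- small_scene(seed = 33, vad = 0.25,
                    background = 10, background_ramp = 140,
                    vessel_intensity = 80)
  g <- suppressWarnings(global_mask(sc$image))
  fused <- binarize_enface(sc$image)
  expect_gte(dice(fused$mask, sc$truth$truth_mask),
             dice(g, sc$truth$truth_mask))
  expect_gte(dice(fused$mask, sc$truth$truth_mask), 0.9)
})
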