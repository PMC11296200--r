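# transfer functions, gradients, histograms, and the ray caster

test_that("1D transfer function interpolates linearly and clamps", {
  tf <- opaque_white_tf()
  expect_equal(as.vector(evaluate_tf(tf, 127.5)), c(0.5, 0.5, 0.5, 0.5))
  expect_equal(as.vector(evaluate_tf(tf, 0)), c(0, 0, 0, 0))
  # clamping outside the covered range
  tf2 <- transfer_function_1d(c(50, 100), rbind(c(1, 0, 0, 0.2), c(0, 1, 0, 0.8)))
  expect_equal(as.vector(evaluate_tf(tf2, 10)), c(1, 0, 0, 0.2))
  expect_equal(as.vector(evaluate_tf(tf2, 200)), c(0, 1, 0, 0.8))
})

test_that("1D evaluation at a control point returns exactly that point", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(2:6, 1)
    values <- sort(sample(0:255, n))
    rgba <- matrix(stats::runif(4 * n), n, 4)
    tf <- transfer_function_1d(values, rgba)
    got <- evaluate_tf(tf, values)
    expect_equal(unname(got), unname(rgba))
  }
})

test_that("2D transfer function honours region order, falloff and emptiness", {
  tf <- transfer_function_2d(list(
    tf2d_region(c(0, 100), c(0, 10), c(1, 0, 0, 0.5), "flat"),
    tf2d_region(c(50, 150), c(0, 10), c(0, 1, 0, 0.8), "flat")))
  expect_equal(as.vector(evaluate_tf(tf, 25, 5)), c(1, 0, 0, 0.5))
  expect_equal(as.vector(evaluate_tf(tf, 75, 5)), c(0, 1, 0, 0.8))  # later wins
  expect_equal(as.vector(evaluate_tf(tf, 200, 5)), c(0, 0, 0, 0))   # no region
  expect_equal(as.vector(evaluate_tf(tf, 75, 50)), c(0, 0, 0, 0))   # gradient out

  fall <- transfer_function_2d(list(
    tf2d_region(c(0, 100), c(0, 10), c(1, 1, 1, 1), "linear-edge")))
  expect_equal(unname(evaluate_tf(fall, 50, 5)[, "alpha"]), 1)     # centre
  expect_equal(unname(evaluate_tf(fall, 0, 5)[, "alpha"]), 0)      # value edge
  expect_equal(unname(evaluate_tf(fall, 75, 5)[, "alpha"]), 0.5)   # halfway out
  expect_equal(unname(evaluate_tf(fall, 50, 10)[, "alpha"]), 0)    # gradient edge
})

test_that("gradient magnitude handles constants, ramps, and a stencil oracle", {
  cst <- volume_grid(array(9, c(4, 4, 4)))
  expect_true(all(gradient_magnitude(cst)$data == 0))

  d <- c(6, 5, 5)
  ramp <- volume_grid(array(rep(2 * (0:5), times = 25), dim = d))
  g <- gradient_magnitude(ramp)$data
  expect_true(all(abs(g[2:5, , ] - 2) < 1e-12))  # interior central difference
  expect_true(all(abs(g[c(1, 6), , ] - 2) < 1e-12))  # one-sided borders

  set.seed(42)
  vol <- volume_grid(array(stats::rnorm(125), c(5, 5, 5)),
                     spacing = c(0.5, 1, 2))
  g <- gradient_magnitude(vol)$data
  A <- vol$data; sp <- vol$spacing
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    comp <- numeric(3)
    for (a in 1:3) {
      idx <- c(i, j, k)
      hi <- idx; hi[a] <- min(idx[a] + 1, 5)
      lo <- idx; lo[a] <- max(idx[a] - 1, 1)
      comp[a] <- (A[hi[1], hi[2], hi[3]] - A[lo[1], lo[2], lo[3]]) /
        ((hi[a] - lo[a]) * sp[a])
    }
    expect_equal(g[i, j, k], sqrt(sum(comp^2)), tolerance = 1e-12)
  }
})

test_that("the 2D value/gradient histogram conserves counts", {
  z <- volume_grid(array(0, c(4, 4, 4)), value_kind = "unsigned-8-bit")
  h <- tf_histogram2d(z, value_bins = 16, gradient_bins = 8)
  expect_equal(h$counts[1, 1], 64L)
  expect_equal(sum(h$counts), 64L)

  for (seed in 1:5) {
    vol <- random_volume(c(5, 6, 4), seed)
    h <- tf_histogram2d(vol, value_bins = 32, gradient_bins = 16)
    expect_equal(sum(h$counts), prod(dim(vol$data)))
  }
})

test_that("disjoint structures occupy disjoint value columns", {
  d <- c(6, 6, 6)
  a <- array(0, d); a[2:3, 2:3, 2:3] <- 1
  b <- array(0, d); b[5:6, 5:6, 5:6] <- 1
  lm <- merge_masks(list(a = volume_grid(a, value_kind = "unsigned-8-bit"),
                         b = volume_grid(b, value_kind = "unsigned-8-bit")))
  h <- tf_histogram2d(lm, value_bins = 256, gradient_bins = 8)
  occupied <- which(rowSums(h$counts) > 0) - 1L  # value bin v+1 holds value v
  expect_setequal(occupied, c(0, 128, 255))

  f1 <- label_footprint(lm, 1, h)
  f2 <- label_footprint(lm, 2, h)
  expect_true(all(f1[, "value_bin"] == 129L))
  expect_true(all(f2[, "value_bin"] == 256L))
  expect_length(intersect(f1[, "value_bin"], f2[, "value_bin"]), 0L)
  expect_error(label_footprint(lm, 99, h), "unknown label_id")

  # empty structure has an empty footprint
  lm2 <- merge_masks(list(x = volume_grid(array(0, d), value_kind = "unsigned-8-bit")))
  h2 <- tf_histogram2d(lm2)
  expect_equal(nrow(label_footprint(lm2, 1, h2)), 0L)
})

test_that("a fully transparent transfer function reproduces the background", {
  vol <- random_volume(c(8, 8, 8), 3)
  tf <- transfer_function_1d(c(0, 255), rbind(c(1, 1, 1, 0), c(1, 1, 1, 0)))
  sc <- flat_scene(camera_position = c(-30, 3.5, 3.5),
                   camera_target = c(3.5, 3.5, 3.5),
                   background = c(0.2, 0.4, 0.6))
  img <- render(vol, tf, sc, image_size = c(16, 16))
  expect_true(all(img[, , 1] == 0.2))
  expect_true(all(img[, , 2] == 0.4))
  expect_true(all(img[, , 3] == 0.6))
})

test_that("a single opaque voxel projects to the analytically predicted pixel", {
  d <- c(5, 9, 11)
  A <- array(0, d)
  hot <- c(2, 3, 7)  # zero-based (slice, row, col)
  A[hot[1] + 1, hot[2] + 1, hot[3] + 1] <- 255
  vol <- volume_grid(A, value_kind = "unsigned-8-bit")
  # the opaque window [100, 255] spans 1.2 voxels along the ray, wider
  # than the sampling step, so the hit cannot fall between samples
  tf <- transfer_function_2d(list(
    tf2d_region(c(100, 255), c(0, 1e9), c(1, 0.5, 0.25, 1), "flat")))
  W <- 11L; H <- 9L
  sc <- flat_scene(camera_position = c(-40, 4, 5),
                   camera_target = c(2, 4, 5),
                   camera_up = c(0, 1, 0), step_size_voxels = 0.25,
                   view_width = 11, background = c(0, 0, 0))
  img <- render(vol, tf, sc, image_size = c(W, H))

  # analytic projection through the stated orthographic camera model:
  # right = normalize(f x up) = +col axis, up' = right x f = +row axis;
  # pixel (i, j) samples col = 5 + ((j+.5)/W*2-1)*vw/2, row = 4 + ndc_y*vh/2
  f <- c(1, 0, 0); up <- c(0, 1, 0)
  right <- c(0, 0, 1); up2 <- c(0, 1, 0)
  vw <- 11; vh <- vw * H / W
  j_hit <- which(vapply(0:(W - 1), function(j)
    abs(5 + (((j + 0.5) / W) * 2 - 1) * vw / 2 - hot[3]) < 1e-9, logical(1))) - 1L
  i_hit <- which(vapply(0:(H - 1), function(i)
    abs(4 + (1 - ((i + 0.5) / H) * 2) * vh / 2 - hot[2]) < 1e-9, logical(1))) - 1L
  expect_length(j_hit, 1L); expect_length(i_hit, 1L)

  lit <- which(img[, , 1] > 0, arr.ind = TRUE)
  expect_identical(unname(lit), cbind(i_hit + 1L, j_hit + 1L))
  expect_equal(as.vector(img[i_hit + 1, j_hit + 1, ]), c(1, 0.5, 0.25))
})

two_slab_setup <- function(a1, a2, step, camera_x = -100) {
  n <- 30L
  A <- array(0, c(n, 3, 3))
  A[1:15, , ] <- 100
  A[16:30, , ] <- 200
  vol <- volume_grid(A, value_kind = "unsigned-8-bit")
  # per-voxel opacities chosen so each 15-voxel slab integrates to a1 / a2
  a0_1 <- 1 - (1 - a1)^(1 / 15)
  a0_2 <- 1 - (1 - a2)^(1 / 15)
  tf <- transfer_function_2d(list(
    tf2d_region(c(50, 150), c(0, 1e9), c(1, 0, 0, a0_1), "flat"),
    tf2d_region(c(150, 255), c(0, 1e9), c(0, 0, 1, a0_2), "flat")))
  sc <- flat_scene(camera_position = c(camera_x, 1, 1),
                   camera_target = c(15, 1, 1),
                   view_width = 1, step_size_voxels = step,
                   background = c(0, 0, 0), opacity_termination = 1)
  render(vol, tf, sc, image_size = c(1, 1))
}

test_that("two homogeneous slabs composite to the closed form within 1%", {
  a1 <- 0.6; a2 <- 0.8
  img <- two_slab_setup(a1, a2, step = 0.25)
  # closed form: c1*a1 + c2*a2*(1 - a1), c1 red, c2 blue
  expect_equal(img[1, 1, 1], a1, tolerance = 0.01)
  expect_equal(img[1, 1, 3], a2 * (1 - a1), tolerance = 0.01)
})

test_that("halving the step size converges in the Cauchy sense", {
  # the same two slabs under a piecewise-linear 1D transfer function:
  # the opacity integrand is smooth across the slab transition, so the
  # midpoint sampling error genuinely shrinks with the step
  n <- 30L; B <- array(0, c(n, 3, 3)); B[1:15, , ] <- 100; B[16:30, , ] <- 200
  slabs <- volume_grid(B, value_kind = "unsigned-8-bit")
  tf <- transfer_function_1d(c(100, 200),
                             rbind(c(1, 0, 0, 1 - 0.4^(1 / 15)),
                                   c(0, 0, 1, 1 - 0.2^(1 / 15))))
  pixel <- function(step)
    render(slabs, tf, flat_scene(camera_position = c(-100, 1, 1),
                                 camera_target = c(15, 1, 1), view_width = 1,
                                 step_size_voxels = step,
                                 opacity_termination = 1),
           image_size = c(1, 1))[1, 1, 1]
  vals <- vapply(c(0.5, 0.25, 0.125), pixel, numeric(1))
  expect_lt(abs(vals[3] - vals[2]), abs(vals[2] - vals[1]))
})

test_that("raising transfer-function opacity never brightens over white background", {
  vol <- volume_grid(array(128, c(8, 4, 4)), value_kind = "unsigned-8-bit")
  # termination off: truncating accumulation at the threshold is what the
  # early-exit optimization trades away, the compositing itself is monotone
  sc <- flat_scene(camera_position = c(-30, 1.5, 1.5),
                   camera_target = c(3.5, 1.5, 1.5),
                   background = c(1, 1, 1), view_width = 4,
                   opacity_termination = 1)
  pix <- vapply(seq(0.05, 0.95, by = 0.1), function(a) {
    tf <- transfer_function_1d(c(0, 255), rbind(c(0, 0, 0, a), c(0, 0, 0, a)))
    render(vol, tf, sc, image_size = c(4, 4))[2, 2, 1]
  }, numeric(1))
  expect_true(all(diff(pix) <= 1e-12))
})

test_that("orthographic images are equivariant under joint translation", {
  vol <- random_volume(c(6, 6, 6), 17)
  tf <- transfer_function_1d(c(0, 255), rbind(c(0, 0, 0, 0), c(1, 1, 1, 0.8)))
  sc <- scene_params(camera_position = c(-20, 2.5, 2.5),
                     camera_target = c(2.5, 2.5, 2.5), view_width = 10)
  img1 <- render(vol, tf, sc, image_size = c(12, 12))
  shift <- c(3, -2, 5)
  vol2 <- volume_grid(vol$data, origin = vol$origin + shift,
                      value_kind = vol$value_kind)
  sc2 <- scene_params(camera_position = sc$camera_position + shift,
                      camera_target = sc$camera_target + shift,
                      view_width = 10)
  img2 <- render(vol2, tf, sc2, image_size = c(12, 12))
  expect_equal(img1, img2, tolerance = 1e-12)
})

test_that("degenerate cameras are rejected", {
  vol <- random_volume(c(4, 4, 4), 1)
  sc <- scene_params(camera_position = c(-10, 0, 0), camera_target = c(5, 0, 0),
                     camera_up = c(1, 0, 0))
  expect_error(render(vol, opaque_white_tf(), sc, image_size = c(4, 4)),
               "degenerate camera")
})

test_that("label maps render with nearest-neighbour sampling and object overrides", {
  d <- c(6, 8, 8)
  a <- array(0, d); a[2:5, 2:4, 2:7] <- 1
  b <- array(0, d); b[2:5, 5:7, 2:7] <- 1
  lm <- merge_masks(list(a = volume_grid(a, value_kind = "unsigned-8-bit"),
                         b = volume_grid(b, value_kind = "unsigned-8-bit")))
  sc <- flat_scene(camera_position = c(-30, 3.5, 3.5),
                   camera_target = c(3.5, 3.5, 3.5), view_width = 8)
  img <- render(lm, scene = sc, image_size = c(8, 8))
  expect_true(any(img > 0))
  # hiding both structures gives pure background
  ob <- object_params(list("1" = list(visible = FALSE),
                           "2" = list(visible = FALSE)))
  img2 <- render(lm, scene = sc, objects = ob, image_size = c(8, 8))
  expect_true(all(img2 == 0))
  # colour override shows up
  ob3 <- object_params(list("1" = list(colour = c(1, 0, 0, 1)),
                            "2" = list(visible = FALSE)))
  img3 <- render(lm, scene = sc, objects = ob3, image_size = c(8, 8))
  expect_true(any(img3[, , 1] > 0))
  expect_true(all(img3[, , 2] == 0))
})

test_that("overlay degenerates to single-volume renders when one side is transparent", {
  ph <- generate_phantom(two_sphere_spec())
  lm <- merge_masks(ph$masks)
  tomo8 <- volume_grid(array(clamp(round(ph$tomogram$data), 0, 255),
                             dim(ph$tomogram$data)),
                       value_kind = "unsigned-8-bit")
  tf_orig <- transfer_function_1d(c(0, 255), rbind(c(0, 0, 0, 0), c(1, 1, 1, 0.9)))
  transparent <- transfer_function_1d(c(0, 255),
                                      rbind(c(0, 0, 0, 0), c(0, 0, 0, 0)))
  sc <- flat_scene(camera_position = c(-40, 6.5, 7.5),
                   camera_target = c(5.5, 6.5, 7.5), view_width = 18)
  size <- c(16, 16)

  img_orig <- render(tomo8, tf_orig, sc, image_size = size)
  img_ov1 <- render_overlay(tomo8, lm, tf_orig, tf_labels = transparent,
                            scene = sc, image_size = size)
  expect_equal(img_ov1, img_orig, tolerance = 1e-12)

  img_lab <- render(lm, scene = sc, image_size = size)
  img_ov2 <- render_overlay(tomo8, lm, transparent, tf_labels = NULL,
                            scene = sc, image_size = size)
  expect_equal(img_ov2, img_lab, tolerance = 1e-12)

  # with both visible, label-coloured pixels contain the label-only set
  img_both <- render_overlay(tomo8, lm, tf_orig, scene = sc, image_size = size)
  lab_pixels <- apply(img_lab, c(1, 2), function(p) any(p > 0))
  both_pixels <- apply(img_both, c(1, 2), function(p) any(p > 0))
  expect_true(all(both_pixels[lab_pixels]))
})
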