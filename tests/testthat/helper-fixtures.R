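# shared builders for small in-code fixtures

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

random_volume <- function(d, seed, kind = "unsigned-8-bit",
                          max_val = 255) {
  set.seed(seed)
  volume_grid(array(sample(0:max_val, prod(d), replace = TRUE), dim = d),
              value_kind = kind)
}

random_mask <- function(d, seed, p = 0.4) {
  set.seed(seed)
  volume_grid(array(as.numeric(stats::runif(prod(d)) < p), dim = d),
              value_kind = "unsigned-8-bit")
}

random_grey <- function(nr, nc, seed) {
  set.seed(seed)
  grey_image(matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc))
}

two_sphere_spec <- function(seed = 1) {
  phantom_spec(
    grid_shape = c(12, 14, 16),
    structures = list(
      list(name = "core", shape = "sphere", centre = c(5, 6, 7), radius = 3),
      list(name = "shell", shape = "shell", centre = c(5, 6, 7),
           inner_radius = 4, outer_radius = 5)),
    seed = seed)
}

random_phantom_spec <- function(seed) {
  set.seed(seed)
  d <- sample(10:16, 3, replace = TRUE)
  n <- sample(2:4, 1)
  ctr <- function() c(stats::runif(1, 4, d[1] - 5),
                      stats::runif(1, 4, d[2] - 5),
                      stats::runif(1, 4, d[3] - 5))
  shapes <- replicate(n, {
    kind <- sample(c("sphere", "ellipsoid", "tube", "shell"), 1)
    switch(kind,
      sphere = list(shape = "sphere", centre = ctr(), radius = stats::runif(1, 1.5, 3.5)),
      ellipsoid = list(shape = "ellipsoid", centre = ctr(),
                       semiaxes = stats::runif(3, 1.5, 3.5)),
      tube = list(shape = "tube", axis = sample(c("slice", "row", "col"), 1),
                  centre = c(stats::runif(1, 4, min(d) - 5),
                             stats::runif(1, 4, min(d) - 5)),
                  radius = stats::runif(1, 1, 3)),
      shell = list(shape = "shell", centre = ctr(),
                   inner_radius = stats::runif(1, 1, 2),
                   outer_radius = stats::runif(1, 2.5, 3.5)))
  }, simplify = FALSE)
  for (k in seq_along(shapes)) shapes[[k]]$name <- paste0("s", k)
  phantom_spec(grid_shape = d, structures = shapes, seed = seed)
}

# brute-force merge oracle: per-voxel loop over structures
oracle_merge <- function(masks, policy) {
  n <- length(masks)
  values <- assign_voxel_values(n)
  d <- dim(masks[[1]]$data)
  out <- array(0, dim = d)
  for (i in seq_len(prod(d))) {
    js <- integer(0)
    for (k in seq_len(n)) if (masks[[k]]$data[i] > 0) js <- c(js, k)
    if (length(js) == 0L) next
    if (policy == "error" && length(js) > 1L) return(NULL)
    k <- if (policy == "first-wins") js[1] else js[length(js)]
    out[i] <- values[k]
  }
  out
}

# brute-force Sobel with replicated borders (independent of the package path)
sobel_oracle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gpix <- function(r, c) m[clamp(r, 1, nr), clamp(c, 1, nc)]
  out <- matrix(0, nr, nc)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dcol
  ky <- t(kx)                                                 # d/drow
  for (r in 1:nr) for (c in 1:nc) {
    gx <- 0; gy <- 0
    for (dr in -1:1) for (dc in -1:1) {
      gx <- gx + kx[dr + 2, dc + 2] * gpix(r + dr, c + dc)
      gy <- gy + ky[dr + 2, dc + 2] * gpix(r + dr, c + dc)
    }
    out[r, c] <- min(255, floor(sqrt(gx^2 + gy^2) + 0.5))
  }
  out
}

opaque_white_tf <- function() {
  transfer_function_1d(c(0, 255), rbind(c(0, 0, 0, 0), c(1, 1, 1, 1)))
}

flat_scene <- function(...) {
  scene_params(ambient = 1, diffuse = 0, specular = 0, ...)
}
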