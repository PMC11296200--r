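# Software volume ray caster: per-pixel rays through the volume in
# physical space, trilinear (scalar) or nearest-neighbour (label)
# sampling, front-to-back alpha compositing with step-size-corrected
# opacity, and Blinn-Phong shading with gradient normals.

#' Global scene parameters for the renderer
#'
#' @param camera_position,camera_target,camera_up camera pose in mm;
#'   `camera_up` must not be parallel to the view direction.
#' @param projection `"orthographic"` or `"perspective"`.
#' @param fov_degrees vertical field of view (perspective only).
#' @param light_direction unit vector pointing from the scene towards the
#'   light (normalized internally).
#' @param ambient,diffuse,specular Blinn-Phong coefficients in \[0, 1\].
#' @param shininess specular exponent (> 0).
#' @param background RGB background colour in \[0, 1\].
#' @param step_size_voxels ray sampling step in voxels (times the smallest
#'   spacing component), in (0, 1\].
#' @param opacity_termination early ray termination threshold in (0, 1\].
#' @param view_width orthographic view window width in mm; `NULL` fits the
#'   volume's bounding sphere.
#' @return a `scene_params`.
#' @export
scene_params <- function(camera_position = c(0, 0, -400),
                         camera_target = c(0, 0, 0),
                         camera_up = c(0, 1, 0),
                         projection = c("orthographic", "perspective"),
                         fov_degrees = 30,
                         light_direction = c(0, 0, -1),
                         ambient = 0.2, diffuse = 0.7, specular = 0.2,
                         shininess = 32,
                         background = c(0, 0, 0),
                         step_size_voxels = 0.5,
                         opacity_termination = 0.99,
                         view_width = NULL) {
  projection <- match.arg(projection)
  stopifnot(length(camera_position) == 3L, length(camera_target) == 3L,
            length(camera_up) == 3L, length(light_direction) == 3L,
            length(background) == 3L)
  for (coef in c(ambient, diffuse, specular))
    if (!is.finite(coef) || coef < 0 || coef > 1)
      stop("ambient/diffuse/specular must lie in [0, 1]")
  if (shininess <= 0) stop("shininess must be positive")
  if (step_size_voxels <= 0 || step_size_voxels > 1)
    stop("step_size_voxels must lie in (0, 1]")
  if (opacity_termination <= 0 || opacity_termination > 1)
    stop("opacity_termination must lie in (0, 1]")
  l <- light_direction / sqrt(sum(light_direction^2))
  structure(list(camera_position = as.numeric(camera_position),
                 camera_target = as.numeric(camera_target),
                 camera_up = as.numeric(camera_up),
                 projection = projection, fov_degrees = fov_degrees,
                 light_direction = l,
                 ambient = ambient, diffuse = diffuse, specular = specular,
                 shininess = shininess,
                 background = as.numeric(background),
                 step_size_voxels = step_size_voxels,
                 opacity_termination = opacity_termination,
                 view_width = view_width),
            class = "scene_params")
}

#' Per-label rendering overrides
#'
#' @param overrides named list keyed by `label_id` (as character), each a
#'   list with any of `colour` (RGBA), `opacity` (scale in \[0, 1\]),
#'   `visible` (logical).
#' @return an `object_params`.
#' @export
object_params <- function(overrides = list()) {
  structure(list(overrides = overrides), class = "object_params")
}

#' Gradient magnitude of a volume
#'
#' Central differences in the interior, one-sided at the borders, each
#' axis divided by its spacing; zero along any length-1 axis.
#'
#' @param vol a [volume_grid()].
#' @return real-valued `volume_grid` of gradient magnitudes (1/mm units
#'   times the voxel value scale).
#' @export
gradient_magnitude <- function(vol) {
  g <- grad_components(vol$data, vol$spacing)
  volume_grid(sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2),
              spacing = vol$spacing, origin = vol$origin,
              orientation = vol$orientation, value_kind = "real")
}

grad_components <- function(A, spacing) {
  d <- dim(A)
  out <- vector("list", 3L)
  for (a in 1:3) {
    n <- d[a]; h <- spacing[a]
    D <- array(0, dim = d)
    if (n >= 2L) {
      ix <- function(k) {
        idx <- list(quote(expr =), quote(expr =), quote(expr =))
        idx[[a]] <- k
        do.call(`[`, c(list(A), idx))
      }
      asn <- function(k, val) {
        idx <- list(quote(expr =), quote(expr =), quote(expr =))
        idx[[a]] <- k
        eval(as.call(c(quote(`[<-`), list(quote(D)), idx, list(val))))
      }
      if (n >= 3L)
        D <- asn(2:(n - 1), (ix(3:n) - ix(1:(n - 2))) / (2 * h))
      D <- asn(1, (ix(2) - ix(1)) / h)
      D <- asn(n, (ix(n) - ix(n - 1)) / h)
    }
    out[[a]] <- D
  }
  out
}

#' Joint histogram of voxel value and gradient magnitude
#'
#' The domain of a 2D transfer function: the value axis spans \[0, 255\]
#' for 8-bit volumes (otherwise the observed range) and the gradient axis
#' spans \[0, observed maximum\].
#'
#' @param vol a [volume_grid()] or `label_map`.
#' @param grad gradient-magnitude volume matching `vol`'s shape
#'   (computed with [gradient_magnitude()] when `NULL`).
#' @param value_bins,gradient_bins bin counts.
#' @return a `histogram_2d` with a `counts` matrix
#'   (`value_bins` x `gradient_bins`) summing to the voxel total.
#' @export
tf_histogram2d <- function(vol, grad = NULL, value_bins = 64L,
                           gradient_bins = 64L) {
  if (inherits(vol, "label_map")) vol <- vol$grid
  stopifnot(inherits(vol, "volume_grid"))
  if (is.null(grad)) grad <- gradient_magnitude(vol)
  if (inherits(grad, "volume_grid")) grad <- grad$data
  if (!identical(dim(vol$data), dim(grad)))
    stop("volume and gradient shapes differ")
  value_range <- if (vol$value_kind == "unsigned-8-bit") c(0, 255)
                 else range(vol$data)
  gradient_max <- max(grad)
  vb <- bin_index(vol$data, value_range[1], value_range[2], value_bins)
  gb <- bin_index(grad, 0, gradient_max, gradient_bins)
  counts <- matrix(0L, value_bins, gradient_bins)
  tab <- table(factor(vb, levels = seq_len(value_bins)),
               factor(gb, levels = seq_len(gradient_bins)))
  counts[] <- as.integer(tab)
  structure(list(value_bins = as.integer(value_bins),
                 gradient_bins = as.integer(gradient_bins),
                 counts = counts, value_range = value_range,
                 gradient_max = gradient_max),
            class = "histogram_2d")
}

bin_index <- function(x, lo, hi, bins) {
  if (hi <= lo) return(array(1L, dim = dim(x)))
  clamp(floor((x - lo) / (hi - lo) * bins) + 1L, 1L, bins)
}

#' Histogram footprint of one segmented structure
#'
#' The set of (value bin, gradient bin) cells occupied by the voxels of
#' one label, in the bin space of `hist` (the gradient is taken from the
#' label grid itself). Structures with distinct voxel values occupy
#' disjoint value columns, which is what lets them be picked apart in the
#' 2D transfer-function editor.
#'
#' @param labels a `label_map`.
#' @param label_id id of the structure in `labels$table`.
#' @param hist a `histogram_2d` built on `labels`.
#' @return integer matrix with columns `value_bin`, `gradient_bin`
#'   (unique occupied cells; zero rows for an empty structure).
#' @export
label_footprint <- function(labels, label_id, hist) {
  stopifnot(inherits(labels, "label_map"), inherits(hist, "histogram_2d"))
  row <- which(labels$table$label_id == label_id)
  if (length(row) != 1L) stop(sprintf("unknown label_id %s", label_id))
  vv <- labels$table$voxel_value[row]
  sel <- labels$grid$data == vv
  if (!any(sel))
    return(matrix(integer(0), 0L, 2L,
                  dimnames = list(NULL, c("value_bin", "gradient_bin"))))
  grad <- gradient_magnitude(labels$grid)$data
  vb <- bin_index(labels$grid$data, hist$value_range[1], hist$value_range[2],
                  hist$value_bins)
  gb <- bin_index(grad, 0, hist$gradient_max, hist$gradient_bins)
  cells <- unique(cbind(value_bin = as.integer(vb[sel]),
                        gradient_bin = as.integer(gb[sel])))
  cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
}

# --- ray casting -----------------------------------------------------------

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# trilinear sample of array A at continuous zero-based coords q (n x 3),
# border-replicated
trilinear_sample <- function(A, q) {
  d <- dim(A)
  q1 <- clamp(q[, 1], 0, d[1] - 1); q2 <- clamp(q[, 2], 0, d[2] - 1)
  q3 <- clamp(q[, 3], 0, d[3] - 1)
  f1 <- pmin(floor(q1), d[1] - 2); f2 <- pmin(floor(q2), d[2] - 2)
  f3 <- pmin(floor(q3), d[3] - 2)
  if (d[1] == 1L) f1 <- 0; if (d[2] == 1L) f2 <- 0; if (d[3] == 1L) f3 <- 0
  w1 <- q1 - f1; w2 <- q2 - f2; w3 <- q3 - f3
  g1 <- pmin(f1 + 1, d[1] - 1); g2 <- pmin(f2 + 1, d[2] - 1)
  g3 <- pmin(f3 + 1, d[3] - 1)
  at <- function(i, j, k) A[i + d[1] * (j + d[2] * k) + 1]
  (1 - w1) * ((1 - w2) * ((1 - w3) * at(f1, f2, f3) + w3 * at(f1, f2, g3)) +
              w2 * ((1 - w3) * at(f1, g2, f3) + w3 * at(f1, g2, g3))) +
  w1 * ((1 - w2) * ((1 - w3) * at(g1, f2, f3) + w3 * at(g1, f2, g3)) +
        w2 * ((1 - w3) * at(g1, g2, f3) + w3 * at(g1, g2, g3)))
}

nearest_sample <- function(A, q) {
  d <- dim(A)
  i <- clamp(round_half_up(q[, 1]), 0, d[1] - 1)
  j <- clamp(round_half_up(q[, 2]), 0, d[2] - 1)
  k <- clamp(round_half_up(q[, 3]), 0, d[3] - 1)
  A[i + d[1] * (j + d[2] * k) + 1]
}

# build the per-source sampling closure used by the ray marcher
make_source <- function(x, tf, objects) {
  if (inherits(x, "label_map")) {
    lut <- matrix(0, 256L, 4L)
    tab <- x$table
    for (r in seq_len(nrow(tab))) {
      rgba <- c(tab$red[r], tab$green[r], tab$blue[r], tab$alpha[r])
      if (!is.null(tf)) {
        if (!inherits(tf, "transfer_function_1d"))
          stop("label maps take a 1D transfer function (or none)")
        rgba <- as.vector(evaluate_tf(tf, tab$voxel_value[r]))
      }
      if (!is.null(objects)) {
        ov <- objects$overrides[[as.character(tab$label_id[r])]]
        if (!is.null(ov)) {
          if (!is.null(ov$colour)) rgba <- as.numeric(ov$colour)
          if (!is.null(ov$opacity)) rgba[4] <- rgba[4] * ov$opacity
          if (isFALSE(ov$visible)) rgba[4] <- 0
        }
      }
      lut[tab$voxel_value[r] + 1L, ] <- rgba
    }
    grid <- x$grid
    colour_fn <- function(q, grad_fn) {
      v <- nearest_sample(grid$data, q)
      lut[v + 1L, , drop = FALSE]
    }
    list(grid = grid, colour = colour_fn, label_mode = TRUE)
  } else {
    stopifnot(inherits(x, "volume_grid"))
    grid <- x
    if (is.null(tf)) stop("rendering a scalar volume requires a transfer function")
    colour_fn <- function(q, grad_fn) {
      v <- trilinear_sample(grid$data, q)
      if (inherits(tf, "transfer_function_2d")) {
        g <- grad_fn(q)
        evaluate_tf(tf, clamp(v, 0, 255), sqrt(rowSums(g^2)))
      } else {
        evaluate_tf(tf, clamp(v, 0, 255))
      }
    }
    list(grid = grid, colour = colour_fn, label_mode = FALSE)
  }
}

ray_march <- function(sources, scene, image_size) {
  grid <- sources[[1]]$grid
  for (s in sources)
    if (!same_geometry(s$grid, grid))
      stop("overlay volumes must share one grid; use overlay_with_original()")
  d <- dim(grid$data)
  W <- as.integer(image_size[1]); H <- as.integer(image_size[2])

  f <- scene$camera_target - scene$camera_position
  if (sqrt(sum(f^2)) < 1e-12) stop("degenerate camera: position equals target")
  f <- f / sqrt(sum(f^2))
  r0 <- cross3(f, scene$camera_up)
  if (sqrt(sum(r0^2)) < 1e-9)
    stop("degenerate camera: up vector parallel to view direction")
  right <- r0 / sqrt(sum(r0^2))
  up <- cross3(right, f)

  corners <- as.matrix(expand.grid(s = c(-0.5, d[1] - 0.5),
                                   r = c(-0.5, d[2] - 0.5),
                                   c = c(-0.5, d[3] - 0.5)))
  phys_corners <- grid_index_to_phys(grid, corners)
  centre <- colMeans(phys_corners)
  radius <- max(sqrt(rowSums(sweep(phys_corners, 2, centre)^2)))

  px <- expand.grid(i = 0:(H - 1L), j = 0:(W - 1L))
  ndc_x <- ((px$j + 0.5) / W) * 2 - 1
  ndc_y <- 1 - ((px$i + 0.5) / H) * 2
  np <- nrow(px)

  if (scene$projection == "orthographic") {
    vw <- if (is.null(scene$view_width)) 2 * radius else scene$view_width
    vh <- vw * H / W
    origins <- matrix(scene$camera_position, np, 3L, byrow = TRUE) +
      outer(ndc_x * vw / 2, right) + outer(ndc_y * vh / 2, up)
    dirs <- matrix(f, np, 3L, byrow = TRUE)
  } else {
    tanv <- tan(scene$fov_degrees * pi / 360)
    tanh_ <- tanv * W / H
    dirs <- matrix(f, np, 3L, byrow = TRUE) +
      outer(ndc_x * tanh_, right) + outer(ndc_y * tanv, up)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    origins <- matrix(scene$camera_position, np, 3L, byrow = TRUE)
  }

  q0 <- grid_phys_to_index(grid, origins)
  dq <- (dirs %*% grid$orientation) / matrix(grid$spacing, np, 3L, byrow = TRUE)

  tmin <- rep(-Inf, np); tmax <- rep(Inf, np)
  for (a in 1:3) {
    lo <- -0.5; hi <- d[a] - 0.5
    par <- abs(dq[, a]) < 1e-12
    t1 <- (lo - q0[, a]) / dq[, a]; t2 <- (hi - q0[, a]) / dq[, a]
    tl <- pmin(t1, t2); th <- pmax(t1, t2)
    inside <- q0[, a] >= lo & q0[, a] <= hi
    tl[par] <- ifelse(inside[par], -Inf, Inf)
    th[par] <- ifelse(inside[par], Inf, -Inf)
    tmin <- pmax(tmin, tl); tmax <- pmin(tmax, th)
  }
  tnear <- pmax(tmin, 0)
  hit <- tmax > tnear & is.finite(tnear)

  dt <- scene$step_size_voxels * min(grid$spacing)
  ref_step <- min(grid$spacing)

  # per-source gradient fields for shading / 2D transfer functions
  shading_on <- scene$diffuse > 0 || scene$specular > 0
  grad_fns <- lapply(sources, function(src) {
    comps <- NULL
    function(q) {
      if (is.null(comps))
        comps <<- grad_components(src$grid$data, src$grid$spacing)
      cbind(trilinear_sample(comps[[1]], q),
            trilinear_sample(comps[[2]], q),
            trilinear_sample(comps[[3]], q))
    }
  })

  Cr <- numeric(np); Cg <- numeric(np); Cb <- numeric(np); A <- numeric(np)
  n_steps <- if (any(hit)) ceiling(max((tmax - tnear)[hit]) / dt) else 0L
  l <- scene$light_direction

  for (k in seq_len(n_steps)) {
    t <- tnear + (k - 0.5) * dt
    active <- which(hit & t <= tmax & A < scene$opacity_termination)
    if (length(active) == 0L) break
    q <- q0[active, , drop = FALSE] + dq[active, , drop = FALSE] * t[active]
    for (si in seq_along(sources)) {
      rgba <- sources[[si]]$colour(q, grad_fns[[si]])
      a0 <- rgba[, 4]
      lit <- which(a0 > 0)
      if (length(lit) == 0L) next
      a <- 1 - (1 - a0[lit])^(dt / ref_step)
      rgb <- rgba[lit, 1:3, drop = FALSE]
      if (shading_on) {
        gidx <- grad_fns[[si]](q[lit, , drop = FALSE])
        gphys <- gidx %*% t(sources[[si]]$grid$orientation)
        gn <- sqrt(rowSums(gphys^2))
        nrm <- -gphys / ifelse(gn > 0, gn, 1)
        ndotl <- pmax(0, nrm %*% l)
        hvec <- l - dirs[active[lit], , drop = FALSE]
        hvec <- hvec / sqrt(rowSums(hvec^2))
        ndoth <- pmax(0, rowSums(nrm * hvec))
        shade <- scene$ambient + scene$diffuse * as.vector(ndotl)
        spec <- scene$specular * ndoth^scene$shininess
        spec[gn == 0] <- 0
        shade[gn == 0] <- scene$ambient
        rgb <- rgb * shade + spec
      } else {
        rgb <- rgb * scene$ambient
      }
      idx <- active[lit]
      w <- (1 - A[idx]) * a
      Cr[idx] <- Cr[idx] + w * rgb[, 1]
      Cg[idx] <- Cg[idx] + w * rgb[, 2]
      Cb[idx] <- Cb[idx] + w * rgb[, 3]
      A[idx] <- A[idx] + w
    }
  }

  bg <- scene$background
  Cr <- Cr + (1 - A) * bg[1]; Cg <- Cg + (1 - A) * bg[2]
  Cb <- Cb + (1 - A) * bg[3]
  img <- array(0, dim = c(H, W, 3L))
  img[, , 1] <- matrix(clamp(Cr, 0, 1), H, W)
  img[, , 2] <- matrix(clamp(Cg, 0, 1), H, W)
  img[, , 3] <- matrix(clamp(Cb, 0, 1), H, W)
  img
}

#' Render a volume or label map
#'
#' Casts one ray per pixel through the volume in physical space, samples
#' trilinearly (scalar volumes) or by nearest neighbour (label maps, so
#' labels never blend into non-existent values), applies the transfer
#' function, shades with Blinn-Phong using the negated normalized
#' gradient as normal, and composites front to back with per-sample
#' opacity corrected for step size
#' (`a = 1 - (1 - a0)^(step / reference_step)`, reference step one voxel).
#' Rays terminate early once accumulated opacity reaches
#' `opacity_termination`; the result is composited over the background.
#'
#' @param x a [volume_grid()] or `label_map`.
#' @param tf transfer function; optional for label maps (the label
#'   table's colours are used when absent).
#' @param scene a [scene_params()].
#' @param objects optional [object_params()] per-label overrides.
#' @param image_size `c(width, height)` in pixels.
#' @return height x width x 3 RGB array in \[0, 1\].
#' @export
render <- function(x, tf = NULL, scene = scene_params(), objects = NULL,
                   image_size = c(512, 512)) {
  ray_march(list(make_source(x, tf, objects)), scene, image_size)
}

#' Render a label map over the original tomogram
#'
#' Both volumes are sampled along the same rays; at each sample the label
#' contribution is composited first (the segmentation enhances the region
#' of interest), then the original volume, with the same ray machinery as
#' [render()].
#'
#' @param original tomogram `volume_grid`, co-registered with `labels`
#'   (see [overlay_with_original()]).
#' @param labels a `label_map`.
#' @param tf_original transfer function for the tomogram.
#' @param tf_labels optional transfer function for the labels.
#' @param scene a [scene_params()].
#' @param objects optional [object_params()].
#' @param image_size `c(width, height)` in pixels.
#' @return height x width x 3 RGB array in \[0, 1\].
#' @export
render_overlay <- function(original, labels, tf_original, tf_labels = NULL,
                           scene = scene_params(), objects = NULL,
                           image_size = c(512, 512)) {
  ray_march(list(make_source(labels, tf_labels, objects),
                 make_source(original, tf_original, NULL)),
            scene, image_size)
}
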