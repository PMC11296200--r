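# Synthetic phantoms standing in for scanned specimens: geometric
# structures (spheres, ellipsoids, tubes, shells, echoing braincases and
# skeletal elements) rasterized on a voxel grid, exported in
# vendor-style DICOM layouts with a ground-truth manifest, plus a
# synthetic optical-density step tablet. All generators are pure
# functions of (spec, seed).

#' Describe a synthetic phantom
#'
#' Structure geometry is given in voxel units on the zero-based
#' `(slice, row, col)` index grid; a voxel belongs to a structure when its
#' centre lies inside the shape. Supported shapes:
#' \describe{
#'   \item{sphere}{`centre` (3), `radius`}
#'   \item{ellipsoid}{`centre` (3), `semiaxes` (3)}
#'   \item{tube}{`axis` ("slice", "row" or "col"), `centre` (2, the
#'     remaining axes in index order), `radius`; spans the full axis}
#'   \item{shell}{`centre` (3), `inner_radius`, `outer_radius`}
#' }
#'
#' @param grid_shape `(slices, rows, cols)`, each >= 4.
#' @param spacing voxel spacing in mm.
#' @param structures list of `list(name=, shape=, ...)` entries (at most
#'   255).
#' @param tomogram_noise_sd standard deviation of the additive Gaussian
#'   noise on the synthetic tomogram (grey-value units).
#' @param seed RNG seed making the phantom reproducible.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, spacing = c(1, 1, 1), structures,
                         tomogram_noise_sd = 2, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("grid_shape must be three integers >= 4")
  if (length(structures) < 1L || length(structures) > 255L)
    stop("need between 1 and 255 structures")
  if (tomogram_noise_sd < 0) stop("tomogram_noise_sd must be >= 0")
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 structures = structures,
                 tomogram_noise_sd = tomogram_noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

rasterize_structure <- function(st, d) {
  shape <- match.arg(st$shape, c("sphere", "ellipsoid", "tube", "shell"))
  check_bounds <- function(lo, hi, axes = 1:3) {
    if (any(lo < 0) || any(hi > d[axes] - 1L))
      stop(sprintf("out of bounds: structure '%s' exceeds the grid", st$name))
  }
  s <- slice_coords <- 0:(d[1] - 1L)
  r <- 0:(d[2] - 1L); cc <- 0:(d[3] - 1L)
  S <- array(rep(s, times = d[2] * d[3]), dim = d)
  R <- array(rep(rep(r, each = d[1]), times = d[3]), dim = d)
  C <- array(rep(cc, each = d[1] * d[2]), dim = d)
  inside <- switch(shape,
    sphere = {
      ctr <- st$centre; rad <- st$radius
      check_bounds(ctr - rad, ctr + rad)
      (S - ctr[1])^2 + (R - ctr[2])^2 + (C - ctr[3])^2 <= rad^2
    },
    ellipsoid = {
      ctr <- st$centre; ax <- st$semiaxes
      check_bounds(ctr - ax, ctr + ax)
      ((S - ctr[1]) / ax[1])^2 + ((R - ctr[2]) / ax[2])^2 +
        ((C - ctr[3]) / ax[3])^2 <= 1
    },
    tube = {
      axis <- match.arg(st$axis, c("slice", "row", "col"))
      others <- setdiff(1:3, match(axis, c("slice", "row", "col")))
      ctr <- st$centre; rad <- st$radius
      check_bounds(ctr - rad, ctr + rad, axes = others)
      U <- list(S, R, C)[[others[1]]]
      V <- list(S, R, C)[[others[2]]]
      (U - ctr[1])^2 + (V - ctr[2])^2 <= rad^2
    },
    shell = {
      ctr <- st$centre
      check_bounds(ctr - st$outer_radius, ctr + st$outer_radius)
      d2 <- (S - ctr[1])^2 + (R - ctr[2])^2 + (C - ctr[3])^2
      d2 >= st$inner_radius^2 & d2 <= st$outer_radius^2
    })
  array(as.numeric(inside), dim = d)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# independent per-voxel overlap resolution used for the ground truth
brute_force_combined <- function(mask_vecs, values, policy) {
  nvox <- length(mask_vecs[[1]])
  n <- length(mask_vecs)
  out <- numeric(nvox)
  for (i in seq_len(nvox)) {
    js <- which(vapply(seq_len(n), function(k) mask_vecs[[k]][i] > 0,
                       logical(1)))
    if (length(js) == 0L) next
    if (policy == "error" && length(js) > 1L) return(NULL)
    k <- switch(policy, "last-wins" = js[length(js)], "first-wins" = js[1],
                "error" = js[1])
    out[i] <- values[k]
  }
  out
}

#' Generate a synthetic phantom with ground truth
#'
#' Rasterizes the structures of a [phantom_spec()], builds a synthetic
#' tomogram (background grey 20, per-structure base intensities evenly
#' spaced over \[80, 220\], additive Gaussian noise, painted in structure
#' order), and records a ground-truth manifest with per-structure
#' pre-overlap voxel counts and the combined label array under each
#' overlap policy, computed by an independent per-voxel loop.
#'
#' @param spec a [phantom_spec()].
#' @return list with `tomogram` ([volume_grid()]), `masks` (named list of
#'   binary grids) and `manifest`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  masks <- lapply(spec$structures, function(st)
    volume_grid(rasterize_structure(st, d), spacing = spec$spacing,
                value_kind = "unsigned-8-bit"))
  names(masks) <- vapply(spec$structures, `[[`, character(1), "name")
  if (anyDuplicated(names(masks))) stop("structure names must be unique")
  n <- length(masks)

  base <- if (n == 1L) 150 else round_half_up(seq(80, 220, length.out = n))
  tomo <- array(20, dim = d)
  for (k in seq_len(n)) tomo[masks[[k]]$data > 0] <- base[k]
  tomo <- with_seed(spec$seed,
                    tomo + stats::rnorm(length(tomo), 0, spec$tomogram_noise_sd))
  tomogram <- volume_grid(tomo, spacing = spec$spacing, value_kind = "real")

  values <- assign_voxel_values(n)
  mask_vecs <- lapply(masks, function(m) as.vector(m$data))
  combined <- lapply(c("last-wins", "first-wins", "error"), function(p) {
    v <- brute_force_combined(mask_vecs, values, p)
    if (is.null(v)) NULL else array(v, dim = d)
  })
  names(combined) <- c("last-wins", "first-wins", "error")

  manifest <- list(
    spec = spec,
    voxel_counts = vapply(masks, function(m) sum(m$data), numeric(1)),
    masks = masks,
    label_values = values,
    combined = combined,
    base_intensities = base,
    tablet_ods = NULL)
  list(tomogram = tomogram, masks = masks, manifest = manifest)
}

#' Export phantom masks in a vendor-style DICOM layout
#'
#' `"multi-dir"` writes one DICOM series per structure with binary 0/255
#' slices (Mimics/Avizo mask-export style, optionally zipped);
#' `"single-dir"` writes one combined label-valued series (VG Studio
#' style), collapsing overlaps last-wins with the standard voxel-value
#' scheme. The returned layout feeds [read_export()] directly.
#'
#' @param masks named list of binary `volume_grid` masks.
#' @param style `"multi-dir"` or `"single-dir"`.
#' @param out_root output directory.
#' @param zip zip each series directory (store-only archives)?
#' @return an [export_layout()].
#' @export
export_vendor_style <- function(masks, style = c("multi-dir", "single-dir"),
                                out_root, zip = FALSE) {
  style <- match.arg(style)
  if (length(masks) < 1L) stop("need at least one mask")
  nm <- names(masks)
  if (!dir.exists(out_root) && !dir.create(out_root, recursive = TRUE))
    stop(sprintf("cannot create directory '%s'", out_root))
  if (style == "multi-dir") {
    dirs <- character(length(masks))
    for (k in seq_along(masks)) {
      m <- masks[[k]]
      vol <- volume_grid(m$data * 255, spacing = m$spacing, origin = m$origin,
                         orientation = m$orientation,
                         value_kind = "unsigned-8-bit")
      dd <- file.path(out_root, nm[k])
      write_dicom_series(vol, dd)
      if (zip) {
        zp <- paste0(dd, ".zip")
        zip_store(zp, list.files(dd, full.names = TRUE))
        unlink(dd, recursive = TRUE)
        dirs[k] <- zp
      } else dirs[k] <- dd
    }
    return(export_layout("multi-directory", dirs, structure_names = nm))
  }
  ref <- masks[[1]]
  values <- assign_voxel_values(length(masks))
  out <- array(0, dim = dim(ref$data))
  for (k in seq_along(masks)) out[masks[[k]]$data > 0] <- values[k]
  vol <- volume_grid(out, spacing = ref$spacing, origin = ref$origin,
                     orientation = ref$orientation,
                     value_kind = "unsigned-8-bit")
  dd <- file.path(out_root, "combined")
  write_dicom_series(vol, dd)
  present <- values[vapply(values, function(v) any(out == v), logical(1))]
  keep <- match(present, values)
  export_layout("single-directory", dd, structure_names = nm[keep])
}

#' Generate a synthetic optical-density step tablet
#'
#' Emulates a calibrated film step tablet: `n_steps` equal-width vertical
#' bands whose optical densities are linearly spaced from `od_min` to
#' `od_max`. Band brightness follows the transmittance model
#' `grey = 255 * 10^-(OD - od_min)` (the lightest step is normalized to
#' 255), so brightness decreases as density increases. The exact band
#' mean greys are returned as the calibration knots alongside the
#' quantized 8-bit image; an 8-bit rendering cannot resolve the darkest
#' bands of the default tablet, which is why densitometric calibration is
#' fit from band means rather than from quantized pixels.
#'
#' @param n_steps number of steps (>= 2); default 21.
#' @param od_min,od_max density range; defaults 0.05 and 3.05.
#' @param geometry list with `band_width` and `height` in pixels.
#' @return list with `image` (a [grey_image()]), `ods` (ground-truth OD
#'   per band) and `greys` (exact band mean grey per band).
#' @export
generate_step_tablet <- function(n_steps = 21L, od_min = 0.05, od_max = 3.05,
                                 geometry = list(band_width = 16L,
                                                 height = 48L)) {
  n_steps <- as.integer(n_steps)
  if (n_steps < 2L) stop("n_steps must be >= 2")
  if (!(od_min < od_max)) stop("od_min must be smaller than od_max")
  ods <- seq(od_min, od_max, length.out = n_steps)
  greys <- 255 * 10^(-(ods - od_min))
  gaps <- abs(diff(greys))
  if (any(gaps < 1e-9)) {
    i <- which(gaps < 1e-9)[1]
    stop(sprintf("unresolvable steps: bands %d and %d share grey value %.9g",
                 i, i + 1L, greys[i]))
  }
  bw <- as.integer(geometry$band_width); h <- as.integer(geometry$height)
  img <- matrix(0L, h, n_steps * bw)
  for (k in seq_len(n_steps))
    img[, ((k - 1L) * bw + 1L):(k * bw)] <- clamp(round_half_up(greys[k]), 0, 255)
  list(image = grey_image(img), ods = ods, greys = greys, band_width = bw)
}

# --- store-only zip writer -------------------------------------------------
# (archives readable by any unzip; compression is deliberately absent)

# 32-bit XOR on doubles (R integers overflow at 2^31)
xor32 <- function(a, b) {
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
    bitwXor(as.integer(al), as.integer(bl))
}

crc32_table <- local({
  tab <- numeric(256)
  for (i in 0:255) {
    c <- i
    for (j in 1:8) {
      odd <- c %% 2 == 1
      c <- c %/% 2
      if (odd) c <- xor32(c, 3988292384)
    }
    tab[i + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  v <- as.integer(bytes)
  crc <- 4294967295
  for (b in v)
    crc <- xor32(crc %/% 256, crc32_table[(xor32(crc, b) %% 256) + 1])
  xor32(crc, 4294967295)
}

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
u32le <- function(x) {
  c(u16le(x %% 65536), u16le(x %/% 65536))
}

zip_store <- function(zip_path, files) {
  entries <- list()
  offset <- 0
  body <- raw(0)
  for (f in files) {
    data <- readBin(f, "raw", file.info(f)$size)
    name <- charToRaw(basename(f))
    crc <- crc32(data)
    local_hdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), u16le(20), u16le(0),
                   u16le(0), u16le(0), u16le(0x21), u32le(crc),
                   u32le(length(data)), u32le(length(data)),
                   u16le(length(name)), u16le(0), name)
    entries[[length(entries) + 1]] <- list(name = name, crc = crc,
                                           size = length(data),
                                           offset = offset)
    body <- c(body, local_hdr, data)
    offset <- offset + length(local_hdr) + length(data)
  }
  central <- raw(0)
  for (e in entries) {
    central <- c(central,
                 as.raw(c(0x50, 0x4b, 0x01, 0x02)), u16le(20), u16le(20),
                 u16le(0), u16le(0), u16le(0), u16le(0x21), u32le(e$crc),
                 u32le(e$size), u32le(e$size), u16le(length(e$name)),
                 u16le(0), u16le(0), u16le(0), u16le(0), u32le(0),
                 u32le(e$offset), e$name)
  }
  end <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), u16le(0), u16le(0),
           u16le(length(entries)), u16le(length(entries)),
           u32le(length(central)), u32le(length(body)), u16le(0))
  con <- file(zip_path, "wb"); on.exit(close(con))
  writeBin(c(body, central, end), con)
  invisible(zip_path)
}
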