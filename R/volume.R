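#' 3D scalar volume with physical geometry
#'
#' `volume_grid` is the universal voxel container of the package: a 3D array
#' indexed `(slice, row, col)` (zero-based in all physical-coordinate
#' formulas) together with voxel spacing, origin and a direction-cosine
#' matrix. The physical position of the centre of voxel `(s, r, c)` is
#' `origin + orientation %*% (spacing * c(s, r, c))`.
#'
#' @param data 3D numeric array indexed `(slice, row, col)`.
#' @param spacing numeric length-3, voxel spacing in millimetres for the
#'   `(slice, row, col)` axes. All components must be positive.
#' @param origin numeric length-3, physical position (mm) of the centre of
#'   voxel `(0, 0, 0)`.
#' @param orientation 3x3 direction-cosine matrix; column `j` is the unit
#'   vector along index axis `j` in physical space. Columns must be unit
#'   length and pairwise orthogonal (tolerance `1e-6`).
#' @param value_kind one of `"unsigned-8-bit"`, `"unsigned-16-bit"`,
#'   `"signed-16-bit"`, `"real"`.
#'
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data,
                        spacing = c(1, 1, 1),
                        origin = c(0, 0, 0),
                        orientation = diag(3),
                        value_kind = "real") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed (slice, row, col)")
  if (any(dim(data) < 1L)) stop("data extents must be >= 1 along every axis")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values")
  orientation <- matrix(as.numeric(orientation), 3L, 3L)
  gram <- crossprod(orientation)
  if (max(abs(gram - diag(3))) > 1e-6)
    stop("orientation columns must be unit length and pairwise orthogonal")
  value_kind <- match.arg(value_kind, c("unsigned-8-bit", "unsigned-16-bit",
                                        "signed-16-bit", "real"))
  storage.mode(data) <- "double"
  check_value_kind(data, value_kind)
  structure(list(data = data, spacing = spacing, origin = origin,
                 orientation = orientation, value_kind = value_kind),
            class = "volume_grid")
}

value_kind_range <- function(kind) {
  switch(kind,
         "unsigned-8-bit"  = c(0, 255),
         "unsigned-16-bit" = c(0, 65535),
         "signed-16-bit"   = c(-32768, 32767),
         "real"            = c(-Inf, Inf))
}

check_value_kind <- function(data, kind) {
  if (kind == "real") return(invisible(TRUE))
  rng <- value_kind_range(kind)
  v <- range(data)
  if (v[1] < rng[1] || v[2] > rng[2] || any(data != round(data)))
    stop(sprintf("data incompatible with value kind '%s'", kind))
  invisible(TRUE)
}

is_integer_kind <- function(kind) kind != "real"

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_grid: %d x %d x %d (slice x row x col), %s\n",
              d[1], d[2], d[3], x$value_kind))
  cat(sprintf("  spacing (mm): %s\n", paste(signif(x$spacing, 6), collapse = " x ")))
  cat(sprintf("  origin (mm):  %s\n", paste(signif(x$origin, 6), collapse = ", ")))
  cat(sprintf("  value range:  [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

# physical position of zero-based voxel indices; idx is n x 3 (slice,row,col)
grid_index_to_phys <- function(vol, idx) {
  idx <- matrix(idx, ncol = 3L)
  sweep(idx %*% diag(vol$spacing) %*% t(vol$orientation), 2L, vol$origin, "+")
}

# inverse map: physical points (n x 3) to continuous zero-based indices
grid_phys_to_index <- function(vol, pts) {
  pts <- matrix(pts, ncol = 3L)
  rel <- sweep(pts, 2L, vol$origin, "-") %*% vol$orientation
  sweep(rel, 2L, vol$spacing, "/")
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$orientation - b$orientation)) <= tol
}

# rounding used everywhere a real becomes an integer grey/voxel value:
# half-away-from-zero, unlike base round()'s round-half-even
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
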