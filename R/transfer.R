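# Transfer functions map voxel attributes to optical properties: 1D from
# voxel value alone (piecewise-linear colour/opacity ramp), 2D from
# (voxel value, gradient magnitude) rectangles, letting surfaces (high
# gradient) be styled apart from homogeneous interiors.

#' 1D transfer function
#'
#' Piecewise-linear interpolation of RGBA between control points along the
#' voxel-value axis; evaluation clamps outside the covered range.
#'
#' @param values strictly increasing voxel values in \[0, 255\] (at least
#'   two).
#' @param rgba n x 4 matrix of RGBA colours in \[0, 1\].
#' @return a `transfer_function_1d`.
#' @export
transfer_function_1d <- function(values, rgba) {
  values <- as.numeric(values)
  rgba <- matrix(as.numeric(rgba), ncol = 4L)
  if (length(values) < 2L) stop("need at least two control points")
  if (nrow(rgba) != length(values)) stop("one RGBA row per control point")
  if (any(diff(values) <= 0)) stop("control-point values must be strictly increasing")
  if (any(values < 0 | values > 255)) stop("control-point values must lie in [0, 255]")
  if (any(rgba < 0 | rgba > 1)) stop("RGBA components must lie in [0, 1]")
  points <- data.frame(value = values, red = rgba[, 1], green = rgba[, 2],
                       blue = rgba[, 3], alpha = rgba[, 4])
  structure(list(points = points), class = "transfer_function_1d")
}

#' Rectangular region of a 2D transfer function
#'
#' @param value_interval `c(lo, hi)` within \[0, 255\].
#' @param gradient_interval `c(lo, hi)` with `lo >= 0`.
#' @param colour RGBA in \[0, 1\].
#' @param opacity_falloff `"flat"` (constant opacity inside) or
#'   `"linear-edge"` (opacity scaled by the fractional distance to the
#'   nearest region edge, peaking at the centre).
#' @return a region description for [transfer_function_2d()].
#' @export
tf2d_region <- function(value_interval, gradient_interval, colour,
                        opacity_falloff = c("flat", "linear-edge")) {
  opacity_falloff <- match.arg(opacity_falloff)
  value_interval <- as.numeric(value_interval)
  gradient_interval <- as.numeric(gradient_interval)
  colour <- as.numeric(colour)
  if (length(value_interval) != 2L || diff(value_interval) <= 0)
    stop("value_interval must be a non-empty [lo, hi]")
  if (length(gradient_interval) != 2L || diff(gradient_interval) <= 0 ||
      gradient_interval[1] < 0)
    stop("gradient_interval must be a non-empty [lo, hi] with lo >= 0")
  if (length(colour) != 4L || any(colour < 0 | colour > 1))
    stop("colour must be RGBA in [0, 1]")
  list(value_interval = value_interval, gradient_interval = gradient_interval,
       colour = colour, opacity_falloff = opacity_falloff)
}

#' 2D transfer function over (voxel value, gradient magnitude)
#'
#' Later regions override earlier ones where they overlap; points covered
#' by no region are fully transparent.
#'
#' @param regions list of [tf2d_region()] descriptions.
#' @return a `transfer_function_2d`.
#' @export
transfer_function_2d <- function(regions) {
  if (length(regions) < 1L) stop("need at least one region")
  structure(list(regions = regions), class = "transfer_function_2d")
}

#' Evaluate a transfer function
#'
#' Vectorized over `value` (and `gradient` for the 2D case).
#'
#' @param tf a [transfer_function_1d()] or [transfer_function_2d()].
#' @param value voxel values in \[0, 255\].
#' @param gradient gradient magnitudes (2D transfer functions only).
#' @return n x 4 RGBA matrix.
#' @export
evaluate_tf <- function(tf, value, gradient = NULL) {
  UseMethod("evaluate_tf")
}

#' @export
evaluate_tf.transfer_function_1d <- function(tf, value, gradient = NULL) {
  p <- tf$points
  out <- matrix(0, length(value), 4L,
                dimnames = list(NULL, c("red", "green", "blue", "alpha")))
  for (j in 1:4)
    out[, j] <- stats::approx(p$value, p[[j + 1L]], xout = value,
                              rule = 2, ties = "ordered")$y
  out
}

#' @export
evaluate_tf.transfer_function_2d <- function(tf, value, gradient = NULL) {
  if (is.null(gradient)) stop("a 2D transfer function needs gradient magnitudes")
  if (length(gradient) != length(value))
    stop("value and gradient lengths differ")
  out <- matrix(0, length(value), 4L,
                dimnames = list(NULL, c("red", "green", "blue", "alpha")))
  for (rg in tf$regions) {
    vi <- rg$value_interval; gi <- rg$gradient_interval
    inside <- value >= vi[1] & value <= vi[2] &
      gradient >= gi[1] & gradient <= gi[2]
    if (!any(inside)) next
    a <- rg$colour[4]
    if (rg$opacity_falloff == "linear-edge") {
      fv <- 1 - abs(value[inside] - mean(vi)) / (diff(vi) / 2)
      fg <- 1 - abs(gradient[inside] - mean(gi)) / (diff(gi) / 2)
      a <- a * pmin(fv, fg)
    }
    out[inside, 1] <- rg$colour[1]
    out[inside, 2] <- rg$colour[2]
    out[inside, 3] <- rg$colour[3]
    out[inside, 4] <- a
  }
  out
}
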