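# Image-analysis battery used to compare a revisualized rendering against
# the source platform's rendering: greyscale conversion, grey-value
# histogram, surface-plot heightfield, Sobel edges, optical-density
# calibration against a step tablet, and image-pair correlation.

#' Read a PNG or TIFF image
#'
#' @param path image path; format chosen by extension.
#' @return numeric array in \[0, 1\] (HxW or HxWxC).
#' @export
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    img <- tiff::readTIFF(path)
    img
  } else stop("unsupported image format (use PNG or TIFF)")
}

as_grey_matrix <- function(img) {
  if (is.matrix(img)) return(img)
  stop("expected a single-channel greyscale image")
}

#' Convert an RGB image to 8-bit greyscale
#'
#' Uses the unweighted channel mean `round((R + G + B) / 3)` — the
#' historical default of common desktop image-analysis tools — or CIE
#' luminance weights when `weights = "luminance"`.
#'
#' @param img HxWx3 RGB array, either 8-bit integers in \[0, 255\] or
#'   reals in \[0, 1\] (as returned by [read_image()]).
#' @param weights `"mean"` (default) or `"luminance"`
#'   (0.299, 0.587, 0.114).
#' @return integer matrix of grey values in \[0, 255\] (a `grey_image`).
#' @export
rgb_to_grey8 <- function(img, weights = c("mean", "luminance")) {
  weights <- match.arg(weights)
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("input must be an RGB image with 3 channels")
  img <- img[, , 1:3, drop = FALSE]
  if (max(img) <= 1 && !all(img == round(img))) img <- img * 255
  w <- if (weights == "mean") c(1, 1, 1) / 3 else c(0.299, 0.587, 0.114)
  grey <- img[, , 1] * w[1] + img[, , 2] * w[2] + img[, , 3] * w[3]
  grey_image(round_half_up(clamp(grey, 0, 255)))
}

#' 8-bit greyscale image container
#'
#' @param pixels matrix of integers in \[0, 255\].
#' @return a `grey_image` (integer matrix with class attribute).
#' @export
grey_image <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (any(pixels < 0 | pixels > 255 | pixels != round(pixels)))
    stop("grey values must be integers in [0, 255]")
  structure(pixels, class = c("grey_image", class(matrix())))
}

#' Grey-value histogram
#'
#' @param img a [grey_image()] (or plain matrix of values in \[0, 255\]).
#' @return integer vector of 256 counts (index `v + 1` holds the count of
#'   grey value `v`); counts sum to the pixel count.
#' @export
grey_histogram <- function(img) {
  tabulate(as.vector(img) + 1L, nbins = 256L)
}

#' Surface-plot heightfield
#'
#' Block-mean downsampled intensity field: the height over each
#' `downsample` x `downsample` block is the mean grey value of its pixels
#' (edge blocks average whatever pixels remain). `downsample = 1` is the
#' identity.
#'
#' @param img a [grey_image()].
#' @param downsample integer block size >= 1.
#' @return numeric matrix of block means.
#' @export
surface_plot_data <- function(img, downsample = 1L) {
  downsample <- as.integer(downsample)
  if (downsample < 1L) stop("downsample must be >= 1")
  m <- unclass(img)
  if (downsample == 1L) return(m + 0)
  ri <- (seq_len(nrow(m)) - 1L) %/% downsample
  ci <- (seq_len(ncol(m)) - 1L) %/% downsample
  sums <- rowsum(m, ri)
  sums <- t(rowsum(t(sums), ci))
  cnt <- outer(tabulate(ri + 1L), tabulate(ci + 1L))
  unname(sums / cnt)
}

#' Sobel edge detection
#'
#' Standard 3x3 Sobel kernels with edge-replication padding; the edge
#' image is `sqrt(gx^2 + gy^2)` rounded and clamped to \[0, 255\].
#'
#' @param img a [grey_image()], at least 3x3.
#' @return a `grey_image` of edge magnitudes.
#' @export
sobel_edges <- function(img) {
  m <- unclass(img) + 0
  if (nrow(m) < 3L || ncol(m) < 3L) stop("image must be at least 3x3")
  nr <- nrow(m); nc <- ncol(m)
  pad <- rbind(m[1, , drop = FALSE], m, m[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  sh <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  # gx: horizontal (column-direction) derivative; gy: vertical
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  grey_image(clamp(round_half_up(sqrt(gx^2 + gy^2)), 0, 255))
}

#' Fit a grey-value to optical-density calibration curve
#'
#' Monotone piecewise-linear interpolation through the step-tablet knots:
#' at every supplied step grey the curve returns the supplied OD exactly;
#' outside the covered grey range the OD is clamped to the end values.
#'
#' @param step_grey mean grey value of each tablet step.
#' @param step_od optical density of each step (strictly monotone).
#' @return a `calibration_curve`; evaluate with `predict(curve, grey)`.
#' @export
fit_calibration <- function(step_grey, step_od) {
  step_grey <- as.numeric(step_grey); step_od <- as.numeric(step_od)
  if (length(step_grey) != length(step_od) || length(step_od) < 2L)
    stop("need matching step_grey/step_od vectors of length >= 2")
  dod <- diff(step_od)
  if (!(all(dod > 0) || all(dod < 0)))
    stop("non-monotone calibration: step ODs must be strictly monotone")
  if (anyDuplicated(step_grey))
    stop("non-monotone calibration: duplicate step grey values")
  ord <- order(step_grey)
  structure(list(step_grey = step_grey[ord], step_od = step_od[ord],
                 interpolator_kind = "monotone-piecewise"),
            class = "calibration_curve")
}

#' @export
predict.calibration_curve <- function(object, grey, ...) {
  stats::approx(object$step_grey, object$step_od, xout = as.numeric(grey),
                rule = 2, ties = "ordered")$y
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: %d steps, OD [%g, %g], grey [%g, %g]\n",
              length(x$step_od), min(x$step_od), max(x$step_od),
              min(x$step_grey), max(x$step_grey)))
  invisible(x)
}

#' Median optical density of an image
#'
#' Maps every pixel through the calibration curve and takes the median
#' (for an even pixel count, the mean of the two middle values).
#'
#' @param img a [grey_image()].
#' @param cal a [fit_calibration()] curve.
#' @return median OD (scalar).
#' @export
median_od <- function(img, cal) {
  stopifnot(inherits(cal, "calibration_curve"))
  stats::median(predict(cal, as.vector(unclass(img))))
}

#' Pearson correlation and regression line between two images
#'
#' @param a,b [grey_image()]s of equal shape; `b`'s pixels are regressed
#'   on `a`'s.
#' @return list with `pearson_r`, `slope`, `intercept`.
#' @export
image_correlation <- function(a, b) {
  av <- as.vector(unclass(a)); bv <- as.vector(unclass(b))
  if (length(av) != length(bv) || !identical(dim(a), dim(b)))
    stop("images must have equal shapes")
  va <- stats::var(av); vb <- stats::var(bv)
  if (va == 0 || vb == 0)
    stop("degenerate correlation: an image has zero variance")
  r <- stats::cor(av, bv)
  slope <- stats::cov(av, bv) / va
  list(pearson_r = r, slope = slope, intercept = mean(bv) - slope * mean(av))
}
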