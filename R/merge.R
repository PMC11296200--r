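# Collapse per-structure masks into one labelled volume: the
# interoperability step that lets a segmentation travel between
# visualization platforms as a single 8-bit dataset.

# qualitative 12-colour palette (Set3-like), cycled for label defaults
LABEL_PALETTE <- matrix(c(
  0.55, 0.83, 0.78,   1.00, 1.00, 0.70,   0.75, 0.73, 0.85,
  0.98, 0.50, 0.45,   0.50, 0.69, 0.83,   0.99, 0.71, 0.38,
  0.70, 0.87, 0.41,   0.99, 0.80, 0.90,   0.85, 0.85, 0.85,
  0.74, 0.50, 0.74,   0.80, 0.92, 0.77,   1.00, 0.93, 0.44
), ncol = 3, byrow = TRUE)

default_label_colour <- function(k) {
  c(LABEL_PALETTE[(k - 1L) %% nrow(LABEL_PALETTE) + 1L, ], 1)
}

#' Threshold a volume into a binary mask
#'
#' @param vol a [volume_grid()].
#' @param threshold finite scalar; voxels strictly above it become 1.
#' @return unsigned 8-bit `volume_grid` with values \{0, 1\}.
#' @export
binarize <- function(vol, threshold = 0) {
  stopifnot(inherits(vol, "volume_grid"), is.finite(threshold))
  volume_grid(array(as.numeric(vol$data > threshold), dim = dim(vol$data)),
              spacing = vol$spacing, origin = vol$origin,
              orientation = vol$orientation, value_kind = "unsigned-8-bit")
}

#' Voxel values assigned to merged structures
#'
#' Each segmented structure receives a distinct 8-bit voxel value, evenly
#' spaced over \[1, 255\] so that structures stay separable in the
#' transfer-function domain: `value_k = round(k * 255 / n)`.
#'
#' @param n number of structures, `1 <= n <= 255`.
#' @return strictly increasing integer vector of length `n`.
#' @export
assign_voxel_values <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (n > 255L) stop("too many structures: at most 255 fit in 8 bits")
  as.integer(round_half_up(seq_len(n) * 255 / n))
}

#' Nearest-neighbour resampling onto a reference grid
#'
#' Every output voxel takes the value of the input voxel whose centre is
#' nearest in physical space (labels and masks must never be
#' interpolated). When the two geometries already match the input is
#' returned unchanged.
#'
#' @param vol volume to resample.
#' @param reference volume supplying the output shape, spacing, origin and
#'   orientation.
#' @return `volume_grid` on the reference geometry.
#' @export
resample_nearest <- function(vol, reference) {
  stopifnot(inherits(vol, "volume_grid"), inherits(reference, "volume_grid"))
  if (same_geometry(vol, reference, tol = 0)) return(vol)
  dr <- dim(reference$data); dv <- dim(vol$data)
  idx <- as.matrix(expand.grid(s = 0:(dr[1] - 1L), r = 0:(dr[2] - 1L),
                               c = 0:(dr[3] - 1L)))
  phys <- grid_index_to_phys(reference, idx)
  q <- grid_phys_to_index(vol, phys)
  # orthonormal orientation: nearest centre = per-axis round-and-clamp
  qi <- round_half_up(q)
  for (a in 1:3) qi[, a] <- clamp(qi[, a], 0, dv[a] - 1L)
  lin <- qi[, 1] + dv[1] * (qi[, 2] + dv[2] * qi[, 3]) + 1L
  out <- array(0, dim = dr)
  out[idx[, 1] + dr[1] * (idx[, 2] + dr[2] * idx[, 3]) + 1L] <- vol$data[lin]
  volume_grid(out, spacing = reference$spacing, origin = reference$origin,
              orientation = reference$orientation, value_kind = vol$value_kind)
}

#' Merge binary masks into a labelled volume
#'
#' Structure `k` (in list order) is painted with voxel value
#' `assign_voxel_values(n)[k]`. Voxels claimed by several structures are
#' resolved by `policy`: `"last-wins"` (default; the later-listed
#' structure overwrites, matching typical mask-export semantics),
#' `"first-wins"`, or `"error"`.
#'
#' @param masks named list of binary `volume_grid` masks sharing one
#'   geometry (use [resample_nearest()] first if they do not), or a list
#'   of `list(name=, vol=)` pairs.
#' @param policy overlap policy.
#' @param colours optional n x 4 RGBA matrix in \[0,1\] overriding the
#'   default qualitative palette.
#' @param values optional integer vector overriding the evenly spaced
#'   voxel-value scheme (distinct, in \[1, 255\]).
#' @return a `label_map`: list with `grid` (unsigned 8-bit
#'   [volume_grid()]) and `table` (data frame of label_id, name,
#'   voxel_value, RGBA colour, source, voxel_count).
#' @export
merge_masks <- function(masks, policy = c("last-wins", "first-wins", "error"),
                        colours = NULL, values = NULL) {
  policy <- match.arg(policy)
  if (length(masks) < 1L) stop("need at least one mask")
  nm <- names(masks)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("masks must be a named list")
  n <- length(masks)
  ref <- masks[[1]]
  for (m in masks) {
    stopifnot(inherits(m, "volume_grid"))
    if (!same_geometry(m, ref))
      stop("masks do not share one geometry; resample_nearest() them first")
    if (any(!m$data %in% c(0, 1)))
      stop("masks must be binary {0,1}; binarize() them first")
  }
  if (is.null(values)) values <- assign_voxel_values(n)
  values <- as.integer(values)
  if (length(values) != n || anyDuplicated(values) ||
      any(values < 1L | values > 255L))
    stop("values must be n distinct integers in [1, 255]")

  d <- dim(ref$data)
  out <- array(0L, dim = d)
  if (policy == "error") {
    claimed <- array(0L, dim = d)
    for (k in seq_len(n)) {
      inside <- masks[[k]]$data > 0
      both <- inside & claimed > 0
      if (any(both)) {
        i <- which(both)[1]
        sub <- arrayInd(i, d) - 1L
        stop(sprintf(
          "overlap at voxel (%d, %d, %d) between structures '%s' and '%s'",
          sub[1], sub[2], sub[3], nm[claimed[i]], nm[k]))
      }
      claimed[inside] <- k
      out[inside] <- values[k]
    }
  } else if (policy == "last-wins") {
    for (k in seq_len(n)) out[masks[[k]]$data > 0] <- values[k]
  } else {
    for (k in seq_len(n)) {
      take <- masks[[k]]$data > 0 & out == 0L
      out[take] <- values[k]
    }
  }

  if (is.null(colours))
    colours <- t(vapply(seq_len(n), default_label_colour, numeric(4)))
  colours <- matrix(colours, ncol = 4L)
  counts <- vapply(values, function(v) sum(out == v), numeric(1))
  table <- data.frame(
    label_id = seq_len(n), name = nm, voxel_value = values,
    red = colours[, 1], green = colours[, 2], blue = colours[, 3],
    alpha = colours[, 4],
    source = nm, voxel_count = as.integer(counts),
    stringsAsFactors = FALSE)
  grid <- volume_grid(array(as.numeric(out), dim = d),
                      spacing = ref$spacing, origin = ref$origin,
                      orientation = ref$orientation,
                      value_kind = "unsigned-8-bit")
  new_label_map(grid, table)
}

new_label_map <- function(grid, table) {
  stopifnot(inherits(grid, "volume_grid"),
            grid$value_kind == "unsigned-8-bit")
  present <- unique(as.vector(grid$data))
  present <- present[present != 0]
  if (!all(present %in% table$voxel_value))
    stop("label map grid contains voxel values missing from the table")
  if (anyDuplicated(table$voxel_value))
    stop("label table voxel_values must be unique")
  structure(list(grid = grid, table = table), class = "label_map")
}

#' Construct a label map from a labelled grid and a table
#'
#' @param grid unsigned 8-bit [volume_grid()] whose non-zero values are
#'   label voxel values (0 is background).
#' @param table data frame with at least `label_id`, `name`,
#'   `voxel_value`; missing colour columns get palette defaults and
#'   missing `voxel_count` is computed from the grid.
#' @return a `label_map`.
#' @export
label_map <- function(grid, table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  n <- nrow(table)
  if (is.null(table$red)) {
    cols <- t(vapply(seq_len(n), default_label_colour, numeric(4)))
    table$red <- cols[, 1]; table$green <- cols[, 2]
    table$blue <- cols[, 3]; table$alpha <- cols[, 4]
  }
  if (is.null(table$source)) table$source <- table$name
  if (is.null(table$voxel_count))
    table$voxel_count <- vapply(table$voxel_value,
                                function(v) sum(grid$data == v), numeric(1))
  new_label_map(grid, table)
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$grid$data)
  cat(sprintf("label_map: %d structure(s) on a %d x %d x %d grid\n",
              nrow(x$table), d[1], d[2], d[3]))
  print(x$table[, c("label_id", "name", "voxel_value", "voxel_count")],
        row.names = FALSE)
  invisible(x)
}

#' Register a label map with the original tomogram for overlay rendering
#'
#' Returns the pair on one common grid (the label map's), resampling the
#' tomogram by nearest neighbour when its geometry differs. No voxel
#' values are altered on the label side.
#'
#' @param labels a `label_map`.
#' @param original the original tomogram `volume_grid`.
#' @return list with elements `original` and `labels`, co-registered.
#' @export
overlay_with_original <- function(labels, original) {
  stopifnot(inherits(labels, "label_map"), inherits(original, "volume_grid"))
  original <- resample_nearest(original, labels$grid)
  if (!same_geometry(original, labels$grid))
    stop("internal error: geometries still differ after resampling")
  list(original = original, labels = labels)
}
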