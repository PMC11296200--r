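# Interchange formats: RAW (+ JSON sidecar), lossless 8-bit greyscale
# image stacks, ITK MetaImage (.mhd/.raw), the package's open processed
# volume container (MetaImage payload + JSON label table + provenance),
# and the XML scene file.
#
# The processed volume container is an open analogue of the internal
# format of GUI volume-exploration tools; it is NOT bit-compatible with
# any vendor's internal format.

kind_to_bytes <- function(kind) {
  switch(kind, "unsigned-8-bit" = 1L, "unsigned-16-bit" = 2L,
         "signed-16-bit" = 2L, "real" = 8L)
}

# serialize (slice,row,col) arrays in C order: col fastest, slice slowest
vol_serialize_order <- function(data) as.vector(aperm(data, c(3, 2, 1)))
vol_deserialize_order <- function(vec, d) {
  aperm(array(vec, dim = c(d[3], d[2], d[1])), c(3, 2, 1))
}

write_payload <- function(con, data, kind) {
  v <- vol_serialize_order(data)
  switch(kind,
    "unsigned-8-bit" = writeBin(as.raw(v), con),
    "unsigned-16-bit" = ,
    "signed-16-bit" = writeBin(as.integer(v), con, size = 2L, endian = "little"),
    "real" = writeBin(as.double(v), con, size = 8L, endian = "little"))
}

read_payload <- function(bytes, d, kind) {
  n <- prod(d)
  v <- switch(kind,
    "unsigned-8-bit" = as.integer(bytes),
    "unsigned-16-bit" = readBin(bytes, "integer", n = n, size = 2L,
                                signed = FALSE, endian = "little"),
    "signed-16-bit" = readBin(bytes, "integer", n = n, size = 2L,
                              signed = TRUE, endian = "little"),
    "real" = readBin(bytes, "double", n = n, size = 8L, endian = "little"))
  vol_deserialize_order(as.numeric(v), d)
}

#' Export a volume as headerless RAW with a JSON sidecar
#'
#' Little-endian, slice-major order (slice slowest, column fastest). A
#' JSON sidecar at `<path>.json` records shape, value kind and geometry;
#' [read_raw()] uses it when `shape`/`value_kind` are not supplied.
#'
#' @param vol a [volume_grid()].
#' @param path output file.
#' @return the sidecar path, invisibly.
#' @export
write_raw <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  con <- file(path, "wb"); on.exit(close(con))
  write_payload(con, vol$data, vol$value_kind)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(shape = dim(vol$data), value_kind = vol$value_kind,
         spacing = vol$spacing, origin = vol$origin,
         byte_order = "little-endian"),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @rdname write_raw
#' @param shape integer length-3 `(slices, rows, cols)`; taken from the
#'   sidecar when `NULL`.
#' @param value_kind value kind of the payload; taken from the sidecar
#'   when `NULL`.
#' @export
read_raw <- function(path, shape = NULL, value_kind = NULL) {
  sidecar <- paste0(path, ".json")
  spacing <- c(1, 1, 1); origin <- c(0, 0, 0)
  if ((is.null(shape) || is.null(value_kind)) && !file.exists(sidecar))
    stop("shape/value_kind not given and no sidecar found")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(shape)) shape <- meta$shape
    if (is.null(value_kind)) value_kind <- meta$value_kind
    if (!is.null(meta$spacing)) spacing <- meta$spacing
    if (!is.null(meta$origin)) origin <- meta$origin
  }
  shape <- as.integer(shape)
  bytes <- readBin(path, "raw", file.info(path)$size)
  expected <- prod(shape) * kind_to_bytes(value_kind)
  if (length(bytes) != expected)
    stop(sprintf("size mismatch: file has %d bytes, shape %s as %s needs %d",
                 length(bytes), paste(shape, collapse = "x"), value_kind,
                 expected))
  volume_grid(read_payload(bytes, shape, value_kind),
              spacing = spacing, origin = origin, value_kind = value_kind)
}

coerce_to_8bit <- function(vol) {
  v <- vol$data
  if (vol$value_kind == "unsigned-8-bit") return(v)
  if (all(v == round(v)) && min(v) >= 0 && max(v) <= 255) return(v)
  rng <- range(v)
  message(sprintf("rescaling [%g, %g] to 8-bit for image-stack export",
                  rng[1], rng[2]))
  if (rng[2] == rng[1]) return(array(0, dim = dim(v)))
  round_half_up((v - rng[1]) / (rng[2] - rng[1]) * 255)
}

#' Export a volume as an 8-bit greyscale image stack
#'
#' One lossless greyscale PNG per slice, zero-padded numeric filenames
#' (`slice_00000.png`, ...) defining the order. Values already in
#' \[0, 255\] pass through; anything else is min-max rescaled (a constant
#' volume maps to all zeros). Round trip is an identity for 8-bit input.
#'
#' @param vol a [volume_grid()].
#' @param dir output directory (created if missing).
#' @return number of images written, invisibly.
#' @export
write_image_stack <- function(vol, dir) {
  stopifnot(inherits(vol, "volume_grid"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("cannot create directory '%s'", dir))
  data <- coerce_to_8bit(vol)
  d <- dim(data)
  for (s in seq_len(d[1]))
    png::writePNG(matrix(data[s, , ], d[2], d[3]) / 255,
                  file.path(dir, sprintf("slice_%05d.png", s - 1L)))
  jsonlite::write_json(
    list(spacing = vol$spacing, origin = vol$origin, n_slices = d[1]),
    file.path(dir, "stack.json"), auto_unbox = TRUE, digits = NA)
  invisible(d[1])
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("directory '%s' does not exist", dir))
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L)
    stop(sprintf("empty series: no images in '%s'", dir))
  slices <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    round_half_up(m * 255)
  })
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inhomogeneous stack: images disagree on size")
  spacing <- c(1, 1, 1); origin <- c(0, 0, 0)
  meta_path <- file.path(dir, "stack.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$spacing)) spacing <- meta$spacing
    if (!is.null(meta$origin)) origin <- meta$origin
  }
  data <- array(0, dim = c(length(slices), dims[1, 1], dims[2, 1]))
  for (s in seq_along(slices)) data[s, , ] <- slices[[s]]
  volume_grid(data, spacing = spacing, origin = origin,
              value_kind = "unsigned-8-bit")
}

MET_TYPES <- c("unsigned-8-bit" = "MET_UCHAR", "unsigned-16-bit" = "MET_USHORT",
               "signed-16-bit" = "MET_SHORT", "real" = "MET_DOUBLE")

# index axes (slice,row,col) map to ITK (z,y,x): reverse both orders
AXIS_REVERSAL <- matrix(c(0, 0, 1, 0, 1, 0, 1, 0, 0), 3, 3)

#' Export / import ITK MetaImage volumes
#'
#' Standard `.mhd` text header plus a raw payload file, interoperable with
#' ITK-based toolkits. Geometry (spacing, offset, direction matrix) is
#' preserved through the round trip.
#'
#' @param vol a [volume_grid()].
#' @param path path to the `.mhd` header; the payload goes to the same
#'   stem with extension `.raw`.
#' @return `path`, invisibly.
#' @export
write_metaimage <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  d <- dim(vol$data)
  raw_name <- paste0(sub("\\.mhd$", "", path), ".raw")
  tm <- AXIS_REVERSAL %*% vol$orientation %*% AXIS_REVERSAL
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =", fmt(t(tm))),
    paste("Offset =", fmt(rev(vol$origin))),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =", fmt(rev(vol$spacing))),
    paste("DimSize =", paste(rev(d), collapse = " ")),
    paste("ElementType =", MET_TYPES[[vol$value_kind]]),
    paste("ElementDataFile =", basename(raw_name)))
  writeLines(header, path)
  con <- file(raw_name, "wb"); on.exit(close(con))
  write_payload(con, vol$data, vol$value_kind)
  invisible(path)
}

#' @rdname write_metaimage
#' @export
read_metaimage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    parts <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(parts) != 3L)
      stop(sprintf("bad header: unparseable line '%s'", ln))
    kv[[parts[2]]] <- trimws(parts[3])
  }
  for (key in c("NDims", "DimSize", "ElementType", "ElementDataFile"))
    if (is.null(kv[[key]])) stop(sprintf("bad header: missing key '%s'", key))
  if (kv$NDims != "3") stop("bad header: only NDims = 3 is supported")
  nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  dsize <- as.integer(nums(kv$DimSize))
  if (length(dsize) != 3L) stop("bad header: DimSize must have 3 entries")
  d <- rev(dsize)  # (slice, row, col)
  met <- kv$ElementType
  kind <- names(MET_TYPES)[match(met, MET_TYPES)]
  if (met == "MET_FLOAT") kind <- "real"
  if (is.na(kind) || is.null(kind))
    stop(sprintf("bad header: unsupported ElementType '%s'", met))
  if (!is.null(kv$BinaryDataByteOrderMSB) &&
      tolower(kv$BinaryDataByteOrderMSB) == "true")
    stop("bad header: big-endian payloads are not supported")
  if (!is.null(kv$CompressedData) && tolower(kv$CompressedData) == "true")
    stop("bad header: compressed payloads are not supported")
  spacing <- if (!is.null(kv$ElementSpacing)) rev(nums(kv$ElementSpacing)) else c(1, 1, 1)
  origin <- if (!is.null(kv$Offset)) rev(nums(kv$Offset)) else c(0, 0, 0)
  orientation <- diag(3)
  if (!is.null(kv$TransformMatrix)) {
    tm <- matrix(nums(kv$TransformMatrix), 3, 3, byrow = TRUE)
    orientation <- AXIS_REVERSAL %*% tm %*% AXIS_REVERSAL
  }
  if (kv$ElementDataFile == "LOCAL")
    stop("bad header: LOCAL payloads are not supported; use a .raw file")
  raw_path <- file.path(dirname(path), kv$ElementDataFile)
  if (!file.exists(raw_path))
    stop(sprintf("bad header: payload file '%s' not found", kv$ElementDataFile))
  nbytes <- if (met == "MET_FLOAT") 4L else kind_to_bytes(kind)
  bytes <- readBin(raw_path, "raw", file.info(raw_path)$size)
  if (length(bytes) != prod(d) * nbytes)
    stop(sprintf("bad header: DimSize %s does not match payload of %d bytes",
                 kv$DimSize, length(bytes)))
  data <- if (met == "MET_FLOAT") {
    vol_deserialize_order(readBin(bytes, "double", n = prod(d), size = 4L,
                                  endian = "little"), d)
  } else read_payload(bytes, d, kind)
  volume_grid(data, spacing = spacing, origin = origin,
              orientation = orientation, value_kind = kind)
}

FORMAT_REGISTRY <- list(
  "raw" = function(vol, path) write_raw(vol, path),
  "image-stack" = function(vol, path) write_image_stack(vol, path),
  "metaimage" = function(vol, path) write_metaimage(vol, path))

#' Registered standard export formats
#'
#' @return character vector of the standard volume writers:
#'   `raw`, `image-stack`, `metaimage`.
#' @export
list_export_formats <- function() sort(names(FORMAT_REGISTRY))

#' Export a volume through a registered standard writer
#'
#' @param vol a [volume_grid()].
#' @param format one of [list_export_formats()].
#' @param path output path (a directory for `image-stack`).
#' @export
export_volume <- function(vol, format, path) {
  if (!format %in% names(FORMAT_REGISTRY))
    stop(sprintf("unknown format '%s'; available: %s", format,
                 paste(list_export_formats(), collapse = ", ")))
  FORMAT_REGISTRY[[format]](vol, path)
}

#' Save / load the processed labelled-volume container
#'
#' The container is a JSON manifest referencing a MetaImage payload next
#' to it, plus the label table, a provenance log and a payload checksum.
#' It is an open interchange container, not bit-compatible with any
#' vendor-internal processed format.
#'
#' @param pv a `processed_volume` (see [processed_volume()]) or a
#'   `label_map`.
#' @param path path of the JSON manifest (conventionally `*.pvl.json`).
#' @return `path`, invisibly.
#' @export
save_processed <- function(pv, path) {
  if (inherits(pv, "label_map"))
    pv <- processed_volume(pv$grid, pv$table, provenance = character(0))
  stopifnot(inherits(pv, "processed_volume"))
  stem <- sub("\\.json$", "", path)
  mhd <- paste0(stem, ".mhd")
  write_metaimage(pv$grid, mhd)
  raw_name <- paste0(stem, ".raw")
  manifest <- list(
    format_version = pv$format_version,
    metaimage = basename(mhd),
    payload_md5 = unname(tools::md5sum(raw_name)),
    table = pv$table,
    provenance = pv$provenance)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname save_processed
#' @export
load_processed <- function(path) {
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(manifest$table) || is.null(manifest$metaimage))
    stop("corrupt container: missing label-table or payload reference")
  mhd <- file.path(dirname(path), manifest$metaimage)
  if (!file.exists(mhd)) stop("corrupt container: payload header missing")
  raw_name <- paste0(sub("\\.mhd$", "", mhd), ".raw")
  if (!is.null(manifest$payload_md5)) {
    md5 <- unname(tools::md5sum(raw_name))
    if (!identical(md5, manifest$payload_md5))
      stop("corrupt container: payload checksum mismatch")
  }
  grid <- read_metaimage(mhd)
  table <- as.data.frame(manifest$table, stringsAsFactors = FALSE)
  processed_volume(grid, table,
                   provenance = as.character(manifest$provenance),
                   format_version = manifest$format_version)
}

#' Processed labelled-volume object
#'
#' @param grid a [volume_grid()].
#' @param table label table (possibly empty for a pure tomogram).
#' @param provenance character log of source directories and merge policy.
#' @param format_version container version string.
#' @return a `processed_volume`.
#' @export
processed_volume <- function(grid, table = data.frame(),
                             provenance = character(0),
                             format_version = "1.0") {
  stopifnot(inherits(grid, "volume_grid"))
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  structure(list(grid = grid, table = table,
                 provenance = as.character(provenance),
                 format_version = format_version),
            class = "processed_volume")
}

# --- XML scene file --------------------------------------------------------

fmt_nums <- function(x) paste(sprintf("%.17g", x), collapse = " ")
parse_nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])

#' Scene file: render settings plus transfer functions and volume paths
#'
#' @param scene a [scene_params()].
#' @param tf_1d optional [transfer_function_1d()].
#' @param tf_2d optional [transfer_function_2d()].
#' @param volume_paths character vector of volume file paths.
#' @return a `scene_file`.
#' @export
scene_file <- function(scene = scene_params(), tf_1d = NULL, tf_2d = NULL,
                       volume_paths = character(0)) {
  stopifnot(inherits(scene, "scene_params"))
  if (!is.null(tf_1d)) stopifnot(inherits(tf_1d, "transfer_function_1d"))
  if (!is.null(tf_2d)) stopifnot(inherits(tf_2d, "transfer_function_2d"))
  structure(list(scene = scene, tf_1d = tf_1d, tf_2d = tf_2d,
                 volume_paths = as.character(volume_paths),
                 extra_xml = character(0)),
            class = "scene_file")
}

#' Save / load a scene as XML
#'
#' The scene round-trips losslessly (geometry to full double precision);
#' unknown XML elements found under the root are preserved verbatim when
#' the file is rewritten.
#'
#' @param sf a [scene_file()].
#' @param path XML file path.
#' @return `path` invisibly / the loaded `scene_file`.
#' @export
save_scene <- function(sf, path) {
  stopifnot(inherits(sf, "scene_file"))
  sc <- sf$scene
  doc <- xml2::xml_new_root("scene", version = "1.0")
  xml2::xml_add_child(doc, "camera",
                      position = fmt_nums(sc$camera_position),
                      target = fmt_nums(sc$camera_target),
                      up = fmt_nums(sc$camera_up))
  xml2::xml_add_child(doc, "projection", type = sc$projection,
                      fov_degrees = fmt_nums(sc$fov_degrees))
  xml2::xml_add_child(doc, "lighting",
                      direction = fmt_nums(sc$light_direction),
                      ambient = fmt_nums(sc$ambient),
                      diffuse = fmt_nums(sc$diffuse),
                      specular = fmt_nums(sc$specular),
                      shininess = fmt_nums(sc$shininess))
  rnd <- xml2::xml_add_child(doc, "render",
                             background = fmt_nums(sc$background),
                             step_size_voxels = fmt_nums(sc$step_size_voxels),
                             opacity_termination = fmt_nums(sc$opacity_termination))
  if (!is.null(sc$view_width))
    xml2::xml_set_attr(rnd, "view_width", fmt_nums(sc$view_width))
  if (!is.null(sf$tf_1d)) {
    node <- xml2::xml_add_child(doc, "tf1d")
    for (i in seq_len(nrow(sf$tf_1d$points)))
      xml2::xml_add_child(node, "point",
                          value = fmt_nums(sf$tf_1d$points$value[i]),
                          rgba = fmt_nums(unlist(sf$tf_1d$points[i, c("red", "green", "blue", "alpha")])))
  }
  if (!is.null(sf$tf_2d)) {
    node <- xml2::xml_add_child(doc, "tf2d")
    for (rg in sf$tf_2d$regions)
      xml2::xml_add_child(node, "region",
                          value = fmt_nums(rg$value_interval),
                          gradient = fmt_nums(rg$gradient_interval),
                          rgba = fmt_nums(rg$colour),
                          falloff = rg$opacity_falloff)
  }
  vols <- xml2::xml_add_child(doc, "volumes")
  for (p in sf$volume_paths) xml2::xml_add_child(vols, "volume", path = p)
  for (chunk in sf$extra_xml)
    xml2::xml_add_child(doc, xml2::read_xml(chunk))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname save_scene
#' @export
load_scene <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop(sprintf("scene XML parse error: %s", conditionMessage(e))))
  attr_num <- function(node, name) parse_nums(xml2::xml_attr(node, name))
  cam <- xml2::xml_find_first(doc, "./camera")
  proj <- xml2::xml_find_first(doc, "./projection")
  lig <- xml2::xml_find_first(doc, "./lighting")
  rnd <- xml2::xml_find_first(doc, "./render")
  view_width <- xml2::xml_attr(rnd, "view_width")
  sc <- scene_params(
    camera_position = attr_num(cam, "position"),
    camera_target = attr_num(cam, "target"),
    camera_up = attr_num(cam, "up"),
    projection = xml2::xml_attr(proj, "type"),
    fov_degrees = if (!is.na(xml2::xml_attr(proj, "fov_degrees")))
      attr_num(proj, "fov_degrees") else 30,
    light_direction = attr_num(lig, "direction"),
    ambient = attr_num(lig, "ambient"),
    diffuse = attr_num(lig, "diffuse"),
    specular = attr_num(lig, "specular"),
    shininess = attr_num(lig, "shininess"),
    background = attr_num(rnd, "background"),
    step_size_voxels = attr_num(rnd, "step_size_voxels"),
    opacity_termination = attr_num(rnd, "opacity_termination"),
    view_width = if (!is.na(view_width)) parse_nums(view_width) else NULL)

  tf1 <- NULL
  node <- xml2::xml_find_first(doc, "./tf1d")
  if (!inherits(node, "xml_missing")) {
    pts <- xml2::xml_find_all(node, "./point")
    values <- vapply(pts, function(p) attr_num(p, "value"), numeric(1))
    rgba <- t(vapply(pts, function(p) attr_num(p, "rgba"), numeric(4)))
    tf1 <- transfer_function_1d(values, rgba)
  }
  tf2 <- NULL
  node <- xml2::xml_find_first(doc, "./tf2d")
  if (!inherits(node, "xml_missing")) {
    regions <- lapply(xml2::xml_find_all(node, "./region"), function(rg)
      tf2d_region(value_interval = attr_num(rg, "value"),
                  gradient_interval = attr_num(rg, "gradient"),
                  colour = attr_num(rg, "rgba"),
                  opacity_falloff = xml2::xml_attr(rg, "falloff")))
    tf2 <- transfer_function_2d(regions)
  }
  vols <- xml2::xml_find_all(doc, "./volumes/volume")
  paths <- vapply(vols, function(v) xml2::xml_attr(v, "path"), character(1))

  known <- c("camera", "projection", "lighting", "render", "tf1d", "tf2d",
             "volumes")
  extra <- xml2::xml_find_all(doc, "./*")
  extra <- extra[!xml2::xml_name(extra) %in% known]
  sf <- scene_file(sc, tf_1d = tf1, tf_2d = tf2, volume_paths = paths)
  sf$extra_xml <- vapply(extra, function(n) as.character(n), character(1))
  sf
}
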