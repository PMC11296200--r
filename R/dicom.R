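# Minimal DICOM slice codec: uncompressed little-endian, explicit or
# implicit VR, slice-per-file secondary-capture style series. Covers the
# geometry/pixel essentials needed to exchange segmentation masks and
# tomograms with mainstream 3D visualization software exports; no
# sequences, no compressed transfer syntaxes.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_SC_STORAGE <- "1.2.840.10008.5.1.4.1.1.7"

# VRs whose explicit encoding uses a 4-byte length after 2 reserved bytes
DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# dictionary for the tags this codec understands (needed for implicit VR)
DCM_DICT <- c(
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0060" = "CS",
  "0020,0013" = "IS", "0020,0032" = "DS", "0020,0037" = "DS",
  "0028,0002" = "US", "0028,0004" = "CS", "0028,0010" = "US",
  "0028,0011" = "US", "0028,0030" = "DS", "0028,0100" = "US",
  "0028,0101" = "US", "0028,0102" = "US", "0028,0103" = "US",
  "0028,1052" = "DS", "0028,1053" = "DS", "7fe0,0010" = "OW"
)

raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

dcm_pad <- function(payload, vr) {
  if (length(payload) %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB", "OW", "UN")) as.raw(0L) else charToRaw(" ")
    payload <- c(payload, pad)
  }
  payload
}

dcm_element <- function(group, element, vr, payload) {
  payload <- dcm_pad(payload, vr)
  len <- if (vr %in% DCM_LONG_VRS) {
    c(as.raw(c(0L, 0L)), raw_u32(length(payload)))
  } else {
    if (length(payload) > 65534L) stop("element too long for short VR")
    raw_u16(length(payload))
  }
  c(raw_u16(group), raw_u16(element), charToRaw(vr), len, payload)
}

dcm_str_element <- function(group, element, vr, s) {
  dcm_element(group, element, vr, charToRaw(s))
}

dcm_ds <- function(x) paste(sprintf("%.10g", x), collapse = "\\")

new_uid <- function() {
  paste0("2.25.", paste(sample(0:9, 30, replace = TRUE), collapse = ""))
}

# --- writing ---------------------------------------------------------------

dcm_write_slice <- function(path, pixels, ipp, iop_row, iop_col,
                            pixel_spacing, instance_number,
                            bits_allocated = 8L, pixel_representation = 0L,
                            rescale_slope = 1, rescale_intercept = 0) {
  stopifnot(is.matrix(pixels))
  sop_uid <- new_uid()

  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_str_element(0x0002, 0x0002, "UI", UID_SC_STORAGE),
    dcm_str_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_str_element(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    dcm_str_element(0x0002, 0x0012, "UI", "2.25.1")
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", raw_u32(length(meta_body))),
            meta_body)

  px <- as.integer(t(pixels))  # row-major: column index fastest
  pixel_raw <- writeBin(px, raw(), size = bits_allocated %/% 8L,
                        endian = "little")

  body <- c(
    dcm_str_element(0x0008, 0x0016, "UI", UID_SC_STORAGE),
    dcm_str_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_str_element(0x0008, 0x0060, "CS", "OT"),
    dcm_str_element(0x0020, 0x0013, "IS", as.character(instance_number)),
    dcm_str_element(0x0020, 0x0032, "DS", dcm_ds(ipp)),
    dcm_str_element(0x0020, 0x0037, "DS", dcm_ds(c(iop_row, iop_col))),
    dcm_element(0x0028, 0x0002, "US", raw_u16(1L)),
    dcm_str_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", raw_u16(nrow(pixels))),
    dcm_element(0x0028, 0x0011, "US", raw_u16(ncol(pixels))),
    dcm_str_element(0x0028, 0x0030, "DS", dcm_ds(pixel_spacing)),
    dcm_element(0x0028, 0x0100, "US", raw_u16(bits_allocated)),
    dcm_element(0x0028, 0x0101, "US", raw_u16(bits_allocated)),
    dcm_element(0x0028, 0x0102, "US", raw_u16(bits_allocated - 1L)),
    dcm_element(0x0028, 0x0103, "US", raw_u16(pixel_representation)),
    dcm_str_element(0x0028, 0x1052, "DS", dcm_ds(rescale_intercept)),
    dcm_str_element(0x0028, 0x1053, "DS", dcm_ds(rescale_slope)),
    dcm_element(0x7fe0, 0x0010, if (bits_allocated == 8L) "OB" else "OW",
                pixel_raw)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# --- parsing ---------------------------------------------------------------

dcm_parse <- function(bytes) {
  n <- length(bytes)
  rd_u16 <- function(p) readBin(bytes[p:(p + 1L)], "integer", size = 2L,
                                signed = FALSE, endian = "little")
  read_u32 <- function(p) {
    lo <- readBin(bytes[p:(p + 1L)], "integer", size = 2L, signed = FALSE,
                  endian = "little")
    hi <- readBin(bytes[(p + 2L):(p + 3L)], "integer", size = 2L,
                  signed = FALSE, endian = "little")
    lo + hi * 65536
  }

  pos <- 1L
  if (n >= 132L && rawToChar(bytes[129:132]) == "DICM") pos <- 133L

  looks_explicit <- function(p) {
    if (p + 5L > n) return(FALSE)
    vr <- rawToChar(bytes[(p + 4L):(p + 5L)])
    grepl("^[A-Z]{2}$", vr)
  }
  if (!looks_explicit(pos) && pos == 1L)
    stop("not a DICOM file (no DICM magic, no recognizable element)")

  elements <- list()
  explicit <- TRUE  # file meta group is always explicit
  syntax_checked <- FALSE

  while (pos + 7L <= n) {
    group <- rd_u16(pos); element <- rd_u16(pos + 2L)

    if (group != 0x0002 && !syntax_checked) {
      syntax_checked <- TRUE
      ts <- elements[["0002,0010"]]
      if (!is.null(ts)) {
        uid <- raw_to_string(ts$value)
        if (uid == UID_EXPLICIT_LE) explicit <- TRUE
        else if (uid == UID_IMPLICIT_LE) explicit <- FALSE
        else stop(sprintf("unsupported transfer syntax '%s'", uid))
      } else {
        explicit <- looks_explicit(pos)
      }
    }

    key <- sprintf("%04x,%04x", group, element)
    if (explicit || group == 0x0002) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (!grepl("^[A-Z]{2}$", vr))
        stop("corrupt element: bad VR")
      if (vr %in% DCM_LONG_VRS) {
        len <- read_u32(pos + 8L); hdr <- 12L
      } else {
        len <- rd_u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- if (!is.na(DCM_DICT[key])) unname(DCM_DICT[key]) else "UN"
      len <- read_u32(pos + 4L); hdr <- 8L
    }
    if (len >= 4294967295) stop("unsupported undefined-length element")
    if (pos + hdr + len - 1L > n) stop("truncated DICOM element")
    value <- if (len > 0L) bytes[(pos + hdr):(pos + hdr + len - 1L)] else raw(0L)
    elements[[key]] <- list(vr = vr, value = value)
    pos <- pos + hdr + len
  }
  elements
}

raw_to_string <- function(v) trimws(rawToChar(v[v != as.raw(0L)]))

dcm_el_str <- function(els, key) {
  el <- els[[key]]
  if (is.null(el)) return(NULL)
  raw_to_string(el$value)
}

dcm_el_num <- function(els, key) {
  s <- dcm_el_str(els, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]])
}

dcm_el_us <- function(els, key) {
  el <- els[[key]]
  if (is.null(el)) return(NULL)
  readBin(el$value, "integer", n = length(el$value) %/% 2L, size = 2L,
          signed = FALSE, endian = "little")[1]
}

dcm_read_slice <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  els <- dcm_parse(bytes)

  rows <- dcm_el_us(els, "0028,0010")
  cols <- dcm_el_us(els, "0028,0011")
  if (is.null(rows) || is.null(cols) || is.null(els[["7fe0,0010"]]))
    stop("DICOM file lacks image pixel module")
  bits <- dcm_el_us(els, "0028,0100")
  if (is.null(bits)) bits <- 16L
  if (!bits %in% c(8L, 16L)) stop(sprintf("unsupported BitsAllocated %d", bits))
  signed <- identical(dcm_el_us(els, "0028,0103"), 1L)

  ipp <- dcm_el_num(els, "0020,0032")
  iop <- dcm_el_num(els, "0020,0037")
  if (is.null(iop)) {
    message("note: no direction cosines in ", basename(path),
            "; assuming axis-aligned identity orientation")
    iop <- c(1, 0, 0, 0, 1, 0)
  }
  inst <- dcm_el_num(els, "0020,0013")
  inst <- if (is.null(inst)) NA_integer_ else as.integer(inst[1])
  if (is.null(ipp)) ipp <- c(0, 0, if (is.na(inst)) 0 else inst - 1)
  spacing <- dcm_el_num(els, "0028,0030")
  if (is.null(spacing)) spacing <- c(1, 1)
  slope <- dcm_el_num(els, "0028,1053"); if (is.null(slope)) slope <- 1
  intercept <- dcm_el_num(els, "0028,1052"); if (is.null(intercept)) intercept <- 0

  raw_px <- els[["7fe0,0010"]]$value
  need <- as.numeric(rows) * cols * (bits %/% 8L)
  if (length(raw_px) < need) stop("pixel data shorter than Rows x Columns")
  px <- readBin(raw_px, "integer", n = rows * cols, size = bits %/% 8L,
                signed = if (bits == 8L) FALSE else signed, endian = "little")
  pixels <- matrix(px, nrow = rows, ncol = cols, byrow = TRUE)

  row_dir <- iop[1:3]  # direction of increasing column index
  col_dir <- iop[4:6]  # direction of increasing row index
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])

  list(
    file_path = path,
    instance_number = inst,
    position_along_normal = sum(ipp[1:3] * normal),
    rows = as.integer(rows), cols = as.integer(cols),
    pixel_spacing = spacing[1:2],
    rescale_slope = slope[1], rescale_intercept = intercept[1],
    ipp = ipp[1:3], row_dir = row_dir, col_dir = col_dir, normal = normal,
    bits_allocated = as.integer(bits), signed = signed,
    pixels = pixels
  )
}

# --- module surface --------------------------------------------------------

#' Scan a directory (or zip archive) of DICOM slices
#'
#' Parses every readable DICOM file under `dir`, skipping non-DICOM files
#' with a warning, and returns slice records sorted by the projection of
#' each slice's position onto the stack normal (ties broken by ascending
#' instance number). A `.zip` archive is unpacked to a temporary directory
#' and scanned transparently.
#'
#' @param dir path to a directory of slice files, or a `.zip` archive.
#' @return list of slice records (one per parseable file), sorted.
#' @export
scan_directory <- function(dir) {
  if (length(dir) != 1L) stop("`dir` must be a single path")
  if (file.exists(dir) && !dir.exists(dir) && grepl("\\.zip$", dir, ignore.case = TRUE)) {
    exdir <- tempfile("dcmzip")
    utils::unzip(dir, exdir = exdir)
    dir <- exdir
  }
  if (!dir.exists(dir)) stop(sprintf("directory '%s' does not exist", dir))
  files <- list.files(dir, full.names = TRUE, recursive = TRUE)
  files <- files[!dir.exists(files)]
  records <- list()
  for (f in files) {
    rec <- tryCatch(dcm_read_slice(f), error = function(e) {
      warning(sprintf("skipping non-DICOM file '%s' (%s)",
                      basename(f), conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  if (length(records) == 0L)
    stop(sprintf("empty series: no parseable DICOM files in '%s'", dir))
  rows <- vapply(records, `[[`, integer(1), "rows")
  cols <- vapply(records, `[[`, integer(1), "cols")
  if (length(unique(rows)) > 1L || length(unique(cols)) > 1L)
    stop("inhomogeneous series: slices disagree on Rows/Columns")
  pos <- vapply(records, `[[`, numeric(1), "position_along_normal")
  inst <- vapply(records, `[[`, integer(1), "instance_number")
  inst[is.na(inst)] <- .Machine$integer.max
  records[order(pos, inst)]
}

#' Assemble sorted slice records into a volume
#'
#' Stacks slices into a `(slice, row, col)` array. Inter-slice spacing is
#' the median of consecutive position deltas (positions are authoritative;
#' nominal thickness tags are ignored); a single slice gets spacing
#' 1.0 mm. Stored values are mapped through the rescale slope/intercept.
#'
#' @param records list of slice records from [scan_directory()].
#' @return a [volume_grid()].
#' @export
assemble_volume <- function(records) {
  if (length(records) == 0L) stop("empty series: no slice records")
  rows <- unique(vapply(records, `[[`, integer(1), "rows"))
  cols <- unique(vapply(records, `[[`, integer(1), "cols"))
  psp <- unique(vapply(records, function(r) paste(r$pixel_spacing, collapse = ","),
                       character(1)))
  if (length(rows) > 1L || length(cols) > 1L || length(psp) > 1L)
    stop("inhomogeneous series: slices disagree on shape or pixel spacing")

  pos <- vapply(records, `[[`, numeric(1), "position_along_normal")
  inst <- vapply(records, `[[`, integer(1), "instance_number")
  inst[is.na(inst)] <- .Machine$integer.max
  ord <- order(pos, inst)
  records <- records[ord]; pos <- pos[ord]

  n <- length(records)
  if (n == 1L) {
    dslice <- 1.0
  } else {
    deltas <- diff(pos)
    dslice <- stats::median(deltas)
    bad <- which(abs(deltas - dslice) > 0.01 * abs(dslice) | deltas <= 0)
    if (length(bad) > 0L)
      stop(sprintf(
        "irregular spacing: gap between slices %d and %d is %.6g mm (median %.6g mm)",
        bad[1] - 1L, bad[1], deltas[bad[1]], dslice))
  }

  r1 <- records[[1]]
  data <- array(0, dim = c(n, rows, cols))
  slopes <- vapply(records, `[[`, numeric(1), "rescale_slope")
  intercepts <- vapply(records, `[[`, numeric(1), "rescale_intercept")
  for (s in seq_len(n))
    data[s, , ] <- records[[s]]$pixels * slopes[s] + intercepts[s]

  identity_rescale <- all(slopes == 1) && all(intercepts == 0)
  kind <- if (!identity_rescale) "real"
          else if (r1$bits_allocated == 8L) "unsigned-8-bit"
          else if (r1$signed) "signed-16-bit" else "unsigned-16-bit"

  rev3 <- function(v) v[3:1]
  orientation <- cbind(rev3(r1$normal), rev3(r1$col_dir), rev3(r1$row_dir))
  volume_grid(data,
              spacing = c(dslice, r1$pixel_spacing[1], r1$pixel_spacing[2]),
              origin = rev3(r1$ipp),
              orientation = orientation,
              value_kind = kind)
}

#' Describe a vendor-style segmentation export
#'
#' @param mode `"multi-directory"` (one DICOM series per segmented
#'   structure, Mimics/Avizo style) or `"single-directory"` (one combined
#'   label-valued series, VG Studio style).
#' @param source_dirs paths to the series directories (or zip archives).
#' @param structure_names optional structure names; in multi mode one per
#'   directory, in single mode one per expected label value.
#' @return an `export_layout` object.
#' @export
export_layout <- function(mode = c("multi-directory", "single-directory"),
                          source_dirs, structure_names = NULL) {
  mode <- match.arg(mode)
  source_dirs <- as.character(source_dirs)
  if (mode == "multi-directory" && length(source_dirs) < 1L)
    stop("multi-directory mode needs at least one source directory")
  if (mode == "single-directory" && length(source_dirs) != 1L)
    stop("single-directory mode takes exactly one source directory")
  structure(list(mode = mode, source_dirs = source_dirs,
                 structure_names = structure_names),
            class = "export_layout")
}

#' Import a vendor-style segmentation export as named binary masks
#'
#' Multi-directory layouts yield one mask per directory (any non-zero
#' stored value counts as inside: both 0/255 and label-valued vendor masks
#' are accepted and normalized to \{0, 1\}). Single-directory layouts are
#' split by distinct non-zero voxel value into one binary mask per value,
#' named by `structure_names` or auto-named `label_k`; each split mask
#' records the voxel value it carried in the export as attribute
#' `source_value`, so a later [merge_masks()] can reproduce the original
#' labelling through its `values` argument.
#'
#' @param layout an [export_layout()].
#' @return named list of binary `volume_grid` masks (values \{0, 1\},
#'   unsigned 8-bit).
#' @export
read_export <- function(layout) {
  stopifnot(inherits(layout, "export_layout"))
  to_binary <- function(vol) {
    volume_grid(array(as.numeric(vol$data > 0), dim = dim(vol$data)),
                spacing = vol$spacing, origin = vol$origin,
                orientation = vol$orientation, value_kind = "unsigned-8-bit")
  }
  if (layout$mode == "multi-directory") {
    vols <- lapply(layout$source_dirs,
                   function(d) to_binary(assemble_volume(scan_directory(d))))
    nm <- layout$structure_names
    if (is.null(nm)) nm <- basename(sub("\\.zip$", "", layout$source_dirs,
                                        ignore.case = TRUE))
    if (length(nm) != length(vols))
      stop("structure_names length must match the number of directories")
    names(vols) <- nm
    return(vols)
  }
  combined <- assemble_volume(scan_directory(layout$source_dirs))
  values <- sort(unique(as.vector(combined$data)))
  values <- values[values != 0]
  if (length(values) == 0L) {
    warning("single-directory export contains no segmented voxels")
    return(structure(list(), names = character(0)))
  }
  nm <- layout$structure_names
  if (is.null(nm)) nm <- sprintf("label_%d", seq_along(values))
  if (length(nm) != length(values))
    stop(sprintf("structure_names has %d entries but the export holds %d labels",
                 length(nm), length(values)))
  vols <- lapply(values, function(v) {
    m <- volume_grid(array(as.numeric(combined$data == v),
                           dim = dim(combined$data)),
                     spacing = combined$spacing, origin = combined$origin,
                     orientation = combined$orientation,
                     value_kind = "unsigned-8-bit")
    attr(m, "source_value") <- v  # voxel value this mask carried in the export
    m
  })
  names(vols) <- nm
  vols
}

#' Write a volume as a DICOM slice series
#'
#' One file per slice, carrying position, orientation, pixel spacing and
#' instance number, so that [scan_directory()] + [assemble_volume()] is an
#' element-wise identity on the data and reproduces the spacing within
#' 1e-6 mm.
#'
#' @param vol an integer-kind [volume_grid()].
#' @param dir output directory (created if missing).
#' @return number of files written, invisibly.
#' @export
write_dicom_series <- function(vol, dir) {
  stopifnot(inherits(vol, "volume_grid"))
  if (!is_integer_kind(vol$value_kind))
    stop("write_dicom_series requires an integer value kind")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("cannot create directory '%s'", dir))
  d <- dim(vol$data)
  rev3 <- function(v) v[3:1]
  bits <- if (vol$value_kind == "unsigned-8-bit") 8L else 16L
  pixrep <- if (vol$value_kind == "signed-16-bit") 1L else 0L
  for (s in seq_len(d[1])) {
    ipp <- rev3(as.vector(grid_index_to_phys(vol, c(s - 1, 0, 0))))
    dcm_write_slice(
      file.path(dir, sprintf("slice_%05d.dcm", s - 1L)),
      pixels = matrix(vol$data[s, , ], d[2], d[3]),
      ipp = ipp,
      iop_row = rev3(vol$orientation[, 3]),
      iop_col = rev3(vol$orientation[, 2]),
      pixel_spacing = vol$spacing[2:3],
      instance_number = s,
      bits_allocated = bits, pixel_representation = pixrep)
  }
  invisible(d[1])
}
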