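# interchange formats: RAW, image stack, MetaImage, processed container,
# XML scene

test_that("RAW round trip is bit-identical with correct file size", {
  v8 <- volume_grid(array(as.numeric(0:7), c(2, 2, 2)),
                    value_kind = "unsigned-8-bit")
  path <- withr::local_tempfile(fileext = ".raw")
  write_raw(v8, path)
  expect_equal(file.info(path)$size, 8)
  expect_identical(read_raw(path)$data, v8$data)

  v16 <- random_volume(c(3, 4, 5), 2, kind = "unsigned-16-bit",
                       max_val = 65535)
  path16 <- withr::local_tempfile(fileext = ".raw")
  write_raw(v16, path16)
  back <- read_raw(path16)
  expect_identical(back$data, v16$data)
  expect_identical(back$value_kind, "unsigned-16-bit")

  vr <- volume_grid(array(stats::rnorm(24), c(2, 3, 4)))
  pr <- withr::local_tempfile(fileext = ".raw")
  write_raw(vr, pr)
  expect_identical(read_raw(pr)$data, vr$data)
})

test_that("RAW rejects a shape that disagrees with the payload", {
  v <- random_volume(c(2, 3, 4), 5)
  path <- withr::local_tempfile(fileext = ".raw")
  write_raw(v, path)
  expect_error(read_raw(path, shape = c(2, 3, 5),
                        value_kind = "unsigned-8-bit"), "size mismatch")
})

test_that("image stack round-trips 8-bit volumes exactly and is idempotent", {
  vol <- random_volume(c(5, 7, 6), 8)
  dir <- withr::local_tempdir()
  expect_equal(write_image_stack(vol, dir), 5L)
  expect_length(list.files(dir, pattern = "\\.png$"), 5L)
  back <- read_image_stack(dir)
  expect_identical(back$data, vol$data)
  dir2 <- withr::local_tempdir()
  write_image_stack(back, dir2)
  for (f in list.files(dir, pattern = "png$"))
    expect_identical(readBin(file.path(dir, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6))
})

test_that("out-of-range volumes are min-max rescaled; constants map to zero", {
  v16 <- volume_grid(array(c(1000, 2000, 3000, 4000, 1000, 1500, 2500, 3500),
                           c(2, 2, 2)), value_kind = "unsigned-16-bit")
  dir <- withr::local_tempdir()
  expect_message(write_image_stack(v16, dir), "rescaling")
  back <- read_image_stack(dir)
  expect_equal(range(back$data), c(0, 255))

  cst <- volume_grid(array(4000, c(2, 2, 2)), value_kind = "unsigned-16-bit")
  dir2 <- withr::local_tempdir()
  suppressMessages(write_image_stack(cst, dir2))
  expect_true(all(read_image_stack(dir2)$data == 0))
})

test_that("reading a stack validates homogeneity and non-emptiness", {
  dir <- withr::local_tempdir()
  expect_error(read_image_stack(dir), "empty series")
  png::writePNG(matrix(0.5, 4, 4), file.path(dir, "slice_00000.png"))
  png::writePNG(matrix(0.5, 5, 4), file.path(dir, "slice_00001.png"))
  expect_error(read_image_stack(dir), "inhomogeneous stack")
})

test_that("MetaImage round trip preserves data, spacing, origin, orientation", {
  vol <- volume_grid(array(sample(0:255, 60, replace = TRUE), c(3, 4, 5)),
                     spacing = c(0.5, 0.25, 0.25), origin = c(3, -1, 2),
                     value_kind = "unsigned-8-bit")
  path <- file.path(withr::local_tempdir(), "vol.mhd")
  write_metaimage(vol, path)
  hdr <- readLines(path)
  expect_true(any(grepl("ElementType = MET_UCHAR", hdr)))
  back <- read_metaimage(path)
  expect_identical(back$data, vol$data)
  expect_lt(max(abs(back$spacing - vol$spacing)), 1e-9)
  expect_lt(max(abs(back$origin - vol$origin)), 1e-9)
  expect_lt(max(abs(back$orientation - vol$orientation)), 1e-9)

  vr <- volume_grid(array(stats::rnorm(24), c(2, 3, 4)))
  path2 <- file.path(withr::local_tempdir(), "volr.mhd")
  write_metaimage(vr, path2)
  expect_identical(read_metaimage(path2)$data, vr$data)
})

test_that("MetaImage headers are validated", {
  vol <- random_volume(c(2, 3, 4), 3)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "vol.mhd")
  write_metaimage(vol, path)
  hdr <- readLines(path)
  writeLines(sub("DimSize = 4 3 2", "DimSize = 4 3 3", hdr), path)
  expect_error(read_metaimage(path), "bad header")
  writeLines(hdr[!grepl("ElementType", hdr)], path)
  expect_error(read_metaimage(path), "bad header: missing key 'ElementType'")
})

test_that("a MetaImage written here is readable by an independent ITK reader", {
  py <- Sys.which("python")
  vol <- volume_grid(array(as.numeric(0:59), c(3, 4, 5)),
                     spacing = c(2.5, 0.5, 0.75), origin = c(1, 2, 3),
                     value_kind = "unsigned-8-bit")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "vol.mhd")
  write_metaimage(vol, path)
  script <- paste(
    "import SimpleITK as sitk, numpy as np, sys",
    sprintf("img = sitk.ReadImage('%s')", path),
    "a = sitk.GetArrayFromImage(img)",  # (z, y, x) = (slice, row, col)
    "ok = a.shape == (3, 4, 5)",
    "ok &= img.GetSpacing() == (0.75, 0.5, 2.5)",
    "ok &= img.GetOrigin() == (3.0, 2.0, 1.0)",
    "ok &= int(a[1, 2, 3]) == 1 + 3 * 2 + 12 * 3",
    "sys.stdout.write('PASS' if ok else 'FAIL')",
    sep = "; ")
  out <- system2(py, c("-c", shQuote(script)), stdout = TRUE)
  expect_identical(tail(out, 1), "PASS")
})

test_that("exactly three standard export formats are registered and dispatch", {
  fmts <- list_export_formats()
  expect_identical(fmts, c("image-stack", "metaimage", "raw"))
  expect_identical(list_export_formats(), fmts)  # stable across calls
  vol <- random_volume(c(2, 3, 3), 4)
  dir <- withr::local_tempdir()
  export_volume(vol, "raw", file.path(dir, "v.raw"))
  export_volume(vol, "image-stack", file.path(dir, "stack"))
  export_volume(vol, "metaimage", file.path(dir, "v.mhd"))
  expect_identical(read_raw(file.path(dir, "v.raw"))$data, vol$data)
  expect_identical(read_image_stack(file.path(dir, "stack"))$data, vol$data)
  expect_identical(read_metaimage(file.path(dir, "v.mhd"))$data, vol$data)
  expect_error(export_volume(vol, "nifti", "x"), "unknown format")
})

test_that("a label map exported to MetaImage re-splits into the original masks", {
  ph <- generate_phantom(two_sphere_spec())
  lm <- merge_masks(ph$masks, policy = "first-wins")
  path <- file.path(withr::local_tempdir(), "labels.mhd")
  write_metaimage(lm$grid, path)
  back <- read_metaimage(path)
  for (r in seq_len(nrow(lm$table))) {
    vv <- lm$table$voxel_value[r]
    expect_identical(array(as.numeric(back$data == vv), dim(back$data)),
                     array(as.numeric(lm$grid$data == vv), dim(lm$grid$data)))
  }
})

test_that("the processed container round-trips and detects tampering", {
  ph <- generate_phantom(two_sphere_spec())
  lm <- merge_masks(ph$masks)
  pv <- processed_volume(lm$grid, lm$table,
                         provenance = c("source: phantom", "policy: last-wins"))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "vol.pvl.json")
  save_processed(pv, path)
  back <- load_processed(path)
  expect_identical(back$grid$data, pv$grid$data)
  expect_equal(back$table$voxel_value, pv$table$voxel_value)
  expect_equal(back$table$name, pv$table$name)
  expect_equal(back$table$voxel_count, pv$table$voxel_count)
  expect_identical(back$provenance, pv$provenance)
  expect_identical(back$format_version, "1.0")

  # empty table (pure tomogram) is allowed
  pv2 <- processed_volume(ph$tomogram)
  path2 <- file.path(dir, "tomo.pvl.json")
  save_processed(pv2, path2)
  expect_equal(nrow(load_processed(path2)$table), 0L)

  # tampered payload
  raw_path <- file.path(dir, "vol.pvl.raw")
  bytes <- readBin(raw_path, "raw", file.info(raw_path)$size)
  bytes[1] <- as.raw(255L - as.integer(bytes[1]))
  writeBin(bytes, raw_path)
  expect_error(load_processed(path), "corrupt container")
})

random_scene <- function(seed) {
  set.seed(seed)
  scene_params(
    camera_position = stats::rnorm(3, 0, 100),
    camera_target = stats::rnorm(3),
    camera_up = c(0, 1, 0),
    projection = sample(c("orthographic", "perspective"), 1),
    fov_degrees = stats::runif(1, 10, 80),
    light_direction = stats::rnorm(3),
    ambient = stats::runif(1), diffuse = stats::runif(1),
    specular = stats::runif(1), shininess = stats::runif(1, 1, 100),
    background = stats::runif(3),
    step_size_voxels = stats::runif(1, 0.05, 1),
    opacity_termination = stats::runif(1, 0.5, 1),
    view_width = if (seed %% 2) stats::runif(1, 10, 500) else NULL)
}

test_that("scene XML round-trips field-for-field", {
  dir <- withr::local_tempdir()
  # default scene
  sf <- scene_file()
  p <- file.path(dir, "default.xml")
  save_scene(sf, p)
  expect_equal(load_scene(p)$scene, sf$scene)

  for (seed in 1:50) {
    sf <- scene_file(
      random_scene(seed),
      tf_1d = if (seed %% 2) {
        set.seed(seed + 1000)
        transfer_function_1d(sort(sample(0:255, 4)),
                             matrix(stats::runif(16), 4, 4))
      },
      tf_2d = if (seed %% 3 == 0) {
        transfer_function_2d(list(
          tf2d_region(c(10, 90), c(0, 50), stats::runif(4), "flat"),
          tf2d_region(c(100, 200), c(5, 25), stats::runif(4), "linear-edge")))
      },
      volume_paths = if (seed %% 4 == 0) c("a.pvl.json", "b.mhd") else character(0))
    p <- file.path(dir, sprintf("scene%d.xml", seed))
    save_scene(sf, p)
    back <- load_scene(p)
    expect_equal(back$scene, sf$scene)
    if (!is.null(sf$tf_1d)) expect_equal(back$tf_1d$points, sf$tf_1d$points)
    else expect_null(back$tf_1d)
    if (!is.null(sf$tf_2d)) expect_equal(back$tf_2d, sf$tf_2d)
    else expect_null(back$tf_2d)
    expect_identical(back$volume_paths, sf$volume_paths)
  }
})

test_that("unknown scene elements survive a rewrite verbatim", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "scene.xml")
  save_scene(scene_file(), p)
  doc <- xml2::read_xml(p)
  xml2::xml_add_child(doc, xml2::read_xml('<keyframes n="3"><frame t="0"/></keyframes>'))
  xml2::write_xml(doc, p)
  sf <- load_scene(p)
  expect_length(sf$extra_xml, 1L)
  p2 <- file.path(dir, "scene2.xml")
  save_scene(sf, p2)
  back <- load_scene(p2)
  expect_identical(back$extra_xml, sf$extra_xml)
  expect_match(back$extra_xml, "keyframes")
})

test_that("malformed scene XML is reported as a parse error", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines("<scene><camera position='0 0 0'>", p)
  expect_error(load_scene(p), "parse error")
})
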