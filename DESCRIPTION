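Package: segrevis
Title: Revisualization of Segmented Volume Data Exported as DICOM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imports segmentation results exported from mainstream 3D
    visualization software as single or multiple DICOM slice-series
    directories, collapses them into one labelled volume (one voxel value
    per segmented structure), revisualizes the result with 1D and 2D
    transfer functions through a software ray caster, and exports volumes
    in standard interchange formats (RAW, 8-bit greyscale image stacks,
    ITK MetaImage). A validation battery provides greyscale conversion,
    histograms, surface-plot data, Sobel edge detection, optical-density
    step-tablet calibration and image-pair correlation, plus a synthetic
    phantom generator that emulates vendor-style DICOM exports with
    ground-truth manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    xml2,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
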