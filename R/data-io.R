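#' Packaged post-mortem cohort metadata
#'
#' Returns the packaged 10-brain donor table (sex, age, cause of death,
#' fresh brain weight) used as the cohort design fixture.
#'
#' @return tibble: `brain`, `sex`, `age_years`, `cause_of_death`,
#'   `fresh_brain_weight_g`.
#' @export
load_brain_table <- function() {
  readr::read_csv(
    system.file("extdata", "table1_brains.csv", package = "cytoborder",
                mustWork = TRUE),
    show_col_types = FALSE
  )
}

#' Packaged per-brain area volume table
#'
#' Shrinkage-corrected per-brain, per-hemisphere volumes (mm^3) of the
#' four anterior DLPFC areas, in long format ready for
#' [aggregate_table()].
#'
#' @return tibble: `brain`, `sex`, `hemisphere`, `area`, `volume_mm3`.
#' @export
load_volume_table <- function() {
  readr::read_csv(
    system.file("extdata", "table4_volumes.csv", package = "cytoborder",
                mustWork = TRUE),
    show_col_types = FALSE
  )
}

#' Write a synthetic section to disk
#'
#' Writes the grayscale image as 16-bit TIFF (or PNG) with the ground
#' truth (contours, border positions, seed) as a JSON sidecar.
#'
#' @param section a `synthetic_section`.
#' @param path output image path (`.tif`/`.tiff` or `.png`).
#' @return `path`, invisibly.
#' @export
write_section <- function(section, path) {
  stopifnot(inherits(section, "synthetic_section"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) abort("package `tiff` required.")
    tiff::writeTIFF(section$image, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) abort("package `png` required.")
    png::writePNG(section$image, path)
  } else {
    abort("unsupported extension: use .tif/.tiff or .png")
  }
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(pixel_size_um = section$pixel_size_um,
         truth_borders_um = section$truth_borders_um,
         truth_labels = section$truth_labels,
         outer_contour = section$geometry$outer,
         inner_contour = section$geometry$inner,
         seed = section$seed),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write cohort label volumes as NIfTI-1
#'
#' One `.nii.gz` per subject with the voxel size in the header.
#'
#' @param cohort a [make_cohort()] result.
#' @param dir output directory (created if missing).
#' @return character vector of paths, invisibly.
#' @export
write_cohort_nifti <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!requireNamespace("RNifti", quietly = TRUE)) abort("package `RNifti` required.")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(cohort$subjects))
  for (s in seq_along(cohort$subjects)) {
    paths[s] <- file.path(dir, sprintf("subject%02d_labels.nii.gz", s))
    img <- RNifti::asNifti(cohort$subjects[[s]])
    RNifti::pixdim(img) <- cohort$voxel_size_mm
    RNifti::writeNifti(img, paths[s])
  }
  invisible(paths)
}
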