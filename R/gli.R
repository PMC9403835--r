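#' Segment cell bodies in a stained section image
#'
#' Cell bodies are dark on a light background in cell-body stains, so the
#' foreground is the set of pixels *darker* than the threshold. The default
#' threshold is Otsu's, the standard histogram split maximizing
#' between-class variance.
#'
#' @param image numeric matrix of intensities in \[0, 1\], or a
#'   `synthetic_section` (its image is used).
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold required for `method = "fixed"`; ignored for otsu.
#' @param pixel_size_um pixel size carried through for provenance; taken
#'   from a `synthetic_section` input automatically.
#' @return an object of class `binary_image`: list with `pixels` (logical
#'   matrix, `TRUE` = cell body), `pixel_size_um`, `method`, `threshold`.
#' @export
segment_cell_bodies <- function(image, method = c("otsu", "fixed"),
                                threshold = NULL, pixel_size_um = 1.02) {
  if (inherits(image, "synthetic_section")) {
    pixel_size_um <- image$pixel_size_um
    image <- image$image
  }
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image) || any(!is.finite(image))) {
    abort("`image` must be a finite numeric matrix.")
  }
  if (nrow(image) < 16 || ncol(image) < 16) {
    abort("`image` must be at least 16 x 16 pixels.")
  }
  if (method == "fixed") {
    if (is.null(threshold)) abort("`method = \"fixed\"` requires `threshold`.")
  } else {
    threshold <- EBImage::otsu(image, range = c(0, 1), levels = 256)
  }
  structure(list(pixels = image < threshold, pixel_size_um = pixel_size_um,
                 method = method, threshold = as.double(threshold)),
            class = "binary_image")
}

#' Compute a gray level index (GLI) map
#'
#' Partitions the binary image into non-overlapping square measuring fields
#' of `field_size_px` pixels and records, for each field, the fraction of
#' foreground (cell-body) pixels — an estimate of the local volume fraction
#' of cell bodies. Trailing partial fields are discarded.
#'
#' @param binary a [segment_cell_bodies()] result, or a logical matrix.
#' @param field_size_px measuring-field edge length in pixels (default 16).
#' @param pixel_size_um pixel size (taken from a `binary_image` input).
#' @return an object of class `gli_map`: list with `values` (matrix of
#'   fractions in \[0, 1\]; rows/cols index fields), `field_size_px`,
#'   `pixel_size_um`. The field at row i, column j covers image pixels
#'   `((i-1)*fs + 1):(i*fs)` by `((j-1)*fs + 1):(j*fs)`.
#' @export
compute_gli <- function(binary, field_size_px = 16, pixel_size_um = 1.02) {
  if (inherits(binary, "binary_image")) {
    pixel_size_um <- binary$pixel_size_um
    binary <- binary$pixels
  }
  if (!is.matrix(binary) || !is.logical(binary)) {
    abort("`binary` must be a logical matrix (TRUE = cell body).")
  }
  if (!is_number(field_size_px) || field_size_px < 1) {
    abort("`field_size_px` must be >= 1.")
  }
  fs <- as.integer(field_size_px)
  gr <- nrow(binary) %/% fs
  gc <- ncol(binary) %/% fs
  if (gr < 1 || gc < 1) abort("image smaller than one measuring field.")
  m <- binary[seq_len(gr * fs), seq_len(gc * fs), drop = FALSE] * 1
  colgrp <- t(rowsum(t(m), rep(seq_len(gc), each = fs)))
  sums <- rowsum(colgrp, rep(seq_len(gr), each = fs))
  structure(list(values = unname(sums) / fs^2, field_size_px = fs,
                 pixel_size_um = pixel_size_um),
            class = "gli_map")
}

#' @export
print.gli_map <- function(x, ...) {
  cat("<gli_map>", paste(dim(x$values), collapse = " x "), "fields of",
      x$field_size_px, "px; mean GLI", signif(mean(x$values), 3), "\n")
  invisible(x)
}

#' @export
as_tibble.gli_map <- function(x, ...) {
  tibble(
    field_row = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
    field_col = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
    gli = as.vector(x$values)
  )
}

#' Full image-to-GLI-map step for a section
#'
#' Convenience wrapper chaining [segment_cell_bodies()] and [compute_gli()].
#'
#' @param section a `synthetic_section` or intensity matrix.
#' @param field_size_px measuring-field size.
#' @param ... passed to [segment_cell_bodies()].
#' @return a `gli_map`.
#' @export
section_gli <- function(section, field_size_px = 16, ...) {
  compute_gli(segment_cell_bodies(section, ...), field_size_px)
}
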