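#' Define the laminar structure of a cortical area
#'
#' A laminar specification describes an area by the relative thickness of
#' the six cortical layers (I-VI, as fractions of cortical depth) and the
#' cell-body packing density of each layer, expressed as the expected
#' foreground (stained) area fraction, i.e. the value a GLI measurement of a
#' homogeneous band of that layer converges to.
#'
#' @param layer_fractions numeric(6), proportions of cortical depth occupied
#'   by layers I-VI; must sum to 1.
#' @param layer_density numeric(6), expected cell-body area fraction per
#'   layer, each in \[0, 1\].
#' @param cell_radius_px numeric(2), mean and standard deviation of rendered
#'   cell-body radii in pixels (used only by the raster renderer).
#' @param name optional area name.
#' @return an object of class `laminar_spec`.
#' @export
#' @examples
#' laminar_spec(rep(1 / 6, 6), c(0.05, 0.45, 0.30, 0.50, 0.30, 0.40))
laminar_spec <- function(layer_fractions, layer_density,
                         cell_radius_px = c(3, 0.5), name = NULL) {
  if (length(layer_fractions) != 6L || !is.numeric(layer_fractions)) {
    abort("`layer_fractions` must be a numeric vector of length 6 (layers I-VI).")
  }
  if (abs(sum(layer_fractions) - 1) > 1e-9) {
    abort(sprintf("`layer_fractions` must sum to 1 (got %.12f).", sum(layer_fractions)))
  }
  if (any(layer_fractions < 0)) abort("`layer_fractions` must be non-negative.")
  if (length(layer_density) != 6L || !is.numeric(layer_density) ||
      any(layer_density < 0 | layer_density > 1)) {
    abort("`layer_density` must be 6 values in [0, 1].")
  }
  if (length(cell_radius_px) != 2L || cell_radius_px[1] <= 0) {
    abort("`cell_radius_px` must be c(mean, sd) with mean > 0.")
  }
  structure(
    list(layer_fractions = as.double(layer_fractions),
         layer_density = as.double(layer_density),
         cell_radius_px = as.double(cell_radius_px),
         name = name),
    class = "laminar_spec"
  )
}

#' @export
print.laminar_spec <- function(x, ...) {
  cat("<laminar_spec>", if (!is.null(x$name)) x$name else "", "\n")
  cat("  layer fractions:", paste(signif(x$layer_fractions, 3), collapse = " "), "\n")
  cat("  layer densities:", paste(signif(x$layer_density, 3), collapse = " "), "\n")
  invisible(x)
}

#' Laminar density curve over normalized cortical depth
#'
#' Evaluates the piecewise-constant cell-density curve implied by a laminar
#' specification on an equidistant grid over normalized depth \[0, 1\]
#' (0 = layer I/II side, 1 = layer VI/white-matter side). Optional Gaussian
#' smoothing softens the layer transitions, emulating the gradual laminar
#' boundaries of real cortex.
#'
#' @param spec a [laminar_spec()].
#' @param n_points number of equidistant depth samples (>= 10).
#' @param smooth_sd standard deviation of the Gaussian smoothing kernel in
#'   normalized depth units; 0 (default) keeps the curve exactly
#'   piecewise constant.
#' @return a tibble with columns `depth` (in \[0, 1\]) and `density`.
#' @export
#' @examples
#' make_laminar_profile(laminar_spec(rep(1 / 6, 6), rep(0.3, 6)), 101)
make_laminar_profile <- function(spec, n_points = 101, smooth_sd = 0) {
  stopifnot(inherits(spec, "laminar_spec"))
  if (!is_number(n_points) || n_points < 10) abort("`n_points` must be >= 10.")
  depth <- seq(0, 1, length.out = n_points)
  edges <- cumsum(c(0, spec$layer_fractions))
  # band index of each depth: depth in [edges[i], edges[i+1]) -> layer i
  band <- findInterval(depth, edges, rightmost.closed = TRUE, left.open = FALSE)
  band <- pmin(pmax(band, 1L), 6L)
  density <- spec$layer_density[band]
  if (smooth_sd > 0) {
    h <- depth[2] - depth[1]
    half <- max(1L, ceiling(3 * smooth_sd / h))
    k <- stats::dnorm(seq(-half, half) * h, sd = smooth_sd)
    k <- k / sum(k)
    padded <- c(rep(density[1], half), density, rep(density[n_points], half))
    density <- stats::filter(padded, k, sides = 2)[(half + 1):(half + n_points)]
    density <- as.double(density)
  }
  tibble(depth = depth, density = density)
}
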