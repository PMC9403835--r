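#' Cortical ribbon geometry
#'
#' A ribbon is the strip of cortex between the outer contour (layer I/II
#' boundary) and the inner contour (layer VI/white-matter boundary), both
#' given as ordered polylines in micrometres. Both contours must run in the
#' same direction (first points on the same open end of the ribbon).
#'
#' @param outer,inner numeric matrices (n x 2) of ordered (x, y) vertices in
#'   micrometres; image convention (origin top-left, y down).
#' @param pixel_size_um edge length of one image pixel in micrometres
#'   (default 1.02, the scanning resolution the workflow was designed for).
#' @return an object of class `ribbon_geometry`.
#' @export
ribbon_geometry <- function(outer, inner, pixel_size_um = 1.02) {
  outer <- as.matrix(outer); inner <- as.matrix(inner)
  if (ncol(outer) != 2L || nrow(outer) < 2L) abort("`outer` must be an n x 2 matrix, n >= 2.")
  if (ncol(inner) != 2L || nrow(inner) < 2L) abort("`inner` must be an n x 2 matrix, n >= 2.")
  stop_if_not_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (polylines_intersect(outer, inner)) {
    abort("outer and inner contours intersect; they must bound a ribbon.")
  }
  if (nrow(outer) > 3L && polylines_intersect(outer[1:floor(nrow(outer) / 2), , drop = FALSE],
                                              outer[(floor(nrow(outer) / 2) + 2):nrow(outer), , drop = FALSE])) {
    abort("`outer` contour is self-intersecting.")
  }
  structure(list(outer = unname(outer), inner = unname(inner),
                 pixel_size_um = pixel_size_um),
            class = "ribbon_geometry")
}

#' Flat ribbon between two parallel straight contours
#'
#' Convenience constructor for a rectangular cortical ribbon: the outer
#' contour runs along y = 0, the inner along y = `thickness_um`.
#'
#' @param length_um,thickness_um ribbon extent in micrometres.
#' @param pixel_size_um pixel size.
#' @param n_vertices vertices per contour.
#' @return a [ribbon_geometry()].
#' @export
flat_ribbon <- function(length_um, thickness_um, pixel_size_um = 1.02,
                        n_vertices = 2) {
  x <- seq(0, length_um, length.out = max(2, n_vertices))
  ribbon_geometry(cbind(x, 0), cbind(x, thickness_um), pixel_size_um)
}

#' Annular ribbon between concentric circular arcs
#'
#' The outer contour is the arc at radius `r0`, the inner at `r1 > r0`,
#' both spanning `angle_deg` degrees and centred at `centre`.
#'
#' @param r0,r1 arc radii in micrometres (outer contour at `r0`).
#' @param angle_deg angular span in degrees.
#' @param centre centre of the arcs (x, y) in micrometres.
#' @param pixel_size_um pixel size.
#' @param n_vertices vertices per contour.
#' @return a [ribbon_geometry()].
#' @export
annulus_ribbon <- function(r0, r1, angle_deg = 90, centre = c(0, 0),
                           pixel_size_um = 1.02, n_vertices = 90) {
  stopifnot(r1 > r0, r0 > 0)
  th <- seq(0, angle_deg * pi / 180, length.out = n_vertices)
  outer <- cbind(centre[1] + r0 * cos(th), centre[2] + r0 * sin(th))
  inner <- cbind(centre[1] + r1 * cos(th), centre[2] + r1 * sin(th))
  ribbon_geometry(outer, inner, pixel_size_um)
}

# Per-pixel ribbon coordinates: for pixel centres (um), distance-based depth
# in [0,1] and arc-length of the nearest outer-contour foot point.
ribbon_pixel_frame <- function(geometry, nx, ny, pixel_size_um) {
  cx <- (seq_len(nx) - 0.5) * pixel_size_um
  cy <- (seq_len(ny) - 0.5) * pixel_size_um
  px <- rep(cx, each = ny)
  py <- rep(cy, times = nx)
  poly <- rbind(geometry$outer, geometry$inner[rev(seq_len(nrow(geometry$inner))), ])
  inside <- point_in_polygon(px, py, poly)
  d_out <- dist_to_polyline(px, py, geometry$outer)
  d_in <- dist_to_polyline(px, py, geometry$inner)
  depth <- d_out / (d_out + d_in)
  arc <- arclength_of_nearest(px, py, geometry$outer)
  list(px = px, py = py, inside = inside, depth = depth, arc = arc,
       nx = nx, ny = ny)
}

#' Render a synthetic cell-body-stained section
#'
#' Draws a silver-stain-like grayscale image of a cortical ribbon: cell
#' bodies are rendered as dark anti-aliased disks on a light background,
#' placed by an inhomogeneous Poisson (Boolean) process whose local covered
#' fraction follows the laminar density profile of the area owning each
#' point (ownership by the nearest foot point on the outer contour).
#' Under the Boolean model the expected foreground fraction of a
#' homogeneous band equals the specified layer density.
#'
#' @param geometry a [ribbon_geometry()].
#' @param areas list of [laminar_spec()]s, ordered along the outer contour.
#' @param border_arclengths strictly increasing arc-length positions (um)
#'   on the outer contour where area identity changes; length must be
#'   `length(areas) - 1`.
#' @param seed integer seed; the image is a pure function of arguments + seed.
#' @param background,cell_intensity background and cell-body intensities on
#'   the \[0, 1\] scale (cells darker).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param margin_px blank margin around the ribbon's bounding box.
#' @return an object of class `synthetic_section` with fields `image`
#'   (ny x nx matrix in \[0, 1\]), `geometry`, `truth_borders_um`,
#'   `truth_labels` (tibble: area index per arc-length interval), `seed`.
#' @export
render_section <- function(geometry, areas, border_arclengths = numeric(0),
                           seed = 1L, background = 0.9, cell_intensity = 0.1,
                           noise_sd = 0.02, margin_px = 4) {
  stopifnot(inherits(geometry, "ribbon_geometry"))
  if (inherits(areas, "laminar_spec")) areas <- list(areas)
  if (!all(vapply(areas, inherits, logical(1), "laminar_spec"))) {
    abort("`areas` must be a list of laminar_spec objects.")
  }
  arc_total <- max(polyline_arclength(geometry$outer))
  if (length(border_arclengths) != length(areas) - 1L) {
    abort("need length(areas) - 1 border positions.")
  }
  if (length(border_arclengths) &&
      (is.unsorted(border_arclengths, strictly = TRUE) ||
       any(border_arclengths <= 0) || any(border_arclengths >= arc_total))) {
    abort("`border_arclengths` must be strictly increasing and inside (0, total arc length).")
  }

  ps <- geometry$pixel_size_um
  allpts <- rbind(geometry$outer, geometry$inner)
  nx <- ceiling(max(allpts[, 1]) / ps) + margin_px
  ny <- ceiling(max(allpts[, 2]) / ps) + margin_px
  frame <- ribbon_pixel_frame(geometry, nx, ny, ps)
  if (!any(frame$inside)) abort("ribbon encloses no pixels (zero-area ribbon).")

  # per-pixel target foreground fraction
  edges <- c(0, border_arclengths, arc_total)
  area_of_pixel <- findInterval(frame$arc, edges, rightmost.closed = TRUE)
  area_of_pixel <- pmin(pmax(area_of_pixel, 1L), length(areas))
  f <- numeric(length(frame$px))
  for (a in seq_along(areas)) {
    sel <- frame$inside & area_of_pixel == a
    if (!any(sel)) next
    spec <- areas[[a]]
    band_edges <- cumsum(c(0, spec$layer_fractions))
    band <- findInterval(frame$depth[sel], band_edges, rightmost.closed = TRUE)
    band <- pmin(pmax(band, 1L), 6L)
    f[sel] <- spec$layer_density[band]
  }
  f <- pmin(f, 0.97)  # Boolean-model intensity diverges as f -> 1

  img <- withr::with_seed(as.integer(seed), {
    # mean disk area in px^2 (E[pi R^2] for R ~ N(mu, sd))
    rad_mu <- mean(vapply(areas, function(s) s$cell_radius_px[1], 0))
    rad_sd <- mean(vapply(areas, function(s) s$cell_radius_px[2], 0))
    mean_disk_area <- pi * (rad_mu^2 + rad_sd^2)
    lambda <- -log(1 - f) / mean_disk_area  # cells per px^2
    lambda_max <- max(lambda)
    cov_mat <- matrix(0, ny, nx)
    if (lambda_max > 0) {
      n_cand <- rpois(1, lambda_max * nx * ny)
      if (n_cand > 0) {
        cxp <- runif(n_cand, 0, nx)
        cyp <- runif(n_cand, 0, ny)
        ix <- pmin(pmax(ceiling(cxp), 1L), nx)
        iy <- pmin(pmax(ceiling(cyp), 1L), ny)
        lam_here <- lambda[(ix - 1L) * ny + iy]
        keep <- runif(n_cand) < lam_here / lambda_max
        cxp <- cxp[keep]; cyp <- cyp[keep]
        radii <- pmax(0.8, rnorm(sum(keep), rad_mu, rad_sd))
        for (k in seq_along(cxp)) {
          r <- radii[k]
          x0 <- max(1L, floor(cxp[k] - r)); x1 <- min(nx, ceiling(cxp[k] + r) + 1L)
          y0 <- max(1L, floor(cyp[k] - r)); y1 <- min(ny, ceiling(cyp[k] + r) + 1L)
          if (x0 > x1 || y0 > y1) next
          xs <- (x0:x1) - 0.5; ys <- (y0:y1) - 0.5
          dmat <- sqrt(outer((ys - cyp[k])^2, (xs - cxp[k])^2, "+"))
          covk <- pmin(pmax(r + 0.5 - dmat, 0), 1)  # anti-aliased edge
          cov_mat[y0:y1, x0:x1] <- pmin(1, cov_mat[y0:y1, x0:x1] + covk)
        }
      }
    }
    out <- background + (cell_intensity - background) * cov_mat
    if (noise_sd > 0) out <- out + rnorm(length(out), 0, noise_sd)
    matrix(pmin(pmax(out, 0), 1), ny, nx)
  })

  truth_labels <- tibble(
    area = seq_along(areas),
    name = vapply(seq_along(areas),
                  function(i) areas[[i]]$name %||% paste0("area", i), ""),
    arc_from_um = edges[-length(edges)],
    arc_to_um = edges[-1]
  )
  structure(
    list(image = img, geometry = geometry, pixel_size_um = ps,
         areas = areas, truth_borders_um = border_arclengths,
         truth_labels = truth_labels, seed = as.integer(seed)),
    class = "synthetic_section"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_section <- function(x, ...) {
  cat("<synthetic_section>", paste(dim(x$image), collapse = " x "), "px,",
      length(x$areas), "area(s),", length(x$truth_borders_um), "true border(s)\n")
  invisible(x)
}

#' Generate a stack of adjacent serial sections
#'
#' Renders `n_sections` sections of the same ribbon whose true border
#' positions jitter independently per section within
#' `+/- border_jitter_um` around the base positions, emulating the
#' near-constant border locations seen across adjacent serial sections.
#'
#' @inheritParams render_section
#' @param n_sections number of sections (>= 1).
#' @param border_jitter_um half-width of the uniform jitter applied to each
#'   border position per section.
#' @param ... further arguments passed to [render_section()].
#' @return list of `synthetic_section` objects; each carries its own jittered
#'   `truth_borders_um`.
#' @export
make_stack <- function(geometry, areas, border_arclengths, n_sections = 3,
                       border_jitter_um = 0, seed = 1L, ...) {
  if (!is_number(n_sections) || n_sections < 1) abort("`n_sections` must be >= 1.")
  arc_total <- max(polyline_arclength(geometry$outer))
  lapply(seq_len(n_sections), function(s) {
    sseed <- child_seed(seed, s)
    jit <- withr::with_seed(sseed, {
      if (border_jitter_um > 0 && length(border_arclengths)) {
        runif(length(border_arclengths), -border_jitter_um, border_jitter_um)
      } else rep(0, length(border_arclengths))
    })
    pos <- pmin(pmax(border_arclengths + jit, 1e-6), arc_total - 1e-6)
    sec <- render_section(geometry, areas, pos, seed = child_seed(sseed, 1L), ...)
    sec$section_id <- s
    sec
  })
}
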