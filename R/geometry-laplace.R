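#' Solve the Laplace equation between the cortical contours
#'
#' Computes the scalar potential phi on the ribbon between the outer
#' (layer I/II) and inner (layer VI/white matter) contours with Dirichlet
#' conditions phi = 0 on the outer and phi = 1 on the inner contour and
#' zero-flux (reflecting) conditions on the ribbon's lateral open ends.
#' Field lines of this potential are the curvilinear traverses running
#' perpendicular to the cortical layers. Solved by red-black successive
#' over-relaxation on a regular grid.
#'
#' @param geometry a [ribbon_geometry()] (or pass `outer`/`inner` matrices).
#' @param grid_res_um grid cell size in micrometres.
#' @param tol convergence tolerance: maximum absolute update per sweep.
#' @param max_iter maximum number of sweeps.
#' @param omega SOR relaxation factor (1 < omega < 2).
#' @param outer,inner contour matrices, used when `geometry` is missing.
#' @return an object of class `potential_field`: `phi` (matrix, NA outside
#'   the ribbon), `mask`, `fixed` (Dirichlet cells), `origin_um`,
#'   `grid_res_um`, `residual`, `converged`, `iterations`, `geometry`.
#' @export
solve_laplace <- function(geometry = NULL, grid_res_um = 5, tol = 1e-5,
                          max_iter = 20000, omega = 1.9,
                          outer = NULL, inner = NULL) {
  if (is.null(geometry)) geometry <- ribbon_geometry(outer, inner)
  stopifnot(inherits(geometry, "ribbon_geometry"))
  stop_if_not_number(grid_res_um, "grid_res_um", positive = TRUE)
  res <- grid_res_um

  allpts <- rbind(geometry$outer, geometry$inner)
  x0 <- min(allpts[, 1]) - 2 * res
  y0 <- min(allpts[, 2]) - 2 * res
  nx <- ceiling((max(allpts[, 1]) - x0) / res) + 2L
  ny <- ceiling((max(allpts[, 2]) - y0) / res) + 2L

  cxs <- x0 + (seq_len(nx) - 0.5) * res
  cys <- y0 + (seq_len(ny) - 0.5) * res
  px <- rep(cxs, each = ny)
  py <- rep(cys, times = nx)
  poly <- rbind(geometry$outer,
                geometry$inner[rev(seq_len(nrow(geometry$inner))), ])
  mask <- matrix(point_in_polygon(px, py, poly), ny, nx)

  # rasterize Dirichlet contours: mark every cell the polyline passes through
  raster_cells <- function(pts) {
    al <- polyline_arclength(pts)
    s <- seq(0, al[length(al)], by = res / 3)
    p <- polyline_point_at(pts, s)
    i <- pmin(pmax(ceiling((p[, 2] - y0) / res), 1L), ny)
    j <- pmin(pmax(ceiling((p[, 1] - x0) / res), 1L), nx)
    unique(cbind(i, j))
  }
  out_cells <- raster_cells(geometry$outer)
  in_cells <- raster_cells(geometry$inner)

  fixed <- matrix(FALSE, ny, nx)
  phi <- matrix(0, ny, nx)
  fixed[out_cells] <- TRUE
  phi[in_cells] <- 1
  fixed[in_cells] <- TRUE
  mask[out_cells] <- TRUE
  mask[in_cells] <- TRUE
  if (!any(mask & !fixed)) abort("no interior cells: ribbon not enclosed at this grid resolution.")

  # initialize interior with distance-based guess to speed convergence
  interior <- mask & !fixed
  if (any(interior)) {
    ii <- which(interior)
    pxi <- x0 + (((ii - 1L) %/% ny) + 0.5) * res
    pyi <- y0 + (((ii - 1L) %% ny) + 0.5) * res
    d_o <- dist_to_polyline(pxi, pyi, geometry$outer)
    d_i <- dist_to_polyline(pxi, pyi, geometry$inner)
    phi[ii] <- d_o / (d_o + d_i)
  }

  color <- (row(phi) + col(phi)) %% 2 == 0
  upd_r <- interior & color
  upd_b <- interior & !color
  maskn <- mask * 1

  nb_mean <- function(p) {
    # mean over in-mask 4-neighbors; missing neighbors reflect (zero flux)
    S <- matrix(0, ny, nx); cnt <- matrix(0, ny, nx)
    S[-1, ] <- S[-1, ] + p[-ny, ] * maskn[-ny, ]; cnt[-1, ] <- cnt[-1, ] + maskn[-ny, ]
    S[-ny, ] <- S[-ny, ] + p[-1, ] * maskn[-1, ]; cnt[-ny, ] <- cnt[-ny, ] + maskn[-1, ]
    S[, -1] <- S[, -1] + p[, -nx] * maskn[, -nx]; cnt[, -1] <- cnt[, -1] + maskn[, -nx]
    S[, -nx] <- S[, -nx] + p[, -1] * maskn[, -1]; cnt[, -nx] <- cnt[, -nx] + maskn[, -1]
    S / pmax(cnt, 1)
  }

  residual <- Inf
  it <- 0L
  while (it < max_iter && residual > tol) {
    it <- it + 1L
    old <- phi
    m <- nb_mean(phi)
    phi[upd_r] <- (1 - omega) * phi[upd_r] + omega * m[upd_r]
    m <- nb_mean(phi)
    phi[upd_b] <- (1 - omega) * phi[upd_b] + omega * m[upd_b]
    residual <- max(abs(phi[interior] - old[interior]))
  }
  converged <- residual <= tol
  if (!converged) {
    warn(sprintf("Laplace solve hit max_iter = %d (residual %.2e > tol %.2e).",
                 max_iter, residual, tol))
  }
  phi_out <- phi
  phi_out[!mask] <- NA_real_
  structure(list(phi = phi_out, mask = mask, fixed = fixed,
                 origin_um = c(x0, y0), grid_res_um = res,
                 residual = residual, converged = converged, iterations = it,
                 geometry = geometry),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat("<potential_field>", paste(dim(x$phi), collapse = " x "), "grid at",
      x$grid_res_um, "um;", x$iterations, "sweeps; residual",
      format(x$residual, digits = 3),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

# Bilinear interpolation of a grid quantity at um coordinates.
# NA corners fall back to the mean of available corners; all-NA -> NA.
interp_grid <- function(grid, origin_um, res, x, y) {
  ny <- nrow(grid); nx <- ncol(grid)
  gx <- (x - origin_um[1]) / res + 0.5  # fractional column index
  gy <- (y - origin_um[2]) / res + 0.5
  j0 <- floor(gx); i0 <- floor(gy)
  fx <- gx - j0; fy <- gy - i0
  j0 <- pmin(pmax(j0, 1), nx - 1); i0 <- pmin(pmax(i0, 1), ny - 1)
  v00 <- grid[cbind(i0, j0)]; v01 <- grid[cbind(i0, j0 + 1)]
  v10 <- grid[cbind(i0 + 1, j0)]; v11 <- grid[cbind(i0 + 1, j0 + 1)]
  w00 <- (1 - fx) * (1 - fy); w01 <- fx * (1 - fy)
  w10 <- (1 - fx) * fy; w11 <- fx * fy
  V <- cbind(v00, v01, v10, v11)
  W <- cbind(w00, w01, w10, w11)
  W[is.na(V)] <- 0
  V[is.na(V)] <- 0
  tot <- rowSums(W)
  out <- rowSums(V * W) / tot
  out[tot == 0] <- NA_real_
  out
}

# Gradient grids of phi (per um), one-sided at mask boundaries.
field_gradient <- function(field) {
  phi <- field$phi; res <- field$grid_res_um
  ny <- nrow(phi); nx <- ncol(phi)
  pad <- function(m, dr, dc) {
    out <- matrix(NA_real_, ny, nx)
    rs <- seq_len(ny) + dr; cs <- seq_len(nx) + dc
    ok_r <- rs >= 1 & rs <= ny; ok_c <- cs >= 1 & cs <= nx
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  right <- pad(phi, 0, 1); left <- pad(phi, 0, -1)
  down <- pad(phi, 1, 0); up <- pad(phi, -1, 0)
  gx <- (right - left) / (2 * res)
  gx[is.na(gx)] <- ((right - phi) / res)[is.na(gx)]
  gx[is.na(gx)] <- ((phi - left) / res)[is.na(gx)]
  gy <- (down - up) / (2 * res)
  gy[is.na(gy)] <- ((down - phi) / res)[is.na(gy)]
  gy[is.na(gy)] <- ((phi - up) / res)[is.na(gy)]
  list(gx = gx, gy = gy)
}

#' Trace cortical traverses as field lines of the potential
#'
#' Seeds points at equal arc-length spacing on the outer contour and
#' integrates the normalized gradient of phi (fixed-step midpoint scheme,
#' step = grid resolution / 2) from phi ~ 0 until phi >= 1 - eps near the
#' inner contour. Traverses whose gradient vanishes or that exit the ribbon
#' before reaching the inner contour are flagged and excluded with a
#' warning; retained traverses are re-indexed consecutively along the
#' contour (original seed ranks kept in `seed_index`).
#'
#' @param field a converged [solve_laplace()] result.
#' @param n_traverses number of seeds, or give `seed_spacing_um`.
#' @param seed_spacing_um alternative to `n_traverses`: arc-length spacing.
#' @param eps termination band: integration stops at phi >= 1 - eps.
#' @param min_phi_reached traverses ending below this phi are excluded.
#' @return an object of class `traverse_set`: list with `traverses` (list;
#'   each has `points` (m x 2, um), `index`, `seed_index`,
#'   `seed_arclength_um`, `length_um`), `excluded` (seed indices),
#'   and the generating `field`.
#' @export
trace_traverses <- function(field, n_traverses = NULL, seed_spacing_um = NULL,
                            eps = 1e-3, min_phi_reached = 0.95) {
  stopifnot(inherits(field, "potential_field"))
  if (!field$converged) abort("potential field did not converge; refuse to trace.")
  outer <- field$geometry$outer
  total <- max(polyline_arclength(outer))
  if (is.null(n_traverses) && is.null(seed_spacing_um)) {
    abort("give `n_traverses` or `seed_spacing_um`.")
  }
  if (is.null(n_traverses)) n_traverses <- max(2L, floor(total / seed_spacing_um) + 1L)
  seeds_s <- seq(0, total, length.out = n_traverses + 2L)[-c(1L, n_traverses + 2L)]
  seeds <- polyline_point_at(outer, seeds_s)

  g <- field_gradient(field)
  res <- field$grid_res_um
  h <- res / 2
  maxsteps <- ceiling(6 * (nrow(field$phi) + ncol(field$phi)))

  grad_at <- function(x, y) {
    c(interp_grid(g$gx, field$origin_um, res, x, y),
      interp_grid(g$gy, field$origin_um, res, x, y))
  }
  phi_at <- function(x, y) interp_grid(field$phi, field$origin_um, res, x, y)

  traverses <- list()
  excluded <- integer(0)
  for (k in seq_len(n_traverses)) {
    p <- seeds[k, ]
    pts <- matrix(p, 1, 2)
    ok <- TRUE
    reached <- FALSE
    for (step in seq_len(maxsteps)) {
      cur_phi <- phi_at(p[1], p[2])
      if (!is.na(cur_phi) && cur_phi >= 1 - eps) { reached <- TRUE; break }
      g1 <- grad_at(p[1], p[2])
      n1 <- sqrt(sum(g1^2))
      if (is.na(n1) || n1 < 1e-12) { ok <- FALSE; break }
      g1 <- g1 / n1
      pm <- p + (h / 2) * g1
      g2 <- grad_at(pm[1], pm[2])
      n2 <- sqrt(sum(g2^2))
      if (is.na(n2) || n2 < 1e-12) g2 <- g1 else g2 <- g2 / n2
      p <- p + h * g2
      pts <- rbind(pts, p)
      if (step == maxsteps) ok <- FALSE
    }
    end_phi <- phi_at(p[1], p[2])
    if (!ok || is.na(end_phi) || end_phi < min_phi_reached) {
      excluded <- c(excluded, k)
      next
    }
    if (reached && nrow(pts) >= 2) {
      # refine the endpoint: clip the last step to the phi = 1 - eps crossing
      a <- pts[nrow(pts) - 1L, ]; bpt <- pts[nrow(pts), ]
      lo <- 0; hi <- 1
      for (bis in 1:12) {
        mid <- (lo + hi) / 2
        q <- a + mid * (bpt - a)
        qphi <- phi_at(q[1], q[2])
        if (is.na(qphi) || qphi >= 1 - eps) hi <- mid else lo <- mid
      }
      pts[nrow(pts), ] <- a + hi * (bpt - a)
    }
    traverses[[length(traverses) + 1L]] <- list(
      points = unname(pts), seed_index = k,
      seed_arclength_um = seeds_s[k],
      length_um = sum(sqrt(rowSums(diff(pts)^2)))
    )
  }
  if (length(excluded)) {
    warn(sprintf("%d traverse(s) excluded (vanishing gradient or ribbon exit): seeds %s",
                 length(excluded), paste(excluded, collapse = ", ")))
  }
  for (i in seq_along(traverses)) traverses[[i]]$index <- i
  structure(list(traverses = traverses, excluded = excluded, field = field),
            class = "traverse_set")
}

#' @export
print.traverse_set <- function(x, ...) {
  lens <- vapply(x$traverses, `[[`, 0, "length_um")
  cat("<traverse_set>", length(x$traverses), "traverses (",
      length(x$excluded), "excluded ); mean length",
      signif(mean(lens), 4), "um\n")
  invisible(x)
}

#' @export
as_tibble.traverse_set <- function(x, ...) {
  purrr::map_dfr(x$traverses, function(tr) {
    tibble(index = tr$index, point = seq_len(nrow(tr$points)),
           x = tr$points[, 1], y = tr$points[, 2])
  })
}

#' Map outer-contour arc-length positions to traverse indices
#'
#' Ground-truth border positions are recorded in micrometres of arc length
#' along the outer contour; profile-level statistics work in traverse
#' (profile) indices. This maps each arc-length position to the index of
#' the traverse with the nearest seed point.
#'
#' @param arclength_um numeric vector of positions (um).
#' @param traverses a [trace_traverses()] result.
#' @return integer vector of traverse indices.
#' @export
arclength_to_traverse <- function(arclength_um, traverses) {
  seeds <- vapply(traverses$traverses, `[[`, 0, "seed_arclength_um")
  vapply(arclength_um, function(s) which.min(abs(seeds - s)), 0L)
}
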