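#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero, the
#' convention used when comparing computed aggregates against printed tables
#' (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# scalar numeric check
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_if_not_number <- function(x, name, positive = FALSE) {
  if (!is_number(x)) abort(sprintf("`%s` must be a single finite number.", name))
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}

# Vectorized even-odd point-in-polygon test.
# px, py: query points; poly: closed or open matrix of vertices (n x 2),
# treated as closed. Points exactly on an edge may fall on either side;
# callers rasterizing masks follow with an explicit boundary pass.
point_in_polygon <- function(px, py, poly) {
  nv <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  j <- c(nv, seq_len(nv - 1L))
  inside <- rep(FALSE, length(px))
  for (i in seq_len(nv)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j[i]]; yj <- ys[j[i]]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) * (xj - xi) / (yj - yi)
      flip <- px[crosses] < xint
      idx <- which(crosses)[flip]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

# Cumulative arc length of an n x 2 polyline, starting at 0.
polyline_arclength <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  seg <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(seg))
}

# Resample a polyline at given arc-length positions (linear interpolation).
polyline_point_at <- function(pts, s) {
  al <- polyline_arclength(pts)
  s <- pmin(pmax(s, 0), al[length(al)])
  x <- stats::approx(al, pts[, 1], xout = s, ties = "ordered")$y
  y <- stats::approx(al, pts[, 2], xout = s, ties = "ordered")$y
  cbind(x, y)
}

# Minimum distance from points (px, py) to a polyline (n x 2).
# Vectorized over points, loops over segments.
dist_to_polyline <- function(px, py, pts) {
  best <- rep(Inf, length(px))
  for (i in seq_len(nrow(pts) - 1L)) {
    ax <- pts[i, 1]; ay <- pts[i, 2]
    bx <- pts[i + 1L, 1]; by <- pts[i + 1L, 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d <- sqrt((px - ax)^2 + (py - ay)^2)
    } else {
      t <- pmin(pmax(((px - ax) * dx + (py - ay) * dy) / len2, 0), 1)
      d <- sqrt((px - ax - t * dx)^2 + (py - ay - t * dy)^2)
    }
    best <- pmin(best, d)
  }
  best
}

# Arc-length position on a polyline of the foot point nearest to each query
# point. Returns the arc length (not the distance).
arclength_of_nearest <- function(px, py, pts) {
  al <- polyline_arclength(pts)
  best <- rep(Inf, length(px))
  bests <- rep(0, length(px))
  for (i in seq_len(nrow(pts) - 1L)) {
    ax <- pts[i, 1]; ay <- pts[i, 2]
    bx <- pts[i + 1L, 1]; by <- pts[i + 1L, 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(pmax(((px - ax) * dx + (py - ay) * dy) / len2, 0), 1)
    d2 <- (px - ax - t * dx)^2 + (py - ay - t * dy)^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    bests[upd] <- al[i] + t[upd] * sqrt(len2)
  }
  bests
}

# Do two polylines (open) intersect? Standard segment-pair orientation test.
polylines_intersect <- function(a, b) {
  orient <- function(px, py, qx, qy, rx, ry) {
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  }
  for (i in seq_len(nrow(a) - 1L)) {
    for (j in seq_len(nrow(b) - 1L)) {
      o1 <- orient(a[i, 1], a[i, 2], a[i + 1, 1], a[i + 1, 2], b[j, 1], b[j, 2])
      o2 <- orient(a[i, 1], a[i, 2], a[i + 1, 1], a[i + 1, 2], b[j + 1, 1], b[j + 1, 2])
      o3 <- orient(b[j, 1], b[j, 2], b[j + 1, 1], b[j + 1, 2], a[i, 1], a[i, 2])
      o4 <- orient(b[j, 1], b[j, 2], b[j + 1, 1], b[j + 1, 2], a[i + 1, 1], a[i + 1, 2])
      if (o1 != o2 && o3 != o4) return(TRUE)
    }
  }
  FALSE
}

# Derive a reproducible child seed from a base seed and an index; kept below
# 2^31 so it is a valid R integer.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 1299721) %% 2147483647)
}
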