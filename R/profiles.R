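#' Extract a depth-normalized GLI profile along one traverse
#'
#' Samples the GLI map by bilinear interpolation at `n_points` equally
#' spaced arc-length positions along the traverse and rescales the depth
#' axis to 0-100% cortical depth, so profiles from cortex of different
#' thickness are comparable.
#'
#' @param gli a [compute_gli()] result.
#' @param traverse one traverse (element of a [trace_traverses()] result's
#'   `traverses` list).
#' @param n_points number of equidistant depth samples (default 101).
#' @return a tibble with columns `traverse_index`, `depth` (percent, 0-100)
#'   and `gli`.
#' @export
extract_profile <- function(gli, traverse, n_points = 101) {
  stopifnot(inherits(gli, "gli_map"))
  vals <- extract_profile_values(gli, traverse, n_points)
  tibble(traverse_index = traverse$index %||% NA_integer_,
         depth = seq(0, 100, length.out = n_points), gli = vals)
}

# numeric workhorse shared by extract_profile/extract_profiles
extract_profile_values <- function(gli, traverse, n_points) {
  res <- gli$field_size_px * gli$pixel_size_um
  al <- polyline_arclength(traverse$points)
  s <- seq(0, al[length(al)], length.out = n_points)
  p <- polyline_point_at(traverse$points, s)
  out_of_map <- p[, 1] < 0 | p[, 1] > ncol(gli$values) * res |
    p[, 2] < 0 | p[, 2] > nrow(gli$values) * res
  v <- interp_grid(gli$values, c(0, 0), res, p[, 1], p[, 2])
  v[out_of_map] <- NA_real_
  if (any(is.na(v))) {
    abort(sprintf("traverse %s exits the GLI map footprint.",
                  traverse$index %||% "?"))
  }
  v
}

#' Extract profiles for a whole traverse set
#'
#' @inheritParams extract_profile
#' @param traverses a [trace_traverses()] result.
#' @param section_id carried into the result for multi-section bookkeeping.
#' @return a `profile_set` (see [simulate_section_profiles()] for the
#'   structure): matrix of profiles ordered by traverse index.
#' @export
extract_profiles <- function(gli, traverses, n_points = 101, section_id = 1L) {
  stopifnot(inherits(traverses, "traverse_set"))
  if (!length(traverses$traverses)) abort("no traverses to sample.")
  values <- do.call(rbind, lapply(traverses$traverses, function(tr) {
    extract_profile_values(gli, tr, n_points)
  }))
  structure(list(values = values,
                 depths = seq(0, 100, length.out = n_points),
                 truth_borders = integer(0), section_id = section_id),
            class = "profile_set")
}

#' Pointwise mean GLI profile
#'
#' Arithmetic mean over a set of equally sampled profiles, the quantity
#' used to characterize an area (typically 15-20 profiles from three
#' sections per area, hemisphere and brain).
#'
#' @param profiles a `profile_set`, or a numeric matrix (profiles in rows).
#' @return a tibble with columns `depth` and `gli`.
#' @export
mean_profile <- function(profiles) {
  if (inherits(profiles, "profile_set")) {
    depths <- profiles$depths
    m <- profiles$values
  } else if (is.matrix(profiles)) {
    m <- profiles
    depths <- seq(0, 100, length.out = ncol(m))
  } else {
    abort("`profiles` must be a profile_set or a numeric matrix.")
  }
  if (nrow(m) < 1) abort("empty profile set.")
  tibble(depth = depths, gli = colMeans(m))
}

#' Sliding-window profile block layout
#'
#' For each tested border position `k` the two adjacent blocks are the `b`
#' profiles ending just before `k` and the `b` profiles starting at `k`:
#' left block `[k - b, k - 1]`, right block `[k, k + b - 1]` (1-based).
#' Standard runs restrict the block size to 12-30 profiles.
#'
#' @param n_profiles number of profiles available.
#' @param b block size.
#' @param standard enforce the standard 12-30 block-size range.
#' @return a tibble with columns `position`, `left_from`, `left_to`,
#'   `right_from`, `right_to`.
#' @export
build_blocks <- function(n_profiles, b, standard = TRUE) {
  if (!is_number(b) || b < 1) abort("`b` must be a positive integer.")
  if (standard && (b < 12 || b > 30)) {
    abort(sprintf("block size b = %d outside the standard 12-30 range (set standard = FALSE to override).", b))
  }
  if (n_profiles < 2 * b) {
    abort(sprintf("need at least 2b = %d profiles, got %d.", 2 * b, n_profiles))
  }
  k <- seq.int(b + 1L, n_profiles - b + 1L)
  tibble(position = k, left_from = k - b, left_to = k - 1L,
         right_from = k, right_to = k + b - 1L)
}
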