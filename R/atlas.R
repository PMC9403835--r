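#' Per-area probability map from multi-subject label volumes
#'
#' The probability at a voxel is the fraction of subjects whose label at
#' that voxel equals the area id — the voxelwise subject overlap after
#' registration to a common space.
#'
#' @param volumes list of 3D integer label arrays (0 = background), all of
#'   the same dimensions, or a `synthetic_cohort` (its subjects are used).
#' @param area area id.
#' @param voxel_size_mm voxel edge lengths (taken from a cohort input).
#' @return an object of class `probability_map`: list with `prob` (3D array
#'   of fractions), `area`, `n_subjects`, `voxel_size_mm`.
#' @export
probability_map <- function(volumes, area, voxel_size_mm = 1) {
  if (inherits(volumes, "synthetic_cohort")) {
    voxel_size_mm <- volumes$voxel_size_mm
    volumes <- volumes$subjects
  }
  if (!length(volumes)) abort("no volumes given.")
  dims <- dim(volumes[[1]])
  ok <- vapply(volumes, function(v) identical(dim(v), dims), TRUE)
  if (!all(ok)) abort("all label volumes must share the same dimensions.")
  acc <- array(0, dims)
  for (v in volumes) acc <- acc + (v == area)
  structure(list(prob = acc / length(volumes), area = area,
                 n_subjects = length(volumes),
                 voxel_size_mm = rep(voxel_size_mm, length.out = 3)),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat("<probability_map> area", x$area, "over", x$n_subjects, "subjects; ",
      sum(x$prob > 0), "voxels with p > 0\n")
  invisible(x)
}

#' Maximum probability map (winner-take-all parcellation)
#'
#' Assigns every voxel to the area with the highest probability among those
#' exceeding `min_prob_threshold`; voxels where no area exceeds the
#' threshold stay unassigned (0). Ties are broken by (1) the higher mean
#' probability over the voxel's 26-neighborhood, then (2) the lower area
#' id; the number of voxels decided at each stage is reported.
#'
#' @param pmaps list of [probability_map()]s over the same grid.
#' @param min_prob_threshold probabilities must exceed this to compete.
#' @return an object of class `mpm_volume`: list with `labels` (3D integer
#'   array, 0 = unassigned), `winning_prob` (3D array), `areas`,
#'   `tie_report` (tibble: ties_total, ties_by_neighborhood, ties_by_id).
#' @export
maximum_probability_map <- function(pmaps, min_prob_threshold = 0) {
  if (!length(pmaps)) abort("no probability maps given.")
  dims <- dim(pmaps[[1]]$prob)
  areas <- vapply(pmaps, `[[`, 0, "area")
  P <- vapply(pmaps, function(p) {
    if (!identical(dim(p$prob), dims)) abort("probability maps are not aligned.")
    p$prob
  }, array(0, dims))
  P <- matrix(P, nrow = prod(dims))  # voxels x areas
  P[P <= min_prob_threshold] <- 0
  best <- apply(P, 1, max)
  n_best <- rowSums(P == best & best > 0)
  labels <- integer(prod(dims))
  clear <- best > 0 & n_best == 1
  labels[clear] <- areas[max.col(P[clear, , drop = FALSE], ties.method = "first")]

  ties <- which(best > 0 & n_best > 1)
  ties_nb <- 0L; ties_id <- 0L
  if (length(ties)) {
    nb_means <- neighborhood_mean(array(P, c(dims, length(areas))))
    nb_means <- matrix(nb_means, nrow = prod(dims))
    for (v in ties) {
      contenders <- which(P[v, ] == best[v])
      nb <- nb_means[v, contenders]
      top <- contenders[nb == max(nb)]
      if (length(top) == 1L) ties_nb <- ties_nb + 1L else ties_id <- ties_id + 1L
      labels[v] <- areas[min(top)]
    }
  }
  labels_arr <- array(labels, dims)
  if (all(areas == round(areas))) storage.mode(labels_arr) <- "integer"
  structure(list(labels = labels_arr,
                 winning_prob = array(best, dims), areas = areas,
                 tie_report = tibble(ties_total = length(ties),
                                     ties_by_neighborhood = ties_nb,
                                     ties_by_id = ties_id)),
            class = "mpm_volume")
}

# mean over the 26-neighborhood (center excluded) for each voxel of each
# area layer of a 4D array dims x n_areas
neighborhood_mean <- function(A4) {
  d <- dim(A4)
  nx <- d[1]; ny <- d[2]; nz <- d[3]; na <- d[4]
  S <- array(0, d); cnt <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- seq_len(nx) + dx; ys <- seq_len(ny) + dy; zs <- seq_len(nz) + dz
    okx <- xs >= 1 & xs <= nx; oky <- ys >= 1 & ys <= ny; okz <- zs >= 1 & zs <= nz
    S[okx, oky, okz, ] <- S[okx, oky, okz, ] + A4[xs[okx], ys[oky], zs[okz], , drop = FALSE]
    cnt[okx, oky, okz, ] <- cnt[okx, oky, okz, ] + 1
  }
  S / cnt
}

#' @export
print.mpm_volume <- function(x, ...) {
  cat("<mpm_volume>", paste(dim(x$labels), collapse = " x "), "voxels;",
      sum(x$labels > 0), "assigned;", x$tie_report$ties_total, "tie(s)\n")
  invisible(x)
}

#' Centre of gravity of a probability map or label mask
#'
#' Probability-weighted mean of voxel-centre coordinates in millimetres.
#' Coordinate convention: world mm = (0-based index + 0.5) * voxel size,
#' i.e. the first voxel's centre is at half a voxel.
#'
#' @param x a [probability_map()], or a 3D array of weights (e.g. a binary
#'   mask or `labels == k`).
#' @param voxel_size_mm voxel size (taken from a probability map input).
#' @return a tibble with columns `x`, `y`, `z` (mm) and `weight` (total).
#' @export
center_of_gravity <- function(x, voxel_size_mm = 1) {
  if (inherits(x, "probability_map")) {
    voxel_size_mm <- x$voxel_size_mm
    x <- x$prob
  }
  voxel_size_mm <- rep(voxel_size_mm, length.out = 3)
  w <- as.vector(x)
  tot <- sum(w)
  if (tot <= 0) abort("empty support: centre of gravity undefined.")
  d <- dim(x)
  idx <- arrayInd(seq_along(w), d)
  cog_vox <- colSums(idx * w) / tot  # 1-based index mean
  tibble(x = (cog_vox[1] - 0.5) * voxel_size_mm[1],
         y = (cog_vox[2] - 0.5) * voxel_size_mm[2],
         z = (cog_vox[3] - 0.5) * voxel_size_mm[3],
         weight = tot)
}

#' Centre-of-gravity table for a cohort parcellation
#'
#' Convenience wrapper producing one row per area from a list of
#' probability maps, in the column layout of a stereotaxic
#' centre-of-gravity table.
#'
#' @param pmaps list of [probability_map()]s.
#' @return tibble: `area`, `x`, `y`, `z` (mm).
#' @export
cog_table <- function(pmaps) {
  purrr::map_dfr(pmaps, function(p) {
    dplyr::bind_cols(tibble(area = p$area),
                     center_of_gravity(p)[, c("x", "y", "z")])
  })
}
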