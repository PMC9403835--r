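#' Generate a synthetic multi-subject cohort of area label volumes
#'
#' Emulates a post-mortem mapping cohort: each subject carries a 3D label
#' volume in one common voxel space in which every area is a connected
#' ellipsoidal blob, randomly perturbed around a shared template, plus a
#' fresh / histologically processed whole-brain volume pair for shrinkage
#' correction. Default design is 10 subjects with alternating male/female
#' sex assignment (5/5).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_areas number of areas (adjacent blobs along one axis).
#' @param dim grid dimensions (3 integers).
#' @param voxel_size_mm voxel edge lengths (scalar or length 3), mm.
#' @param area_shape_variability SD (in voxels) of the random displacement
#'   of each area's blob centre per subject; blob radii jitter
#'   proportionally. 0 makes all subjects identical.
#' @param shrinkage_range range of fresh/processed volume ratios.
#' @param fresh_volume_mean_mm3,fresh_volume_sd_mm3 distribution of fresh
#'   whole-brain volumes (defaults around 1.24 litres, the scale of adult
#'   human brains).
#' @param seed integer seed.
#' @return an object of class `synthetic_cohort`: list with `subjects`
#'   (list of 3D integer label arrays, 0 = background), `sex` (factor),
#'   `area_ids`, `voxel_size_mm`, and `volumes` (tibble: subject, sex,
#'   fresh_volume_mm3, processed_volume_mm3, shrinkage_factor).
#' @export
make_cohort <- function(n_subjects = 10, n_areas = 4, dim = c(24, 24, 24),
                        voxel_size_mm = 1, area_shape_variability = 1,
                        shrinkage_range = c(1.5, 2.5),
                        fresh_volume_mean_mm3 = 1.24e6,
                        fresh_volume_sd_mm3 = 1.2e5,
                        seed = 1L) {
  if (!is_number(n_subjects) || n_subjects < 2) abort("`n_subjects` must be >= 2.")
  if (length(dim) != 3L) abort("`dim` must have length 3.")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3)
  dim <- as.integer(dim)

  # template: n_areas ellipsoids spread along x, centred in y/z
  cx <- seq(dim[1] / (n_areas + 1), dim[1] * n_areas / (n_areas + 1),
            length.out = n_areas)
  centres0 <- cbind(cx, dim[2] / 2, dim[3] / 2)
  radii0 <- matrix(rep(c(dim[1] / (2.5 * n_areas), dim[2] / 4, dim[3] / 4),
                       each = n_areas), n_areas, 3)

  ix <- seq_len(dim[1]); iy <- seq_len(dim[2]); iz <- seq_len(dim[3])
  gx <- array(rep(ix, times = dim[2] * dim[3]), dim)
  gy <- array(rep(rep(iy, each = dim[1]), times = dim[3]), dim)
  gz <- array(rep(iz, each = dim[1] * dim[2]), dim)

  sex <- factor(rep(c("male", "female"), length.out = n_subjects),
                levels = c("male", "female"))

  res <- withr::with_seed(as.integer(seed), {
    subjects <- vector("list", n_subjects)
    fresh <- pmax(5e5, rnorm(n_subjects, fresh_volume_mean_mm3, fresh_volume_sd_mm3))
    factors <- runif(n_subjects, shrinkage_range[1], shrinkage_range[2])
    for (s in seq_len(n_subjects)) {
      centres <- centres0 +
        matrix(rnorm(n_areas * 3, 0, area_shape_variability), n_areas, 3)
      radii <- radii0 *
        exp(matrix(rnorm(n_areas * 3, 0, 0.05 * area_shape_variability),
                   n_areas, 3))
      # normalized squared ellipsoid distance per area; winner = nearest
      best_d <- array(Inf, dim)
      labels <- array(0L, dim)
      for (a in seq_len(n_areas)) {
        d <- ((gx - centres[a, 1]) / radii[a, 1])^2 +
             ((gy - centres[a, 2]) / radii[a, 2])^2 +
             ((gz - centres[a, 3]) / radii[a, 3])^2
        take <- d <= 1 & d < best_d
        labels[take] <- a
        best_d[take] <- d[take]
      }
      subjects[[s]] <- labels
    }
    list(subjects = subjects, fresh = fresh, factors = factors)
  })

  structure(
    list(subjects = res$subjects, sex = sex, area_ids = seq_len(n_areas),
         voxel_size_mm = voxel_size_mm,
         volumes = tibble(
           subject = seq_len(n_subjects), sex = sex,
           fresh_volume_mm3 = res$fresh,
           processed_volume_mm3 = res$fresh / res$factors,
           shrinkage_factor = res$factors
         ),
         seed = as.integer(seed)),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", length(x$subjects), "subjects,",
      length(x$area_ids), "areas, grid",
      paste(dim(x$subjects[[1]]), collapse = " x "), "\n")
  invisible(x)
}
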