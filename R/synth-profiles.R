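#' Simulate GLI profiles of a cortical ribbon directly
#'
#' Profile-level counterpart of the raster renderer: draws depth-normalized
#' GLI profiles straight from the laminar density curves of the areas along
#' the ribbon, with additive Gaussian measurement noise. This is the
#' generator used for large statistical simulations (null calibration,
#' border-recovery power), where rendering and resampling thousands of
#' full-resolution images would add nothing to the quantity under test.
#'
#' @param areas list of [laminar_spec()]s ordered along the ribbon.
#' @param n_profiles number of profiles (traverse positions).
#' @param border_positions integer profile indices where area identity
#'   changes: the border at position `k` separates profiles `1..k-1` from
#'   `k..n` (same convention as the sliding-window border positions).
#' @param n_points depth samples per profile (default 101, i.e. 0-100%).
#' @param noise_sd per-sample Gaussian noise SD on the GLI scale.
#' @param smooth_sd laminar-transition smoothing passed to
#'   [make_laminar_profile()].
#' @param seed integer seed.
#' @return an object of class `profile_set`: list with `values`
#'   (n_profiles x n_points matrix in \[0, 1\]), `depths` (percent, 0-100),
#'   `truth_borders` (the border positions), `section_id`.
#' @export
simulate_section_profiles <- function(areas, n_profiles,
                                      border_positions = integer(0),
                                      n_points = 101, noise_sd = 0.05,
                                      smooth_sd = 0.02, seed = 1L) {
  if (inherits(areas, "laminar_spec")) areas <- list(areas)
  if (length(border_positions) != length(areas) - 1L) {
    abort("need length(areas) - 1 border positions.")
  }
  if (length(border_positions) &&
      (is.unsorted(border_positions, strictly = TRUE) ||
       any(border_positions < 2) || any(border_positions > n_profiles))) {
    abort("`border_positions` must be strictly increasing indices in 2..n_profiles.")
  }
  curves <- lapply(areas, function(a) make_laminar_profile(a, n_points, smooth_sd)$density)
  edges <- c(1, border_positions, n_profiles + 1)
  owner <- findInterval(seq_len(n_profiles), edges, rightmost.closed = FALSE)
  owner <- pmin(owner, length(areas))
  values <- withr::with_seed(as.integer(seed), {
    v <- do.call(rbind, lapply(owner, function(a) curves[[a]]))
    v <- v + matrix(rnorm(length(v), 0, noise_sd), nrow(v), ncol(v))
    pmin(pmax(v, 0), 1)
  })
  structure(list(values = values, depths = seq(0, 100, length.out = n_points),
                 truth_borders = as.integer(border_positions),
                 section_id = 1L, seed = as.integer(seed)),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat("<profile_set>", nrow(x$values), "profiles x", ncol(x$values),
      "depth samples;", length(x$truth_borders), "true border(s)\n")
  invisible(x)
}

#' @export
as_tibble.profile_set <- function(x, ...) {
  n <- nrow(x$values)
  tibble(
    profile = rep(seq_len(n), each = length(x$depths)),
    depth = rep(x$depths, times = n),
    gli = as.vector(t(x$values))
  )
}

#' Simulate a stack of serial sections at the profile level
#'
#' Generates `n_sections` adjacent [simulate_section_profiles()] draws whose
#' true border positions jitter independently per section by at most
#' `jitter_profiles` profile indices, emulating the near-constant border
#' positions across adjacent serial sections.
#'
#' @inheritParams simulate_section_profiles
#' @param n_sections number of sections.
#' @param jitter_profiles maximum absolute integer jitter per section.
#' @return list of `profile_set` objects with per-section `truth_borders`
#'   and `section_id`.
#' @export
simulate_profile_stack <- function(areas, n_profiles,
                                   border_positions = integer(0),
                                   n_sections = 5, jitter_profiles = 2,
                                   n_points = 101, noise_sd = 0.05,
                                   smooth_sd = 0.02, seed = 1L) {
  lapply(seq_len(n_sections), function(s) {
    sseed <- child_seed(seed, s)
    jit <- withr::with_seed(sseed, {
      if (jitter_profiles > 0 && length(border_positions)) {
        sample(seq(-jitter_profiles, jitter_profiles),
               length(border_positions), replace = TRUE)
      } else rep(0L, length(border_positions))
    })
    pos <- pmin(pmax(border_positions + jit, 2L), n_profiles)
    ps <- simulate_section_profiles(areas, n_profiles, pos, n_points,
                                    noise_sd, smooth_sd,
                                    seed = child_seed(sseed, 1L))
    ps$section_id <- s
    ps
  })
}
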