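#' Ten-feature shape parameterization of GLI profiles
#'
#' Treats a profile y(x) as a frequency distribution over cortical depth x
#' (percent) and computes five depth-weighted shape parameters — mean
#' amplitude, centre-of-gravity depth, standard deviation, skewness and
#' kurtosis — for the profile itself and for the absolute first derivative
#' (central differences, one-sided at the ends). The resulting
#' 10-dimensional feature vector is the unit of statistical comparison for
#' border detection.
#'
#' Conventions: the mean amplitude is the plain average of y; the remaining
#' four are moments of depth weighted by y. If the weighted SD is zero the
#' skewness and kurtosis are set to 0. A derivative that is identically
#' zero (constant profile) gets centre of gravity at mid-depth and zero
#' spread by the same convention.
#'
#' @param profiles a `profile_set`, a numeric matrix (profiles in rows), or
#'   a single numeric profile vector.
#' @param depths depth axis (percent); defaults to an equidistant 0-100
#'   grid, or the set's own axis.
#' @param derivative `"absolute"` (default) to use |y'| for the derivative
#'   moments, `"signed"` to use y' as is.
#' @return a tibble with one row per profile: `profile` plus the 10
#'   features `gli_mean`, `gli_cog`, `gli_sd`, `gli_skew`, `gli_kurt`,
#'   `deriv_mean`, `deriv_cog`, `deriv_sd`, `deriv_skew`, `deriv_kurt`.
#' @export
#' @examples
#' profile_features(c(0.2, 0.4, 0.6, 0.4, 0.2), depths = c(0, 25, 50, 75, 100))
profile_features <- function(profiles, depths = NULL,
                             derivative = c("absolute", "signed")) {
  derivative <- match.arg(derivative)
  if (inherits(profiles, "profile_set")) {
    depths <- profiles$depths
    m <- profiles$values
  } else if (is.matrix(profiles)) {
    m <- profiles
  } else if (is.numeric(profiles)) {
    m <- matrix(profiles, nrow = 1)
  } else {
    abort("`profiles` must be a profile_set, matrix or numeric vector.")
  }
  p <- ncol(m)
  if (p < 5) abort("profiles need at least 5 points.")
  if (is.null(depths)) depths <- seq(0, 100, length.out = p)
  if (length(depths) != p) abort("`depths` length must match the profile length.")
  if (any(rowSums(m != 0) == 0)) {
    abort("all-zero profile: centre of gravity undefined.")
  }

  f_y <- weighted_moments(m, depths)
  dx <- diff(depths)
  d <- cbind((m[, 2] - m[, 1]) / dx[1],
             (m[, 3:p, drop = FALSE] - m[, 1:(p - 2), drop = FALSE]) /
               rep(dx[-1] + dx[-(p - 1)], each = nrow(m)),
             (m[, p] - m[, p - 1]) / dx[p - 1])
  if (derivative == "absolute") d <- abs(d)
  f_d <- weighted_moments(d, depths)

  out <- cbind(f_y, f_d)
  colnames(out) <- c("gli_mean", "gli_cog", "gli_sd", "gli_skew", "gli_kurt",
                     "deriv_mean", "deriv_cog", "deriv_sd", "deriv_skew",
                     "deriv_kurt")
  dplyr::bind_cols(tibble(profile = seq_len(nrow(m))), as_tibble(out))
}

# rows of m are weight functions over x; returns n x 5 matrix
# (mean amplitude, cog, sd, skewness, kurtosis)
weighted_moments <- function(m, x) {
  n <- nrow(m)
  m0 <- rowSums(m)
  mean_amp <- rowMeans(m)
  zero_w <- abs(m0) < 1e-300
  m0[zero_w] <- 1  # placeholder, fixed below
  m1 <- as.vector(m %*% x)
  m2 <- as.vector(m %*% x^2)
  m3 <- as.vector(m %*% x^3)
  m4 <- as.vector(m %*% x^4)
  c1 <- m1 / m0
  mu2 <- m2 / m0 - c1^2
  mu3 <- m3 / m0 - 3 * c1 * m2 / m0 + 2 * c1^3
  mu4 <- m4 / m0 - 4 * c1 * m3 / m0 + 6 * c1^2 * m2 / m0 - 3 * c1^4
  mu2 <- pmax(mu2, 0)
  s <- sqrt(mu2)
  g1 <- ifelse(s > 1e-12, mu3 / s^3, 0)
  g2 <- ifelse(s > 1e-12, mu4 / s^4, 0)
  c1[zero_w] <- mean(range(x))
  s[zero_w] <- 0; g1[zero_w] <- 0; g2[zero_w] <- 0
  cbind(mean_amp, c1, s, g1, g2)
}

#' Z-score a feature matrix across a profile set
#'
#' The ten features have incommensurate units, so before distance
#' computation each feature is standardized (zero mean, unit SD) across the
#' section's profile set. Constant features are mapped to 0.
#'
#' @param features tibble from [profile_features()] or a numeric matrix.
#' @return a numeric matrix (n x 10) of standardized features.
#' @export
standardize_features <- function(features) {
  m <- feature_matrix(features)
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  sdv[sdv < 1e-300] <- 1
  sweep(sweep(m, 2, mu), 2, sdv, "/")
}

# accept tibble (with or without profile column) or matrix
feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  df <- as.data.frame(features)
  df$profile <- NULL
  as.matrix(df)
}
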