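make_gli_map <- function(values, field_size_px = 16, pixel_size_um = 1) {
  structure(list(values = values, field_size_px = field_size_px,
                 pixel_size_um = pixel_size_um), class = "gli_map")
}

fake_traverse <- function(x, y, index = 1L) {
  list(points = cbind(x, y), index = index,
       length_um = sum(sqrt(diff(x)^2 + diff(y)^2)))
}

test_that("a constant GLI map yields a constant profile", {
  g <- make_gli_map(matrix(0.4, 20, 20))
  tr <- fake_traverse(c(100, 100), c(20, 280))
  pr <- extract_profile(g, tr, 101)
  expect_equal(pr$gli, rep(0.4, 101))
  expect_equal(range(pr$depth), c(0, 100))
})

test_that("a GLI ramp in depth produces a linear profile", {
  vals <- matrix(rep(seq(0, 1, length.out = 30), 20), 30, 20)
  g <- make_gli_map(vals)  # value = linear in y
  tr <- fake_traverse(c(160, 160), c(8 + 8, 29 * 16 + 8 - 8))
  pr <- extract_profile(g, tr, 51)
  line <- pr$gli[1] + (pr$gli[51] - pr$gli[1]) * pr$depth / 100
  expect_lt(max(abs(pr$gli - line)), 1e-9)
})

test_that("depth normalization makes profiles thickness-invariant", {
  # same laminar pattern over ribbons of thickness d and 2d: the map value
  # depends only on relative depth
  pattern <- function(rel) 0.2 + 0.5 * exp(-((rel - 0.6) / 0.15)^2)
  g1 <- make_gli_map(matrix(rep(pattern(seq(0, 1, length.out = 25)), 10), 25, 10))
  g2 <- make_gli_map(matrix(rep(pattern(seq(0, 1, length.out = 49)), 10), 49, 10))
  tr1 <- fake_traverse(c(80, 80), c(8, 24 * 16 + 8))
  tr2 <- fake_traverse(c(80, 80), c(8, 48 * 16 + 8))
  p1 <- extract_profile(g1, tr1, 101)$gli
  p2 <- extract_profile(g2, tr2, 101)$gli
  expect_lt(max(abs(p1 - p2)), 0.05)
})

test_that("a traverse leaving the map footprint raises a named error", {
  g <- make_gli_map(matrix(0.4, 10, 10))
  tr <- fake_traverse(c(80, 80), c(8, 500), index = 7L)
  expect_error(extract_profile(g, tr, 21), "traverse 7")
})

test_that("mean profile is the pointwise arithmetic mean", {
  m <- withr::with_seed(2, matrix(runif(20 * 101), 20, 101))
  mp <- mean_profile(m)
  oracle <- sapply(seq_len(101), function(j) sum(m[, j]) / 20)
  expect_equal(mp$gli, oracle)
  one <- mean_profile(m[1, , drop = FALSE])
  expect_equal(one$gli, m[1, ])
  k <- m[1, ]
  expect_equal(mean_profile(rbind(k, -k + 2 * 0.35))$gli, rep(0.35, 101))
  expect_error(mean_profile(m[0, , drop = FALSE]), "empty")
})

test_that("block layout follows the sliding-window contract", {
  bl <- build_blocks(60, 20)
  expect_equal(range(bl$position), c(21, 41))  # 21 boundaries
  expect_equal(nrow(bl), 21)
  expect_equal(bl$left_from, bl$position - 20)
  expect_equal(bl$right_to, bl$position + 19)
  # consecutive positions share 2b - 2 members within each side
  expect_equal(length(intersect(bl$left_from[1]:bl$left_to[1],
                                bl$left_from[2]:bl$left_to[2])) +
                 length(intersect(bl$right_from[1]:bl$right_to[1],
                                  bl$right_from[2]:bl$right_to[2])),
               2 * 20 - 2)
  expect_silent(build_blocks(24, 12))
  expect_error(build_blocks(80, 31), "12-30")
  expect_silent(build_blocks(80, 31, standard = FALSE))
  expect_error(build_blocks(23, 12), "at least 2b")
})

test_that("feature vectors match the direct-summation oracle", {
  y <- c(0.2, 0.4, 0.6, 0.4, 0.2)
  x <- c(0, 25, 50, 75, 100)
  f <- as.numeric(profile_features(y, depths = x)[1, -1])
  expect_equal(f, oracle_features(y, x), tolerance = 1e-12)
  # random profiles too
  m <- withr::with_seed(8, matrix(runif(5 * 101, 0.05, 0.8), 5, 101))
  F <- profile_features(m)
  xs <- seq(0, 100, length.out = 101)
  for (i in 1:5) {
    expect_equal(as.numeric(F[i, -1]), oracle_features(m[i, ], xs),
                 tolerance = 1e-10)
  }
})

test_that("feature symmetry conventions hold", {
  f <- profile_features(rep(0.3, 101))
  expect_equal(f$gli_mean, 0.3)
  expect_equal(f$gli_cog, 50)
  expect_equal(f$gli_skew, 0)
  tri <- c(seq(0.1, 0.6, length.out = 51), seq(0.6, 0.1, length.out = 51)[-1])
  ft <- profile_features(tri)
  expect_equal(ft$gli_cog, 50, tolerance = 1e-9)
  expect_equal(ft$gli_skew, 0, tolerance = 1e-9)
  expect_error(profile_features(rep(0, 101)), "all-zero")
  expect_error(profile_features(c(0.1, 0.2, 0.3)), "at least 5")
})

test_that("features are stable under geometric stretching of the traverse", {
  # same laminar pattern over ribbons of thickness d and 2d, sampled to the
  # standard 101 depth points: the 10 features move by < 2%
  pattern <- function(rel) 0.2 + 0.5 * exp(-((rel - 0.6) / 0.15)^2)
  g1 <- make_gli_map(matrix(rep(pattern(seq(0, 1, length.out = 25)), 10), 25, 10))
  g2 <- make_gli_map(matrix(rep(pattern(seq(0, 1, length.out = 49)), 10), 49, 10))
  tr1 <- fake_traverse(c(80, 80), c(8, 24 * 16 + 8))
  tr2 <- fake_traverse(c(80, 80), c(8, 48 * 16 + 8))
  f1 <- as.numeric(profile_features(extract_profile(g1, tr1, 101)$gli)[1, -1])
  f2 <- as.numeric(profile_features(extract_profile(g2, tr2, 101)$gli)[1, -1])
  # relative 2% for features of appreciable size; near-zero features
  # (e.g. a skewness of ~0.003) are compared absolutely
  rel <- abs(f2 - f1) / pmax(abs(f1), 1e-6)
  expect_true(all(rel < 0.02 | abs(f2 - f1) < 0.02))
})

test_that("i.i.d. profile features show no drift between halves", {
  st <- simulate_section_profiles(list(area_low_iv), 200, seed = 31)
  Fm <- cytoborder:::feature_matrix(profile_features(st))
  half <- nrow(Fm) / 2
  stat_obs <- sum((colMeans(Fm[1:half, ]) - colMeans(Fm[(half + 1):(2 * half), ]))^2)
  perm <- withr::with_seed(32, replicate(500, {
    idx <- sample(nrow(Fm))
    sum((colMeans(Fm[idx[1:half], ]) - colMeans(Fm[idx[(half + 1):(2 * half)], ]))^2)
  }))
  p <- mean(perm >= stat_obs)
  expect_gt(p, 0.01)
})

test_that("standardization gives zero mean and unit variance per feature", {
  m <- withr::with_seed(3, matrix(rnorm(300, 5, 2), 30, 10))
  z <- standardize_features(m)
  expect_equal(colMeans(z), rep(0, 10), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), rep(1, 10), tolerance = 1e-12)
  mc <- m; mc[, 4] <- 7
  expect_true(all(standardize_features(mc)[, 4] == 0))
})
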