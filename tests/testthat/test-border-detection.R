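fake_distance <- function(d2, significant = rep(TRUE, length(d2)), b = 15) {
  structure(tibble::tibble(position = seq_along(d2) + b, b = b, d2 = d2,
                           p_value = ifelse(significant, 1e-6, 0.5),
                           significant = significant),
            class = c("distance_function", class(tibble::tibble())))
}

test_that("md_function scans every valid position with correct dfs", {
  X <- withr::with_seed(1, matrix(rnorm(70 * 10), 70, 10))
  dfun <- md_function(X, b = 15)
  expect_equal(dfun$position, 16:56)
  expect_true(all(dfun$d2 >= 0))
  expect_true(all(dfun$df1 == 10 & dfun$df2 == 2 * 15 - 10 - 1))
  expect_equal(dfun$alpha_corrected[1], 0.001 / nrow(dfun))
})

test_that("the D2 curve is translation-equivariant", {
  X <- withr::with_seed(2, matrix(rnorm(90 * 10), 90, 10))
  d_full <- md_function(X, b = 12, standardize = FALSE)
  d_shift <- md_function(X[11:90, ], b = 12, standardize = FALSE)
  common_full <- d_full$d2[d_full$position %in% 23:78]
  common_shift <- d_shift$d2[d_shift$position %in% 13:68]
  expect_equal(common_full, common_shift, tolerance = 1e-10)
})

test_that("a step change in feature means is localized by the global maximum", {
  hits <- 0
  n_sim <- 200
  for (s in seq_len(n_sim)) {
    X <- withr::with_seed(5000 + s, {
      m <- matrix(rnorm(60 * 10), 60, 10)
      m[31:60, ] <- m[31:60, ] + 2  # per-feature standardized shift of 2
      m
    })
    dfun <- md_function(X, b = 20, standardize = FALSE)
    k_hat <- dfun$position[which.max(dfun$d2)]
    if (abs(k_hat - 31) <= 3) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("homogeneous profiles almost never flag significance", {
  flagged <- 0
  n_sim <- 500
  for (s in seq_len(n_sim)) {
    X <- withr::with_seed(9000 + s, matrix(rnorm(60 * 10), 60, 10))
    dfun <- md_function(X, b = 15, standardize = FALSE)
    if (any(dfun$significant)) flagged <- flagged + 1
  }
  expect_lte(flagged / n_sim, 0.002)
})

test_that("detect_maxima applies the window, significance and tie rules", {
  # monotone curve: no interior candidate, end only
  mono <- fake_distance(seq(1, 10, length.out = 10))
  expect_equal(detect_maxima(mono)$position, max(mono$position))
  mono2 <- fake_distance(seq(1, 10, length.out = 10),
                         significant = c(rep(TRUE, 9), FALSE))
  expect_equal(nrow(detect_maxima(mono2)), 0)
  # two separated significant peaks
  two <- fake_distance(c(1, 5, 1, 1, 1, 1, 6, 1, 1))
  expect_equal(detect_maxima(two)$position - two$position[1] + 1, c(2, 7))
  # plateau: leftmost index wins
  plat <- fake_distance(c(1, 4, 4, 4, 1, 1, 1))
  expect_equal(detect_maxima(plat)$position, plat$position[2])
  # insignificant peaks are dropped
  insig <- fake_distance(c(1, 5, 1), significant = c(FALSE, FALSE, FALSE))
  expect_equal(nrow(detect_maxima(insig)), 0)
})

test_that("accept_borders clusters across block sizes by single linkage", {
  acc <- accept_borders(tibble::tibble(b = c(14, 20, 26),
                                       position = c(100, 100, 100)))
  expect_equal(acc$position, 100)
  expect_equal(acc$n_block_sizes, 3)
  expect_equal(nrow(accept_borders(tibble::tibble(b = c(20, 21),
                                                  position = c(100, 100)))), 0)
  acc3 <- accept_borders(tibble::tibble(b = c(14, 20, 26),
                                        position = c(100, 102, 103)),
                         position_tol = 4)
  expect_equal(acc3$position, 102)
  expect_equal(acc3$spread, 3)
  # two well-separated clusters stay separate
  acc4 <- accept_borders(tibble::tibble(b = c(12, 14, 16, 20, 22, 24),
                                        position = c(50, 51, 50, 90, 91, 90)))
  expect_equal(sort(acc4$position), c(50, 90))
})

test_that("cross-section confirmation requires adjacent support", {
  cand <- function(pos, sizes = list(c(12, 14, 16))) {
    tibble::tibble(position = pos, n_block_sizes = lengths(sizes),
                   block_sizes = sizes, positions = as.list(pos),
                   spread = 0)
  }
  none <- cand(numeric(0), sizes = list())
  # identical candidate in sections 1-3 -> accepted
  acc <- confirm_across_sections(list(cand(40), cand(40), cand(40)))
  expect_equal(acc$position, 40)
  expect_equal(acc$n_sections, 3)
  # gap in section 2 breaks the chain
  acc2 <- confirm_across_sections(list(cand(40), none, cand(40)))
  expect_equal(nrow(acc2), 0)
  # jittered positions within tolerance chain up; median reported
  acc3 <- confirm_across_sections(list(cand(40), cand(42), cand(41), none))
  expect_equal(acc3$position, 41)
  expect_equal(acc3$spread, 2)
})

test_that("end-to-end: a five-section stack recovers exactly the true border", {
  ok <- 0; extras <- 0
  n_sim <- 25
  for (s in seq_len(n_sim)) {
    st <- simulate_profile_stack(list(area_low_iv, area_high_iv), 100, 50L,
                                 n_sections = 5, jitter_profiles = 2,
                                 seed = 400 + s)
    b <- detect_borders(st)$borders
    if (any(abs(b$position - 50) <= 10)) ok <- ok + 1
    if (any(abs(b$position - 50) > 10)) extras <- extras + 1
  }
  expect_gte(ok / n_sim, 0.9)
  expect_lte(extras / n_sim, 0.1)
})

test_that("accepted borders report their multi-scale and serial support", {
  st <- simulate_profile_stack(list(area_low_iv, area_high_iv), 100, 50L,
                               n_sections = 5, jitter_profiles = 1, seed = 77)
  res <- detect_borders(st, keep_distances = TRUE)
  expect_equal(nrow(res$borders), 1)
  expect_gte(res$borders$n_block_sizes, 3)
  expect_gte(res$borders$n_sections, 3)
  expect_length(res$per_section, 5)
  expect_length(res$distances, 5)
  expect_s3_class(res$distances[[1]], "distance_function")
})
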