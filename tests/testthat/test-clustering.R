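test_that("nearest points merge first and duplicates merge at zero height", {
  X <- matrix(c(0, 1, 10), ncol = 1)
  dend <- hierarchical_cluster(X, standardize = FALSE)
  m <- tidy(dend)
  expect_equal(sort(abs(m[1, c("cluster_a", "cluster_b")][[1]])), 1)
  expect_equal(unlist(m[1, c("cluster_a", "cluster_b")], use.names = FALSE) |>
                 sort(), c(-2, -1))
  expect_equal(m$height[1], 0.5)  # |0 - 1|^2 / 2
  Xd <- rbind(c(2, 3), c(2, 3), c(9, 1))
  dd <- hierarchical_cluster(Xd, standardize = FALSE)
  expect_equal(tidy(dd)$height[1], 0)
})

test_that("merge heights equal the greedy Ward ESS cost on random fixtures", {
  for (s in 1:4) {
    X <- withr::with_seed(70 + s, matrix(rnorm(5 * 3), 5, 3))
    dend <- hierarchical_cluster(X, standardize = FALSE)
    expect_equal(dend$hclust$height, oracle_ward_heights(X), tolerance = 1e-10)
  }
})

test_that("Ward heights are monotone and order-invariant", {
  X <- withr::with_seed(9, matrix(rnorm(12 * 10), 12, 10))
  dend <- hierarchical_cluster(X)
  expect_true(all(diff(dend$hclust$height) >= -1e-12))
  perm <- withr::with_seed(10, sample(12))
  dend_p <- hierarchical_cluster(X[perm, ])
  expect_equal(sort(dend_p$hclust$height), sort(dend$hclust$height),
               tolerance = 1e-10)
})

test_that("well-separated groups are recovered at the top split", {
  ok <- 0
  for (s in 1:50) {
    X <- withr::with_seed(500 + s, {
      rbind(matrix(rnorm(6 * 4, 0, 1), 6, 4),
            matrix(rnorm(6 * 4, 10, 1), 6, 4))
    })
    dend <- hierarchical_cluster(X, standardize = FALSE)
    grp <- cutree(dend$hclust, k = 2)
    if (length(unique(grp[1:6])) == 1 && length(unique(grp[7:12])) == 1 &&
        grp[1] != grp[7]) ok <- ok + 1
  }
  expect_equal(ok, 50)
})

test_that("anterior areas cluster with the pole, apart from posterior areas", {
  specs <- dlpfc_area_specs()
  pole <- list(
    Fp1 = laminar_spec(c(0.10, 0.10, 0.29, 0.12, 0.19, 0.20),
                       c(0.08, 0.48, 0.33, 0.50, 0.31, 0.41), name = "Fp1"),
    Fp2 = laminar_spec(c(0.10, 0.11, 0.29, 0.12, 0.18, 0.20),
                       c(0.08, 0.46, 0.31, 0.52, 0.29, 0.43), name = "Fp2")
  )
  posterior <- list(
    p8d1 = laminar_spec(c(0.10, 0.08, 0.36, 0.06, 0.24, 0.16),
                        c(0.08, 0.28, 0.45, 0.30, 0.48, 0.25), name = "8d1"),
    p8d2 = laminar_spec(c(0.10, 0.08, 0.37, 0.06, 0.23, 0.16),
                        c(0.08, 0.26, 0.47, 0.28, 0.50, 0.27), name = "8d2"),
    p8v1 = laminar_spec(c(0.10, 0.09, 0.36, 0.05, 0.25, 0.15),
                        c(0.08, 0.30, 0.44, 0.32, 0.46, 0.24), name = "8v1"),
    p8v2 = laminar_spec(c(0.10, 0.08, 0.35, 0.06, 0.25, 0.16),
                        c(0.08, 0.27, 0.46, 0.31, 0.47, 0.26), name = "8v2")
  )
  all_specs <- c(specs, pole, posterior)
  ok <- 0; n_runs <- 20
  for (r in seq_len(n_runs)) {
    feats <- purrr::imap_dfr(all_specs, function(sp, nm) {
      st <- simulate_section_profiles(list(sp), 18, noise_sd = 0.05,
                                      seed = cytoborder:::child_seed(600 + r,
                                                                     match(nm, names(all_specs))))
      f <- profile_features(mean_profile(st)$gli)
      f$profile <- NULL
      dplyr::bind_cols(tibble::tibble(area = nm), f)
    })
    dend <- hierarchical_cluster(feats, label_col = "area")
    grp <- cutree(dend$hclust, k = 2)
    ant <- grp[1:6]; post <- grp[7:10]
    if (length(unique(ant)) == 1 && length(unique(post)) == 1 &&
        ant[1] != post[1]) ok <- ok + 1
  }
  expect_gte(ok / n_runs, 0.9)
})

test_that("newick export reflects the leaf set", {
  X <- withr::with_seed(3, matrix(rnorm(4 * 2), 4, 2))
  dend <- hierarchical_cluster(cbind(tibble::tibble(area = c("a", "b", "c", "d")),
                                     as.data.frame(X)),
                               label_col = "area", standardize = FALSE)
  nwk <- dendrogram_newick(dend)
  expect_match(nwk, "^\\(")
  for (lbl in c("a", "b", "c", "d")) expect_match(nwk, lbl)
})

test_that("the discriminant axis aligns with a one-coordinate separation", {
  X <- withr::with_seed(21, {
    rbind(cbind(rnorm(30, 0), matrix(rnorm(30 * 4), 30, 4)),
          cbind(rnorm(30, 5), matrix(rnorm(30 * 4), 30, 4)))
  })
  cls <- rep(c("A", "B"), each = 30)
  proj <- canonical_discriminant(X, cls)
  a1 <- proj$axes[, 1]
  cosine <- abs(a1[1]) / sqrt(sum(a1^2))
  expect_gt(cosine, 0.95)
  expect_false(proj$degenerate)
  expect_equal(nrow(proj$centroids), 2)
})

test_that("identical class means flag a degenerate projection", {
  X <- withr::with_seed(22, matrix(rnorm(20 * 3), 20, 3))
  Xs <- rbind(X, X)  # class B identical to class A
  cls <- rep(c("A", "B"), each = 20)
  expect_warning(proj <- canonical_discriminant(Xs, cls), "degenerate")
  expect_true(proj$degenerate)
})

test_that("the projection maximizes between/within variance over raw features", {
  X <- withr::with_seed(23, {
    mu <- rbind(c(1, 0, 2), c(0, 1.5, 0), c(2, 2, 1))
    do.call(rbind, lapply(1:3, function(k) {
      sweep(matrix(rnorm(15 * 3), 15, 3), 2, mu[k, ], "+")
    }))
  })
  cls <- rep(letters[1:3], each = 15)
  proj <- canonical_discriminant(X, cls)
  bw_ratio <- function(v) {
    gm <- tapply(v, cls, mean)
    b <- sum(table(cls) * (gm - mean(v))^2)
    w <- sum((v - gm[cls])^2)
    b / w
  }
  r_proj <- bw_ratio(proj$scores$axis1)
  for (j in 1:3) expect_gte(r_proj + 1e-10, bw_ratio(X[, j]))
})

test_that("the discriminant projection agrees with a reference LDA", {
  skip_if_not_installed("MASS")
  X <- withr::with_seed(24, {
    rbind(matrix(rnorm(25 * 4, 0), 25, 4),
          sweep(matrix(rnorm(25 * 4), 25, 4), 2, c(2, 1, 0, -1), "+"))
  })
  cls <- rep(c("A", "B"), each = 25)
  proj <- canonical_discriminant(X, cls)
  ld <- MASS::lda(X, grouping = cls)
  a <- proj$axes[, 1] / sqrt(sum(proj$axes[, 1]^2))
  b <- ld$scaling[, 1] / sqrt(sum(ld$scaling[, 1]^2))
  expect_gt(abs(sum(a * b)), 0.999)
})
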