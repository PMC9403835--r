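# Shared fixtures and tiny independent oracles used across the suite.

# two generic areas differing only in layer-IV density (the canonical
# detection contrast)
area_low_iv <- laminar_spec(rep(1 / 6, 6), c(0.05, 0.45, 0.30, 0.20, 0.30, 0.40),
                            name = "lowIV")
area_high_iv <- laminar_spec(rep(1 / 6, 6), c(0.05, 0.45, 0.30, 0.60, 0.30, 0.40),
                             name = "highIV")

# small flat ribbon rendered quickly (coarse pixels)
small_section <- function(seed = 1, areas = list(area_low_iv),
                          borders = numeric(0), length_um = 300,
                          thickness_um = 150, pixel_size_um = 1.5, ...) {
  render_section(flat_ribbon(length_um, thickness_um, pixel_size_um),
                 areas, borders, seed = seed, ...)
}

# direct-summation 10-feature oracle, written independently of the package
# implementation (explicit loops over the definition)
oracle_features <- function(y, x) {
  n <- length(y)
  wmom <- function(w) {
    sw <- sum(w)
    if (sw == 0) return(c(mean(w), mean(range(x)), 0, 0, 0))
    c1 <- sum(x * w) / sw
    mu2 <- sum((x - c1)^2 * w) / sw
    s <- sqrt(mu2)
    g1 <- if (s > 0) sum((x - c1)^3 * w) / (sw * s^3) else 0
    g2 <- if (s > 0) sum((x - c1)^4 * w) / (sw * s^4) else 0
    c(mean(w), c1, s, g1, g2)
  }
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  for (i in 2:(n - 1)) d[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  c(wmom(y), wmom(abs(d)))
}

# Gaussian-elimination solver (no pivot-free shortcuts), used as the
# linear-algebra oracle for the Mahalanobis distance
oracle_solve <- function(A, b) {
  n <- nrow(A)
  M <- cbind(A, b)
  for (k in seq_len(n)) {
    piv <- which.max(abs(M[k:n, k])) + k - 1L
    if (piv != k) M[c(k, piv), ] <- M[c(piv, k), ]
    M[k, ] <- M[k, ] / M[k, k]
    for (r in seq_len(n)[-k]) M[r, ] <- M[r, ] - M[r, k] * M[k, ]
  }
  M[, n + 1]
}

# greedy Ward agglomeration oracle: at every step merge the pair whose
# union minimally increases the within-cluster sum of squares; returns the
# sequence of merge costs
oracle_ward_heights <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), function(i) X[i, , drop = FALSE])
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      a <- clusters[[i]]; b <- clusters[[j]]
      na <- nrow(a); nb <- nrow(b)
      d <- colMeans(a) - colMeans(b)
      cost <- na * nb / (na + nb) * sum(d^2)
      if (cost < best) { best <- cost; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- rbind(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# split-plot sums-of-squares oracle: explicit loops over the cell-mean
# decomposition (df: subject, sex, area, hemisphere, y; balanced)
oracle_splitplot_ss <- function(df) {
  gm <- mean(df$y)
  areas <- unique(df$area); hems <- unique(df$hemisphere)
  subjects <- unique(df$subject)
  A <- length(areas); H <- length(hems)
  sex_of <- sapply(subjects, function(s) df$sex[df$subject == s][1])
  cm <- function(...) {
    sel <- Reduce(`&`, list(...))
    mean(df$y[sel])
  }
  ss <- list(sex = 0, subj_within = 0, area = 0, sex_area = 0, area_subj = 0,
             hem = 0, sex_hem = 0, hem_subj = 0)
  for (g in unique(df$sex)) {
    ng <- sum(sex_of == g)
    ss$sex <- ss$sex + A * H * ng * (cm(df$sex == g) - gm)^2
  }
  for (s in subjects) {
    ss$subj_within <- ss$subj_within +
      A * H * (cm(df$subject == s) - cm(df$sex == sex_of[s]))^2
  }
  for (a in areas) {
    ss$area <- ss$area + length(subjects) * H * (cm(df$area == a) - gm)^2
  }
  for (g in unique(df$sex)) for (a in areas) {
    ng <- sum(sex_of == g)
    ss$sex_area <- ss$sex_area + H * ng *
      (cm(df$sex == g, df$area == a) - cm(df$sex == g) - cm(df$area == a) + gm)^2
  }
  for (s in subjects) for (a in areas) {
    g <- sex_of[s]
    ss$area_subj <- ss$area_subj + H *
      (cm(df$subject == s, df$area == a) - cm(df$subject == s) -
         cm(df$sex == g, df$area == a) + cm(df$sex == g))^2
  }
  for (h in hems) {
    ss$hem <- ss$hem + length(subjects) * A * (cm(df$hemisphere == h) - gm)^2
  }
  for (g in unique(df$sex)) for (h in hems) {
    ng <- sum(sex_of == g)
    ss$sex_hem <- ss$sex_hem + A * ng *
      (cm(df$sex == g, df$hemisphere == h) - cm(df$sex == g) -
         cm(df$hemisphere == h) + gm)^2
  }
  for (s in subjects) for (h in hems) {
    g <- sex_of[s]
    ss$hem_subj <- ss$hem_subj + A *
      (cm(df$subject == s, df$hemisphere == h) - cm(df$subject == s) -
         cm(df$sex == g, df$hemisphere == h) + cm(df$sex == g))^2
  }
  ss$total <- sum((df$y - gm)^2)
  ss
}

# simulate a per-brain x hemisphere x area GLI/volume record table
simulate_records <- function(n_per_sex = 5, areas = paste0("A", 1:4),
                             sex_effect = 0, subj_sd = 0.02, cell_sd = 0.01,
                             base = 0.2, seed = 1) {
  withr::with_seed(seed, {
    subj <- paste0("S", seq_len(2 * n_per_sex))
    sex <- rep(c("male", "female"), each = n_per_sex)
    out <- expand.grid(brain = subj, hemisphere = c("left", "right"),
                       area = areas, stringsAsFactors = FALSE)
    out$sex <- sex[match(out$brain, subj)]
    re <- rnorm(length(subj), 0, subj_sd)
    out$mean_gli <- base + re[match(out$brain, subj)] +
      ifelse(out$sex == "female", sex_effect, 0) +
      rnorm(nrow(out), 0, cell_sd)
    out$mean_gli <- pmin(pmax(out$mean_gli, 0), 1)
    out
  })
}
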