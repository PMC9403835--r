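# Precompute cumulative sums and cumulative crossproducts of a feature
# matrix so every sliding-window block mean / covariance is a difference of
# two rows. Makes the multi-block-size scan linear in the number of
# positions instead of re-aggregating each block.
feature_cumulants <- function(X) {
  n <- nrow(X); p <- ncol(X)
  cumX <- rbind(0, apply(X, 2, cumsum))
  P <- matrix(0, n, p * p)
  for (i in seq_len(p)) {
    P[, ((i - 1) * p + 1):(i * p)] <- X[, i] * X
  }
  cumP <- rbind(0, apply(P, 2, cumsum))
  list(cumX = cumX, cumP = cumP, n = n, p = p)
}

# Sliding Mahalanobis scan at one block size over precomputed cumulants.
md_scan <- function(cum, b, alpha = 0.001, cond_limit = 1e8,
                    lambdas = c(0, 1e-4, 1e-3, 1e-2)) {
  n <- cum$n; p <- cum$p
  if (n < 2 * b) abort(sprintf("need at least 2b = %d profiles, got %d.", 2 * b, n))
  ks <- seq.int(b + 1L, n - b + 1L)
  m <- length(ks)
  d2 <- numeric(m); lambda <- numeric(m)
  for (i in seq_len(m)) {
    k <- ks[i]
    sA <- cum$cumX[k, ] - cum$cumX[k - b, ]
    sB <- cum$cumX[k + b, ] - cum$cumX[k, ]
    mA <- sA / b; mB <- sB / b
    cpA <- cum$cumP[k, ] - cum$cumP[k - b, ]
    cpB <- cum$cumP[k + b, ] - cum$cumP[k, ]
    Cv <- (cpA - b * as.vector(outer(mA, mA)) +
           cpB - b * as.vector(outer(mB, mB))) / (2 * b - 2)
    C <- matrix(Cv, p, p)
    C <- (C + t(C)) / 2
    delta <- mA - mB
    sol <- shrunk_solve(C, delta, cond_limit, lambdas)
    d2[i] <- max(0, sum(delta * sol$z))
    lambda[i] <- sol$lambda
  }
  ht <- hotelling_test(d2, b, b, p)
  out <- dplyr::bind_cols(tibble(position = ks, b = b, d2 = d2), ht,
                          tibble(lambda = lambda))
  out$alpha_corrected <- alpha / m
  out$significant <- out$p_value <= out$alpha_corrected
  class(out) <- c("distance_function", class(out))
  out
}

#' Sliding-window Mahalanobis distance function
#'
#' Moves two adjacent blocks of `b` profiles along the cortical ribbon and
#' computes, at every valid border position, the Mahalanobis distance
#' between the blocks' mean feature vectors together with Hotelling's T2
#' test. Significance is Bonferroni-corrected over the number of tested
#' positions at this block size, at family-wise level `alpha`.
#'
#' Positions follow the [build_blocks()] convention: position `k` separates
#' profiles `k - b .. k - 1` from `k .. k + b - 1`.
#'
#' @param features a [profile_features()] tibble, a numeric feature matrix
#'   (profiles x features), or a `profile_set` (features computed on the
#'   fly).
#' @param b block size (12-30 in standard runs; see `standard`).
#' @param alpha family-wise significance level (default 0.001).
#' @param standardize z-score features across the profile set first
#'   (recommended; the features have incommensurate units).
#' @param standard enforce the standard 12-30 block-size range.
#' @param cond_limit,lambdas covariance conditioning controls, see
#'   [mahalanobis_blocks()].
#' @return a `distance_function` tibble: `position`, `b`, `d2`, `t2`, `f`,
#'   `df1`, `df2`, `p_value`, `lambda`, `alpha_corrected`, `significant`.
#' @export
md_function <- function(features, b, alpha = 0.001, standardize = TRUE,
                        standard = TRUE, cond_limit = 1e8,
                        lambdas = c(0, 1e-4, 1e-3, 1e-2)) {
  if (inherits(features, "profile_set")) features <- profile_features(features)
  X <- feature_matrix(features)
  build_blocks(nrow(X), b, standard = standard)  # validates b and n
  if (standardize) X <- standardize_features(X)
  md_scan(feature_cumulants(X), b, alpha, cond_limit, lambdas)
}

#' Significant local maxima of a distance function
#'
#' Candidate border positions: strict local maxima of D2 over a +/- `w`
#' position window that are significant after Bonferroni correction.
#' Plateaus count once, at their leftmost index.
#'
#' @param dist a [md_function()] result.
#' @param w half-width of the local-maximum window (positions).
#' @return tibble of candidates: `position`, `b`, `d2`, `p_value`.
#' @export
detect_maxima <- function(dist, w = 2) {
  d2 <- dist$d2
  n <- length(d2)
  is_max <- logical(n)
  for (i in seq_len(n)) {
    win <- max(1, i - w):min(n, i + w)
    mx <- max(d2[win])
    is_max[i] <- d2[i] == mx && i == win[which.max(d2[win] == mx)]
  }
  out <- dist[is_max & dist$significant,
              c("position", "b", "d2", "p_value"), drop = FALSE]
  as_tibble(out)
}

#' Consensus border candidates across block sizes
#'
#' Clusters candidate positions from different block sizes by
#' single-linkage with tolerance `position_tol`; clusters supported by at
#' least `min_block_sizes` distinct block sizes yield a consensus position
#' (the median of the cluster's positions).
#'
#' @param candidates tibble with columns `position` and `b` (e.g. row-bound
#'   [detect_maxima()] results over the block-size range), or a named list
#'   mapping block size to positions.
#' @param min_block_sizes minimum number of distinct supporting block sizes.
#' @param position_tol single-linkage tolerance in profile indices.
#' @return tibble: `position` (consensus), `n_block_sizes`, `block_sizes`
#'   (list), `positions` (list), `spread`.
#' @export
accept_borders <- function(candidates, min_block_sizes = 3, position_tol = 4) {
  if (is.list(candidates) && !is.data.frame(candidates)) {
    candidates <- purrr::map_dfr(names(candidates), function(bn) {
      tibble(b = as.numeric(bn), position = candidates[[bn]])
    })
  }
  if (!nrow(candidates)) {
    return(tibble(position = numeric(0), n_block_sizes = integer(0),
                  block_sizes = list(), positions = list(), spread = numeric(0)))
  }
  cand <- dplyr::arrange(candidates, .data$position)
  gaps <- diff(cand$position)
  cluster <- cumsum(c(1, gaps > position_tol))
  cand$.cluster <- cluster
  out <- cand |>
    dplyr::group_by(.data$.cluster) |>
    dplyr::summarise(
      n_block_sizes = dplyr::n_distinct(.data$b),
      block_sizes = list(sort(unique(.data$b))),
      positions = list(.data$position),
      spread = diff(range(.data$position)),
      position = median(.data$position),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_block_sizes >= min_block_sizes) |>
    dplyr::select(-".cluster") |>
    dplyr::relocate("position")
  out
}

#' Confirm borders across adjacent serial sections
#'
#' Matches per-section consensus candidates across consecutive sections by
#' position proximity and accepts chains spanning at least `min_sections`
#' adjacent sections. A gap (no matching candidate in the next section)
#' breaks the chain: only strictly adjacent support counts.
#'
#' @param per_section list of [accept_borders()] tibbles, ordered by
#'   section; names or a `section_id` attribute are not required — list
#'   order defines adjacency.
#' @param min_sections minimum chain length.
#' @param position_tol maximum position difference (profile indices)
#'   between matching candidates in adjacent sections.
#' @return an `accepted_borders` tibble: `position` (median over the
#'   chain), `n_sections`, `sections` (list), `n_block_sizes` (distinct
#'   sizes supporting the chain), `block_sizes` (list), `spread`.
#' @export
confirm_across_sections <- function(per_section, min_sections = 3,
                                    position_tol = 4) {
  chains <- list()  # each: positions, sections, sizes
  done <- list()
  for (s in seq_along(per_section)) {
    cand <- per_section[[s]]
    used <- rep(FALSE, nrow(cand))
    # age out chains not extended in the previous section
    keep <- vapply(chains, function(ch) tail(ch$sections, 1) == s - 1L, TRUE)
    done <- c(done, chains[!keep])
    chains <- chains[keep]
    if (length(chains) && nrow(cand)) {
      for (ci in seq_along(chains)) {
        dpos <- abs(cand$position - tail(chains[[ci]]$positions, 1))
        dpos[used] <- Inf
        j <- which.min(dpos)
        if (length(j) && is.finite(dpos[j]) && dpos[j] <= position_tol) {
          chains[[ci]]$positions <- c(chains[[ci]]$positions, cand$position[j])
          chains[[ci]]$sections <- c(chains[[ci]]$sections, s)
          chains[[ci]]$sizes <- union(chains[[ci]]$sizes, cand$block_sizes[[j]])
          used[j] <- TRUE
        }
      }
    }
    if (nrow(cand)) {
      for (j in which(!used)) {
        chains[[length(chains) + 1L]] <- list(
          positions = cand$position[j], sections = s,
          sizes = cand$block_sizes[[j]]
        )
      }
    }
  }
  done <- c(done, chains)
  done <- purrr::keep(done, ~ length(.x$sections) >= min_sections)
  out <- purrr::map_dfr(done, function(ch) {
    tibble(position = median(ch$positions),
           n_sections = length(ch$sections),
           sections = list(ch$sections),
           n_block_sizes = length(ch$sizes),
           block_sizes = list(sort(ch$sizes)),
           spread = diff(range(ch$positions)))
  })
  if (!nrow(out)) {
    out <- tibble(position = numeric(0), n_sections = integer(0),
                  sections = list(), n_block_sizes = integer(0),
                  block_sizes = list(), spread = numeric(0))
  }
  class(out) <- c("accepted_borders", class(out))
  out
}

#' Full border detection over a stack of serial sections
#'
#' Runs the complete statistical chain on each section — feature
#' extraction, z-scoring, sliding Mahalanobis distance over the block-size
#' range with Bonferroni-corrected Hotelling tests, significant local
#' maxima, consensus over block sizes — and then confirms candidates
#' across adjacent sections.
#'
#' @param sections list of `profile_set`s (or feature matrices), ordered as
#'   adjacent serial sections.
#' @param block_sizes block sizes to scan (default 12:30).
#' @param alpha family-wise significance level per block size.
#' @param w local-maximum window half-width.
#' @param min_block_sizes,position_tol consensus rule across block sizes.
#' @param min_sections,section_tol confirmation rule across sections.
#' @param keep_distances return the per-section distance functions
#'   (memory-heavy for long stacks).
#' @return list with `borders` (an `accepted_borders` tibble),
#'   `per_section` (list of per-section consensus candidate tibbles) and,
#'   if requested, `distances`.
#' @export
detect_borders <- function(sections, block_sizes = 12:30, alpha = 0.001,
                           w = 2, min_block_sizes = 3, position_tol = 4,
                           min_sections = 3, section_tol = 4,
                           keep_distances = FALSE) {
  if (inherits(sections, "profile_set")) sections <- list(sections)
  per_section <- vector("list", length(sections))
  distances <- if (keep_distances) vector("list", length(sections))
  for (s in seq_along(sections)) {
    feats <- sections[[s]]
    if (inherits(feats, "profile_set")) feats <- profile_features(feats)
    X <- standardize_features(feats)
    cum <- feature_cumulants(X)
    cands <- purrr::map_dfr(block_sizes, function(b) {
      detect_maxima(md_scan(cum, b, alpha), w = w)
    })
    if (keep_distances) {
      distances[[s]] <- purrr::map_dfr(block_sizes, ~ md_scan(cum, .x, alpha))
    }
    per_section[[s]] <- accept_borders(cands, min_block_sizes, position_tol)
  }
  res <- list(
    borders = confirm_across_sections(per_section, min_sections, section_tol),
    per_section = per_section
  )
  if (keep_distances) res$distances <- distances
  res
}
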