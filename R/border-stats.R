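#' Mahalanobis distance between two profile blocks
#'
#' Squared Mahalanobis distance between the mean feature vectors of two
#' blocks, D2 = (mA - mB)' C^-1 (mA - mB), with C the pooled sample
#' covariance ((nA-1) SA + (nB-1) SB) / (nA + nB - 2). When the pooled
#' covariance is ill-conditioned (condition number above `cond_limit`) it
#' is shrunk toward its diagonal, C <- (1 - lambda) C + lambda diag(C),
#' with the smallest lambda from `lambdas` that restores conditioning; the
#' lambda used is recorded as an attribute.
#'
#' @param block_a,block_b numeric matrices (observations x features) of
#'   equal block size and feature dimension.
#' @param cond_limit condition-number limit triggering shrinkage.
#' @param lambdas candidate shrinkage intensities, tried in order.
#' @return scalar D2 (>= 0) with attribute `lambda`.
#' @export
mahalanobis_blocks <- function(block_a, block_b, cond_limit = 1e8,
                               lambdas = c(0, 1e-4, 1e-3, 1e-2)) {
  block_a <- feature_matrix(block_a); block_b <- feature_matrix(block_b)
  if (ncol(block_a) != ncol(block_b)) abort("feature dimensions differ.")
  if (nrow(block_a) != nrow(block_b)) abort("block sizes differ.")
  na <- nrow(block_a); nb <- nrow(block_b)
  if (na < 2) abort("blocks need at least 2 observations.")
  ma <- colMeans(block_a); mb <- colMeans(block_b)
  C <- ((na - 1) * cov(block_a) + (nb - 1) * cov(block_b)) / (na + nb - 2)
  sol <- shrunk_solve(C, ma - mb, cond_limit, lambdas)
  structure(max(0, sum((ma - mb) * sol$z)), lambda = sol$lambda)
}

# solve C z = delta with diagonal shrinkage fallback; returns z and lambda
shrunk_solve <- function(C, delta, cond_limit = 1e8,
                         lambdas = c(0, 1e-4, 1e-3, 1e-2)) {
  dC <- diag(diag(C), nrow(C))
  for (lam in lambdas) {
    Cs <- if (lam == 0) C else (1 - lam) * C + lam * dC
    rc <- tryCatch(rcond(Cs), error = function(e) 0)
    if (rc > 0 && 1 / rc < cond_limit) {
      z <- tryCatch(solve(Cs, delta), error = function(e) NULL)
      if (!is.null(z)) return(list(z = z, lambda = lam))
    }
  }
  abort("pooled covariance singular even after maximum shrinkage.")
}

#' Hotelling's T-squared test from a Mahalanobis distance
#'
#' Converts a two-block squared Mahalanobis distance into Hotelling's T2,
#' the corresponding F statistic and its p-value:
#' T2 = (nA nB / (nA + nB)) D2, F = T2 (nA + nB - p - 1) / ((nA + nB - 2) p)
#' on (p, nA + nB - p - 1) degrees of freedom.
#'
#' @param d2 squared Mahalanobis distance (scalar or vector).
#' @param n_a,n_b block sizes.
#' @param p feature dimension (default 10).
#' @return a tibble with columns `t2`, `f`, `df1`, `df2`, `p_value`.
#' @export
#' @examples
#' hotelling_test(2, 20, 20)  # T2 = 20, F = 20 * 29 / (38 * 10)
hotelling_test <- function(d2, n_a, n_b, p = 10) {
  df2 <- n_a + n_b - p - 1
  if (df2 < 1) {
    abort(sprintf("df2 = nA + nB - p - 1 = %d < 1: use a larger block size.", df2))
  }
  t2 <- (n_a * n_b / (n_a + n_b)) * d2
  f <- t2 * df2 / ((n_a + n_b - 2) * p)
  tibble(t2 = t2, f = f, df1 = p, df2 = df2,
         p_value = pf(f, p, df2, lower.tail = FALSE))
}
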