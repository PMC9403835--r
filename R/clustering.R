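#' Hierarchical clustering of areal feature vectors
#'
#' Agglomerative clustering with Euclidean distance and Ward's minimum-
#' variance linkage, the standard similarity analysis for mean areal GLI
#' profiles. Heights are reported as the Ward merge cost, i.e. the
#' increase in total within-cluster sum of squares caused by each merge
#' (conventions differ between software; this one makes the first merge of
#' two points x, y cost |x - y|^2 / 2).
#'
#' @param features data frame or matrix of observations x features;
#'   non-feature label columns can be named in `label_col`.
#' @param label_col optional column with leaf labels.
#' @param standardize z-score features across observations first (default
#'   TRUE; the features have incommensurate units).
#' @return an object of class `area_dendrogram`: list with `hclust` (the
#'   [stats::hclust] object, heights = Ward ESS merge cost), `labels`,
#'   `standardize`.
#' @export
hierarchical_cluster <- function(features, label_col = NULL,
                                 standardize = TRUE) {
  labels <- NULL
  if (!is.null(label_col)) {
    labels <- as.character(features[[label_col]])
    features <- features[setdiff(names(features), label_col)]
  }
  m <- feature_matrix(features)
  if (nrow(m) < 2) abort("need at least 2 observations.")
  if (any(!is.finite(m))) abort("non-finite feature values.")
  if (standardize) m <- standardize_features(m)
  d2 <- dist(m)^2
  hc <- hclust(as.dist(d2 / 2), method = "ward.D")
  hc$labels <- labels %||% rownames(m) %||% as.character(seq_len(nrow(m)))
  structure(list(hclust = hc, labels = hc$labels, standardize = standardize),
            class = "area_dendrogram")
}

#' @export
print.area_dendrogram <- function(x, ...) {
  cat("<area_dendrogram>", length(x$labels), "leaves; Ward/Euclidean;",
      "top merge cost", signif(max(x$hclust$height), 4), "\n")
  invisible(x)
}

#' @export
tidy.area_dendrogram <- function(x, ...) {
  hc <- x$hclust
  nm <- nrow(hc$merge)
  size <- integer(nm)
  for (i in seq_len(nm)) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    size[i] <- (if (a < 0) 1L else size[a]) + (if (b < 0) 1L else size[b])
  }
  tibble(merge = seq_len(nm),
         cluster_a = hc$merge[, 1], cluster_b = hc$merge[, 2],
         height = hc$height, size = size)
}

#' Export a dendrogram as a Newick tree
#'
#' Branch lengths are height increments between nested merges.
#'
#' @param x an [hierarchical_cluster()] result.
#' @param file optional path; if missing the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(x, file = NULL) {
  phy <- ape::as.phylo(x$hclust)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}

#' Canonical discriminant projection of labelled feature vectors
#'
#' Descriptive linear discriminant projection: axes are the leading
#' eigenvectors of W^-1 B, with W the pooled within-class scatter (shrunk
#' toward its diagonal if ill-conditioned) and B the between-class scatter
#' of class means. At most (number of classes - 1) axes are returned,
#' scaled so that the within-class covariance of the scores is spherical
#' (axes orthonormal in the within-class metric).
#'
#' @param features data frame or matrix of observations x features.
#' @param class vector of class labels (length = observations), or the
#'   name of a column of `features` holding them.
#' @param n_axes number of axes to keep (default min(2, classes - 1)).
#' @param cond_limit,lambdas conditioning controls for W, as in
#'   [mahalanobis_blocks()].
#' @return an object of class `discriminant_projection`: list with `axes`
#'   (features x n_axes matrix), `scores` (tibble: class, axis scores),
#'   `centroids` (tibble), `eigenvalues`, `degenerate` (TRUE when the
#'   between-class scatter vanishes, i.e. identical class means).
#' @export
canonical_discriminant <- function(features, class, n_axes = NULL,
                                   cond_limit = 1e8,
                                   lambdas = c(0, 1e-4, 1e-3, 1e-2)) {
  if (is.character(class) && length(class) == 1L && class %in% names(features)) {
    cls <- factor(features[[class]])
    features <- features[setdiff(names(features), class)]
  } else {
    cls <- factor(class)
  }
  m <- feature_matrix(features)
  if (nlevels(cls) < 2) abort("need at least 2 classes.")
  if (any(table(cls) < 2)) abort("every class needs at least 2 observations.")
  p <- ncol(m)
  mu <- colMeans(m)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (lv in levels(cls)) {
    rows <- m[cls == lv, , drop = FALSE]
    ck <- colMeans(rows)
    W <- W + crossprod(sweep(rows, 2, ck))
    B <- B + nrow(rows) * tcrossprod(ck - mu)
  }
  W <- W / (nrow(m) - nlevels(cls))

  degenerate <- sum(B^2) < 1e-20 * max(1, sum(W^2))
  n_axes <- n_axes %||% min(2L, nlevels(cls) - 1L)
  if (degenerate) {
    warn("identical class means: between-class scatter is zero; projection degenerate.")
    axes <- matrix(0, p, n_axes)
    eigenvalues <- rep(0, n_axes)
  } else {
    # whiten W (with shrinkage if needed), then eigen-decompose in the
    # whitened space: axes = W^{-1/2} U
    dW <- diag(diag(W), p)
    Ws <- W
    for (lam in lambdas) {
      Ws <- if (lam == 0) W else (1 - lam) * W + lam * dW
      rc <- tryCatch(rcond(Ws), error = function(e) 0)
      if (rc > 0 && 1 / rc < cond_limit) break
      if (lam == lambdas[length(lambdas)]) {
        abort("within-class scatter singular even after maximum shrinkage.")
      }
    }
    eW <- eigen(Ws, symmetric = TRUE)
    Wmh <- eW$vectors %*% diag(1 / sqrt(pmax(eW$values, 1e-300)), p) %*% t(eW$vectors)
    M <- Wmh %*% B %*% Wmh
    eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
    k <- min(n_axes, nlevels(cls) - 1L)
    axes <- Wmh %*% eM$vectors[, seq_len(k), drop = FALSE]
    eigenvalues <- eM$values[seq_len(k)]
    if (k < n_axes) {
      axes <- cbind(axes, matrix(0, p, n_axes - k))
      eigenvalues <- c(eigenvalues, rep(0, n_axes - k))
    }
  }
  sc <- m %*% axes
  colnames(sc) <- paste0("axis", seq_len(ncol(sc)))
  scores <- dplyr::bind_cols(tibble(class = cls), as_tibble(sc))
  centroids <- scores |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("axis"), mean),
                     .groups = "drop")
  structure(list(axes = axes, scores = scores, centroids = centroids,
                 eigenvalues = eigenvalues, degenerate = degenerate),
            class = "discriminant_projection")
}

#' @export
print.discriminant_projection <- function(x, ...) {
  cat("<discriminant_projection>", ncol(x$axes), "axis/axes,",
      nrow(x$scores), "observations",
      if (x$degenerate) "(degenerate)" else "", "\n")
  invisible(x)
}

#' @export
tidy.discriminant_projection <- function(x, ...) x$scores
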