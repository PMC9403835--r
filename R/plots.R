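#' Plot a distance function with its significant maxima
#'
#' Mirrors the standard border-detection display: D2 against the profile
#' index, significant positions highlighted.
#'
#' @param object a [md_function()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.distance_function <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$d2)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_point(data = dplyr::filter(object, .data$significant),
                        colour = "red", size = 1.6) +
    ggplot2::labs(x = "profile index",
                  y = expression(D^2),
                  title = sprintf("Mahalanobis distance function (b = %d)",
                                  object$b[1])) +
    ggplot2::theme_minimal()
}

#' Plot candidate borders across block sizes
#'
#' The block-size / position scatter used to judge multi-scale support:
#' one dot per significant maximum, accepted consensus positions as
#' vertical lines.
#'
#' @param candidates tibble with `position` and `b` (row-bound
#'   [detect_maxima()] output).
#' @param accepted optional [accept_borders()] tibble.
#' @return a ggplot.
#' @export
plot_block_size_support <- function(candidates, accepted = NULL) {
  p <- ggplot2::ggplot(candidates,
                       ggplot2::aes(x = .data$position, y = .data$b)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "profile index", y = "block size b") +
    ggplot2::theme_minimal()
  if (!is.null(accepted) && nrow(accepted)) {
    p <- p + ggplot2::geom_vline(xintercept = accepted$position,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot a GLI profile (or mean profile)
#'
#' @param profile tibble with `depth` and `gli` (e.g. [mean_profile()]).
#' @return a ggplot.
#' @export
plot_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$depth, y = .data$gli)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cortical depth (%)", y = "GLI") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.distance_function
#' @export
autoplot.area_dendrogram <- function(object, ...) {
  hc <- object$hclust
  ord <- hc$order
  seg <- dendro_segments(hc)
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_along(ord),
                                labels = hc$labels[ord]) +
    ggplot2::labs(x = NULL, y = "Ward merge cost") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# horizontal/vertical segments of an hclust tree in leaf-order coordinates
dendro_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- numeric(n)
  leaf_x[hc$order] <- seq_len(n)
  mx <- numeric(nrow(hc$merge)); my <- numeric(nrow(hc$merge))
  segs <- list()
  pos <- function(k) if (k < 0) c(leaf_x[-k], 0) else c(mx[k], my[k])
  for (i in seq_len(nrow(hc$merge))) {
    a <- pos(hc$merge[i, 1]); b <- pos(hc$merge[i, 2])
    h <- hc$height[i]
    mx[i] <- (a[1] + b[1]) / 2; my[i] <- h
    segs[[length(segs) + 1L]] <- tibble(
      x = c(a[1], a[1], b[1]), y = c(a[2], h, h),
      xend = c(a[1], b[1], b[1]), yend = c(h, h, b[2])
    )
  }
  dplyr::bind_rows(segs)
}

#' @rdname autoplot.distance_function
#' @export
autoplot.discriminant_projection <- function(object, ...) {
  sc <- object$scores
  if (!"axis2" %in% names(sc)) sc$axis2 <- 0
  ce <- object$centroids
  if (!"axis2" %in% names(ce)) ce$axis2 <- 0
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(data = ce, shape = 4, size = 4, stroke = 1.5) +
    ggplot2::stat_ellipse(level = 0.68, linetype = "dashed") +
    ggplot2::labs(x = "canonical axis 1", y = "canonical axis 2") +
    ggplot2::theme_minimal()
}

#' Display a GLI map or section image
#'
#' @param object a `gli_map`.
#' @param ... unused.
#' @return a ggplot raster of the GLI values.
#' @export
autoplot.gli_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$field_col, y = .data$field_row,
                                   fill = .data$gli)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "GLI") +
    ggplot2::theme_minimal()
}
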