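#' Barycentric coordinates for a compositional plot
#'
#' Places the K archetypes on a regular polygon (ordered by descending total
#' alpha mass, clockwise from the top of the unit circle) and positions each
#' individual at the alpha-weighted barycentric combination of the vertices.
#' Pure geometry; the companion [compositional_plot()] renders it.
#'
#' @param alpha N x K matrix of simplex-valued rows, K >= 2.
#' @param labels optional N population labels.
#' @return list with `points` (tibble: sample, x, y, label) and `vertices`
#'   (tibble: archetype, x, y).
#' @export
compositional_coords <- function(alpha, labels = NULL) {
  alpha <- as.matrix(alpha)
  k <- ncol(alpha)
  if (k < 2) stop("compositional coordinates require K >= 2")
  ord <- order(colSums(alpha), decreasing = TRUE)
  arch_names <- colnames(alpha) %||% paste0("A", seq_len(k))
  # clockwise from the top: angle pi/2 - 2*pi*(rank-1)/k
  rank_of <- match(seq_len(k), ord)
  theta <- pi / 2 - 2 * pi * (rank_of - 1) / k
  vx <- cos(theta)
  vy <- sin(theta)
  pts <- alpha %*% cbind(vx, vy)
  samples <- rownames(alpha) %||% paste0("ind_", seq_len(nrow(alpha)))
  list(
    points = tibble::tibble(sample = samples, x = pts[, 1], y = pts[, 2],
                            label = labels %||% NA_character_),
    vertices = tibble::tibble(archetype = arch_names, x = vx, y = vy)
  )
}

#' Compositional plot of ancestry fractions
#'
#' Each individual is drawn inside a regular K-gon at the barycentric
#' combination of the archetype vertices given by its ancestry fractions;
#' individuals near a vertex are nearly pure, points along edges or
#' diagonals are admixed.
#'
#' @param alpha N x K matrix of simplex-valued rows.
#' @param labels optional N population labels used for point colour.
#' @param out optional file path; when given the plot is saved (device
#'   chosen from the extension by [ggplot2::ggsave()]).
#' @return the ggplot object, invisibly when `out` is given.
#' @export
compositional_plot <- function(alpha, labels = NULL, out = NULL) {
  cc <- compositional_coords(alpha, labels)
  poly <- cc$vertices[c(seq_len(nrow(cc$vertices)), 1L), ]
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = poly, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "grey60") +
    ggplot2::geom_point(
      data = cc$points,
      ggplot2::aes(x = .data$x, y = .data$y,
                   colour = if (all(is.na(cc$points$label))) NULL else .data$label),
      size = 1, alpha = 0.8) +
    ggplot2::geom_text(data = cc$vertices,
                       ggplot2::aes(x = 1.08 * .data$x, y = 1.08 * .data$y,
                                    label = .data$archetype)) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "population", x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = 6, height = 6)
    return(invisible(p))
  }
  p
}

#' Stacked-bar data for an ancestry bar plot
#'
#' Orders individuals by group label and lays out one stacked bar per
#' individual whose segment heights are the ancestry fractions. Returns the
#' plot-ready table plus the cumulative group boundaries, so the geometry is
#' testable without rendering.
#'
#' @param alpha N x K matrix of simplex-valued rows.
#' @param group_labels N labels used for ordering and separators.
#' @return list with `segments` (tibble: position, sample, group, archetype,
#'   height) and `boundaries` (tibble: group, end) where `end` is the
#'   cumulative individual count at the right edge of each group.
#' @export
ancestry_bar_data <- function(alpha, group_labels = NULL) {
  alpha <- as.matrix(alpha)
  n <- nrow(alpha)
  k <- ncol(alpha)
  groups <- group_labels %||% rep("all", n)
  ord <- order(groups, seq_len(n))
  arch_names <- colnames(alpha) %||% paste0("A", seq_len(k))
  samples <- rownames(alpha) %||% paste0("ind_", seq_len(n))
  segs <- tibble::tibble(
    position = rep(seq_len(n), times = k),
    sample = rep(samples[ord], times = k),
    group = rep(groups[ord], times = k),
    archetype = rep(arch_names, each = n),
    height = as.vector(alpha[ord, , drop = FALSE])
  )
  counts <- table(factor(groups, levels = unique(groups[ord])))
  list(segments = segs,
       boundaries = tibble::tibble(group = names(counts),
                                   end = cumsum(as.integer(counts))))
}

#' Ancestry bar plot
#'
#' One narrow stacked bar per individual, grouped by population label, with
#' segment heights equal to the ancestry fractions (the familiar admixture
#' bar plot).
#'
#' @inheritParams ancestry_bar_data
#' @param out optional output file path.
#' @return the ggplot object, invisibly when `out` is given.
#' @export
ancestry_barplot <- function(alpha, group_labels = NULL, out = NULL) {
  bd <- ancestry_bar_data(alpha, group_labels)
  p <- ggplot2::ggplot(bd$segments,
                       ggplot2::aes(x = .data$position, y = .data$height,
                                    fill = .data$archetype)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_vline(data = bd$boundaries,
                        ggplot2::aes(xintercept = .data$end + 0.5),
                        colour = "white", linewidth = 0.3) +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(
      breaks = bd$boundaries$end - diff(c(0, bd$boundaries$end)) / 2,
      labels = bd$boundaries$group, expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = "ancestry fraction", fill = "archetype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1),
                   panel.grid = ggplot2::element_blank())
  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = 8, height = 3.5)
    return(invisible(p))
  }
  p
}

#' Plot an archetypal fit
#'
#' `type = "composition"` draws the polygon compositional plot of the
#' ancestry fractions; `type = "bars"` the stacked bar plot.
#'
#' @param object an `aa_fit`.
#' @param type `"composition"` or `"bars"`.
#' @param labels optional per-sample labels.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.aa_fit <- function(object, type = c("composition", "bars"),
                            labels = NULL, ...) {
  type <- match.arg(type)
  if (type == "composition") compositional_plot(object$alpha, labels)
  else ancestry_barplot(object$alpha, labels)
}
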