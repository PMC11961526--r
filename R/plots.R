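#' Isometric-size boxplots per group for one element
#'
#' The per-element group comparison figure: one box (median, quartiles,
#' Tukey 1.5 x IQR whiskers) of specimen isometric size per group.
#'
#' @param tab Specimen tibble.
#' @param element Element name.
#' @param subset_id Variable subset the size index is computed over
#'   (default `"all"`).
#' @param registry Measurement registry.
#' @return A ggplot object.
#' @export
plot_isize_boxplots <- function(tab, element, subset_id = "all",
                                registry = measurement_registry()) {
  m <- select_matrix(tab, element, subset_id, registry = registry)
  spec <- assign_groups(m$specimens)
  df <- tibble::tibble(group_label = spec$group_label, isize = isize(m$x))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group_label, y = .data$isize)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(
      title = paste0("Isometric size, ", element, " (", subset_id, " variables)"),
      x = NULL, y = "iSize (log units)"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scatterplot of two measurement or index axes
#'
#' @param points Tibble from [build_scatter()].
#' @return A ggplot object, points coloured by group.
#' @export
plot_scatter <- function(points) {
  ggplot2::ggplot(points, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$group_label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = unique(points$x_label), y = unique(points$y_label),
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' Save the standard figure set for an assemblage
#'
#' Writes per-element isometric-size boxplots and any requested scatter
#' figures as PNG files.
#'
#' @param tab Specimen tibble.
#' @param dir Output directory.
#' @param elements Elements to plot.
#' @param scatters Optional list of `list(element =, x =, y =)` specs.
#' @param registry Measurement registry.
#' @return Paths written, invisibly.
#' @export
save_figures <- function(tab, dir,
                         elements = setdiff(osteo_elements(), "pelvis"),
                         scatters = NULL,
                         registry = measurement_registry()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (el in elements) {
    p <- file.path(dir, paste0("isize_", el, ".png"))
    g <- plot_isize_boxplots(tab, el, registry = registry)
    ggplot2::ggsave(p, g, width = 6, height = 4, dpi = 150)
    paths <- c(paths, p)
  }
  for (sc in scatters) {
    pts <- build_scatter(tab, sc$element, sc$x, sc$y, registry = registry)
    p <- file.path(dir, paste0("scatter_", sc$element, "_", sc$x, "_", sc$y, ".png"))
    ggplot2::ggsave(p, plot_scatter(pts), width = 6, height = 4, dpi = 150)
    paths <- c(paths, p)
  }
  invisible(paths)
}
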