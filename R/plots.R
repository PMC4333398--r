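#' @importFrom ggplot2 ggplot aes geom_line geom_tile geom_vline geom_point
#'   labs scale_fill_gradient2 theme_minimal facet_wrap
NULL

#' Plot an average metagene profile
#'
#' @param object A `metagene_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  anchor <- attr(object, "anchor") %||% "anchor"
  ggplot(as_tibble(object), aes(x = .data$offset, y = .data$value)) +
    geom_vline(xintercept = 0, linetype = "dotted", colour = "grey40") +
    geom_line(na.rm = TRUE) +
    labs(
      x = paste0("position relative to ", toupper(anchor), " (bp)"),
      y = paste0("signal (", attr(object, "scale") %||% "a.u.", ")")
    ) +
    theme_minimal()
}

#' Heat map of a metagene matrix
#'
#' Rows keep the matrix order (use [length_sorted_heatmap()] first for the
#' length-ordered layout).
#'
#' @param object A `metagene_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metagene_matrix <- function(object, ...) {
  anchor <- attr(object, "anchor") %||% "anchor"
  long <- as_tibble(object) |>
    mutate(.row = factor(.data$gene_id, levels = rev(.data$gene_id))) |>
    tidyr::pivot_longer(-c("gene_id", ".row"),
                        names_to = "offset", values_to = "value") |>
    mutate(offset = as.numeric(.data$offset))
  ggplot(long, aes(x = .data$offset, y = .data$.row, fill = .data$value)) +
    geom_tile() +
    geom_vline(xintercept = 0, linetype = "dotted", colour = "grey20") +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                         midpoint = 0, na.value = "grey90") +
    labs(x = paste0("position relative to ", toupper(anchor), " (bp)"),
         y = NULL, fill = attr(object, "scale") %||% "value") +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

#' Plot cluster centroid profiles
#'
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @return A ggplot with one panel per cluster.
#' @export
autoplot.cluster_result <- function(object, ...) {
  cen <- as_tibble(object$centroids, .name_repair = "minimal")
  cen$cluster <- factor(seq_len(nrow(cen)))
  long <- tidyr::pivot_longer(cen, -"cluster",
                              names_to = "offset", values_to = "value") |>
    mutate(offset = as.numeric(.data$offset))
  ggplot(long, aes(x = .data$offset, y = .data$value)) +
    geom_line() +
    facet_wrap(~cluster) +
    labs(x = "offset (bp)", y = "centroid (z-score units)") +
    theme_minimal()
}
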