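#' Plot an airway tree projected onto the reference plane
#'
#' Projects every centreline onto the trachea--mainstem plane (x: lateral,
#' y: along the trachea) with line width proportional to branch diameter.
#'
#' @param object An [airway_tree()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot airway_tree
#' @export
autoplot.airway_tree <- function(object, ...) {
  nref <- unitv(object$reference_plane$normal)
  zax <- unitv(object$frame$trachea_axis %||% c(0, 0, -1))
  xax <- vcross(nref, zax)
  df <- dplyr::bind_rows(lapply(object$branches, function(b) {
    tibble::tibble(
      id = b$id,
      u = as.numeric(b$centerline %*% xax),
      v = as.numeric(b$centerline %*% zax),
      diameter_mm = b$diameter_mm,
      generation = b$generation
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v, group = .data$id,
                                   linewidth = .data$diameter_mm,
                                   colour = .data$generation)) +
    ggplot2::geom_path(lineend = "round") +
    ggplot2::scale_linewidth(range = c(0.2, 4), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (mm)", y = "caudal (mm)",
                  colour = "generation") +
    ggplot2::theme_minimal()
}

#' Plot a bifurcating-plane rotation series
#'
#' @param series Tibble from [plane_rotation_series()].
#' @return A ggplot object.
#' @export
plot_rotation_series <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$index, y = .data$rotation_deg)) +
    ggplot2::geom_hline(yintercept = c(-90, 0, 90), linetype = 3,
                        colour = "grey60") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$planarity), size = 2) +
    ggplot2::scale_y_continuous(breaks = c(-90, -45, 0, 45, 90),
                                limits = c(-95, 95)) +
    ggplot2::labs(x = "bifurcation number from the carina",
                  y = "bifurcating-plane rotation (deg)") +
    ggplot2::theme_minimal()
}

#' Plot diameter ratios against generation
#'
#' The bimodal minor-daughter ratio (in-plane vs out-of-plane) is the
#' signature of the monopodial morphology.
#'
#' @param records Tibble from [compute_bifurcations()].
#' @return A ggplot object.
#' @export
plot_diameter_ratios <- function(records) {
  long <- tidyr::pivot_longer(records, c("d1_ratio", "d2_ratio"),
                              names_to = "ratio", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$value,
                                     colour = .data$planarity)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~ratio) +
    ggplot2::labs(x = "parent generation", y = "daughter/parent diameter ratio") +
    ggplot2::theme_minimal()
}
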