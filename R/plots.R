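# ggplot2 figure methods for the result objects.

#' Plot area-binned 2D location histograms
#'
#' One heat-map panel per cell-area bin, foci per cell per bin; the old pole
#' points up (positive long-axis offsets).
#'
#' @param object A [build_location_histograms()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.location_histogram <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$short_mid, y = .data$long_mid,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~ round(.data$area_mid, 2), nrow = 1) +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "short-axis offset (µm)",
                  y = "long-axis offset (µm, old pole up)",
                  fill = "foci / cell / bin",
                  title = "Focus locations by cell area")
}

#' Plot an initiation-aligned RMSD curve
#'
#' Long- and short-axis RMSD versus time since initiation with SEM ribbons.
#' Horizontal reference lines (e.g. `sqrt(2)` times fitted location SDs) can
#' be supplied.
#'
#' @param object An [rmsd_curve()] result.
#' @param ref_lines Optional named numeric vector of horizontal references.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rmsd_curve <- function(object, ref_lines = NULL, ...) {
  long <- as_tibble(object) %>%
    tidyr::pivot_longer(c("rmsd_long", "rmsd_short"),
                        names_to = "axis", values_to = "rmsd") %>%
    mutate(sem = ifelse(.data$axis == "rmsd_long", .data$sem_long, .data$sem_short),
           axis = ifelse(.data$axis == "rmsd_long", "long axis", "short axis"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t_align, y = .data$rmsd,
                                          colour = .data$axis, fill = .data$axis)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rmsd - .data$sem,
                                      ymax = .data$rmsd + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time since initiation (min)", y = "RMSD (µm)",
                  colour = NULL, fill = NULL,
                  title = "Initiation-aligned, drift-subtracted RMSD")
  if (!is.null(ref_lines)) {
    p <- p + ggplot2::geom_hline(yintercept = ref_lines, linetype = "dashed")
  }
  p
}

#' Plot a spatially binned mean 1-s displacement map
#'
#' Heat map of the mean 1-s displacement per spatial bin; masked bins
#' (those with too few displacements) are black.
#'
#' @param object A [spatial_displacement_map()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spatial_displacement_map <- function(object, ...) {
  d <- as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$short_mid, y = .data$long_mid,
                                       fill = .data$mean_disp)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "plasma", na.value = "black") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "short-axis offset (µm)",
                  y = "long-axis offset (µm, old pole up)",
                  fill = "mean 1-s step (µm)",
                  title = "Spatially binned 1-s displacements")
  if (!all(is.na(d$area_bin))) {
    p <- p + ggplot2::facet_wrap(~ round(.data$area_mid, 2), nrow = 1)
  }
  p
}

#' Plot a displacement- or distance-by-area profile
#'
#' Mean value per cell-area bin with SEM error bars; an optional vertical
#' line marks a model-predicted replication area.
#'
#' @param object An `area_profile` from [displacement_by_area()].
#' @param predicted Optional predicted replication area(s) (um^2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.area_profile <- function(object, predicted = NULL, ...) {
  value <- attr(object, "value")
  d <- as_tibble(object) %>% filter(.data$n > 0)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$area_mid, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cell area (µm²)",
                  y = paste0("mean ", value, " (µm)"),
                  title = "Area-binned profile")
  if (!is.null(predicted)) {
    p <- p + ggplot2::geom_vline(xintercept = predicted, linetype = "dashed",
                                 colour = "cyan4")
  }
  p
}
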