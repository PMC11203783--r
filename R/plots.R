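#' Plot hexagon colour loci
#'
#' Draws the colour hexagon (unit circumradius, vertices at the pure-receptor
#' excitations) with the stimulus loci and the adapting background at the
#' centre.
#'
#' @param object A `bee_loci` tibble from [contrast_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' loci <- contrast_report(gen_cardboard_spectra(), "green_background")
#' autoplot(loci)
#' @export
autoplot.bee_loci <- function(object, ...) {
  # vertices of the hexagon: images of the unit cube's corners with one or
  # two receptors fully excited, in clockwise order from "blue" at the top
  ang <- seq(0, 300, by = 60) * pi / 180
  hex <- tibble::tibble(x = sin(ang), y = cos(ang))
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_polygon(data = hex, fill = NA, colour = "grey40") +
    ggplot2::annotate("point", x = 0, y = 0, shape = 8, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$name),
                       vjust = -0.8, size = 3) +
    ggplot2::coord_equal(xlim = c(-1.05, 1.05), ylim = c(-1.05, 1.05)) +
    ggplot2::labs(x = "hexagon x", y = "hexagon y",
                  title = "Bee colour hexagon") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.bee_loci
#' @param loci A `bee_loci` tibble.
#' @export
plot_hexagon <- function(loci, ...) autoplot.bee_loci(loci, ...)

#' Plot a preference summary
#'
#' Shows, per trait and species, the proportion of choices for the
#' alphabetically second variant with a 50% reference line; significant
#' cells (a preferred variant reported) are filled.
#'
#' @param prefs Output of [preference_table()].
#' @return A ggplot object.
#' @export
plot_preferences <- function(prefs) {
  prefs <- dplyr::mutate(prefs,
    share_b = .data$a / (.data$a + .data$b), # `a` counts the second variant

    significant = .data$preferred != "no preference"
  )
  ggplot2::ggplot(prefs, ggplot2::aes(.data$species, .data$share_b,
                                      fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(y = "share choosing second variant", x = NULL,
                  fill = "significant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
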