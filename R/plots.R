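#' Plot a free-energy profile
#'
#' Line plot of G(z) with a ribbon for the error band when present.
#'
#' @param object A [fep] profile.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fep <- function(object, ...) {
  p <- ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$z, y = .data$G))
  if ("err" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$G - .data$err, ymax = .data$G + .data$err),
      alpha = 0.25)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)", y = "G (kJ/mol)",
                  caption = attr(object, "reference"))
}

#' @export
autoplot.wham_fit <- function(object, ...) {
  autoplot.fep(object$profile) +
    ggplot2::labs(title = sprintf("WHAM profile (%d windows, %d iterations)",
                                  nrow(object$f), object$iterations))
}

#' @export
autoplot.translocation_assembly <- function(object, ...) {
  autoplot.fep(object$profile) +
    ggplot2::geom_point(data = object$states,
                        ggplot2::aes(x = .data$x, y = .data$G)) +
    ggplot2::geom_text(data = object$states,
                       ggplot2::aes(x = .data$x, y = .data$G,
                                    label = .data$state),
                       vjust = -1) +
    ggplot2::labs(title = sprintf("%s-terminus first, entry from %s leaflet",
                                  object$terminus, object$entry_side),
                  x = "path coordinate (nm)")
}

#' Plot an asymmetric profile with its region decomposition
#'
#' @param asym The asymmetric [fep] profile.
#' @param regions A `region_decomposition` from [classify_regions()].
#' @return A ggplot object with shaded mimicking/intermediate regions.
#' @export
plot_regions <- function(asym, regions) {
  autoplot.fep(asym) +
    ggplot2::geom_rect(
      data = as_tibble(regions),
      ggplot2::aes(xmin = .data$z_lo, xmax = .data$z_hi,
                   ymin = -Inf, ymax = Inf, fill = .data$region),
      alpha = 0.15, inherit.aes = FALSE) +
    ggplot2::labs(fill = "region")
}

#' Plot a window-overlap matrix
#'
#' @param m Overlap matrix from [overlap_matrix()].
#' @return A ggplot heat map.
#' @export
plot_overlap <- function(m) {
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$overlap <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$overlap)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "window", y = "window")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
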