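#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map of owners and their Delaunay neighbor links
#'
#' @param object a `weight_matrix` with coordinates.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot weight_matrix
#' @export
autoplot.weight_matrix <- function(object, ...) {
  if (is.null(object$coords)) stop("weight matrix has no coordinates")
  xy <- object$coords
  edges <- purrr::map_dfr(seq_along(object$neighbors), function(i) {
    js <- object$neighbors[[i]]
    js <- js[js > i]  # draw each undirected edge once
    if (length(js) == 0) return(NULL)
    tibble::tibble(x = xy[i, 1], y = xy[i, 2], xend = xy[js, 1], yend = xy[js, 2])
  })
  pts <- tibble::tibble(x = xy[, 1], y = xy[, 2])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      linewidth = 0.2, colour = "grey60"
    ) +
    ggplot2::geom_point(data = pts, ggplot2::aes(x = .data$x, y = .data$y), size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "east-west (km)", y = "north-south (km)",
                  title = "Delaunay neighbor structure")
}

#' Trace and density of the spatial dependence draws
#'
#' @param object a `sar_fit`.
#' @param parameter parameter to display (default the spatial dependence).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot sar_fit
#' @export
autoplot.sar_fit <- function(object, parameter = "spatial_dependence", ...) {
  if (parameter == "spatial_dependence") {
    if (object$rho_fixed) stop("rho was fixed; choose a coefficient instead")
    d <- object$rho_draws
  } else {
    if (!parameter %in% colnames(object$beta_draws)) {
      stop("unknown parameter: ", parameter)
    }
    d <- object$beta_draws[, parameter]
  }
  df <- tibble::tibble(iteration = seq_along(d), value = d,
                       chain = factor(object$chain_id))
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$value,
                                   colour = .data$chain)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(y = parameter, title = paste("Retained draws:", parameter))
}

#' Bar chart of the direct/indirect/total effect decomposition
#'
#' @param object an `effects_tbl` from [average_effects()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot effects_tbl
#' @export
autoplot.effects_tbl <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("direct", "indirect", "total"),
                              names_to = "component", values_to = "effect")
  ggplot2::ggplot(long, ggplot2::aes(.data$effect, .data$term,
                                     fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "marginal effect on outcome probability", y = NULL,
                  title = "Average direct, indirect, and total effects")
}
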