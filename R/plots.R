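# Diagnostic plots (ggplot2).

#' Plot per-step fitting diagnostics
#'
#' CC, potential energy and RMSD-to-start against simulated time for one or
#' several fits.
#'
#' @param results a `fit_result`, a list of them, or a records data.frame.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(results) {
  if (inherits(results, "fit_result")) results <- list(results)
  if (is.data.frame(results)) {
    tabs <- list(cbind(id = "1", results))
  } else {
    tabs <- lapply(results, function(r)
      cbind(id = as.character(r$id), r$records))
  }
  tab <- do.call(rbind, tabs)
  long <- rbind(
    data.frame(id = tab$id, time = tab$time, what = "CC", value = tab$cc),
    data.frame(id = tab$id, time = tab$time, what = "potential",
               value = tab$potential),
    data.frame(id = tab$id, time = tab$time, what = "RMSD", value = tab$rmsd))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     group = .data$id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (ps)", y = NULL)
}

#' Scatter plot of a conformational landscape
#'
#' @param landscape a `conf_landscape`.
#' @param axes which two components to display.
#' @param color optional per-particle values (e.g. ground-truth amplitude
#'   or cluster labels).
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape, axes = c(1, 2), color = NULL) {
  tab <- data.frame(x = landscape$coords[, axes[1]],
                    y = landscape$coords[, axes[2]])
  lab <- paste0(toupper(landscape$method), axes)
  if (length(landscape$explained_variance_fraction) >= max(axes))
    lab <- sprintf("%s (%.1f%%)", lab,
                   100 * landscape$explained_variance_fraction[axes])
  p <- if (is.null(color))
    ggplot2::ggplot(tab, ggplot2::aes(x = .data$x, y = .data$y))
  else {
    tab$color <- color
    ggplot2::ggplot(tab, ggplot2::aes(x = .data$x, y = .data$y,
                                      color = .data$color))
  }
  p + ggplot2::geom_point() + ggplot2::labs(x = lab[1], y = lab[2])
}

#' Heat map of a 2-D free-energy landscape
#'
#' @param fe result of [free_energy_map()] over two axes.
#' @return A ggplot object.
#' @export
plot_free_energy <- function(fe) {
  if (length(dim(fe$dG)) != 2) stop("plot_free_energy expects a 2-D map")
  tab <- expand.grid(x = fe$mids[[1]], y = fe$mids[[2]])
  tab$dG <- as.numeric(fe$dG)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$dG)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white", direction = -1) +
    ggplot2::labs(x = paste("axis", fe$axes[1]),
                  y = paste("axis", fe$axes[2]),
                  fill = expression(Delta * G ~ (k[B] * T)))
}
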