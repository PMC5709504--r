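#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_ribbon
#'   geom_raster labs scale_fill_gradient theme_minimal coord_equal
#' @export
ggplot2::autoplot

#' Plot a cell-cycle-time histogram, optionally with fitted curves
#'
#' @param object A [cct_histogram].
#' @param fits Optional list of [fit_cctd()] results to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cct_histogram
#' @export
autoplot.cct_histogram <- function(object, fits = NULL, ...) {
  p <- ggplot(object, aes(x = .data$mid, y = .data$density)) +
    geom_col(width = object$bin_right - object$bin_left,
             fill = "grey80", colour = "grey50") +
    labs(x = "cell-cycle time", y = "density") +
    theme_minimal()
  if (!is.null(fits)) {
    if (inherits(fits, "cct_fit")) fits <- list(fits)
    grid <- seq(min(object$bin_left), max(object$bin_right), length.out = 400)
    curves <- purrr::map_dfr(fits, function(f) {
      p <- f$params
      dens <- if (inherits(p, "eme_params")) {
        function(t) eme_pdf_raw(t, p)
      } else {
        function(t) dgamma(t, shape = p$k, rate = p$rate)
      }
      tibble(t = grid, density = dens(grid), family = f$family)
    })
    p <- p + geom_line(data = curves,
                       aes(x = .data$t, y = .data$density,
                           colour = .data$family))
  }
  p
}

#' @rdname autoplot.cct_histogram
#' @method autoplot cct_fit
#' @export
autoplot.cct_fit <- function(object, ...) {
  h <- cct_histogram(
    bin_edges = c(object$fitted$mid[1] -
                    diff(object$fitted$mid[1:2]) / 2,
                  object$fitted$mid + diff(object$fitted$mid[1:2]) / 2),
    heights = object$fitted$density)
  autoplot(h, fits = object)
}

#' Plot a stage-chain trajectory
#'
#' @param object An `"msc_trajectory"` from [simulate_chain()].
#' @param ... Unused.
#' @return A ggplot of per-stage counts and the total over time.
#' @method autoplot msc_trajectory
#' @export
autoplot.msc_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = dplyr::starts_with("stage_") |
                                dplyr::matches("^total$"),
                              names_to = "series", values_to = "cells")
  ggplot(long, aes(x = .data$time, y = .data$cells, colour = .data$series)) +
    geom_line() +
    labs(x = "time", y = "cells") +
    theme_minimal()
}

#' Plot an ensemble summary
#'
#' Mean total cell count with a +/- one-standard-deviation ribbon.
#'
#' @param object An `"msc_ensemble"` from [ensemble_summary()] or
#'   [simulate_stemcells()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msc_ensemble
#' @export
autoplot.msc_ensemble <- function(object, ...) {
  d <- as_tibble(object)
  d$sd <- sqrt(d$var_total)
  ggplot(d, aes(x = .data$time, y = .data$mean_total)) +
    geom_ribbon(aes(ymin = pmax(0, .data$mean_total - .data$sd),
                    ymax = .data$mean_total + .data$sd),
                fill = "steelblue", alpha = 0.25) +
    geom_line(colour = "steelblue") +
    labs(x = "time", y = "mean cells") +
    theme_minimal()
}

#' Plot lattice density trajectories
#'
#' @param object An `"msc_density"` or `"msc_density_ensemble"`.
#' @param ... Unused.
#' @return A ggplot of density against rescaled time.
#' @method autoplot msc_density
#' @export
autoplot.msc_density <- function(object, ...) {
  ggplot(object, aes(x = .data$tbar, y = .data$density)) +
    geom_line() +
    labs(x = "rescaled time (Pp t)", y = "occupied fraction") +
    theme_minimal()
}

#' @rdname autoplot.msc_density
#' @method autoplot msc_density_ensemble
#' @export
autoplot.msc_density_ensemble <- function(object, ...) {
  ggplot(object, aes(x = .data$tbar, y = .data$mean_density)) +
    geom_ribbon(aes(ymin = .data$mean_density - .data$sd_density,
                    ymax = .data$mean_density + .data$sd_density),
                fill = "darkgreen", alpha = 0.2) +
    geom_line(colour = "darkgreen") +
    labs(x = "rescaled time (Pp t)", y = "mean occupied fraction") +
    theme_minimal()
}

#' Render a lattice snapshot
#'
#' Greyscale occupancy plot of a stage-labelled grid: empty sites are white
#' and later cell-cycle stages are darker.
#'
#' @param grid Integer stage matrix as returned by [initialise_lattice()] or
#'   attached to [simulate_lattice()] snapshots.
#' @param k Number of stages (defaults to the largest stage present).
#' @return A ggplot object.
#' @export
plot_lattice_snapshot <- function(grid, k = max(grid)) {
  d <- tibble(x = rep(seq_len(nrow(grid)), ncol(grid)),
              y = rep(seq_len(ncol(grid)), each = nrow(grid)),
              stage = as.vector(grid))
  occupied <- d[d$stage > 0, , drop = FALSE]
  ggplot(occupied, aes(x = .data$x, y = .data$y, fill = .data$stage)) +
    geom_raster() +
    scale_fill_gradient(low = "grey85", high = "black", limits = c(1, max(k, 1))) +
    coord_equal(xlim = c(0.5, nrow(grid) + 0.5),
                ylim = c(0.5, ncol(grid) + 0.5)) +
    theme_minimal() +
    labs(x = NULL, y = NULL, fill = "stage")
}
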