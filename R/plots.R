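#' Plot a survival curve
#'
#' Step plot of the estimated survivor function, optionally overlaid with a
#' fitted survival model (dashed) and the 50\% survival line.
#'
#' @param x A \code{survival_curve}.
#' @param fit Optional \code{survival_fit} to overlay.
#' @param ... Passed to \code{plot}.
#' @export
plot.survival_curve <- function(x, fit = NULL, ...) {
  plot(x$generations, x$survival, type = "s", lwd = 2,
       xlab = "Replicative age (generations)", ylab = "Fraction surviving, S(g)",
       ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, col = "steelblue", lty = 3)
  if (!is.null(fit)) {
    gg <- seq(0, max(x$generations), length.out = 200)
    graphics::lines(gg, survival_fn(fit$model, gg), col = "red", lty = 2, lwd = 2)
    graphics::legend("topright", bty = "n",
                     legend = c("Kaplan-Meier",
                                sprintf("%s fit (RLS %.1f)", fit$kind, fit$rls)),
                     col = c("black", "red"), lty = c(1, 2), lwd = 2)
  }
  invisible(x)
}

#' Plot a hazard curve
#'
#' @param x A \code{hazard_curve}.
#' @param ... Passed to \code{plot}.
#' @export
plot.hazard_curve <- function(x, ...) {
  plot(x$generations, x$hazard,
       type = if (x$source == "fitted") "l" else "p", pch = 16,
       xlab = "Replicative age (generations)",
       ylab = expression(paste("Hazard ", lambda(g), " (per generation)")),
       main = sprintf("Hazard (%s)", x$source), ...)
  invisible(x)
}

#' Plot an RLS contour map over the Gompertz coefficients
#'
#' Filled contours of the replicative lifespan over the
#' (\eqn{\alpha}, \eqn{\beta}) plane, with optional strain markers.
#'
#' @param x A \code{\link{rls_contour_grid}}.
#' @param levels Contour levels in generations.
#' @param ... Passed to \code{contour}.
#' @export
plot.contour_grid <- function(x, levels = c(2, 5, 10, 20, 40, 80), ...) {
  graphics::contour(log10(x$alpha_values), x$beta_values, x$rls_matrix,
                    levels = levels,
                    xlab = expression(log[10](alpha)),
                    ylab = expression(beta),
                    main = "RLS (generations)", ...)
  if (!is.null(x$strain_points)) {
    sp <- x$strain_points
    graphics::points(log10(sp$alpha), sp$beta, pch = 19, col = "red")
    graphics::text(log10(sp$alpha), sp$beta, labels = sp$label, pos = 3, cex = 0.8)
  }
  invisible(x)
}

#' Plot a single-cell length trajectory
#'
#' @param x A \code{cell_trajectory}.
#' @param ... Passed to \code{plot}.
#' @export
plot.cell_trajectory <- function(x, ...) {
  plot(x$times, x$lengths, type = "l",
       xlab = "Time (h)", ylab = expression(paste("Length (", mu, "m)")), ...)
  graphics::abline(v = x$division_times, col = "gray70", lty = 3)
  invisible(x)
}
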