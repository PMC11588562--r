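#' Plot the fitness landscape and its adaptive regions
#'
#' Draws the double- and mono-ovulation fitness curves over the resource
#' axis, shades the intervals where double ovulation is favoured, and marks
#' the region boundaries (the roots of the selection quadratic and the
#' twinning threshold `E*`).
#'
#' @param eco An [ovulation_ecology()].
#' @param n_grid Grid resolution for the curves (default 401).
#' @param tol Passed to [partition_resource_space()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the region table.
#' @export
plot_resource_regions <- function(eco, n_grid = 401, tol = 1e-8, ...) {
  regions <- partition_resource_space(eco, tol = tol)
  curve <- ovulation_curve(eco, n_grid = n_grid)
  ylim <- range(curve$W_P, curve$W_S)
  graphics::plot(curve$E, curve$W_P, type = "n", xlim = c(0, 1), ylim = ylim,
                 xlab = "Resource endowment, E", ylab = "Fitness", ...)
  fav <- regions[regions$double_ov_favoured, , drop = FALSE]
  if (nrow(fav) > 0) {
    graphics::rect(fav$lower, ylim[1], fav$upper, ylim[2],
                   col = "#d8ecd8", border = NA)
  }
  graphics::lines(curve$E, curve$W_P, lwd = 2, col = "#b2182b")
  graphics::lines(curve$E, curve$W_S, lwd = 2, col = "#2166ac")
  inner <- regions$lower[-1]
  graphics::abline(v = inner, lty = 3, col = "grey40")
  graphics::abline(v = eco$E_star, lty = 2, col = "grey20")
  graphics::mtext("E*", side = 3, at = eco$E_star, cex = 0.8)
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("#b2182b", "#2166ac"),
                   legend = c(expression(W[P] ~ "(double ovulation)"),
                              expression(W[S] ~ "(mono-ovulation)")))
  invisible(regions)
}
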