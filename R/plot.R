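#' Plot an activation map
#'
#' Draws the RMS topography as a colour image in grid orientation (row 1 at
#' the top, the fiber axis running down the page). Invalid positions are
#' left blank.
#'
#' @param map an [ActivationMap-class].
#' @param main plot title.
#' @param col colour palette.
#' @export
plotActivationMap <- function(map, main = "Activation map",
                              col = grDevices::hcl.colors(64, "viridis")) {
  v <- mapValues(map)
  graphics::image(x = seq_len(ncol(v)), y = seq_len(nrow(v)),
                  z = t(v[rev(seq_len(nrow(v))), , drop = FALSE]),
                  col = col, xlab = "column", ylab = "row (fiber axis)",
                  main = main, axes = FALSE, useRaster = FALSE)
  graphics::axis(1, at = seq_len(ncol(v)))
  graphics::axis(2, at = seq_len(nrow(v)), labels = rev(seq_len(nrow(v))))
  graphics::box()
}

#' @describeIn plotActivationMap overlay of a CoG trajectory on the grid:
#'   the barycentre path coloured from early (light) to late (dark).
#' @param traj a [CoGTrajectory-class].
#' @param geometry a [GridGeometry-class] framing the axes.
#' @param add add to an existing plot.
#' @export
plotCoGTrajectory <- function(traj, geometry = GridGeometry(),
                              main = "CoG trajectory", add = FALSE) {
  n <- length(trajTimes(traj))
  shade <- grDevices::gray(seq(0.8, 0.1, length.out = n))
  if (!add)
    graphics::plot(NA, xlim = c(1, geometry@nCols),
                   ylim = c(geometry@nRows, 1),
                   xlab = "column (y)", ylab = "row (x, fiber axis)",
                   main = main)
  graphics::lines(trajY(traj), trajX(traj), col = "grey70")
  graphics::points(trajY(traj), trajX(traj), pch = 19, col = shade)
}
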