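#' Plotting helpers
#'
#' Base-graphics views of the main result objects: 1D density profiles with
#' their pinned constraints, and the gradient-distribution cloud against
#' the analytic sigmoid relation.
#'
#' @name gliostat-plots
NULL

#' @export
plot.forward_solution <- function(x, which = NULL, ...) {
  if (x$grid$dim != 1) {
    stop("plotting is implemented for 1D trajectories; export 2D/3D fields via write_vtk",
         call. = FALSE)
  }
  xs <- node_coords(x$grid)[, 1]
  cols <- if (is.null(which)) seq_along(x$times) else which
  graphics::matplot(xs, x$states[, cols, drop = FALSE], type = "l", lty = 1,
                    xlab = "x", ylab = "density u", ...)
  graphics::legend("topright", legend = sprintf("t = %g", x$times[cols]),
                   lty = 1, col = seq_along(cols), cex = 0.7, bty = "n")
  invisible(x)
}

#' @export
plot.stationary_solution <- function(x, reference = NULL, ...) {
  if (x$grid$dim != 1) {
    stop("plotting is implemented for 1D solutions; export 2D/3D fields via write_vtk",
         call. = FALSE)
  }
  xs <- node_coords(x$grid)[, 1]
  graphics::plot(xs, x$u, type = "l", xlab = "x", ylab = "density u", ...)
  if (!is.null(reference)) graphics::lines(xs, reference, lty = 2)
  if (length(x$constraints$indices)) {
    graphics::points(xs[x$constraints$indices],
                     rep(x$constraints$value, length(x$constraints$indices)),
                     pch = 16)
  }
  invisible(x)
}

#' @export
plot.gradient_cloud <- function(x, ...) {
  s <- x$samples
  graphics::plot(s$u, s$grad_mag, pch = ".", xlab = "density u",
                 ylab = "|grad u|", ...)
  uu <- seq(0, 1, length.out = 200)
  graphics::lines(uu, sqrt(2 / 3) * (1 - sqrt(uu)) * uu, col = 2, lwd = 2)
  invisible(x)
}
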