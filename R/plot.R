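#' @export
plot.centerline <- function(x, plane = c("xz", "xy", "yz"), add = FALSE,
                            col = "black", lwd = 1.5, ...) {
  plane <- match.arg(plane)
  ax <- switch(plane, xz = c(1L, 3L), xy = c(1L, 2L), yz = c(2L, 3L))
  labs <- c("left-right x (mm)", "antero-posterior y (mm)",
            "cranio-caudal z (mm)")
  pts <- unclass(as.matrix(x))
  if (add) {
    graphics::lines(pts[, ax[1]], pts[, ax[2]], col = col, lwd = lwd, ...)
  } else {
    plot(pts[, ax[1]], pts[, ax[2]], type = "l", asp = 1, col = col,
         lwd = lwd, xlab = labs[ax[1]], ylab = labs[ax[2]], ...)
  }
  invisible(x)
}

#' @export
plot.rod_equilibrium <- function(x, rod = NULL, plane = "xz", ...) {
  plot(x$centerline, plane = plane, col = "firebrick", ...)
  if (!is.null(rod))
    plot(centerline(rod$rest), plane = plane, add = TRUE, col = "grey40",
         lwd = 1)
  graphics::legend("topleft", bty = "n", lwd = c(1.5, 1),
                   col = c("firebrick", "grey40"),
                   legend = c("equilibrium", "rest"))
  invisible(x)
}

#' Plot a breathing simulation
#'
#' Overlays the inspiration (rest, grey) and expiration (equilibrium, red)
#' centerlines of both renal branches, in the frontal (x-z) plane by default.
#'
#' @param x a `breathing_simulation`.
#' @param plane projection plane ("xz", "xy" or "yz").
#' @param ... further arguments to the base plot.
#' @export
plot.breathing_simulation <- function(x, plane = "xz", ...) {
  pts <- rbind(unclass(x$left$inspiration), unclass(x$right$inspiration),
               unclass(x$left$expiration), unclass(x$right$expiration))
  ax <- switch(plane, xz = c(1L, 3L), xy = c(1L, 2L), yz = c(2L, 3L))
  plot(range(pts[, ax[1]]), range(pts[, ax[2]]), type = "n", asp = 1,
       xlab = "mm", ylab = "mm", ...)
  for (side in c("left", "right")) {
    plot(x[[side]]$inspiration, plane = plane, add = TRUE, col = "grey55",
         lwd = 1)
    plot(x[[side]]$expiration, plane = plane, add = TRUE, col = "firebrick")
  }
  graphics::legend("topleft", bty = "n", lwd = c(1, 1.5),
                   col = c("grey55", "firebrick"),
                   legend = c("inspiration (rest)", "expiration"))
  invisible(x)
}
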