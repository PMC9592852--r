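#' Screen geometry
#'
#' Describes the display the reaching task runs on. The pixel pitch (cm per
#' pixel) is derived from the diagonal size and the resolution assuming
#' square pixels, so physical quantities (velocities in cm/s, accuracies in
#' cm) can be recovered from pixel logs.
#'
#' The coordinate convention used throughout the package is Cartesian with
#' the origin at the screen centre and y increasing upward; the reach start
#' point sits at (0, -416) px, below the three targets.
#'
#' @param diagonal_inches Screen diagonal in inches (> 0).
#' @param resolution_x,resolution_y Resolution in pixels (> 0).
#' @return An object of class `screen_geometry` with fields
#'   `diagonal_inches`, `resolution_x`, `resolution_y` and the derived
#'   `px_to_cm` scale (cm per pixel).
#' @examples
#' geom <- screen_geometry(43, 1920, 1080)
#' round(64 * geom$px_to_cm, 2)  # 64 px circle diameter in cm
#' @export
screen_geometry <- function(diagonal_inches = 43,
                            resolution_x = 1920,
                            resolution_y = 1080) {
  if (!is.numeric(diagonal_inches) || length(diagonal_inches) != 1L ||
      !is.finite(diagonal_inches) || diagonal_inches <= 0)
    stop("`diagonal_inches` must be a single positive number", call. = FALSE)
  if (!is.numeric(resolution_x) || resolution_x <= 0 ||
      !is.numeric(resolution_y) || resolution_y <= 0)
    stop("resolution must be positive", call. = FALSE)
  g <- list(diagonal_inches = diagonal_inches,
            resolution_x = as.integer(resolution_x),
            resolution_y = as.integer(resolution_y))
  g$px_to_cm <- derive_px_to_cm_impl(diagonal_inches, resolution_x, resolution_y)
  class(g) <- "screen_geometry"
  g
}

derive_px_to_cm_impl <- function(diag_in, rx, ry) {
  diag_cm <- diag_in * 2.54
  width_cm <- diag_cm * rx / sqrt(rx^2 + ry^2)
  width_cm / rx
}

#' Physical pixel pitch of a screen
#'
#' @param geometry A [screen_geometry()] object.
#' @return Scale in cm per pixel, assuming square pixels.
#' @export
derive_px_to_cm <- function(geometry) {
  if (!inherits(geometry, "screen_geometry"))
    stop("`geometry` must be a screen_geometry object", call. = FALSE)
  geometry$px_to_cm
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("screen_geometry: %g\" %dx%d, %.5f cm/px\n",
              x$diagonal_inches, x$resolution_x, x$resolution_y, x$px_to_cm))
  invisible(x)
}

# Fixed task layout, px, Cartesian (origin screen centre, y up).
#' Task layout constants
#'
#' Start point and the three vertically arranged target centres of the
#' reaching task, in pixels (origin at screen centre, y up).
#'
#' @return Named list with `start` (length-2 numeric) and `targets`
#'   (3 x 2 matrix, rows low/middle/high).
#' @export
task_layout <- function() {
  list(start = c(x = 0, y = -416),
       targets = matrix(c(0, -96,
                          0, 64,
                          0, 224),
                        nrow = 3, byrow = TRUE,
                        dimnames = list(c("low", "middle", "high"),
                                        c("x", "y"))))
}
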