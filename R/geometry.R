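#' Display geometry for stimulus synthesis
#'
#' Describes the monitor as seen by the animal: a flat field spanning a fixed
#' visual angle, discretised into a pixel grid. All stimuli and filters are
#' generated on this grid. The default reduced resolution (64 x 48 pixels over
#' 120 x 90 degrees) oversamples the highest spatial frequency used in the
#' protocol (0.04 cycles/degree) by more than a factor of six, so nothing is
#' lost relative to a full-resolution render.
#'
#' @param azimuth_extent horizontal extent of the display, degrees.
#' @param elevation_extent vertical extent of the display, degrees.
#' @param pixels_x,pixels_y grid size. The aspect ratio must match the
#'   angular extents so that pixels are square in visual angle.
#' @return an object of class `display_geometry` with fields
#'   `azimuth_extent`, `elevation_extent`, `nx`, `ny`, `deg_per_px`, and
#'   centred coordinate vectors `x_deg` (rightward positive) and `y_deg`
#'   (upward positive).
#' @export
display_geometry <- function(azimuth_extent = 120, elevation_extent = 90,
                             pixels_x = 64, pixels_y = 48) {
  stopifnot(azimuth_extent > 0, elevation_extent > 0,
            pixels_x >= 2, pixels_y >= 2)
  dpp_x <- azimuth_extent / pixels_x
  dpp_y <- elevation_extent / pixels_y
  if (abs(dpp_x - dpp_y) > dpp_x * 0.01)
    stop("pixels must be square in visual angle: ",
         "azimuth_extent/pixels_x must equal elevation_extent/pixels_y")
  g <- list(
    azimuth_extent = azimuth_extent,
    elevation_extent = elevation_extent,
    nx = as.integer(pixels_x),
    ny = as.integer(pixels_y),
    deg_per_px = dpp_x,
    # pixel centres, centred on the display midpoint; y increases upward
    x_deg = (seq_len(pixels_x) - (pixels_x + 1) / 2) * dpp_x,
    y_deg = (seq_len(pixels_y) - (pixels_y + 1) / 2) * dpp_y
  )
  class(g) <- "display_geometry"
  g
}

#' @export
print.display_geometry <- function(x, ...) {
  cat(sprintf("<display_geometry> %g x %g deg, %d x %d px (%.3f deg/px)\n",
              x$azimuth_extent, x$elevation_extent, x$nx, x$ny, x$deg_per_px))
  invisible(x)
}

same_geometry <- function(a, b) {
  a$nx == b$nx && a$ny == b$ny &&
    abs(a$deg_per_px - b$deg_per_px) < 1e-9
}
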