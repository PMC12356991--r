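#' Detector system preset
#'
#' Bundles the acquisition geometry and noise model of a (synthetic) digital
#' mammography system: pixel pitch, detector gain and offset of the linear
#' response `pixel = gain * quanta + offset`, electronic noise, and the ROI
#' edge length used for the detection task.  The ROI always covers a
#' 10 mm x 10 mm window, so `roi_side * pixel_pitch` must be 10 mm to within
#' one pixel.
#'
#' @param name short label for the preset.
#' @param pixel_pitch detector pixel pitch in micrometers per pixel.
#' @param gain detector gain in digital units per quantum (>= 0; zero is the
#'   noiseless limit used in tests).
#' @param offset detector offset in digital units.
#' @param electronic_sigma electronic (additive Gaussian) noise SD in digital
#'   units.
#' @param roi_side ROI edge length in pixels.
#' @return An object of class `system_preset`.
#' @examples
#' system_preset("A", 100, 1.2, 50, 6, 100)
#' @export
system_preset <- function(name, pixel_pitch, gain, offset, electronic_sigma,
                          roi_side) {
  stopifnot(is.character(name), length(name) == 1L)
  if (pixel_pitch <= 0) stop("pixel_pitch must be positive")
  if (gain < 0) stop("gain must be non-negative")
  if (electronic_sigma < 0) stop("electronic_sigma must be non-negative")
  roi_mm <- roi_side * pixel_pitch / 1000
  # 1.5 px slack: a 10 mm window on a 70 um grid is 142.9 px, realized as 144
  if (abs(roi_mm - 10) > 1.5 * pixel_pitch / 1000 + 1e-9)
    stop("roi_side x pixel_pitch must be 10 mm to within about one pixel (got ",
         format(roi_mm), " mm)")
  structure(list(name = name, pixel_pitch = pixel_pitch, gain = gain,
                 offset = offset, electronic_sigma = electronic_sigma,
                 roi_side = as.integer(roi_side)),
            class = "system_preset")
}

#' Built-in detector presets
#'
#' Two presets ship by default, mirroring the geometry of the two systems the
#' pipeline is designed around: preset `"A"` uses a 100 um pitch with
#' 100 x 100 px ROIs (indirect-conversion-like), preset `"B"` a 70 um pitch
#' with 144 x 144 px ROIs (direct-conversion-like).  Their noise parameters
#' are package configuration values, not measurements of any vendor hardware.
#'
#' @param name `"A"` or `"B"`.
#' @return A [system_preset()].
#' @export
default_preset <- function(name = c("A", "B")) {
  name <- match.arg(name)
  switch(name,
    A = system_preset("A", pixel_pitch = 100, gain = 1.2, offset = 50,
                      electronic_sigma = 6, roi_side = 100),
    B = system_preset("B", pixel_pitch = 70, gain = 0.9, offset = 30,
                      electronic_sigma = 5, roi_side = 144))
}

#' @export
print.system_preset <- function(x, ...) {
  cat(sprintf("<system_preset %s> pitch %g um, ROI %d px, gain %g, offset %g, sigma_e %g\n",
              x$name, x$pixel_pitch, x$roi_side, x$gain, x$offset,
              x$electronic_sigma))
  invisible(x)
}
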