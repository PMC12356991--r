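#' Dose-reduction noise model parameters
#'
#' The two-component detector model: quantum noise with variance
#' `gain * (I - offset)` plus electronic noise of SD `electronic_sigma`.
#' Defaults are taken from the image's preset when omitted.
#'
#' @param fraction dose fraction gamma in `(0, 1]`.
#' @param gain,offset,electronic_sigma detector noise model, digital units.
#' @return list of class `dose_params`.
#' @export
dose_params <- function(fraction = 0.75, gain, offset, electronic_sigma) {
  if (fraction <= 0 || fraction > 1)
    stop("dose fraction must be in (0, 1]")
  if (gain <= 0) stop("gain must be positive")
  if (electronic_sigma < 0) stop("electronic_sigma must be non-negative")
  structure(list(fraction = fraction, gain = gain, offset = offset,
                 electronic_sigma = electronic_sigma),
            class = "dose_params")
}

#' Simulate a reduced-dose acquisition
#'
#' Scales the offset-corrected signal by the dose fraction gamma and injects
#' zero-mean Gaussian noise with per-pixel variance
#' `gamma * (1 - gamma) * gain * (I - offset) + (1 - gamma^2) * electronic_sigma^2`
#' (clamped at zero before drawing), so that the output has the first two
#' moments of a true gamma-dose acquisition under the quantum-plus-electronic
#' noise model.  Negative outputs are clipped to zero.
#'
#' @param image a [raw_image()].
#' @param params a [dose_params()]; defaults to gamma = 0.75 with the
#'   preset's noise parameters.
#' @param seed integer seed.
#' @return degraded [raw_image()].
#' @export
reduce_dose <- function(image, params = NULL, seed = 1) {
  stopifnot(inherits(image, "raw_image"))
  p <- image$preset
  if (is.null(params))
    params <- dose_params(0.75, gain = p$gain, offset = p$offset,
                          electronic_sigma = p$electronic_sigma)
  out <- dose_transform(image$pixels, params, seed)
  # air region stays empty: the model acts on detected signal only
  out <- out * (image$mask == 1) + image$pixels * (image$mask == 0)
  image$pixels <- out
  image$provenance <- c(image$provenance,
                        list(list(step = "reduce_dose",
                                  fraction = params$fraction, seed = seed)))
  image
}

#' Dose-reduction transform on a bare pixel array
#'
#' The pixel-level core of [reduce_dose()]: scale the offset-corrected signal
#' by gamma and inject the variance-matching Gaussian noise.  Exposed so the
#' same transform can be applied to ROI patches (degradation is applied after
#' lesion insertion in the scoring protocol).
#'
#' @param px numeric matrix.
#' @param params a [dose_params()].
#' @param seed integer seed.
#' @return transformed matrix (clipped at zero).
#' @export
dose_transform <- function(px, params, seed = 1) {
  g <- params$fraction
  v <- pmax(g * (1 - g) * params$gain * (px - params$offset), 0) +
    (1 - g^2) * params$electronic_sigma^2
  set.seed(seed)
  out <- g * (px - params$offset) + params$offset +
    stats::rnorm(length(px)) * sqrt(v)
  dim(out) <- dim(px)
  pmax(out, 0)
}

#' Directional motion-blur kernel
#'
#' A line of equal weights through the kernel center at the given angle
#' (degrees, counter-clockwise from the horizontal axis), normalized to sum
#' to one.  Defaults to the 5 x 5, 45-degree kernel used for patient-motion
#' simulation.
#'
#' @param size odd kernel edge length.
#' @param angle line angle in degrees.
#' @return Object of class `blur_kernel` with fields `size`, `angle`,
#'   `weights`.
#' @export
make_motion_kernel <- function(size = 5, angle = 45) {
  if (size < 1 || size %% 2 == 0)
    stop("kernel size must be an odd positive integer")
  h <- (size - 1) / 2
  ctr <- h + 1
  th <- angle * pi / 180
  w <- matrix(0, size, size)
  if (abs(cos(th)) >= abs(sin(th))) {
    for (dc in -h:h) {
      dr <- -round(dc * tan(th))
      if (abs(dr) <= h) w[ctr + dr, ctr + dc] <- 1
    }
  } else {
    for (dr in -h:h) {
      dc <- -round(dr / tan(th))
      if (abs(dc) <= h) w[ctr + dr, ctr + dc] <- 1
    }
  }
  w <- w / sum(w)
  structure(list(size = as.integer(size), angle = angle, weights = w),
            class = "blur_kernel")
}

#' Apply motion blur
#'
#' Centered 2D convolution of the pixel array with the kernel weights, using
#' reflective (symmetric, edge-repeating) boundary handling.  The breast mask
#' is unchanged.
#'
#' @param image a [raw_image()].
#' @param kernel a [make_motion_kernel()] (or any `blur_kernel`).
#' @return blurred [raw_image()].
#' @export
motion_blur <- function(image, kernel = make_motion_kernel()) {
  stopifnot(inherits(image, "raw_image"), inherits(kernel, "blur_kernel"))
  if (kernel$size > min(dim(image$pixels)))
    stop("kernel does not fit in image")
  image$pixels <- conv2_reflect(image$pixels, kernel$weights)
  image$provenance <- c(image$provenance,
                        list(list(step = "motion_blur", size = kernel$size,
                                  angle = kernel$angle)))
  image
}

#' Centered 2D convolution with reflective padding
#'
#' `out[i, j] = sum_uv k[u, v] * xpad[i + u - cu, j + v - cv]` with the kernel
#' center at `(cu, cv) = (ceiling(dim/2))` and symmetric edge-repeating
#' padding.  Shared by the blur, Laplacian-of-Gaussian and wavelet filters.
#'
#' @param x numeric matrix.
#' @param k kernel matrix (odd dimensions).
#' @return matrix of the same shape as `x`.
#' @export
conv2_reflect <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  ph <- kh %/% 2; pw <- kw %/% 2
  xp <- pad_reflect(x, ph, pw)
  out <- matrix(0, nrow(x), ncol(x))
  for (u in seq_len(kh)) {
    for (v in seq_len(kw)) {
      if (k[u, v] == 0) next
      out <- out + k[u, v] *
        xp[(u - 1) + seq_len(nrow(x)), (v - 1) + seq_len(ncol(x))]
    }
  }
  out
}

pad_reflect <- function(x, ph, pw) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(if (ph > 0) ph:1 else integer(0), seq_len(nr),
          if (ph > 0) nr:(nr - ph + 1) else integer(0))
  ci <- c(if (pw > 0) pw:1 else integer(0), seq_len(nc),
          if (pw > 0) nc:(nc - pw + 1) else integer(0))
  x[ri, ci]
}
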