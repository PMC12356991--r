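#' Raw mammogram container
#'
#' A linearized 2D pixel array (digital units) together with its binary
#' breast-support mask, the detector preset it was generated/acquired under,
#' and a provenance list recording the seeds and degradations applied to it.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param mask binary (0/1) matrix of the same shape; foreground must be a
#'   single connected component.
#' @param preset a [system_preset()].
#' @param provenance list of provenance records.
#' @param id image identifier.
#' @return Object of class `raw_image`.
#' @export
raw_image <- function(pixels, mask, preset, provenance = list(), id = "img") {
  stopifnot(is.matrix(pixels), is.matrix(mask),
            all(dim(pixels) == dim(mask)),
            inherits(preset, "system_preset"))
  if (any(pixels < 0)) stop("pixels must be non-negative")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  storage.mode(mask) <- "double"
  structure(list(pixels = pixels, mask = mask, preset = preset,
                 provenance = provenance, id = id),
            class = "raw_image")
}

#' @export
print.raw_image <- function(x, ...) {
  tags <- vapply(x$provenance, function(p) p$step, character(1))
  cat(sprintf("<raw_image %s> %d x %d px, preset %s, breast area %d px [%s]\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$preset$name,
              sum(x$mask), paste(tags, collapse = " -> ")))
  invisible(x)
}

#' Isotropic power-law (1/f^beta) Gaussian texture
#'
#' Filters a white Gaussian field in the Fourier domain with amplitude
#' `f^(-beta/2)` (zero frequency removed) so that the radially averaged power
#' spectrum of the result is proportional to `1/f^beta`, then standardizes to
#' zero mean and the requested RMS.  This is the statistically defined
#' parenchymal background used by the synthetic generator: the detection task
#' only requires backgrounds with known statistics, not anatomically realistic
#' parenchyma.
#'
#' @param shape integer vector `c(nrow, ncol)`.
#' @param beta power-spectrum exponent (default 3, mammography-like clutter).
#' @param rms target standard deviation of the field, digital units.
#' @param seed integer seed (RNG state is set internally).
#' @return numeric matrix.
#' @export
power_law_texture <- function(shape, beta = 3, rms = 1, seed = 1) {
  nr <- shape[1]; nc <- shape[2]
  set.seed(seed)
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  fr <- fft_freq(nr); fc <- fft_freq(nc)
  f <- sqrt(outer(fr^2, fc^2, `+`))
  amp <- ifelse(f > 0, f^(-beta / 2), 0)
  tx <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / (nr * nc)
  tx <- tx - mean(tx)
  s <- stats::sd(as.vector(tx))
  if (s > 0) tx <- tx * (rms / s)
  tx
}

# FFT sample frequencies in cycles/pixel (numpy fftfreq layout).
fft_freq <- function(n) {
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1))
  k / n
}

#' Ellipse-plus-half-plane breast support mask
#'
#' The chest wall sits on the left image edge; the breast bulges right as a
#' half-ellipse.  The foreground is a single connected component by
#' construction.
#'
#' @param shape `c(nrow, ncol)`.
#' @param frac_row,frac_col ellipse semi-axes as fractions of the image
#'   height/width.
#' @return binary matrix.
#' @export
breast_support_mask <- function(shape, frac_row = 0.42, frac_col = 0.85) {
  nr <- shape[1]; nc <- shape[2]
  cy <- (nr + 1) / 2
  ry <- frac_row * nr
  rx <- frac_col * nc
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  m <- ((rr - cy) / ry)^2 + ((cc - 1) / rx)^2 <= 1
  storage.mode(m) <- "double"
  m
}

#' Generate a synthetic raw mammogram
#'
#' Produces a breast-masked image whose noiseless texture has a radially
#' averaged power spectrum proportional to `1/f^beta` inside the mask, with
#' quantum noise of variance `gain * (noiseless - offset)` and additive
#' Gaussian electronic noise of SD `electronic_sigma` (both from the preset).
#' Pixels outside the breast support are zero.  Bit-reproducible under a
#' fixed seed.
#'
#' @param preset a [system_preset()].
#' @param shape `c(nrow, ncol)`; each dimension must be at least
#'   `3 * roi_side`.
#' @param texture_exponent power-spectrum exponent beta (default 3).
#' @param mean_signal mean breast-tissue signal in digital units; must exceed
#'   the preset offset.
#' @param texture_rms parenchymal texture RMS in digital units (0 gives a
#'   flat field, used for noise-model verification).
#' @param seed integer seed.
#' @param id image identifier.
#' @return A [raw_image()].
#' @export
generate_background <- function(preset, shape, texture_exponent = 3,
                                mean_signal, texture_rms = 40, seed = 1,
                                id = "img") {
  stopifnot(inherits(preset, "system_preset"))
  if (any(shape < 3 * preset$roi_side))
    stop("shape must be at least 3 x roi_side (",
         3 * preset$roi_side, " px) in both dimensions")
  if (mean_signal <= preset$offset)
    stop("mean_signal must exceed the preset offset")
  mask <- breast_support_mask(shape)
  tx <- if (texture_rms > 0)
    power_law_texture(shape, beta = texture_exponent, rms = texture_rms,
                      seed = seed)
  else matrix(0, shape[1], shape[2])
  noiseless <- mean_signal + tx
  set.seed(seed + 1L)
  qvar <- preset$gain * pmax(noiseless - preset$offset, 0)
  sdtot <- sqrt(qvar + preset$electronic_sigma^2)
  px <- noiseless + stats::rnorm(length(noiseless)) * sdtot
  dim(px) <- shape
  px <- pmax(px, 0) * mask
  raw_image(px, mask, preset,
            provenance = list(list(step = "generate_background", seed = seed,
                                   beta = texture_exponent,
                                   mean_signal = mean_signal,
                                   texture_rms = texture_rms)),
            id = id)
}

#' Microcalcification cluster stencil
#'
#' Binary stencil `M` of a cluster of `n_calcs` non-overlapping round blobs of
#' roughly `calc_diameter` placed uniformly at random inside a
#' `window` x `window` mm window at the preset's pixel pitch.  Defaults follow
#' the study protocol: five ~200 um calcifications in a 1 cm^2 window.
#'
#' @param preset a [system_preset()].
#' @param n_calcs number of calcifications (>= 1).
#' @param calc_diameter blob diameter in micrometers; must map to >= 1 px.
#' @param window window edge length in millimeters.
#' @param seed integer seed.
#' @param max_tries placement retry budget before signalling a
#'   `mammoiq_placement_error`.
#' @return Object of class `lesion_mask` with fields `stencil` (binary
#'   matrix), `n_calcs`, and `pixel_pitch`.
#' @export
generate_cluster_mask <- function(preset, n_calcs = 5, calc_diameter = 200,
                                  window = 10, seed = 1, max_tries = 1000) {
  stopifnot(inherits(preset, "system_preset"), n_calcs >= 1)
  wpx <- round(window * 1000 / preset$pixel_pitch)
  d_px <- calc_diameter / preset$pixel_pitch
  if (d_px < 1)
    stop("calc_diameter maps to less than one pixel at this pitch")
  r <- d_px / 2
  # blob support: pixels within Euclidean distance r of the center pixel
  reach <- ceiling(r)
  off <- as.matrix(expand.grid(di = -reach:reach, dj = -reach:reach))
  off <- off[off[, 1]^2 + off[, 2]^2 <= r^2 + 1e-9, , drop = FALSE]
  if (nrow(off) == 0) off <- matrix(0, 1, 2)
  sep <- 2 * reach + 2   # Chebyshev separation keeping blobs 8-disconnected
  lo <- reach + 1; hi <- wpx - reach
  if (hi < lo) stop("window too small for blob size")
  set.seed(seed)
  centers <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(centers) < n_calcs) {
    if (tries >= max_tries) {
      stop(structure(class = c("mammoiq_placement_error", "error", "condition"),
                     list(message = "could not place non-overlapping calcifications",
                          call = sys.call())))
    }
    cand <- c(sample(lo:hi, 1), sample(lo:hi, 1))
    tries <- tries + 1
    if (nrow(centers) == 0 ||
        all(pmax(abs(centers[, 1] - cand[1]), abs(centers[, 2] - cand[2])) >= sep))
      centers <- rbind(centers, cand)
  }
  st <- matrix(0, wpx, wpx)
  for (k in seq_len(n_calcs)) {
    ii <- centers[k, 1] + off[, 1]
    jj <- centers[k, 2] + off[, 2]
    st[cbind(ii, jj)] <- 1
  }
  structure(list(stencil = st, n_calcs = as.integer(n_calcs),
                 centers = unname(centers), pixel_pitch = preset$pixel_pitch),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %d calcs, %d x %d px window (%g um pitch)\n",
              x$n_calcs, nrow(x$stencil), ncol(x$stencil), x$pixel_pitch))
  invisible(x)
}

#' Image manifest with degradation assignment
#'
#' Randomly assigns each image one of the tags `none`, `dose75`, `blur`
#' (disjointly), with `round(n * proportion)` images per degradation, and a
#' per-image generation seed derived from `seed`.
#'
#' @param n_images number of images.
#' @param preset a [system_preset()].
#' @param dose_fraction_images proportion of images tagged for dose reduction.
#' @param blur_images proportion tagged for motion blur.
#' @param seed integer seed.
#' @return A `data.frame` (class `image_manifest`) with columns
#'   `id, path, preset, tag, seed`.
#' @export
generate_manifest <- function(n_images, preset, dose_fraction_images = 0.1,
                              blur_images = 0.1, seed = 1) {
  stopifnot(inherits(preset, "system_preset"))
  if (dose_fraction_images + blur_images > 1)
    stop("degradation proportions must sum to at most 1")
  n_dose <- round(n_images * dose_fraction_images)
  n_blur <- round(n_images * blur_images)
  set.seed(seed)
  ord <- sample.int(n_images)
  tag <- rep("none", n_images)
  tag[ord[seq_len(n_dose)]] <- "dose75"
  if (n_blur > 0) tag[ord[n_dose + seq_len(n_blur)]] <- "blur"
  ids <- sprintf("img%05d", seq_len(n_images))
  m <- data.frame(id = ids, path = paste0(ids, ".tif"),
                  preset = preset$name, tag = tag,
                  seed = seed + seq_len(n_images),
                  stringsAsFactors = FALSE)
  class(m) <- c("image_manifest", "data.frame")
  m
}

#' ROI accounting for a manifest
#'
#' Number of ROI records the detection protocol produces for a manifest:
#' each image contributes `n_per_class` signal-present and `n_per_class`
#' signal-absent ROIs.
#'
#' @param manifest an [generate_manifest()] data frame (or anything with rows).
#' @param n_per_class ROIs per class per image (default 200).
#' @return total ROI record count.
#' @export
roi_accounting <- function(manifest, n_per_class = 200) {
  nrow(manifest) * 2L * n_per_class
}

#' Instance-to-feature ratio
#'
#' Ratio of training instances to retained features, rounded to one decimal;
#' a coarse overfitting-risk bookkeeping number.
#'
#' @param n_instances number of instances (images).
#' @param n_features number of features after consensus selection.
#' @return ratio rounded to one decimal place.
#' @export
instance_feature_ratio <- function(n_instances, n_features) {
  round(n_instances / n_features, 1)
}
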