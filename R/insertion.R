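#' Insert a microcalcification cluster at controlled contrast
#'
#' Hybrid-image attenuation model: at stencil pixels the image becomes
#' `I0 * (1 - lambda)`, elsewhere it is unchanged.  The stencil window is
#' centered on `center` (1-based row/col) and must fit inside the image.
#'
#' @param image a [raw_image()].
#' @param mask a `lesion_mask` from [generate_cluster_mask()].
#' @param contrast contrast level lambda in `[0, 1)`.
#' @param center integer `c(row, col)` of the cluster center.
#' @return The hybrid [raw_image()].
#' @export
insert_cluster <- function(image, mask, contrast, center) {
  stopifnot(inherits(image, "raw_image"), inherits(mask, "lesion_mask"))
  if (contrast < 0 || contrast >= 1)
    stop("contrast must be in [0, 1)")
  st <- mask$stencil
  w <- window_at(center, nrow(st), ncol(st))
  if (w$r0 < 1 || w$c0 < 1 || w$r1 > nrow(image$pixels) ||
      w$c1 > ncol(image$pixels))
    stop(structure(class = c("mammoiq_geometry_error", "error", "condition"),
                   list(message = "stencil window out of image bounds",
                        call = sys.call())))
  px <- image$pixels
  px[w$r0:w$r1, w$c0:w$c1] <- px[w$r0:w$r1, w$c0:w$c1] * (1 - contrast * st)
  image$pixels <- px
  image$provenance <- c(image$provenance,
                        list(list(step = "insert_cluster", contrast = contrast,
                                  center = center)))
  image
}

# 1-based window of size (h, w) centered at `center` (for even sizes the
# center sits at position size %/% 2 within the window, matching ROI
# extraction).
window_at <- function(center, h, w) {
  r0 <- center[1] - h %/% 2 + 1
  c0 <- center[2] - w %/% 2 + 1
  list(r0 = r0, c0 = c0, r1 = r0 + h - 1, c1 = c0 + w - 1)
}

#' Sample lesion/ROI center locations inside the breast
#'
#' Samples `n` centers uniformly without replacement from the breast support
#' eroded by `margin` millimeters (Euclidean distance to the mask boundary,
#' image borders counting as boundary), further restricted so that a
#' `roi_side` window centered there stays inside the image.
#'
#' @param image a [raw_image()].
#' @param n number of centers.
#' @param margin margin in millimeters (default 5).
#' @param seed integer seed.
#' @return integer matrix `n x 2` of (row, col) centers.
#' @export
sample_locations <- function(image, n, margin = 5, seed = 1) {
  stopifnot(inherits(image, "raw_image"))
  if (n == 0) return(matrix(integer(0), 0, 2,
                            dimnames = list(NULL, c("row", "col"))))
  margin_px <- margin * 1000 / image$preset$pixel_pitch
  d <- mask_distance(image$mask)
  side <- image$preset$roi_side
  nr <- nrow(image$mask); nc <- ncol(image$mask)
  half <- side %/% 2
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  fits <- rr - half + 1 >= 1 & rr - half + side <= nr &
          cc - half + 1 >= 1 & cc - half + side <= nc
  ok <- which(d >= margin_px & fits)
  if (length(ok) < n)
    stop(structure(class = c("mammoiq_sampling_error", "error", "condition"),
                   list(message = sprintf(
                     "eroded breast support (%d px) smaller than requested n = %d",
                     length(ok), n), call = sys.call())))
  set.seed(seed)
  idx <- sample(ok, n)
  cbind(row = ((idx - 1) %% nr) + 1, col = ((idx - 1) %/% nr) + 1)
}

# Euclidean distance of each foreground pixel to the nearest background pixel,
# with the image border treated as background (pad with a zero ring).
mask_distance <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  d <- EBImage::distmap(pad, metric = "euclidean")
  as.matrix(d)[2:(nr + 1), 2:(nc + 1)]
}

#' Build the SKE/BKS ROI set for one image
#'
#' Draws `2 * n_per_class` disjoint centers with [sample_locations()]; the
#' first `n_per_class` become signal-present ROIs (the cluster is inserted at
#' the ROI center immediately before extraction), the rest signal-absent
#' ROIs.  Patch size is the preset's `roi_side`.
#'
#' @param image a [raw_image()].
#' @param mask a `lesion_mask`.
#' @param contrast contrast lambda.
#' @param n_per_class ROIs per class (default 200).
#' @param margin sampling margin in mm.
#' @param seed integer seed.
#' @param degrade_patch optional `function(patch, k)` applied to every patch
#'   after insertion (`k` is the ROI index, usable for seed derivation);
#'   realizes the insert-then-degrade protocol for degraded acquisitions.
#' @return Object of class `roi_set`: list with `rois` (each a list with
#'   `patch`, `label`, `center`, `source_id`), `n_present`, `n_absent`.
#' @export
build_roi_set <- function(image, mask, contrast, n_per_class = 200,
                          margin = 5, seed = 1, degrade_patch = NULL) {
  centers <- sample_locations(image, 2 * n_per_class, margin = margin,
                              seed = seed)
  side <- image$preset$roi_side
  rois <- vector("list", 2 * n_per_class)
  for (k in seq_len(2 * n_per_class)) {
    ctr <- centers[k, ]
    present <- k <= n_per_class
    patch <- extract_patch(image$pixels, ctr, side)
    if (present) patch <- apply_stencil(patch, mask$stencil, contrast)
    if (!is.null(degrade_patch)) patch <- degrade_patch(patch, k)
    rois[[k]] <- list(patch = patch,
                      label = if (present) "signal_present" else "signal_absent",
                      center = ctr, source_id = image$id)
  }
  structure(list(rois = rois, n_present = n_per_class,
                 n_absent = n_per_class, roi_side = side,
                 source_id = image$id),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set %s> %d present + %d absent, %d px patches\n",
              x$source_id, x$n_present, x$n_absent, x$roi_side))
  invisible(x)
}

extract_patch <- function(px, center, side) {
  w <- window_at(center, side, side)
  px[w$r0:w$r1, w$c0:w$c1]
}

# Multiply the centered stencil window of `patch` by (1 - lambda * M);
# equivalent to inserting into the full image at the patch center and then
# extracting, for stencils no larger than the patch.
apply_stencil <- function(patch, stencil, contrast) {
  hs <- nrow(stencil); ws <- ncol(stencil)
  hp <- nrow(patch); wp <- ncol(patch)
  if (hs > hp || ws > wp) stop("stencil larger than patch")
  ctr <- c(hp %/% 2, wp %/% 2)
  w <- window_at(ctr, hs, ws)
  patch[w$r0:w$r1, w$c0:w$c1] <-
    patch[w$r0:w$r1, w$c0:w$c1] * (1 - contrast * stencil)
  patch
}
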