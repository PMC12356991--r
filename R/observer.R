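#' Laguerre-Gauss channel set
#'
#' Builds `n_channels` radially symmetric Laguerre-Gauss channel images on the
#' ROI grid: channel `j` (j = 0..n-1) is
#' `u_j(r) = exp(-pi r^2 / a^2) * L_j(2 pi r^2 / a^2)` sampled at pixel
#' centers relative to the ROI center, each normalized to unit Euclidean
#' norm.  The continuous functions are orthonormal; at widths of only a few
#' pixels the discretized channels are not (the Gaussian is undersampled),
#' which is harmless for the Hotelling observer since the covariance solve
#' absorbs channel correlation.  The achieved maximum off-diagonal inner
#' product is stored as `gram_offdiag`.
#'
#' @param roi_side ROI edge length in pixels (>= 8).
#' @param n_channels number of channels (default 5).
#' @param width Gaussian width `a` in pixels (default 1.5, matched to
#'   ~200 um microcalcifications at 100 um pitch).
#' @return Object of class `channel_set`: `basis` (`n_channels x roi_side^2`,
#'   rows are flattened channels), `n_channels`, `width`, `roi_side`,
#'   `gram_offdiag`.
#' @export
make_lg_channels <- function(roi_side, n_channels = 5, width = 1.5) {
  if (roi_side < 8) stop("roi_side must be at least 8")
  if (n_channels < 1) stop("n_channels must be at least 1")
  if (width <= 0) stop("width must be positive")
  ctr <- (roi_side + 1) / 2
  xs <- seq_len(roi_side) - ctr
  r2 <- outer(xs, xs, function(i, j) i^2 + j^2)
  x <- 2 * pi * r2 / width^2
  env <- exp(-pi * r2 / width^2)
  B <- matrix(0, n_channels, roi_side^2)
  for (j in 0:(n_channels - 1)) {
    u <- env * laguerre_poly(j, x)
    nu <- sqrt(sum(u^2))
    if (nu == 0) stop("degenerate channel (width too small for grid)")
    # truncation check: channel mass on the ROI boundary ring
    ring <- c(u[1, ], u[roi_side, ], u[, 1], u[, roi_side])
    if (sqrt(sum(ring^2)) / nu > 0.01)
      warning("channel ", j, " truncated by ROI boundary (width too large)")
    B[j + 1, ] <- as.vector(u) / nu
  }
  G <- B %*% t(B)
  structure(list(basis = B, n_channels = as.integer(n_channels),
                 width = width, roi_side = as.integer(roi_side),
                 gram_offdiag = max(abs(G - diag(n_channels)))),
            class = "channel_set")
}

# Laguerre polynomial L_j evaluated elementwise via the standard recurrence
# (k+1) L_{k+1} = (2k + 1 - x) L_k - k L_{k-1}.
laguerre_poly <- function(j, x) {
  Lk <- array(1, dim = dim(x))
  if (j == 0) return(Lk)
  Lkm1 <- Lk
  Lk <- 1 - x
  if (j >= 2) {
    for (k in 1:(j - 1)) {
      Lnew <- ((2 * k + 1 - x) * Lk - k * Lkm1) / (k + 1)
      Lkm1 <- Lk
      Lk <- Lnew
    }
  }
  Lk
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("<channel_set> %d LG channels, width %g px on %d x %d grid (max offdiag %.2g)\n",
              x$n_channels, x$width, x$roi_side, x$roi_side, x$gram_offdiag))
  invisible(x)
}

#' Cluster-matched (convolutional) channel evaluation
#'
#' Realizes the convolutional reading of the LG channels for a spatially
#' extended, exactly known signal: each channel image is convolved with the
#' known calcification-center layout — equivalently, shifted to each
#' calcification center of the cluster stencil and summed — and re-normalized
#' to unit norm.  With a single centered blob this reduces to the plain
#' centered channel set.  The channel count is unchanged (default 5).
#'
#' @param channels a [make_lg_channels()] channel set.
#' @param mask a `lesion_mask` whose `centers` give the calcification centers
#'   within the stencil window.
#' @return a `channel_set` whose basis rows are the cluster-matched channels.
#' @export
cluster_channels <- function(channels, mask) {
  stopifnot(inherits(channels, "channel_set"), inherits(mask, "lesion_mask"))
  side <- channels$roi_side
  n <- channels$n_channels
  # calcification offsets relative to the stencil window center, mapped to
  # the ROI grid center (same centering convention as ROI extraction)
  sc <- c(nrow(mask$stencil) %/% 2, ncol(mask$stencil) %/% 2)
  B <- matrix(0, n, side^2)
  for (j in seq_len(n)) {
    u <- matrix(channels$basis[j, ], side, side)
    acc <- matrix(0, side, side)
    for (k in seq_len(nrow(mask$centers))) {
      dr <- mask$centers[k, 1] - sc[1]
      dc <- mask$centers[k, 2] - sc[2]
      acc <- acc + shift_mat(u, dr, dc, fill = 0)
    }
    B[j, ] <- as.vector(acc) / sqrt(sum(acc^2))
  }
  G <- B %*% t(B)
  structure(list(basis = B, n_channels = n, width = channels$width,
                 roi_side = side,
                 gram_offdiag = max(abs(G - diag(n)))),
            class = "channel_set")
}

#' Channelize ROI patches
#'
#' Projects patches onto the channel basis: `v = basis %*% vec(patch)`.
#'
#' @param channels a [make_lg_channels()] channel set.
#' @param x a single patch matrix, a `roi_set`, or a list of ROIs.
#' @return `n_channels x m` matrix of channel responses.
#' @export
channelize <- function(channels, x) {
  stopifnot(inherits(x, "roi_set") || is.matrix(x) || is.list(x))
  if (inherits(x, "roi_set")) x <- x$rois
  if (is.matrix(x)) {
    if (all(dim(x) == channels$roi_side))
      return(channels$basis %*% as.vector(x))
    stopifnot(nrow(x) == channels$roi_side^2)
    return(channels$basis %*% x)
  }
  P <- vapply(x, function(r) as.vector(r$patch),
              numeric(channels$roi_side^2))
  channels$basis %*% P
}

# Split a roi_set into channelized present/absent matrices.
channelize_classes <- function(channels, roiset) {
  lab <- vapply(roiset$rois, `[[`, character(1), "label")
  V <- channelize(channels, roiset)
  list(present = V[, lab == "signal_present", drop = FALSE],
       absent = V[, lab == "signal_absent", drop = FALSE])
}

#' Train a channelized Hotelling observer template
#'
#' Channelizes the training ROIs, computes class means and the pooled
#' (average-of-class) covariance, and solves `w = S^-1 (v_present - v_absent)`.
#' The covariance is ridge-regularized by `1e-8 * trace(S)` when
#' ill-conditioned.  The internal-noise scale `s0` is the SD of `w'v` over
#' the signal-absent training ROIs; decision noise is drawn as
#' `N(0, (internal_sigma * s0)^2)`.
#'
#' @param rois_absent,rois_present lists of ROIs, `roi_set`s, or channelized
#'   matrices (`n_channels x m`).
#' @param channels a [make_lg_channels()] channel set.
#' @param internal_sigma internal-noise level, in units of the signal-absent
#'   decision-statistic SD.
#' @return Object of class `cho_template` with fields `channels`,
#'   `mean_present`, `mean_absent`, `pooled_cov`, `weights`, `internal_sigma`,
#'   `s0`, `n_absent`, `n_present`.
#' @export
cho_train <- function(rois_absent, rois_present, channels,
                      internal_sigma = 0) {
  Va <- if (is.matrix(rois_absent)) rois_absent else channelize(channels, rois_absent)
  Vp <- if (is.matrix(rois_present)) rois_present else channelize(channels, rois_present)
  n <- channels$n_channels
  if (ncol(Va) < n + 1 || ncol(Vp) < n + 1)
    stop("need at least n_channels + 1 training ROIs per class")
  ma <- rowMeans(Va); mp <- rowMeans(Vp)
  S <- (stats::cov(t(Va)) + stats::cov(t(Vp))) / 2
  if (rcond(S) < 1e-12) S <- S + diag(1e-8 * sum(diag(S)), n)
  w <- tryCatch(solve(S, mp - ma), error = function(e)
    stop(structure(class = c("mammoiq_training_error", "error", "condition"),
                   list(message = "singular channel covariance after regularization",
                        call = sys.call()))))
  s0 <- stats::sd(as.vector(crossprod(w, Va)))
  structure(list(channels = channels, mean_present = mp, mean_absent = ma,
                 pooled_cov = S, weights = as.vector(w),
                 internal_sigma = internal_sigma, s0 = s0,
                 n_absent = ncol(Va), n_present = ncol(Vp)),
            class = "cho_template")
}

#' @export
print.cho_template <- function(x, ...) {
  da <- sqrt(sum(x$weights * (x$mean_present - x$mean_absent)))
  cat(sprintf("<cho_template> %d channels, trained on %d absent / %d present, d_a = %.3f, internal sigma = %g\n",
              x$channels$n_channels, x$n_absent, x$n_present, da,
              x$internal_sigma))
  invisible(x)
}

#' Decision statistics for ROIs under a trained template
#'
#' `t = w'v + eta`, with `eta ~ N(0, (internal_sigma * s0)^2)` drawn fresh
#' per ROI from the current RNG stream.
#'
#' @param object a [cho_train()] template.
#' @param newdata a patch matrix, `roi_set`, ROI list, or channelized matrix
#'   (`n_channels x m`).
#' @param ... unused.
#' @return numeric vector of decision statistics.
#' @export
predict.cho_template <- function(object, newdata, ...) {
  V <- if (is.matrix(newdata) && nrow(newdata) == object$channels$n_channels &&
           !all(dim(newdata) == object$channels$roi_side))
    newdata
  else channelize(object$channels, newdata)
  if (is.null(dim(V))) V <- matrix(V, ncol = 1)
  t0 <- as.vector(crossprod(object$weights, V))
  if (object$internal_sigma > 0)
    t0 <- t0 + stats::rnorm(length(t0), 0, object$internal_sigma * object$s0)
  t0
}

#' @rdname predict.cho_template
#' @param template a `cho_template`.
#' @param roi a single ROI patch (matrix).
#' @export
decision_statistic <- function(template, roi) {
  predict(template, roi)
}

#' Mann-Whitney AUC estimator
#'
#' Mean over all (present, absent) pairs of the indicator
#' `present > absent`, with ties counting one half.
#'
#' @param scores_present,scores_absent non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores_present, scores_absent) {
  np <- length(scores_present); na <- length(scores_absent)
  if (np == 0 || na == 0) stop("both score lists must be non-empty")
  r <- rank(c(scores_present, scores_absent))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na)
}

#' Pool of channelized training ROIs
#'
#' Builds the virtual readers' training pool: each ensemble image contributes
#' `n_absent_per` signal-absent and `n_present_per` signal-present
#' channelized ROIs (cluster inserted at the ROI center, contrast `contrast`).
#'
#' @param images list of [raw_image()]s.
#' @param mask a `lesion_mask`.
#' @param contrast contrast lambda.
#' @param channels a channel set.
#' @param n_absent_per,n_present_per per-image pool contributions.
#' @param margin sampling margin (mm).
#' @param seed integer seed.
#' @param degrade_patch_list optional list (one `function(patch, k)` or NULL
#'   per image) applied after insertion, for degraded acquisitions.
#' @return Object of class `roi_pool` with channelized matrices `absent`,
#'   `present` (`n_channels x N`).
#' @export
build_roi_pool <- function(images, mask, contrast, channels,
                           n_absent_per = 60, n_present_per = 20,
                           margin = 5, seed = 1, degrade_patch_list = NULL) {
  Va <- vector("list", length(images)); Vp <- Va
  for (i in seq_along(images)) {
    rs <- build_roi_set(images[[i]], mask, contrast,
                        n_per_class = max(n_absent_per, n_present_per),
                        margin = margin, seed = seed + i,
                        degrade_patch = degrade_patch_list[[i]])
    cls <- channelize_classes(channels, rs)
    Vp[[i]] <- cls$present[, seq_len(n_present_per), drop = FALSE]
    Va[[i]] <- cls$absent[, seq_len(n_absent_per), drop = FALSE]
  }
  structure(list(absent = do.call(cbind, Va), present = do.call(cbind, Vp),
                 channels = channels),
            class = "roi_pool")
}

#' @export
print.roi_pool <- function(x, ...) {
  cat(sprintf("<roi_pool> %d absent / %d present channelized ROIs\n",
              ncol(x$absent), ncol(x$present)))
  invisible(x)
}

#' Per-image detectability score
#'
#' Scores one image with `n_readers` virtual readers: each reader draws a
#' fresh training sample (`n_train_absent`/`n_train_present`, default
#' 1500/500) from the pool, trains a CHO template, scores the image's
#' `2 * n_per_class` ROIs (default 400) and computes the Mann-Whitney AUC.
#' Returns the mean and SD over readers.
#'
#' @param image a [raw_image()].
#' @param mask a `lesion_mask`.
#' @param contrast contrast lambda.
#' @param pool a [build_roi_pool()] training pool.
#' @param n_readers number of virtual readers (default 30).
#' @param n_per_class test ROIs per class (default 200).
#' @param internal_sigma internal-noise level.
#' @param n_train_absent,n_train_present per-reader training draw sizes.
#' @param margin sampling margin (mm).
#' @param seed integer seed.
#' @param degrade_patch optional `function(patch, k)` applied after insertion
#'   (insert-then-degrade protocol for degraded acquisitions).
#' @return Object of class `detectability_score`: `image_id`, `auc_mean`,
#'   `auc_sd`, `n_readers`, `auc` (per-reader values).
#' @export
score_image <- function(image, mask, contrast, pool, n_readers = 30,
                        n_per_class = 200, internal_sigma = 0,
                        n_train_absent = 1500, n_train_present = 500,
                        margin = 5, seed = 1, degrade_patch = NULL) {
  stopifnot(n_readers >= 1)
  channels <- pool$channels
  rs <- build_roi_set(image, mask, contrast, n_per_class = n_per_class,
                      margin = margin, seed = seed,
                      degrade_patch = degrade_patch)
  cls <- channelize_classes(channels, rs)
  set.seed(seed + 1L)
  aucs <- numeric(n_readers)
  for (r in seq_len(n_readers)) {
    ia <- sample.int(ncol(pool$absent), n_train_absent)
    ip <- sample.int(ncol(pool$present), n_train_present)
    tpl <- cho_train(pool$absent[, ia, drop = FALSE],
                     pool$present[, ip, drop = FALSE],
                     channels, internal_sigma = internal_sigma)
    tp <- predict(tpl, cls$present)
    ta <- predict(tpl, cls$absent)
    aucs[r] <- auc_mw(tp, ta)
  }
  structure(list(image_id = image$id, auc_mean = mean(aucs),
                 auc_sd = stats::sd(aucs), n_readers = n_readers,
                 auc = aucs),
            class = "detectability_score")
}

#' @export
print.detectability_score <- function(x, ...) {
  cat(sprintf("<detectability_score %s> AUC %.4f +/- %.4f (%d readers)\n",
              x$image_id, x$auc_mean, x$auc_sd, x$n_readers))
  invisible(x)
}

#' Score an image ensemble
#'
#' Applies [score_image()] to every image with per-image derived seeds.
#'
#' @inheritParams score_image
#' @param images list of [raw_image()]s.
#' @param degrade_patch_list optional per-image list of patch transforms.
#' @return data.frame `image_id, auc_mean, auc_sd, n_readers`.
#' @export
score_ensemble <- function(images, mask, contrast, pool, n_readers = 30,
                           n_per_class = 200, internal_sigma = 0,
                           n_train_absent = 1500, n_train_present = 500,
                           margin = 5, seed = 1, degrade_patch_list = NULL) {
  res <- lapply(seq_along(images), function(i)
    score_image(images[[i]], mask, contrast, pool, n_readers = n_readers,
                n_per_class = n_per_class, internal_sigma = internal_sigma,
                n_train_absent = n_train_absent,
                n_train_present = n_train_present, margin = margin,
                seed = seed + 131L * i,
                degrade_patch = degrade_patch_list[[i]]))
  data.frame(image_id = vapply(res, `[[`, character(1), "image_id"),
             auc_mean = vapply(res, `[[`, numeric(1), "auc_mean"),
             auc_sd = vapply(res, `[[`, numeric(1), "auc_sd"),
             n_readers = n_readers, stringsAsFactors = FALSE)
}

#' Calibrate the internal-noise level to an AUC operating band
#'
#' Bisects the internal-noise level `sigma` until the ensemble mean CHO AUC
#' falls inside `[target_low, target_high]` (default the 75%--80% operating
#' band).  Evaluations use common random numbers (fixed reader training draws
#' and fixed noise deviates rescaled by `sigma`), which makes the AUC a
#' deterministic, monotone non-increasing function of `sigma` so the bisection
#' bracket is valid.  If the ensemble is already inside the band at
#' `sigma = 0`, zero is returned; if its AUC at `sigma = 0` is below the
#' band, a `mammoiq_calibration_error` is signalled.
#'
#' @param images list of [raw_image()]s (the calibration ensemble).
#' @param mask a `lesion_mask`.
#' @param contrast contrast lambda.
#' @param channels a channel set; defaults to 5 LG channels of width 1.5 px
#'   on the preset ROI grid.
#' @param pool optional pre-built [build_roi_pool()]; built from the ensemble
#'   when omitted.
#' @param target_low,target_high AUC band (default 0.75--0.80).
#' @param n_readers readers per evaluation during calibration.
#' @param n_per_class test ROIs per class per image during calibration.
#' @param n_train_absent,n_train_present per-reader training draw sizes.
#' @param margin sampling margin (mm).
#' @param seed integer seed.
#' @param max_iter bisection iteration cap.
#' @param degrade_patch_list optional per-image list of patch transforms.
#' @return list with `internal_sigma`, `achieved_auc`, `auc_sigma0`,
#'   `n_images`.
#' @export
calibrate_internal_noise <- function(images, mask, contrast, channels = NULL,
                                     pool = NULL, target_low = 0.75,
                                     target_high = 0.80, n_readers = 6,
                                     n_per_class = 100,
                                     n_train_absent = 1500,
                                     n_train_present = 500, margin = 5,
                                     seed = 1, max_iter = 40,
                                     degrade_patch_list = NULL) {
  stopifnot(target_low > 0.5, target_high < 1, target_low < target_high)
  if (is.null(channels))
    channels <- cluster_channels(make_lg_channels(images[[1]]$preset$roi_side),
                                 mask)
  if (is.null(pool))
    pool <- build_roi_pool(images, mask, contrast, channels, seed = seed,
                           degrade_patch_list = degrade_patch_list)
  # cache channelized test ROIs per image
  tests <- lapply(seq_along(images), function(i) {
    rs <- build_roi_set(images[[i]], mask, contrast,
                        n_per_class = n_per_class, margin = margin,
                        seed = seed + 977L * i,
                        degrade_patch = degrade_patch_list[[i]])
    channelize_classes(channels, rs)
  })
  # fixed reader draws and fixed standard-normal noise deviates (common
  # random numbers across sigma evaluations)
  set.seed(seed + 7L)
  readers <- lapply(seq_len(n_readers), function(r)
    list(ia = sample.int(ncol(pool$absent), n_train_absent),
         ip = sample.int(ncol(pool$present), n_train_present),
         zp = matrix(stats::rnorm(length(images) * n_per_class),
                     n_per_class, length(images)),
         za = matrix(stats::rnorm(length(images) * n_per_class),
                     n_per_class, length(images))))
  templates <- lapply(readers, function(rd)
    cho_train(pool$absent[, rd$ia, drop = FALSE],
              pool$present[, rd$ip, drop = FALSE], channels))
  mean_auc <- function(sigma) {
    per_image <- matrix(0, length(images), n_readers)
    for (r in seq_len(n_readers)) {
      tpl <- templates[[r]]
      for (i in seq_along(images)) {
        tp <- as.vector(crossprod(tpl$weights, tests[[i]]$present)) +
          sigma * tpl$s0 * readers[[r]]$zp[, i]
        ta <- as.vector(crossprod(tpl$weights, tests[[i]]$absent)) +
          sigma * tpl$s0 * readers[[r]]$za[, i]
        per_image[i, r] <- auc_mw(tp, ta)
      }
    }
    mean(per_image)
  }
  a0 <- mean_auc(0)
  if (a0 < target_low)
    stop(structure(class = c("mammoiq_calibration_error", "error", "condition"),
                   list(message = sprintf(
                     "ensemble AUC at sigma = 0 (%.3f) is below the target band", a0),
                     call = sys.call())))
  if (a0 <= target_high)
    return(list(internal_sigma = 0, achieved_auc = a0, auc_sigma0 = a0,
                n_images = length(images)))
  lo <- 0; hi <- 1
  while (mean_auc(hi) > target_high && hi < 64) hi <- hi * 2
  sig <- hi; a <- mean_auc(sig)
  for (it in seq_len(max_iter)) {
    if (a >= target_low && a <= target_high) break
    if (a > target_high) lo <- sig else hi <- sig
    sig <- (lo + hi) / 2
    a <- mean_auc(sig)
  }
  list(internal_sigma = sig, achieved_auc = a, auc_sigma0 = a0,
       n_images = length(images))
}
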