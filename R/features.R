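#' Radiomic feature extraction configuration
#'
#' Filter bank and feature-class configuration.  Filters: `original`,
#' `wavelet` (single-level undecimated decomposition, 4 sub-bands), `log`
#' (Laplacian of Gaussian at `log_sigma` pixels), `square`, `squareroot`,
#' `logarithm`, `exponential`, `gradient` (magnitude), `lbp2d` (8-neighbor
#' local binary pattern).  Classes: `shape2d` (original domain only),
#' `firstorder`, `glcm`, `glrlm`, `glszm`, `gldm`, `ngtdm`.  Gray levels are
#' discretized with a fixed bin width (default 25 digital units) from the
#' masked minimum; filtered domains are rescaled to the original masked
#' intensity range before binning so the bin width is meaningful across
#' domains.
#'
#' @param filters character vector of enabled filters.
#' @param classes character vector of enabled feature classes.
#' @param bin_width gray-level bin width in digital units.
#' @param log_sigma Laplacian-of-Gaussian scales in pixels.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(filters = c("original", "wavelet", "log", "square",
                                       "squareroot", "logarithm",
                                       "exponential", "gradient", "lbp2d"),
                           classes = c("shape2d", "firstorder", "glcm",
                                       "glrlm", "glszm", "gldm", "ngtdm"),
                           bin_width = 25, log_sigma = c(2, 3, 4)) {
  all_f <- c("original", "wavelet", "log", "square", "squareroot",
             "logarithm", "exponential", "gradient", "lbp2d")
  all_c <- c("shape2d", "firstorder", "glcm", "glrlm", "glszm", "gldm",
             "ngtdm")
  filters <- match.arg(filters, all_f, several.ok = TRUE)
  classes <- match.arg(classes, all_c, several.ok = TRUE)
  if (bin_width <= 0) stop("bin_width must be positive")
  structure(list(filters = filters, classes = classes, bin_width = bin_width,
                 log_sigma = log_sigma),
            class = "feature_config")
}

#' Reduced configuration for large cohorts
#'
#' A lighter filter/class grid (no LoG, no wavelet high-pass pair, no
#' size-zone/dependence matrices) used for cohort-scale experiments where the
#' full grid is unnecessarily slow.
#'
#' @param bin_width gray-level bin width.
#' @return A [feature_config()].
#' @export
feature_config_reduced <- function(bin_width = 25) {
  feature_config(filters = c("original", "squareroot", "gradient", "wavelet"),
                 classes = c("firstorder", "glcm", "glrlm", "ngtdm"),
                 bin_width = bin_width)
}

# ---- filter bank -----------------------------------------------------------

# Filtered image domains.  Exterior (air) pixels are replaced by the masked
# mean before any filtering so that no feature can depend on air pixels.
filter_domains <- function(px, mask, config) {
  inm <- mask == 1
  fill <- mean(px[inm])
  pf <- px
  pf[!inm] <- fill
  mn <- min(px[inm])
  z <- pf - mn
  zmax <- max(z[inm]); if (zmax <= 0) zmax <- 1
  out <- list()
  for (f in config$filters) {
    switch(f,
      original = { out$original <- pf },
      log = {
        for (s in config$log_sigma)
          out[[paste0("log.sigma", s)]] <- log_of_gaussian(pf, s)
      },
      square = { out$square <- pf^2 },
      squareroot = { out$squareroot <- sqrt(pmax(z, 0)) },
      logarithm = { out$logarithm <- log1p(pmax(z, 0)) },
      exponential = { out$exponential <- exp(4 * z / zmax) },
      gradient = {
        gx <- conv2_reflect(pf, matrix(c(-0.5, 0, 0.5), 1, 3))
        gy <- conv2_reflect(pf, matrix(c(-0.5, 0, 0.5), 3, 1))
        out$gradient <- sqrt(gx^2 + gy^2)
      },
      lbp2d = { out$lbp2d <- lbp_codes(pf) },
      wavelet = {
        lp <- c(1, 2, 1) / 4; hp <- c(-1, 0, 1) / 2
        out$wavelet.LL <- conv2_reflect(pf, outer(lp, lp))
        out$wavelet.LH <- conv2_reflect(pf, outer(lp, hp))
        out$wavelet.HL <- conv2_reflect(pf, outer(hp, lp))
        out$wavelet.HH <- conv2_reflect(pf, outer(hp, hp))
      })
  }
  out
}

# sigma^2-normalized Laplacian of Gaussian via separable smoothing.
log_of_gaussian <- function(x, sigma) {
  r <- ceiling(3 * sigma)
  g <- exp(-((-r:r)^2) / (2 * sigma^2)); g <- g / sum(g)
  sm <- conv2_reflect(x, matrix(g, 1))
  sm <- conv2_reflect(sm, matrix(g, ncol = 1))
  sigma^2 * conv2_reflect(sm, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3))
}

# 8-neighbor local binary pattern codes (0..255).
lbp_codes <- function(x) {
  nb <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
             c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- matrix(0, nrow(x), ncol(x))
  for (k in seq_along(nb)) {
    s <- shift_mat(x, nb[[k]][1], nb[[k]][2], fill = NA)
    ge <- !is.na(s) & s >= x
    code <- code + 2^(k - 1) * ge
  }
  code
}

# Shift a matrix by (dr, dc), filling vacated cells.
shift_mat <- function(x, dr, dc, fill = 0) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- x[rs - dr, cs - dc]
  out
}

# ---- discretization --------------------------------------------------------

# Fixed-bin-width gray levels from the masked minimum.  Filtered domains are
# affinely rescaled to `ref_range` (the original masked range) first.
discretize_levels <- function(img, inm, bin_width, ref_range = NULL) {
  v <- img[inm]
  if (!is.null(ref_range)) {
    rng <- range(v)
    if (diff(rng) > 0)
      v <- ref_range[1] + (v - rng[1]) / diff(rng) * diff(ref_range)
    else v <- rep(ref_range[1], length(v))
  }
  g <- floor((v - min(v)) / bin_width) + 1
  G <- matrix(0L, nrow(img), ncol(img))
  G[inm] <- as.integer(g)
  list(G = G, n_levels = max(g))
}

# ---- feature classes -------------------------------------------------------

fo_features <- function(v, g, n_levels) {
  m <- mean(v)
  va <- mean((v - m)^2)
  sdv <- sqrt(va)
  sk <- if (sdv > 0) mean((v - m)^3) / sdv^3 else 0
  ku <- if (sdv > 0) mean((v - m)^4) / sdv^4 else 0
  p <- tabulate(g, n_levels) / length(g)
  p <- p[p > 0]
  c(mean = m, variance = va, skewness = sk, kurtosis = ku,
    median = stats::median(v), p10 = unname(stats::quantile(v, 0.1)),
    p90 = unname(stats::quantile(v, 0.9)),
    iqr = unname(stats::quantile(v, 0.75) - stats::quantile(v, 0.25)),
    range = max(v) - min(v), mad = mean(abs(v - m)),
    rms = sqrt(mean(v^2)), energy = sum(v^2),
    entropy = -sum(p * log2(p)), uniformity = sum(p^2),
    min = min(v), max = max(v))
}

glcm_features <- function(G, n_levels) {
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  acc <- NULL
  for (o in offs) {
    Gs <- shift_mat(G, -o[1], -o[2], fill = 0L)
    sel <- G > 0 & Gs > 0
    a <- G[sel]; b <- Gs[sel]
    if (length(a) == 0) next
    P <- matrix(tabulate(a + n_levels * (b - 1), n_levels^2),
                n_levels, n_levels)
    P <- P + t(P)
    P <- P / sum(P)
    f <- glcm_stats(P, n_levels)
    acc <- if (is.null(acc)) f else acc + f
  }
  if (is.null(acc)) return(glcm_stats(matrix(1, 1, 1), 1))
  acc / length(offs)
}

glcm_stats <- function(P, n) {
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  pm <- rowSums(P)
  mu <- sum(seq_len(n) * pm)
  s2 <- sum((seq_len(n) - mu)^2 * pm)
  corr <- if (s2 > 0) (sum(P * i * j) - mu^2) / s2 else 0
  pp <- P[P > 0]
  c(contrast = sum(P * (i - j)^2),
    dissimilarity = sum(P * abs(i - j)),
    homogeneity = sum(P / (1 + (i - j)^2)),
    energy = sum(P^2),
    entropy = -sum(pp * log2(pp)),
    correlation = corr,
    cluster_shade = sum(P * (i + j - 2 * mu)^3),
    max_prob = max(P))
}

# Runs pooled over the four principal directions.
glrlm_features <- function(G, n_levels) {
  lines <- c(split(G, row(G)), split(G, col(G)),
             split(G, row(G) - col(G)), split(G, row(G) + col(G)))
  lvs <- vector("list", length(lines))
  lns <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    r <- rle(as.vector(lines[[i]]))
    keep <- r$values > 0
    lvs[[i]] <- r$values[keep]
    lns[[i]] <- r$lengths[keep]
  }
  lv <- unlist(lvs); ln <- unlist(lns)
  N <- length(lv)
  npix <- sum(G > 0)
  if (N == 0) return(c(sre = 0, lre = 0, gln = 0, rln = 0, rp = 0,
                       lglre = 0, hglre = 0, run_entropy = 0))
  maxlen <- max(ln)
  cnt <- tabulate(lv + n_levels * (ln - 1), n_levels * maxlen)
  M <- matrix(cnt, n_levels, maxlen)
  jj <- seq_len(maxlen)
  ii <- seq_len(n_levels)
  nj <- colSums(M); ni <- rowSums(M)
  p <- cnt[cnt > 0] / N
  c(sre = sum(nj / jj^2) / N,
    lre = sum(nj * jj^2) / N,
    gln = sum(ni^2) / N,
    rln = sum(nj^2) / N,
    rp = N / (4 * npix),
    lglre = sum(ni / ii^2) / N,
    hglre = sum(ni * ii^2) / N,
    run_entropy = -sum(p * log2(p)))
}

glszm_features <- function(G, n_levels) {
  zl <- integer(0); zs <- integer(0)
  for (l in seq_len(n_levels)) {
    b <- G == l
    if (!any(b)) next
    lab <- EBImage::bwlabel(b)
    sizes <- tabulate(lab[lab > 0])
    zl <- c(zl, rep(l, length(sizes)))
    zs <- c(zs, sizes)
  }
  Nz <- length(zl)
  npix <- sum(G > 0)
  if (Nz == 0) return(c(sae = 0, lae = 0, gln = 0, szn = 0, zp = 0,
                        lglze = 0, hglze = 0, zone_entropy = 0))
  ps <- table(zs); pl <- table(zl)
  p <- as.vector(table(paste(zl, zs))) / Nz
  c(sae = sum(1 / zs^2) / Nz,
    lae = sum(zs^2) / Nz,
    gln = sum(as.vector(pl)^2) / Nz,
    szn = sum(as.vector(ps)^2) / Nz,
    zp = Nz / npix,
    lglze = sum(1 / zl^2) / Nz,
    hglze = sum(zl^2) / Nz,
    zone_entropy = -sum(p * log2(p)))
}

gldm_features <- function(G, n_levels) {
  nb <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
             c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  dep <- matrix(0L, nrow(G), ncol(G))
  for (o in nb) {
    Gs <- shift_mat(G, o[1], o[2], fill = 0L)
    dep <- dep + (Gs > 0 & Gs == G)
  }
  sel <- G > 0
  lvl <- G[sel]; k <- dep[sel] + 1L   # dependence size j = k+1 in 1..9
  N <- length(lvl)
  maxk <- max(k)
  cnt <- tabulate(lvl + n_levels * (k - 1), n_levels * maxk)
  M <- matrix(cnt, n_levels, maxk)
  jj <- seq_len(maxk); ii <- seq_len(n_levels)
  nj <- colSums(M); ni <- rowSums(M)
  p <- cnt[cnt > 0] / N
  c(sde = sum(nj / jj^2) / N,
    lde = sum(nj * jj^2) / N,
    gln = sum(ni^2) / N,
    dn = sum(nj^2) / N,
    de = -sum(p * log2(p)),
    lgle = sum(ni / ii^2) / N,
    hgle = sum(ni * ii^2) / N)
}

ngtdm_features <- function(G, n_levels) {
  inm <- G > 0
  nbsum <- matrix(0, nrow(G), ncol(G))
  nbcnt <- matrix(0, nrow(G), ncol(G))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nbsum <- nbsum + shift_mat(G * inm, dr, dc, fill = 0)
    nbcnt <- nbcnt + shift_mat(inm * 1, dr, dc, fill = 0)
  }
  sel <- inm & nbcnt > 0
  g <- G[sel]
  abar <- nbsum[sel] / nbcnt[sel]
  N <- length(g)
  s <- vapply(seq_len(n_levels), function(l) sum(abs(l - abar[g == l])),
              numeric(1))
  n_i <- tabulate(g, n_levels)
  p <- n_i / N
  act <- which(p > 0)
  Ngp <- length(act)
  ssum <- sum(s)
  coarse <- if (sum(p * s) > 0) 1 / sum(p * s) else 1e6
  if (Ngp > 1) {
    ij <- expand.grid(i = act, j = act)
    contrast <- sum(p[ij$i] * p[ij$j] * (ij$i - ij$j)^2) /
      (Ngp * (Ngp - 1)) * ssum / N
    busy_den <- sum(abs(outer(act * p[act], act * p[act], `-`)))
    busy <- if (busy_den > 0) sum(p * s) / busy_den else 0
    compl <- sum(abs(ij$i - ij$j) *
                 (p[ij$i] * s[ij$i] + p[ij$j] * s[ij$j]) /
                 (p[ij$i] + p[ij$j])) / N
    strength <- if (ssum > 0)
      sum((p[ij$i] + p[ij$j]) * (ij$i - ij$j)^2) / ssum else 0
  } else {
    contrast <- 0; busy <- 0; compl <- 0; strength <- 0
  }
  c(coarseness = coarse, contrast = contrast, busyness = busy,
    complexity = compl, strength = strength)
}

shape2d_features <- function(mask, pitch) {
  inm <- mask == 1
  area <- sum(inm)
  edge <- inm & !(shift_mat(inm, 1, 0, FALSE) & shift_mat(inm, -1, 0, FALSE) &
                  shift_mat(inm, 0, 1, FALSE) & shift_mat(inm, 0, -1, FALSE))
  per <- sum(edge)
  idx <- which(inm, arr.ind = TRUE)
  cv <- stats::cov(idx)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  bbox <- prod(apply(idx, 2, function(z) diff(range(z)) + 1))
  c(area_px = area,
    area_mm2 = area * (pitch / 1000)^2,
    perimeter_px = per,
    perimeter_area_ratio = per / area,
    major_axis_px = 4 * sqrt(ev[1]),
    minor_axis_px = 4 * sqrt(ev[2]),
    elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    extent = area / bbox)
}

# ---- driver ----------------------------------------------------------------

#' Extract the radiomic feature vector of an image
#'
#' Derives each enabled filter domain (air replaced by the masked mean before
#' filtering, so features never depend on pixels outside the breast mask),
#' discretizes with the configured fixed bin width, and computes the enabled
#' feature classes over the breast mask.  Deterministic; feature names are
#' namespaced `filter_class_statistic`.
#'
#' @param image a [raw_image()].
#' @param config a [feature_config()].
#' @return named numeric vector.
#' @export
extract_features <- function(image, config = feature_config()) {
  stopifnot(inherits(image, "raw_image"), inherits(config, "feature_config"))
  px <- image$pixels
  inm <- image$mask == 1
  if (!any(inm)) stop("breast mask is empty")
  if (any(!is.finite(px))) stop("image intensities must be finite")
  ref_range <- range(px[inm])
  domains <- filter_domains(px, image$mask, config)
  out <- numeric(0)
  if ("shape2d" %in% config$classes) {
    f <- shape2d_features(image$mask, image$preset$pixel_pitch)
    names(f) <- paste("original", "shape2d", names(f), sep = "_")
    out <- c(out, f)
  }
  tex_classes <- setdiff(config$classes, "shape2d")
  for (dn in names(domains)) {
    img <- domains[[dn]]
    dl <- discretize_levels(img, inm, config$bin_width,
                            ref_range = if (dn == "original") NULL else ref_range)
    v <- img[inm]
    for (cl in tex_classes) {
      f <- switch(cl,
        firstorder = fo_features(v, dl$G[inm], dl$n_levels),
        glcm = glcm_features(dl$G, dl$n_levels),
        glrlm = glrlm_features(dl$G, dl$n_levels),
        glszm = glszm_features(dl$G, dl$n_levels),
        gldm = gldm_features(dl$G, dl$n_levels),
        ngtdm = ngtdm_features(dl$G, dl$n_levels))
      names(f) <- paste(dn, cl, names(f), sep = "_")
      out <- c(out, f)
    }
  }
  if (any(!is.finite(out)))
    stop("non-finite feature value in: ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Extract a feature table for a list of images
#'
#' @param images list of [raw_image()]s.
#' @param config a [feature_config()].
#' @return data.frame with an `id` column followed by feature columns.
#' @export
extract_feature_table <- function(images, config = feature_config()) {
  rows <- lapply(images, extract_features, config = config)
  tab <- as.data.frame(do.call(rbind, rows))
  data.frame(id = vapply(images, `[[`, character(1), "id"), tab,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Min-max normalization fit on a row subset
#'
#' `x' = (x - min) / (max - min)` with min/max taken from `fit_rows` only and
#' applied to all rows (values outside the fitted range extrapolate beyond
#' `[0, 1]`; no clipping).  Constant columns map to zero.
#'
#' @param x data.frame or matrix of numeric feature columns.
#' @param fit_rows integer/logical row subset used to fit the ranges
#'   (default: all rows).
#' @return list with `x` (normalized, same type), `record` (data.frame
#'   `feature, min, max`).
#' @export
minmax_fit_apply <- function(x, fit_rows = seq_len(nrow(x))) {
  xm <- as.matrix(x)
  if (length(fit_rows) == 0) stop("fit_rows must be non-empty")
  mins <- apply(xm[fit_rows, , drop = FALSE], 2, min)
  maxs <- apply(xm[fit_rows, , drop = FALSE], 2, max)
  rngs <- maxs - mins
  out <- sweep(xm, 2, mins)
  out <- sweep(out, 2, ifelse(rngs > 0, rngs, 1), `/`)
  out[, rngs == 0] <- 0
  if (is.data.frame(x)) out <- as.data.frame(out)
  list(x = out,
       record = data.frame(feature = colnames(xm), min = mins, max = maxs,
                           row.names = NULL, stringsAsFactors = FALSE))
}
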