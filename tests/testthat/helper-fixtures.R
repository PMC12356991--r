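# Toy acquisition system: coarse 500 um pitch so the 10 mm ROI is only
# 20 x 20 px and whole-pipeline tests stay fast.
toy_preset <- function() {
  system_preset("T", pixel_pitch = 500, gain = 1, offset = 10,
                electronic_sigma = 2, roi_side = 20)
}

toy_image <- function(seed = 1, mean_signal = 200, texture_rms = 10,
                      shape = c(80, 80), id = sprintf("toy%03d", seed)) {
  generate_background(toy_preset(), shape, mean_signal = mean_signal,
                      texture_rms = texture_rms, seed = seed, id = id)
}

# 1 mm calcifications (2 px at the toy pitch)
toy_cluster <- function(seed = 1, n_calcs = 3) {
  generate_cluster_mask(toy_preset(), n_calcs = n_calcs,
                        calc_diameter = 1000, seed = seed)
}

toy_ensemble <- function(n, seed = 1, mean_signal = NULL) {
  lapply(seq_len(n), function(i)
    toy_image(seed = seed + i,
              mean_signal = if (is.null(mean_signal))
                150 + 20 * (i %% 5) else mean_signal,
              id = sprintf("toy%03d", i)))
}

# Brute-force pair-enumeration AUC (independent of the rank-based estimator).
brute_auc <- function(p, a) {
  mean(outer(p, a, `>`) + 0.5 * outer(p, a, `==`))
}

# Nested-loop centered convolution with symmetric (edge-repeating) padding.
conv2_loop <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x)
  ph <- nrow(k) %/% 2; pw <- ncol(k) %/% 2
  reflect <- function(i, n) {
    if (i < 1) 1 - i else if (i > n) 2 * n - i + 1 else i
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (u in seq_len(nrow(k))) for (v in seq_len(ncol(k))) {
      ii <- reflect(i + u - 1 - ph, nr)
      jj <- reflect(j + v - 1 - pw, nc)
      s <- s + k[u, v] * x[ii, jj]
    }
    out[i, j] <- s
  }
  out
}

# Pearson correlation from the raw product-moment formula (no stats::cor).
manual_cor <- function(x, y) {
  xm <- x - sum(x) / length(x)
  ym <- y - sum(y) / length(y)
  den <- sqrt(sum(xm^2) * sum(ym^2))
  if (den == 0) 0 else sum(xm * ym) / den
}

# CFS merit re-implementation on top of manual_cor.
manual_merit <- function(x, y, subset) {
  k <- length(subset)
  rcf <- mean(vapply(subset, function(f) abs(manual_cor(x[, f], y)),
                     numeric(1)))
  rff <- 0
  if (k > 1) {
    pairs <- utils::combn(subset, 2)
    rff <- mean(apply(pairs, 2, function(p)
      abs(manual_cor(x[, p[1]], x[, p[2]]))))
  }
  k * rcf / sqrt(k + k * (k - 1) * rff)
}
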