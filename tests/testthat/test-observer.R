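test_that("channel 0 is a radially symmetric Gaussian", {
  ch <- make_lg_channels(20, n_channels = 1, width = 3)
  u <- matrix(ch$basis[1, ], 20, 20)
  expect_true(all(u > 0))
  expect_equal(u, t(u))                       # symmetric in the two axes
  expect_equal(u, u[20:1, ])                  # mirror symmetric
  # profile matches exp(-pi r^2 / a^2) up to the normalization constant
  ctr <- (20 + 1) / 2
  r2 <- (1 - ctr)^2 + (5 - ctr)^2
  expect_equal(u[1, 5] / u[10, 10],
               exp(-pi * r2 / 9) / exp(-pi * ((10 - ctr)^2 * 2) / 9),
               tolerance = 1e-10)
})

test_that("channels match an independent closed-form Laguerre evaluation", {
  # oracle: explicit polynomial coefficients for L_0..L_4 rather than the
  # recurrence used by the implementation
  L <- list(function(x) rep(1, length(x)),
            function(x) 1 - x,
            function(x) 1 - 2 * x + x^2 / 2,
            function(x) 1 - 3 * x + 3 * x^2 / 2 - x^3 / 6,
            function(x) 1 - 4 * x + 3 * x^2 - 2 * x^3 / 3 + x^4 / 24)
  side <- 30; a <- 1.5
  ch <- make_lg_channels(side, n_channels = 5, width = a)
  ctr <- (side + 1) / 2
  xs <- seq_len(side) - ctr
  r2 <- outer(xs, xs, function(i, j) i^2 + j^2)
  for (j in 1:5) {
    u <- exp(-pi * r2 / a^2) * L[[j]](2 * pi * r2 / a^2)
    u <- as.vector(u) / sqrt(sum(u^2))
    expect_equal(ch$basis[j, ], u, tolerance = 1e-10)
  }
})

test_that("adequately sampled channels are orthonormal to 1e-3", {
  ch <- make_lg_channels(100, n_channels = 5, width = 8)
  expect_lt(ch$gram_offdiag, 1e-3)
  expect_equal(rowSums(ch$basis^2), rep(1, 5))
  # at the default 1.5 px width the discrete grid undersamples the Gaussian
  # and the Gram matrix is far from diagonal; the diagnostic records this
  ch15 <- make_lg_channels(100, n_channels = 5, width = 1.5)
  expect_gt(ch15$gram_offdiag, 0.1)
})

test_that("over-wide channels trigger the truncation warning", {
  w <- capture_warnings(make_lg_channels(20, n_channels = 3, width = 30))
  expect_gt(length(w), 0)
  expect_true(all(grepl("truncated", w)))
})

test_that("cluster-matched channels stay unit-norm and keep the count", {
  m <- toy_cluster(seed = 2)
  ch <- cluster_channels(make_lg_channels(20, width = 1.5), m)
  expect_equal(ch$n_channels, 5L)
  expect_equal(rowSums(ch$basis^2), rep(1, 5))
})

test_that("identical class means give a zero Hotelling template", {
  ch <- make_lg_channels(20)
  set.seed(1)
  V <- matrix(rnorm(5 * 50), 5, 50)
  tpl <- cho_train(V, V, ch)
  expect_equal(tpl$weights, rep(0, 5))
})

test_that("2-channel template equals the hand linear-algebra solution", {
  ch <- make_lg_channels(20, n_channels = 2, width = 3)
  set.seed(2)
  Va <- matrix(rnorm(2 * 40), 2, 40)
  Vp <- matrix(rnorm(2 * 40, mean = 0.5), 2, 40)
  tpl <- cho_train(Va, Vp, ch)
  S <- (cov(t(Va)) + cov(t(Vp))) / 2
  dv <- rowMeans(Vp) - rowMeans(Va)
  # hand 2x2 solve via the adjugate
  det_s <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  w_hand <- c(S[2, 2] * dv[1] - S[1, 2] * dv[2],
              -S[2, 1] * dv[1] + S[1, 1] * dv[2]) / det_s
  expect_equal(tpl$weights, w_hand, tolerance = 1e-10)
  expect_equal(tpl$n_absent, 40L)
})

test_that("too-small training sets are rejected", {
  ch <- make_lg_channels(20)
  V <- matrix(rnorm(5 * 4), 5, 4)
  expect_error(cho_train(V, V, ch), "n_channels")
})

test_that("decision statistic is w'v at zero internal noise", {
  ch <- make_lg_channels(20, n_channels = 2, width = 3)
  set.seed(3)
  Va <- matrix(rnorm(2 * 30), 2, 30)
  Vp <- matrix(rnorm(2 * 30, 1), 2, 30)
  tpl <- cho_train(Va, Vp, ch, internal_sigma = 0)
  v <- matrix(rnorm(2 * 7), 2, 7)
  expect_equal(predict(tpl, v), as.vector(crossprod(tpl$weights, v)))
  expect_equal(predict(tpl, v), predict(tpl, v))  # deterministic
})

test_that("huge internal noise drives AUC to one half", {
  ch <- make_lg_channels(20, n_channels = 2, width = 3)
  set.seed(4)
  Va <- matrix(rnorm(2 * 500), 2, 500)
  Vp <- matrix(rnorm(2 * 500, 2), 2, 500)
  tpl <- cho_train(Va, Vp, ch, internal_sigma = 1e4)
  set.seed(5)
  auc <- auc_mw(predict(tpl, Vp), predict(tpl, Va))
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("Mann-Whitney AUC matches pair enumeration", {
  expect_equal(auc_mw(c(2, 3), c(0, 1)), 1.0)
  expect_equal(auc_mw(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(auc_mw(c(1, 2, 3), c(2, 2)), brute_auc(c(1, 2, 3), c(2, 2)))
  expect_equal(auc_mw(c(1, 2, 3), c(2, 2)), 0.5)
  set.seed(6)
  for (i in 1:20) {
    p <- sample(0:5, sample(1:10, 1), replace = TRUE)
    a <- sample(0:5, sample(1:10, 1), replace = TRUE)
    expect_equal(auc_mw(p, a), brute_auc(p, a))
  }
  expect_error(auc_mw(numeric(0), 1), "non-empty")
})

test_that("CHO AUC matches the Gaussian closed form", {
  # equal-covariance Gaussian channel data: population AUC is
  # Phi(d_a / sqrt(2 (1 + sigma^2))) with d_a^2 = dv' S^-1 dv
  ch <- make_lg_channels(20)
  set.seed(7)
  A <- matrix(rnorm(25), 5, 5)
  S <- A %*% t(A) + diag(5)
  R <- chol(S)
  dv <- c(0.5, 0.3, -0.2, 0.1, 0.4)
  da <- sqrt(sum(dv * solve(S, dv)))
  scale <- 1.4 / da
  dv <- dv * scale; da <- 1.4
  gen <- function(n, mu) t(matrix(rnorm(n * 5), n, 5) %*% R +
                             rep(mu, each = n))
  tpl <- cho_train(gen(3000, rep(0, 5)), gen(3000, dv), ch)
  for (sig in c(0, 1)) {
    tpl$internal_sigma <- sig
    set.seed(8)
    auc <- auc_mw(predict(tpl, gen(4000, dv)), predict(tpl, gen(4000, rep(0, 5))))
    expect_lt(abs(auc - pnorm(da / sqrt(2 * (1 + sig^2)))), 0.01)
  }
})

test_that("per-image scoring is reproducible and uses the requested readers", {
  imgs <- toy_ensemble(8, seed = 20)
  m <- toy_cluster(seed = 1)
  ch <- cluster_channels(make_lg_channels(20), m)
  pool <- build_roi_pool(imgs, m, 0.08, ch, seed = 2)
  s1 <- score_image(imgs[[1]], m, 0.08, pool, n_readers = 5,
                    n_train_absent = 300, n_train_present = 100, seed = 3)
  s2 <- score_image(imgs[[1]], m, 0.08, pool, n_readers = 5,
                    n_train_absent = 300, n_train_present = 100, seed = 3)
  expect_identical(s1$auc_mean, s2$auc_mean)
  expect_equal(s1$n_readers, 5)
  expect_length(s1$auc, 5)
  expect_true(s1$auc_mean >= 0 && s1$auc_mean <= 1)
  expect_gte(s1$auc_sd, 0)
})

test_that("high contrast on easy backgrounds is near-perfectly detectable", {
  imgs <- toy_ensemble(6, seed = 30, mean_signal = 400)
  m <- toy_cluster(seed = 1)
  ch <- cluster_channels(make_lg_channels(20), m)
  pool <- build_roi_pool(imgs, m, 0.5, ch, seed = 2)
  s <- score_image(imgs[[1]], m, 0.5, pool, n_readers = 5,
                   n_train_absent = 300, n_train_present = 100, seed = 3)
  expect_gt(s$auc_mean, 0.95)
})

test_that("internal-noise calibration reaches the operating band", {
  imgs <- toy_ensemble(10, seed = 40, mean_signal = 350)
  m <- toy_cluster(seed = 1)
  ch <- cluster_channels(make_lg_channels(20), m)
  pool <- build_roi_pool(imgs, m, 0.08, ch, seed = 2)
  cal <- calibrate_internal_noise(imgs, m, 0.08, channels = ch, pool = pool,
                                  n_readers = 4, n_per_class = 60,
                                  n_train_absent = 300,
                                  n_train_present = 100, seed = 3)
  expect_gte(cal$achieved_auc, 0.75)
  expect_lte(cal$achieved_auc, 0.80)
  expect_gt(cal$internal_sigma, 0)
  # band already containing the sigma = 0 operating point returns zero
  cal0 <- calibrate_internal_noise(imgs, m, 0.08, channels = ch, pool = pool,
                                   target_low = 0.51,
                                   target_high = 0.999,
                                   n_readers = 4, n_per_class = 60,
                                   n_train_absent = 300,
                                   n_train_present = 100, seed = 3)
  expect_equal(cal0$internal_sigma, 0)
  # unreachable band errors
  expect_error(
    calibrate_internal_noise(imgs, m, 0.001, channels = ch, pool = pool,
                             target_low = 0.97, target_high = 0.99,
                             n_readers = 2, n_per_class = 30,
                             n_train_absent = 300, n_train_present = 100,
                             seed = 3),
    class = "mammoiq_calibration_error")
})
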