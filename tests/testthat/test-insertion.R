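test_that("insertion attenuates stencil pixels by exactly (1 - lambda)", {
  p <- toy_preset()
  img <- raw_image(matrix(1000, 80, 80), breast_support_mask(c(80, 80)), p,
                   id = "const")
  m <- toy_cluster(seed = 2)
  out <- insert_cluster(img, m, contrast = 0.08, center = c(40, 40))
  w <- out$pixels[31:50, 31:50]   # the 20 x 20 stencil window at (40, 40)
  expect_equal(sort(unique(as.vector(w))), c(920, 1000))
  expect_equal(w[m$stencil == 1], rep(920, sum(m$stencil)))
  # complement untouched
  untouched <- out$pixels; untouched[31:50, 31:50] <- 1000
  expect_true(all(untouched == 1000))
})

test_that("zero contrast is the identity and the image sum drops by lambda * sum(I0[M])", {
  img <- toy_image(seed = 9)
  m <- toy_cluster(seed = 3)
  expect_equal(insert_cluster(img, m, 0, c(40, 40))$pixels, img$pixels)
  lam <- 0.3
  out <- insert_cluster(img, m, lam, c(40, 40))
  w <- img$pixels[31:50, 31:50]
  expect_equal(sum(img$pixels) - sum(out$pixels),
               lam * sum(w[m$stencil == 1]))
})

test_that("insertion matches an independent elementwise evaluation", {
  p <- toy_preset()
  set.seed(5)
  px <- matrix(runif(32 * 32, 100, 500), 32, 32)
  img <- raw_image(px, matrix(1, 32, 32), p, id = "rnd")
  m <- toy_cluster(seed = 4)
  out <- insert_cluster(img, m, 0.3, c(16, 16))
  # brute-force oracle: loop over the full image with the placed stencil
  M <- matrix(0, 32, 32)
  M[7:26, 7:26] <- m$stencil
  expected <- px
  for (i in 1:32) for (j in 1:32)
    expected[i, j] <- px[i, j] * (1 - 0.3 * M[i, j])
  expect_equal(out$pixels, expected)
})

test_that("out-of-bounds stencil window raises a geometry error", {
  img <- toy_image(seed = 1)
  m <- toy_cluster()
  expect_error(insert_cluster(img, m, 0.1, c(5, 5)),
               class = "mammoiq_geometry_error")
})

test_that("sampled centers respect the margin (distance-transform oracle)", {
  img <- toy_image(seed = 2)
  ctr <- sample_locations(img, 40, margin = 5, seed = 3)
  expect_equal(nrow(ctr), 40)
  expect_equal(anyDuplicated(ctr), 0L)
  # brute-force Euclidean distance to background or image border
  bg <- which(img$mask == 0, arr.ind = TRUE)
  nr <- nrow(img$mask); nc <- ncol(img$mask)
  margin_px <- 5 * 1000 / img$preset$pixel_pitch
  for (k in seq_len(nrow(ctr))) {
    d_bg <- sqrt(min((bg[, 1] - ctr[k, 1])^2 + (bg[, 2] - ctr[k, 2])^2))
    d_border <- min(ctr[k, 1], ctr[k, 2], nr + 1 - ctr[k, 1],
                    nc + 1 - ctr[k, 2])
    expect_gte(min(d_bg, d_border), margin_px)
  }
  # ROI windows fit in the image
  half <- img$preset$roi_side %/% 2
  side <- img$preset$roi_side
  expect_true(all(ctr[, 1] - half + 1 >= 1 & ctr[, 1] - half + side <= nr))
})

test_that("degenerate and oversubscribed sampling are handled", {
  img <- toy_image(seed = 2)
  expect_equal(nrow(sample_locations(img, 0)), 0)
  expect_error(sample_locations(img, 10000, margin = 5, seed = 1),
               class = "mammoiq_sampling_error")
})

test_that("ROI set has balanced classes built from disjoint centers", {
  img <- toy_image(seed = 6)
  m <- toy_cluster(seed = 1)
  rs <- build_roi_set(img, m, contrast = 0.08, n_per_class = 25, seed = 4)
  expect_equal(rs$n_present, 25)
  expect_equal(rs$n_absent, 25)
  expect_length(rs$rois, 50)
  labs <- vapply(rs$rois, `[[`, character(1), "label")
  expect_equal(sum(labs == "signal_present"), 25)
  centers <- t(vapply(rs$rois, `[[`, numeric(2), "center"))
  expect_equal(anyDuplicated(centers), 0L)
  # present patches equal insert-at-center-then-extract recomputed manually
  k <- 3
  ctr <- rs$rois[[k]]$center
  manual <- insert_cluster(img, m, 0.08, ctr)
  w <- manual$pixels[(ctr[1] - 9):(ctr[1] + 10), (ctr[2] - 9):(ctr[2] + 10)]
  expect_equal(rs$rois[[k]]$patch, w)
})

test_that("present ROIs are darker than absent ones on a constant background", {
  p <- toy_preset()
  img <- raw_image(matrix(300, 80, 80), breast_support_mask(c(80, 80)), p,
                   id = "flat")
  m <- toy_cluster(seed = 2)
  rs <- build_roi_set(img, m, contrast = 0.2, n_per_class = 10, seed = 5)
  mp <- mean(sapply(rs$rois[1:10], function(r) mean(r$patch)))
  ma <- mean(sapply(rs$rois[11:20], function(r) mean(r$patch)))
  expect_lt(mp, ma)
})

test_that("patch degradation hook is applied after insertion", {
  img <- toy_image(seed = 8)
  m <- toy_cluster(seed = 1)
  rs0 <- build_roi_set(img, m, 0.08, n_per_class = 5, seed = 4)
  rs1 <- build_roi_set(img, m, 0.08, n_per_class = 5, seed = 4,
                       degrade_patch = function(patch, k) patch * 2)
  expect_equal(rs1$rois[[1]]$patch, rs0$rois[[1]]$patch * 2)
})
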