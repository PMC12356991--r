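test_that("constant image collapses to degenerate first-order features", {
  p <- toy_preset()
  img <- raw_image(matrix(500, 64, 64), breast_support_mask(c(64, 64)), p,
                   id = "const")
  f <- extract_features(img, feature_config(filters = "original",
                                            classes = "firstorder"))
  expect_equal(unname(f["original_firstorder_variance"]), 0)
  expect_equal(unname(f["original_firstorder_entropy"]), 0)
  expect_equal(unname(f["original_firstorder_skewness"]), 0)
  expect_equal(unname(f["original_firstorder_kurtosis"]), 0)
  expect_equal(unname(f["original_firstorder_mean"]), 500)
})

test_that("first-order mean and variance equal direct masked statistics", {
  img <- toy_image(seed = 12)
  f <- extract_features(img, feature_config(filters = "original",
                                            classes = "firstorder"))
  v <- img$pixels[img$mask == 1]
  expect_equal(unname(f["original_firstorder_mean"]), mean(v))
  expect_equal(unname(f["original_firstorder_variance"]),
               mean((v - mean(v))^2))
  expect_equal(unname(f["original_firstorder_median"]), median(v))
})

test_that("GLCM contrast matches a hand-enumerated co-occurrence matrix", {
  p <- toy_preset()
  px <- matrix(c(1, 1, 2, 3,
                 2, 2, 3, 3,
                 1, 2, 2, 3,
                 3, 3, 2, 1), 4, 4, byrow = TRUE)
  img <- raw_image(px, matrix(1, 4, 4), p, id = "toy4")
  f <- extract_features(img, feature_config(filters = "original",
                                            classes = "glcm", bin_width = 1))
  # oracle: enumerate symmetric co-occurrence pairs per offset with loops
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  contrasts <- sapply(offs, function(o) {
    P <- matrix(0, 3, 3)
    for (i in 1:4) for (j in 1:4) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii >= 1 && ii <= 4 && jj >= 1 && jj <= 4) {
        a <- px[i, j]; b <- px[ii, jj]
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
    }
    P <- P / sum(P)
    s <- 0
    for (a in 1:3) for (b in 1:3) s <- s + P[a, b] * (a - b)^2
    s
  })
  expect_equal(unname(f["original_glcm_contrast"]), mean(contrasts))
})

test_that("no feature depends on pixels outside the breast mask", {
  img <- toy_image(seed = 13, shape = c(64, 64))
  cfg <- feature_config()   # full default filter/class grid
  f1 <- extract_features(img, cfg)
  img2 <- img
  img2$pixels[img2$mask == 0] <- 12345   # rewrite the air
  f2 <- extract_features(img2, cfg)
  expect_identical(f1, f2)
})

test_that("extraction is deterministic with stable namespaced names", {
  img <- toy_image(seed = 14, shape = c(64, 64))
  cfg <- feature_config()
  f1 <- extract_features(img, cfg)
  f2 <- extract_features(img, cfg)
  expect_identical(f1, f2)
  img3 <- toy_image(seed = 15, shape = c(64, 64))
  f3 <- extract_features(img3, cfg)
  expect_identical(names(f1), names(f3))
  expect_true(all(grepl("^[a-zA-Z0-9.]+_[a-z0-9]+_[a-z_0-9]+$", names(f1))))
  # documented count for the default grid: 14 domains x 52 texture features
  # + 8 shape descriptors
  expect_length(f1, 14 * 52 + 8)
  expect_true(all(is.finite(f1)))
})

test_that("reduced configuration drops the expensive domains", {
  img <- toy_image(seed = 16, shape = c(64, 64))
  f <- extract_features(img, feature_config_reduced())
  expect_false(any(grepl("glszm|gldm|log\\.", names(f))))
  expect_true(any(grepl("^wavelet.LL_", names(f))))
  expect_length(f, 7 * (16 + 8 + 8 + 5))
})

test_that("feature table binds per-image rows by id", {
  imgs <- toy_ensemble(3, seed = 50)
  tab <- extract_feature_table(imgs, feature_config(filters = "original",
                                                    classes = "firstorder"))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$id, vapply(imgs, `[[`, character(1), "id"))
  expect_equal(tab$original_firstorder_mean[2],
               mean(imgs[[2]]$pixels[imgs[[2]]$mask == 1]))
})

test_that("min-max scaling maps the fit range to [0, 1] and extrapolates", {
  x <- data.frame(a = c(2, 4, 6), b = c(1, 1, 1))
  out <- minmax_fit_apply(x)
  expect_equal(out$x$a, c(0, 0.5, 1))
  expect_equal(out$x$b, c(0, 0, 0))     # constant column convention
  expect_equal(out$record$min, c(2, 1))
  # fit on a subset, applied to all rows: unseen values extrapolate
  x2 <- data.frame(a = c(2, 4, 6, 8))
  out2 <- minmax_fit_apply(x2, fit_rows = 1:3)
  expect_equal(out2$x$a, c(0, 0.5, 1, 1.5))
})
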