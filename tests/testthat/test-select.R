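test_that("cross-validation plan partitions rows without leakage", {
  plan <- make_cv_plan(103, outer = 10, inner = 5, seed = 3)
  tab <- table(plan$outer)
  expect_equal(length(tab), 10L)
  expect_true(max(tab) - min(tab) <= 1)      # near-equal outer folds
  for (k in 1:10) {
    inn <- plan$inner[[k]]
    expect_true(all(is.na(inn[plan$outer == k])))      # test rows excluded
    expect_true(all(!is.na(inn[plan$outer != k])))     # training rows covered
    expect_equal(sort(unique(inn[!is.na(inn)])), 1:5)
  }
  expect_identical(make_cv_plan(103, seed = 3)$outer, plan$outer)
  expect_error(make_cv_plan(20, 10, 5), class = "mammoiq_plan_error")
})

test_that("single-feature merit is the absolute target correlation", {
  set.seed(4)
  x <- data.frame(f1 = rnorm(50))
  y <- 2 * x$f1 + rnorm(50, sd = 0.5)
  expect_equal(cfs_merit(x, y, "f1"), abs(cor(x$f1, y)))
})

test_that("a perfectly redundant twin adds no merit", {
  set.seed(5)
  f1 <- rnorm(100)
  y <- f1 + rnorm(100, sd = 0.8)
  x <- data.frame(f1 = f1, f2 = f1)     # r_ff = 1
  r <- abs(cor(f1, y))
  # k = 2, rcf = r, rff = 1: merit = 2r / sqrt(2 + 2) = r
  expect_equal(cfs_merit(x, y, c("f1", "f2")), r, tolerance = 1e-12)
})

test_that("merit matches a dual implementation over all subsets", {
  set.seed(6)
  n <- 20
  x <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(x) <- paste0("f", 1:6)
  x$f3 <- x$f1 * 0.8 + rnorm(n, sd = 0.3)
  y <- x$f1 - 0.5 * x$f2 + rnorm(n, sd = 0.5)
  for (k in 1:6) {
    for (sub in as.data.frame(utils::combn(names(x), k))) {
      sub <- as.character(sub)
      expect_equal(cfs_merit(x, y, sub),
                   manual_merit(as.matrix(x), y, sub), tolerance = 1e-10)
    }
  }
  expect_error(cfs_merit(x, y, character(0)), "non-empty")
})

test_that("constant features contribute zero correlation", {
  set.seed(7)
  x <- data.frame(f1 = rnorm(30), f2 = rep(1, 30))
  y <- x$f1
  r <- abs(cor(x$f1, y))
  # rcf = (r + 0)/2, rff = 0
  expect_equal(cfs_merit(x, y, c("f1", "f2")), 2 * (r / 2) / sqrt(2))
})

test_that("merit is invariant to affine rescaling of features", {
  set.seed(8)
  x <- as.data.frame(matrix(rnorm(40 * 3), 40, 3))
  names(x) <- c("a", "b", "c")
  y <- rnorm(40)
  m1 <- cfs_merit(x, y, c("a", "b", "c"))
  x$b <- 100 * x$b - 7
  expect_equal(cfs_merit(x, y, c("a", "b", "c")), m1, tolerance = 1e-12)
})

test_that("best-first search finds the planted predictive feature", {
  set.seed(9)
  n <- 200
  x <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  names(x) <- sprintf("f%02d", 1:10)
  y <- x$f05 + rnorm(n, sd = 0.1)
  res <- best_first_select(x, y)
  expect_true("f05" %in% res$selected)
  expect_gt(res$merit, 0.9)
  expect_true(all(diff(res$merit_trace) >= 0))
})

test_that("best-first with ample patience matches exhaustive enumeration", {
  set.seed(10)
  n <- 60
  x <- as.data.frame(matrix(rnorm(n * 8), n, 8))
  names(x) <- sprintf("g%d", 1:8)
  y <- 0.8 * x$g2 - 0.6 * x$g5 + rnorm(n, sd = 0.7)
  res <- best_first_select(x, y, max_stale = 300)
  best_exh <- 0
  for (k in 1:8)
    for (sub in as.data.frame(utils::combn(names(x), k)))
      best_exh <- max(best_exh, cfs_merit(x, y, as.character(sub)))
  expect_gte(res$merit, best_exh - 1e-12)
})

test_that("all-noise features produce near-zero merit", {
  set.seed(11)
  n <- 200
  x <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  names(x) <- sprintf("n%02d", 1:10)
  y <- rnorm(n)
  res <- best_first_select(x, y)
  expect_lt(max(res$merit_trace), 0.2)
})

test_that("nested CV pools n_outer x n_inner subsets and thresholds them", {
  set.seed(12)
  n <- 120
  x <- as.data.frame(matrix(rnorm(n * 8), n, 8))
  names(x) <- sprintf("f%d", 1:8)
  y <- 2 * x$f1 + rnorm(n, sd = 0.05)
  plan <- make_cv_plan(n, outer = 10, inner = 5, seed = 13)
  sel <- nested_cv_select(x, y, plan, threshold = 1.0)
  expect_equal(sel$n_subsets, 50)
  expect_length(sel$subsets, 50)
  # the planted feature is in every subset; threshold 1.0 keeps exactly it
  expect_equal(sel$consensus, "f1")
  # threshold 0 degenerates to the union of all subsets
  sel0 <- nested_cv_select(x, y, plan, threshold = 0)
  expect_setequal(sel0$consensus, unique(unlist(sel0$subsets)))
  # consensus shrinks monotonically in the threshold
  sizes <- sapply(c(0, 0.1, 0.5, 1.0), function(th)
    length(nested_cv_select(x, y, plan, threshold = th)$consensus))
  expect_true(all(diff(sizes) <= 0))
})

test_that("outer-test rows never influence their fold's selection", {
  set.seed(14)
  n <- 100
  x <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(x) <- sprintf("f%d", 1:6)
  y <- x$f2 + rnorm(n, sd = 0.3)
  plan <- make_cv_plan(n, outer = 10, inner = 5, seed = 15)
  sel <- nested_cv_select(x, y, plan, threshold = 0.5)
  # scramble fold 1's held-out rows: its 5 inner selections must not move
  idx <- which(plan$outer == 1)
  x2 <- x; y2 <- y
  x2[idx, ] <- matrix(rnorm(length(idx) * 6), length(idx), 6)
  y2[idx] <- rnorm(length(idx))
  sel2 <- nested_cv_select(x2, y2, plan, threshold = 0.5)
  expect_identical(sel$subsets[1:5], sel2$subsets[1:5])
})
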