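#' Multilayer-perceptron regressor
#'
#' Fully connected feed-forward network with ReLU hidden layers and a linear
#' output unit, trained by seeded mini-batch gradient descent with momentum
#' on the mean squared error.  Defaults follow the detectability-regression
#' protocol: hidden sizes 30-15-5, learning rate and momentum 0.05, 1200
#' epochs, batch size 100 (clipped to `n` when smaller), weights initialized
#' uniformly in `[-0.5, 0.5]` with biases at +0.1.  No early stopping.
#' Deterministic under a fixed seed.
#'
#' A narrow all-ReLU bottleneck can die during training (every unit inactive
#' for every input), leaving a constant predictor that plain SGD cannot
#' revive.  When that happens on a non-constant target, the fit is restarted
#' from a reinitialization with a seed derived from `seed` (at most
#' `max_restarts` times, still fully deterministic); `n_restarts` on the
#' returned object records how many were needed.
#'
#' @param x numeric matrix/data.frame of (normalized) inputs.
#' @param y numeric target vector.
#' @param hidden integer vector of hidden-layer sizes.
#' @param learning_rate,momentum SGD parameters.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param seed integer seed.
#' @param max_restarts reinitializations allowed after a dead-network fit.
#' @return Object of class `mlp` with weight matrices, the per-epoch loss
#'   trace, fitted training values and the call configuration.
#' @export
mlp <- function(x, y, hidden = c(30, 15, 5), learning_rate = 0.05,
                momentum = 0.05, epochs = 1200, batch_size = 100, seed = 1,
                max_restarts = 4) {
  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  n <- nrow(xm)
  stopifnot(n == length(y), epochs >= 1, batch_size >= 1, all(hidden > 0))
  for (attempt in 0:max_restarts) {
    fit <- mlp_fit_once(xm, y, hidden, learning_rate, momentum, epochs,
                        batch_size, seed + 100003L * attempt)
    alive <- stats::sd(y) == 0 ||
      stats::sd(fit$fitted) > 1e-6 * stats::sd(y)
    if (alive) break
  }
  fit$n_restarts <- attempt
  fit$config$seed <- seed
  fit
}

mlp_fit_once <- function(xm, y, hidden, learning_rate, momentum, epochs,
                         batch_size, seed) {
  n <- nrow(xm)
  bs <- min(batch_size, n)
  sizes <- c(ncol(xm), hidden, 1L)
  L <- length(sizes) - 1L
  set.seed(seed)
  W <- lapply(seq_len(L), function(l)
    matrix(stats::runif(sizes[l] * sizes[l + 1], -0.5, 0.5),
           sizes[l], sizes[l + 1]))
  # small positive bias keeps the narrow ReLU layers initially active (an
  # all-dead 5-unit bottleneck would never recover under plain SGD)
  b <- lapply(seq_len(L), function(l) rep(0.1, sizes[l + 1]))
  vW <- lapply(W, function(w) w * 0)
  vb <- lapply(b, function(z) z * 0)
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = bs)) {
      rows <- perm[start:min(start + bs - 1, n)]
      xb <- xm[rows, , drop = FALSE]
      yb <- y[rows]
      m <- length(rows)
      # forward
      act <- vector("list", L + 1)
      act[[1]] <- xb
      for (l in seq_len(L)) {
        z <- act[[l]] %*% W[[l]] + rep(b[[l]], each = m)
        act[[l + 1]] <- if (l < L) pmax(z, 0) else z
      }
      pred <- act[[L + 1]][, 1]
      err <- pred - yb
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop("MLP training diverged (non-finite loss); config: lr = ",
             learning_rate, ", momentum = ", momentum, ", hidden = ",
             paste(hidden, collapse = "-"))
      ep_loss <- ep_loss + loss; nb <- nb + 1
      # backward
      delta <- matrix(2 * err / m, m, 1)
      for (l in L:1) {
        gW <- crossprod(act[[l]], delta)
        gb <- colSums(delta)
        if (l > 1)
          delta <- (delta %*% t(W[[l]])) * (act[[l]] > 0)
        vW[[l]] <- momentum * vW[[l]] - learning_rate * gW
        vb[[l]] <- momentum * vb[[l]] - learning_rate * gb
        W[[l]] <- W[[l]] + vW[[l]]
        b[[l]] <- b[[l]] + vb[[l]]
      }
    }
    loss_trace[ep] <- ep_loss / nb
  }
  fit <- structure(list(weights = W, biases = b, sizes = sizes,
                        loss_trace = loss_trace,
                        feature_names = colnames(xm),
                        config = list(hidden = hidden,
                                      learning_rate = learning_rate,
                                      momentum = momentum, epochs = epochs,
                                      batch_size = bs, seed = seed),
                        y = y),
                   class = "mlp")
  fit$fitted <- predict(fit, xm)
  fit
}

#' @export
predict.mlp <- function(object, newdata, ...) {
  xm <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(xm)))
    xm <- xm[, object$feature_names, drop = FALSE]
  a <- xm
  L <- length(object$weights)
  for (l in seq_len(L)) {
    z <- a %*% object$weights[[l]] + rep(object$biases[[l]], each = nrow(a))
    a <- if (l < L) pmax(z, 0) else z
  }
  as.vector(a)
}

#' @export
print.mlp <- function(x, ...) {
  cat(sprintf("<mlp> %s, final training MSE %.3g (%d epochs)\n",
              paste(x$sizes, collapse = "-"),
              x$loss_trace[length(x$loss_trace)], x$config$epochs))
  invisible(x)
}

#' @export
summary.mlp <- function(object, ...) {
  res <- object$y - object$fitted
  cat(sprintf("MLP regressor %s\n", paste(object$sizes, collapse = "-")))
  cat(sprintf("  lr %g, momentum %g, %d epochs, batch %d, seed %d\n",
              object$config$learning_rate, object$config$momentum,
              object$config$epochs, object$config$batch_size,
              object$config$seed))
  cat(sprintf("  training MSE %.4g, RMSE %.4g, r %.4f\n",
              mean(res^2), sqrt(mean(res^2)),
              suppressWarnings(stats::cor(object$fitted, object$y))))
  invisible(object)
}

#' @export
coef.mlp <- function(object, ...) {
  list(weights = object$weights, biases = object$biases)
}

#' @export
residuals.mlp <- function(object, ...) {
  object$y - object$fitted
}

#' @export
plot.mlp <- function(x, ...) {
  graphics::plot(x$loss_trace, type = "l", xlab = "epoch",
                 ylab = "training MSE", main = "MLP training loss", ...)
  invisible(x)
}

#' Regression performance metrics
#'
#' Pearson correlation, MAE, RMSE, and the relative errors RAE and RRSE
#' (percent), which normalize the absolute and squared errors by those of the
#' predict-the-training-mean baseline.
#'
#' @param predictions,actuals numeric vectors of equal length (>= 2).
#' @param baseline_mean mean of the fold's training targets.
#' @return list with `r`, `mae`, `rmse`, `rae`, `rrse`.
#' @export
evaluate_regression <- function(predictions, actuals, baseline_mean) {
  stopifnot(length(predictions) == length(actuals), length(actuals) >= 2)
  if (stats::var(actuals) == 0)
    stop(structure(class = c("mammoiq_metric_error", "error", "condition"),
                   list(message = "constant actuals: relative metrics undefined",
                        call = sys.call())))
  e <- predictions - actuals
  r <- if (stats::sd(predictions) > 0)
    stats::cor(predictions, actuals) else 0
  list(r = r,
       mae = mean(abs(e)),
       rmse = sqrt(mean(e^2)),
       rae = 100 * sum(abs(e)) / sum(abs(actuals - baseline_mean)),
       rrse = 100 * sqrt(sum(e^2) / sum((actuals - baseline_mean)^2)))
}

#' Outer-fold cross-validated MLP evaluation
#'
#' For each outer fold: restrict to the consensus features, refit the
#' min-max normalization on the training rows only, train the MLP, predict
#' the held-out fold and compute the metrics with the training-mean baseline.
#' Reports per-fold metrics with their mean and SD.
#'
#' @param x data.frame/matrix of raw (unnormalized) features.
#' @param y numeric target (detectability AUC per image).
#' @param selection a [nested_cv_select()] result (or a character vector of
#'   feature names).
#' @param plan a [make_cv_plan()].
#' @param mlp_args list of arguments forwarded to [mlp()].
#' @param seed base seed; the fold index is added for per-fold weight init.
#' @return Object of class `cv_report`: `per_fold` data.frame
#'   (`fold, r, mae, rmse, rae, rrse`), `mean`, `sd`, `predictions`
#'   data.frame (`fold, actual, predicted`).
#' @export
run_outer_cv <- function(x, y, selection, plan, mlp_args = list(), seed = 1) {
  feats <- if (inherits(selection, "selection_result"))
    selection$consensus else selection
  if (length(feats) == 0) stop("consensus feature set is empty")
  xm <- as.matrix(x)[, feats, drop = FALSE]
  folds <- vector("list", plan$n_outer)
  preds <- list()
  for (k in seq_len(plan$n_outer)) {
    te <- which(plan$outer == k)
    tr <- which(plan$outer != k)
    nm <- minmax_fit_apply(xm, fit_rows = tr)
    args <- c(list(x = nm$x[tr, , drop = FALSE], y = y[tr],
                   seed = seed + k), mlp_args)
    fit <- do.call(mlp, args)
    p <- predict(fit, nm$x[te, , drop = FALSE])
    met <- evaluate_regression(p, y[te], baseline_mean = mean(y[tr]))
    folds[[k]] <- data.frame(fold = k, r = met$r, mae = met$mae,
                             rmse = met$rmse, rae = met$rae, rrse = met$rrse)
    preds[[k]] <- data.frame(fold = k, actual = y[te], predicted = p)
  }
  per_fold <- do.call(rbind, folds)
  mcols <- c("r", "mae", "rmse", "rae", "rrse")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[mcols]),
                 sd = apply(per_fold[mcols], 2, stats::sd),
                 predictions = do.call(rbind, preds),
                 features = feats),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d outer folds, %d features\n",
              nrow(x$per_fold), length(x$features)))
  s <- rbind(mean = x$mean, sd = x$sd)
  print(round(s, 4))
  invisible(x)
}

#' @export
plot.cv_report <- function(x, ...) {
  graphics::plot(x$predictions$actual, x$predictions$predicted,
                 xlab = "actual AUC", ylab = "predicted AUC",
                 main = sprintf("outer-CV predictions (mean r = %.3f)",
                                x$mean["r"]), ...)
  graphics::abline(0, 1, lty = 2, col = 2)
  invisible(x)
}
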