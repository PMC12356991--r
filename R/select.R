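#' Nested cross-validation plan
#'
#' Random partition into `outer` near-equal folds; within each outer training
#' split, a further random partition into `inner` folds.  Every row appears
#' in exactly one outer test fold.
#'
#' @param n number of rows.
#' @param outer,inner fold counts (defaults 10 and 5).
#' @param seed integer seed.
#' @return Object of class `cv_plan`: `outer` (vector of outer fold ids),
#'   `inner` (list per outer fold: vector with inner ids on training rows and
#'   `NA` on that fold's test rows), `n`, `n_outer`, `n_inner`, `seed`.
#' @export
make_cv_plan <- function(n, outer = 10, inner = 5, seed = 1) {
  if (n < outer * inner)
    stop(structure(class = c("mammoiq_plan_error", "error", "condition"),
                   list(message = "too few rows for the requested fold plan",
                        call = sys.call())))
  set.seed(seed)
  of <- sample(rep(seq_len(outer), length.out = n))
  inn <- lapply(seq_len(outer), function(k) {
    v <- rep(NA_integer_, n)
    tr <- which(of != k)
    v[tr] <- sample(rep(seq_len(inner), length.out = length(tr)))
    v
  })
  structure(list(outer = of, inner = inn, n = n, n_outer = outer,
                 n_inner = inner, seed = seed),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %d rows, %d outer x %d inner folds (seed %d)\n",
              x$n, x$n_outer, x$n_inner, x$seed))
  invisible(x)
}

#' CFS merit of a feature subset
#'
#' `merit = k * rcf / sqrt(k + k (k - 1) * rff)`, where `k` is the subset
#' size, `rcf` the mean absolute Pearson correlation between the subset's
#' features and the target, and `rff` the mean absolute pairwise correlation
#' among the subset's features.  Constant columns contribute correlation 0.
#' The formula can exceed 1 for anticorrelated feature pairs; it is reported
#' as computed, not clipped.
#'
#' @param x data.frame or matrix of features.
#' @param y numeric target.
#' @param subset character vector of feature names (or integer indices).
#' @return merit value.
#' @export
cfs_merit <- function(x, y, subset) {
  if (length(subset) == 0) stop("subset must be non-empty")
  xm <- as.matrix(x)
  idx <- if (is.character(subset)) match(subset, colnames(xm)) else subset
  if (anyNA(idx)) stop("unknown feature in subset")
  rcf <- abs(suppressWarnings(stats::cor(xm, y)))
  rcf[is.na(rcf)] <- 0
  rff <- abs(suppressWarnings(stats::cor(xm)))
  rff[is.na(rff)] <- 0
  merit_cached(idx, as.vector(rcf), rff)
}

merit_cached <- function(idx, rcf, rff) {
  k <- length(idx)
  rc <- mean(rcf[idx])
  rf <- if (k > 1) {
    sub <- rff[idx, idx]
    (sum(sub) - k) / (k * (k - 1))
  } else 0
  k * rc / sqrt(k + k * (k - 1) * rf)
}

#' Best-first forward subset search under the CFS merit
#'
#' Greedy best-first search starting from the empty set: the open list holds
#' candidate subsets ranked by merit; the best node is expanded by adding
#' each unused feature; the search stops after `max_stale` consecutive
#' expansions that fail to improve the best merit found.  Deterministic, with
#' lexicographic tie-breaking on feature names.
#'
#' @param x data.frame or matrix of features (named columns).
#' @param y numeric target.
#' @param max_stale non-improving expansions tolerated (default 5).
#' @return list with `selected` (feature names, lexicographic order),
#'   `merit`, `merit_trace` (best merit after each expansion).
#' @export
best_first_select <- function(x, y, max_stale = 5) {
  xm <- as.matrix(x)
  if (ncol(xm) < 1) stop("need at least one feature")
  # order features lexicographically so expansion order (and hence
  # tie-breaking among equal-merit subsets) is name-determined
  ord <- order(colnames(xm))
  xm <- xm[, ord, drop = FALSE]
  nf <- ncol(xm)
  rcf <- abs(suppressWarnings(stats::cor(xm, y)))
  rcf[is.na(rcf)] <- 0
  rcf <- as.vector(rcf)
  rff <- abs(suppressWarnings(stats::cor(xm)))
  rff[is.na(rff)] <- 0
  visited <- new.env(hash = TRUE, parent = emptyenv())
  open_sets <- list(integer(0))
  open_merit <- 0
  best_set <- integer(0); best_merit <- 0
  trace <- numeric(0)
  stale <- 0
  while (length(open_sets) > 0 && stale < max_stale) {
    b <- which.max(open_merit)   # first max -> lexicographically earliest
    node <- open_sets[[b]]
    open_sets <- open_sets[-b]; open_merit <- open_merit[-b]
    improved <- FALSE
    for (f in seq_len(nf)) {
      if (f %in% node) next
      child <- sort(c(node, f))
      key <- paste(child, collapse = ",")
      if (exists(key, envir = visited, inherits = FALSE)) next
      assign(key, TRUE, envir = visited)
      m <- merit_cached(child, rcf, rff)
      open_sets[[length(open_sets) + 1L]] <- child
      open_merit <- c(open_merit, m)
      if (m > best_merit + 1e-12) {
        best_merit <- m; best_set <- child; improved <- TRUE
      }
    }
    stale <- if (improved) 0 else stale + 1
    trace <- c(trace, best_merit)
  }
  list(selected = colnames(xm)[best_set], merit = best_merit,
       merit_trace = trace)
}

#' Consensus feature selection inside nested cross-validation
#'
#' Runs [best_first_select()] on the inner-training rows of each (outer,
#' inner) fold pair — `n_outer * n_inner` runs, 50 by default — pools the
#' selected subsets, and retains the features appearing in at least
#' `threshold` of the pooled subsets (and at least once).
#'
#' @param x data.frame or matrix of features.
#' @param y numeric target.
#' @param plan a [make_cv_plan()].
#' @param threshold consensus proportion (0.5 for the main pipeline, 0.1 for
#'   the degradation variant).
#' @param max_stale forwarded to [best_first_select()].
#' @return Object of class `selection_result`: `subsets` (list of feature-name
#'   vectors), `frequency` (named selection counts / number of subsets),
#'   `consensus` (feature names), `threshold`.
#' @export
nested_cv_select <- function(x, y, plan, threshold = 0.5, max_stale = 5) {
  stopifnot(inherits(plan, "cv_plan"))
  xm <- as.matrix(x)
  subsets <- list()
  for (k in seq_len(plan$n_outer)) {
    inn <- plan$inner[[k]]
    for (j in seq_len(plan$n_inner)) {
      rows <- which(!is.na(inn) & inn != j)
      if (length(rows) < 3)
        stop(structure(class = c("mammoiq_plan_error", "error", "condition"),
                       list(message = "inner-training fold too small for correlation",
                            call = sys.call())))
      subsets[[length(subsets) + 1L]] <-
        best_first_select(xm[rows, , drop = FALSE], y[rows],
                          max_stale = max_stale)$selected
    }
  }
  counts <- table(unlist(subsets))
  freq <- structure(rep(0, ncol(xm)), names = colnames(xm))
  freq[names(counts)] <- as.vector(counts) / length(subsets)
  consensus <- names(freq)[freq >= threshold & freq > 0]
  structure(list(subsets = subsets, frequency = freq, consensus = consensus,
                 threshold = threshold, n_subsets = length(subsets)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d inner subsets, threshold %.2f -> %d consensus features\n",
              x$n_subsets, x$threshold, length(x$consensus)))
  if (length(x$consensus))
    cat("  ", paste(utils::head(x$consensus, 8), collapse = ", "),
        if (length(x$consensus) > 8) "..." else "", "\n")
  invisible(x)
}
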