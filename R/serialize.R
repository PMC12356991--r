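#' Persist an ROI set
#'
#' Writes one archive per image: `<prefix>.npy` holding the flattened patches
#' as columns (`roi_side^2 x n`, float64) and `<prefix>.csv` with the index
#' `source_id, center_row, center_col, label`.
#'
#' @param roiset a [build_roi_set()] result.
#' @param prefix output path prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
write_roi_set <- function(roiset, prefix) {
  stopifnot(inherits(roiset, "roi_set"))
  P <- vapply(roiset$rois, function(r) as.vector(r$patch),
              numeric(roiset$roi_side^2))
  write_npy(P, paste0(prefix, ".npy"))
  idx <- data.frame(
    source_id = vapply(roiset$rois, `[[`, character(1), "source_id"),
    center_row = vapply(roiset$rois, function(r) r$center[1], numeric(1)),
    center_col = vapply(roiset$rois, function(r) r$center[2], numeric(1)),
    label = vapply(roiset$rois, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
  utils::write.csv(idx, paste0(prefix, ".csv"), row.names = FALSE)
  invisible(prefix)
}

#' Load an ROI set written by [write_roi_set()]
#'
#' @param prefix path prefix used at write time.
#' @return a `roi_set`.
#' @export
read_roi_set <- function(prefix) {
  P <- read_npy(paste0(prefix, ".npy"))
  idx <- utils::read.csv(paste0(prefix, ".csv"), stringsAsFactors = FALSE)
  side <- as.integer(sqrt(nrow(P)))
  stopifnot(side^2 == nrow(P), nrow(idx) == ncol(P))
  rois <- lapply(seq_len(ncol(P)), function(k)
    list(patch = matrix(P[, k], side, side), label = idx$label[k],
         center = c(idx$center_row[k], idx$center_col[k]),
         source_id = idx$source_id[k]))
  structure(list(rois = rois,
                 n_present = sum(idx$label == "signal_present"),
                 n_absent = sum(idx$label == "signal_absent"),
                 roi_side = side, source_id = idx$source_id[1]),
            class = "roi_set")
}

#' Persist a trained observer template
#'
#' JSON/NPY hybrid: `<prefix>.json` holds the class statistics, Hotelling
#' weights, internal-noise configuration and channel metadata; the channel
#' basis goes to `<prefix>_basis.npy`.
#'
#' @param template a [cho_train()] template.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_cho_template <- function(template, prefix) {
  stopifnot(inherits(template, "cho_template"))
  meta <- list(mean_present = template$mean_present,
               mean_absent = template$mean_absent,
               pooled_cov = as.vector(template$pooled_cov),
               weights = template$weights,
               internal_sigma = template$internal_sigma,
               s0 = template$s0,
               n_absent = template$n_absent,
               n_present = template$n_present,
               channels = list(n_channels = template$channels$n_channels,
                               width = template$channels$width,
                               roi_side = template$channels$roi_side))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  write_npy(template$channels$basis, paste0(prefix, "_basis.npy"))
  invisible(prefix)
}

#' Load an observer template written by [write_cho_template()]
#'
#' @param prefix path prefix used at write time.
#' @return a `cho_template`.
#' @export
read_cho_template <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  B <- read_npy(paste0(prefix, "_basis.npy"))
  n <- meta$channels$n_channels
  G <- B %*% t(B)
  channels <- structure(list(basis = B, n_channels = as.integer(n),
                             width = meta$channels$width,
                             roi_side = as.integer(meta$channels$roi_side),
                             gram_offdiag = max(abs(G - diag(n)))),
                        class = "channel_set")
  structure(list(channels = channels,
                 mean_present = meta$mean_present,
                 mean_absent = meta$mean_absent,
                 pooled_cov = matrix(meta$pooled_cov, n, n),
                 weights = meta$weights,
                 internal_sigma = meta$internal_sigma,
                 s0 = meta$s0,
                 n_absent = meta$n_absent, n_present = meta$n_present),
            class = "cho_template")
}
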