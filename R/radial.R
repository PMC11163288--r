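#' Radial intensity profile around condensates
#'
#' For each condensate (center, radius `R`), pixel intensities are binned by
#' normalized radius `r/R`; per-condensate profiles (normalized to their own
#' maximum by default) are then averaged with a standard error across
#' condensates. Interface accumulation of aggregate signal shows as a peak
#' in the bin containing `r/R = 1`.
#'
#' @param image `(y, x)` intensity matrix (typically the aggregate channel).
#' @param condensates data.frame with `y_um`, `x_um`, `radius_um` (> 0).
#' @param roi optional [cell_roi()] / logical matrix; pixels outside it are
#'   excluded, and condensates centered outside it are skipped with a
#'   warning.
#' @param pixel_size_um micrometres per pixel.
#' @param r_max_rel outer edge of the profile in units of `R` (>= 1,
#'   default 2).
#' @param bin_width bin width in `r/R` (default 0.1).
#' @param normalize `"per_condensate"` (each profile divided by its own
#'   maximum before averaging) or `"global"` (raw intensities).
#' @return object of class `radial_profile`: data.frame with `r_rel` (bin
#'   centers), `mean`, `se`, plus attributes `n_condensates`, `bin_width`.
#' @export
radial_profile <- function(image, condensates, roi = NULL, pixel_size_um,
                           r_max_rel = 2, bin_width = 0.1,
                           normalize = c("per_condensate", "global")) {
  normalize <- match.arg(normalize)
  stopifnot(is.matrix(image), is.data.frame(condensates),
            all(c("y_um", "x_um", "radius_um") %in% names(condensates)),
            all(condensates$radius_um > 0), r_max_rel >= 1, bin_width > 0,
            pixel_size_um > 0)
  if (!is.null(roi) && inherits(roi, "cell_roi")) roi <- roi$mask
  d <- dim(image)
  yy <- (matrix(seq_len(d[1L]), d[1L], d[2L]) - 0.5) * pixel_size_um
  xx <- (matrix(seq_len(d[2L]), d[1L], d[2L], byrow = TRUE) - 0.5) * pixel_size_um
  edges <- seq(0, r_max_rel, by = bin_width)
  centers <- edges[-1L] - bin_width / 2
  profiles <- matrix(NA_real_, length(centers), nrow(condensates))
  kept <- 0L
  for (i in seq_len(nrow(condensates))) {
    cy <- condensates$y_um[i]; cx <- condensates$x_um[i]
    R <- condensates$radius_um[i]
    if (!is.null(roi)) {
      iy <- min(max(1L, round(cy / pixel_size_um + 0.5)), d[1L])
      ix <- min(max(1L, round(cx / pixel_size_um + 0.5)), d[2L])
      if (!roi[iy, ix]) {
        warning("condensate ", i, " centered outside the ROI; skipped")
        next
      }
    }
    r_rel <- sqrt((yy - cy)^2 + (xx - cx)^2) / R
    sel <- r_rel < r_max_rel
    if (!is.null(roi)) sel <- sel & roi
    bin <- findInterval(r_rel[sel], edges, rightmost.closed = TRUE)
    prof <- vapply(seq_along(centers), function(b) {
      v <- image[sel][bin == b]
      if (length(v)) mean(v) else NA_real_
    }, 0)
    if (normalize == "per_condensate") {
      mx <- max(prof, na.rm = TRUE)
      if (mx > 0) prof <- prof / mx
    }
    kept <- kept + 1L
    profiles[, kept] <- prof
  }
  if (kept == 0L) stop("no usable condensates")
  profiles <- profiles[, seq_len(kept), drop = FALSE]
  out <- data.frame(
    r_rel = centers,
    mean = rowMeans(profiles, na.rm = TRUE),
    se = apply(profiles, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
    }))
  structure(out, n_condensates = kept, bin_width = bin_width,
            class = c("radial_profile", "data.frame"))
}

#' Locate the peak bin of a radial profile
#'
#' @param profile a [radial_profile()].
#' @return the `r_rel` bin center with the maximum mean intensity.
#' @export
profile_peak <- function(profile) {
  profile$r_rel[which.max(profile$mean)]
}
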