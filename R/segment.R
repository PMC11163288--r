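#' Select the reference frame for thresholding
#'
#' The intensity threshold is estimated once, on the frame with the maximum
#' mean cytoplasmic brightness, and then applied to all relevant frames. For
#' multi-section stacks the per-frame mean is taken over all sections within
#' the ROI. Ties break to the earliest frame.
#'
#' @param stack an [image_stack()].
#' @param roi a [cell_roi()].
#' @param channel channel name or index.
#' @return 1-based frame index.
#' @export
select_reference_frame <- function(stack, roi, channel) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "cell_roi"))
  if (!any(roi$mask)) stop("ROI mask is empty")
  ci <- resolve_channel(stack, channel)
  means <- vapply(seq_len(n_frames(stack)), function(t) {
    vol <- stack$data[t, , ci, , , drop = FALSE]
    nz <- dim(stack$data)[2L]
    mean(vapply(seq_len(nz), function(z) {
      fr <- matrix(vol[1L, z, 1L, , ], dim(stack$data)[4L], dim(stack$data)[5L])
      mean(fr[roi$mask])
    }, 0))
  }, 0)
  which.max(means)  # which.max returns the first maximum: earliest-frame tie-break
}

#' Auto-select a clean cytoplasmic background region
#'
#' Reproducible proxy for manually picking "a region within the cytoplasm
#' lacking dense condensates or aggregates": the ROI is tiled into square
#' tiles of `tile_um` micrometres on a side; among tiles lying entirely
#' inside the ROI whose 99th intensity percentile is below the ROI median
#' plus one ROI standard deviation (i.e. tiles without bright objects), the
#' tile with the lowest mean is chosen. If no tile qualifies, the lowest-mean
#' tile is used as a fallback.
#'
#' @param frame `(y, x)` intensity matrix.
#' @param roi a [cell_roi()] congruent with `frame`.
#' @param pixel_size_um micrometres per pixel.
#' @param tile_um tile edge length in micrometres (default 2).
#' @return logical matrix marking the selected region.
#' @export
select_background_region <- function(frame, roi, pixel_size_um, tile_um = 2) {
  stopifnot(is.matrix(frame), inherits(roi, "cell_roi"),
            all(dim(frame) == dim(roi$mask)), pixel_size_um > 0, tile_um > 0)
  n <- max(2L, round(tile_um / pixel_size_um))
  vals <- frame[roi$mask]
  gate <- median(vals) + sd(vals)

  ys <- seq(1L, nrow(frame) - n + 1L, by = n)
  xs <- seq(1L, ncol(frame) - n + 1L, by = n)
  best <- NULL; best_mean <- Inf
  fallback <- NULL; fallback_mean <- Inf
  for (y0 in ys) for (x0 in xs) {
    yy <- y0:(y0 + n - 1L); xx <- x0:(x0 + n - 1L)
    if (!all(roi$mask[yy, xx])) next
    tile <- frame[yy, xx]
    m <- mean(tile)
    if (m < fallback_mean) {
      fallback_mean <- m
      fallback <- c(y0, x0)
    }
    if (quantile(tile, 0.99, names = FALSE) < gate && m < best_mean) {
      best_mean <- m
      best <- c(y0, x0)
    }
  }
  if (is.null(best)) best <- fallback
  if (is.null(best)) stop("ROI too small to hold one ", tile_um, " um tile")
  out <- matrix(FALSE, nrow(frame), ncol(frame))
  out[best[1L]:(best[1L] + n - 1L), best[2L]:(best[2L] + n - 1L)] <- TRUE
  out
}

#' Estimate cytoplasmic background mean and SD
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' intensities inside a background region.
#'
#' @param frame `(y, x)` intensity matrix.
#' @param region logical matrix or a [cell_roi()]; must contain >= 2 pixels.
#' @return named list with `mean` and `sd`.
#' @export
estimate_background <- function(frame, region) {
  if (inherits(region, "cell_roi")) region <- region$mask
  stopifnot(is.matrix(frame), is.logical(region) || all(region %in% c(0, 1)),
            all(dim(frame) == dim(region)))
  vals <- frame[region != 0]
  if (length(vals) < 2L) {
    stop("background region must contain at least 2 pixels (SD undefined)")
  }
  list(mean = mean(vals), sd = sd(vals))
}

#' Intensity threshold: background mean plus k standard deviations
#'
#' @param mean background mean intensity.
#' @param sd background standard deviation (>= 0).
#' @param k SD multiplier; the standard value is 2.5.
#' @return the threshold `mean + k * sd`.
#' @export
compute_threshold <- function(mean, sd, k = 2.5) {
  stopifnot(sd >= 0)
  mean + k * sd
}

#' Threshold-and-label segmentation of a 2D frame
#'
#' Binary mask `intensity > threshold` (strict) restricted to the ROI,
#' 8-connectivity connected components, components smaller than
#' `min_area_px` pixels removed, remaining labels contiguous from 1.
#'
#' @param frame `(y, x)` intensity matrix.
#' @param roi a [cell_roi()] or logical matrix; `NULL` for the whole frame.
#' @param threshold finite intensity threshold.
#' @param min_area_px minimum component size in pixels (default 16).
#' @return object of class `labeled_objects`: list with `labels` (integer
#'   matrix), `n_objects`, and the applied `min_size`.
#' @export
segment_2d <- function(frame, roi = NULL, threshold, min_area_px = 16L) {
  stopifnot(is.matrix(frame), is.finite(threshold), min_area_px >= 1L)
  mask <- frame > threshold
  if (!is.null(roi)) {
    if (inherits(roi, "cell_roi")) roi <- roi$mask
    stopifnot(all(dim(roi) == dim(frame)))
    mask <- mask & (roi != 0)
  }
  labels <- filter_and_relabel(label_components(mask), min_area_px)
  structure(list(labels = labels, n_objects = max(labels),
                 min_size = as.integer(min_area_px), dim = "2d"),
            class = "labeled_objects")
}

#' Threshold-and-label segmentation of a 3D volume
#'
#' As [segment_2d()] with 26-connectivity and a voxel-count filter. The ROI
#' mask (one `(y, x)` raster) is applied to every section.
#'
#' @param volume `(z, y, x)` intensity array with >= 2 sections.
#' @param roi a [cell_roi()] or logical `(y, x)` matrix; `NULL` for all.
#' @param threshold finite intensity threshold.
#' @param min_vox minimum component size in voxels (default 64).
#' @return a `labeled_objects` (3-D `labels`).
#' @export
segment_3d <- function(volume, roi = NULL, threshold, min_vox = 64L) {
  d <- dim(volume)
  if (length(d) != 3L) stop("`volume` must be a (z, y, x) array")
  if (d[1L] < 2L) {
    stop("single-section input: use segment_2d() for 2D frames")
  }
  stopifnot(is.finite(threshold), min_vox >= 1L)
  mask <- volume > threshold
  if (!is.null(roi)) {
    if (inherits(roi, "cell_roi")) roi <- roi$mask
    stopifnot(all(dim(roi) == d[2:3]))
    mask <- mask & aperm(array(roi != 0, dim = c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  }
  labels <- filter_and_relabel(label_components(mask), min_vox)
  structure(list(labels = labels, n_objects = max(labels),
                 min_size = as.integer(min_vox), dim = "3d"),
            class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("<labeled_objects> %s, %d object(s), min size %d\n",
              x$dim, x$n_objects, x$min_size))
  invisible(x)
}

#' Full segmentation of one stack frame with automatic background
#'
#' Convenience wrapper for the standard per-cell procedure: pick the
#' reference frame, auto-select a background region on it, compute the
#' `mean + k SD` threshold there, then segment the requested frame(s) with
#' that single threshold.
#'
#' @param stack an [image_stack()].
#' @param roi a [cell_roi()].
#' @param channel channel name or index to segment.
#' @param frames frame indices to segment (default: all).
#' @param config a [pipeline_config()].
#' @return list with `threshold`, `background` (mean/sd), `reference_frame`,
#'   and `objects`: a data.frame of measured objects over all requested
#'   frames (with a `frame` column).
#' @export
segment_stack <- function(stack, roi, channel, frames = seq_len(n_frames(stack)),
                          config = pipeline_config()) {
  ref <- select_reference_frame(stack, roi, channel)
  ref_frame <- get_frame(stack, ref, channel)
  bg_region <- select_background_region(ref_frame, roi, stack$pixel_size_um)
  bg <- estimate_background(ref_frame, bg_region)
  thr <- compute_threshold(bg$mean, bg$sd, config$threshold_k)
  per_frame <- lapply(frames, function(t) {
    seg <- segment_2d(get_frame(stack, t, channel), roi, thr, config$min_area_px)
    if (seg$n_objects == 0L) return(NULL)
    imgs <- setNames(lapply(stack$channel_names, function(ch) get_frame(stack, t, ch)),
                     stack$channel_names)
    rec <- measure_objects(seg, pixel_size_um = stack$pixel_size_um,
                           intensity = imgs)
    cbind(frame = t, rec)
  })
  objects <- do.call(rbind, per_frame)
  if (is.null(objects)) {
    objects <- data.frame(frame = integer(), object_id = integer())
  }
  list(threshold = thr, background = bg, reference_frame = ref,
       objects = objects)
}
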