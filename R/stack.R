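#' Calibrated multi-channel image stack
#'
#' The central data container: a 5-D intensity array indexed
#' `(t, z, c, y, x)` together with its physical geometry (pixel size, z-step),
#' channel labels, frame interval, and the blue-light activation schedule.
#' Intensities are nonnegative floats in arbitrary detector units; the data
#' model is agnostic to bit depth.
#'
#' The light schedule is a list of `c(on, off)` frame pairs (1-based,
#' inclusive): frames `on..off` are light-on. Intervals must be disjoint,
#' sorted, and within `1..T`.
#'
#' @param data numeric array. Either a full 5-D `(t, z, c, y, x)` array, or a
#'   4-D `(t, c, y, x)` array (interpreted as single-section 2D), or a 2-D
#'   `(y, x)` matrix (one frame, one channel).
#' @param pixel_size_um micrometres per pixel edge (> 0).
#' @param z_step_um micrometres per optical section (> 0); `NULL` for pure 2D.
#' @param channel_names character vector of channel labels.
#' @param frame_interval_s seconds between frames (> 0).
#' @param light_schedule list of `c(on, off)` 1-based inclusive frame pairs.
#' @return an object of class `image_stack`.
#' @seealso [read_stack()], [write_stack()], [get_frame()]
#' @export
image_stack <- function(data, pixel_size_um, z_step_um = NULL,
                        channel_names = NULL, frame_interval_s = 1,
                        light_schedule = list()) {
  if (is.matrix(data)) {
    data <- array(data, dim = c(1L, 1L, 1L, nrow(data), ncol(data)))
  } else if (length(dim(data)) == 4L) {
    d <- dim(data)
    data <- array(aperm(array(data, c(d, 1L)), c(1L, 5L, 2L, 3L, 4L)),
                  dim = c(d[1L], 1L, d[2L], d[3L], d[4L]))
  }
  if (length(dim(data)) != 5L) {
    stop("`data` must be (t, z, c, y, x), (t, c, y, x) or (y, x)")
  }
  if (any(data < 0)) stop("intensities must be nonnegative")
  stopifnot(is.numeric(pixel_size_um), pixel_size_um > 0,
            is.numeric(frame_interval_s), frame_interval_s > 0)
  if (!is.null(z_step_um)) stopifnot(z_step_um > 0)
  if (dim(data)[2L] > 1L && is.null(z_step_um)) {
    stop("multi-section data requires `z_step_um`")
  }
  nc <- dim(data)[3L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) {
    stop("length(channel_names) must equal the channel dimension")
  }
  validate_light_schedule(light_schedule, dim(data)[1L])
  structure(
    list(data = data, pixel_size_um = pixel_size_um, z_step_um = z_step_um,
         channel_names = as.character(channel_names),
         frame_interval_s = frame_interval_s,
         light_schedule = light_schedule),
    class = "image_stack")
}

validate_light_schedule <- function(schedule, n_frames) {
  if (!is.list(schedule)) stop("light_schedule must be a list of c(on, off)")
  if (!length(schedule)) return(invisible(TRUE))
  iv <- do.call(rbind, lapply(schedule, function(x) {
    if (length(x) != 2L) stop("each light interval is c(on, off)")
    as.numeric(x)
  }))
  if (any(iv[, 1L] > iv[, 2L])) stop("light intervals need on <= off")
  if (any(iv[, 1L] < 1L) || any(iv[, 2L] > n_frames)) {
    stop("light intervals must lie within 1..", n_frames)
  }
  if (nrow(iv) > 1L) {
    if (is.unsorted(iv[, 1L], strictly = TRUE)) {
      stop("light intervals must be sorted")
    }
    if (any(iv[-1L, 1L] <= iv[-nrow(iv), 2L])) {
      stop("light intervals must be disjoint")
    }
  }
  invisible(TRUE)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d frame(s) x %d section(s) x %d channel(s), %d x %d px\n",
              d[1L], d[2L], d[3L], d[4L], d[5L]))
  cat(sprintf("  pixel %.4g um%s, frame interval %.4g s, channels: %s\n",
              x$pixel_size_um,
              if (!is.null(x$z_step_um)) sprintf(", z-step %.4g um", x$z_step_um) else "",
              x$frame_interval_s, paste(x$channel_names, collapse = ", ")))
  if (length(x$light_schedule)) {
    cat("  light-on:", paste(vapply(x$light_schedule, function(iv)
      sprintf("[%d,%d]", iv[1L], iv[2L]), ""), collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of frames / channels of an image stack
#' @param stack an [image_stack()].
#' @return integer scalar.
#' @export
n_frames <- function(stack) dim(stack$data)[1L]

#' @rdname n_frames
#' @export
n_channels <- function(stack) dim(stack$data)[3L]

#' Extract a single 2D frame or a z-volume from a stack
#'
#' @param stack an [image_stack()].
#' @param t frame index (1-based).
#' @param channel channel name or index.
#' @param z section index (1-based), defaults to 1.
#' @return `get_frame()`: a `(y, x)` matrix; `get_volume()`: a `(z, y, x)` array.
#' @export
get_frame <- function(stack, t, channel, z = 1L) {
  ci <- resolve_channel(stack, channel)
  stopifnot(t >= 1L, t <= n_frames(stack))
  stack$data[t, z, ci, , , drop = TRUE][, , drop = TRUE]
}

#' @rdname get_frame
#' @export
get_volume <- function(stack, t, channel) {
  ci <- resolve_channel(stack, channel)
  array(stack$data[t, , ci, , ], dim = dim(stack$data)[c(2L, 4L, 5L)])
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    ci <- match(channel, stack$channel_names)
    if (is.na(ci)) {
      stop("unknown channel '", channel, "'; have: ",
           paste(stack$channel_names, collapse = ", "))
    }
    ci
  } else {
    stopifnot(channel >= 1L, channel <= n_channels(stack))
    as.integer(channel)
  }
}

#' Cell region of interest
#'
#' One cell's boolean mask, congruent with a single `(y, x)` frame. Replaces
#' the hand-cropping step of interactive analysis with an explicit object.
#'
#' @param cell_id character label for the cell.
#' @param mask logical matrix, `TRUE` inside the cell; must be non-empty.
#' @param provenance one of `"manual"`, `"synthetic_truth"`, `"auto"`.
#' @return an object of class `cell_roi`.
#' @export
cell_roi <- function(cell_id, mask, provenance = c("manual", "synthetic_truth", "auto")) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  if (!any(mask)) stop("ROI mask is empty")
  structure(list(cell_id = as.character(cell_id), mask = mask,
                 provenance = provenance),
            class = "cell_roi")
}

#' @export
print.cell_roi <- function(x, ...) {
  cat(sprintf("<cell_roi> '%s' (%s): %d px of %d x %d\n", x$cell_id,
              x$provenance, sum(x$mask), nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Fluorescence-to-concentration calibration factors
#'
#' Per-channel linear conversion between detector intensity and protein
#' concentration, as obtained from fluorescence correlation spectroscopy
#' (FCS): `concentration_uM = (I - offset) / slope`.
#'
#' @param slope named numeric vector, intensity units per micromolar (> 0).
#' @param offset named numeric vector, intensity units (>= 0); defaults to 0
#'   for every channel in `slope`.
#' @return an object of class `calibration_factors`.
#' @export
calibration_factors <- function(slope, offset = NULL) {
  stopifnot(is.numeric(slope), !is.null(names(slope)), all(slope > 0))
  if (is.null(offset)) offset <- setNames(rep(0, length(slope)), names(slope))
  stopifnot(all(names(slope) %in% names(offset)) || all(offset >= 0))
  offset <- offset[names(slope)]
  offset[is.na(offset)] <- 0
  names(offset) <- names(slope)
  stopifnot(all(offset >= 0))
  structure(list(slope = slope, offset = offset), class = "calibration_factors")
}

#' Pipeline configuration constants
#'
#' Bundles the analysis constants used throughout the pipeline. Defaults are
#' the standard values: threshold multiplier `k = 2.5` (background mean plus
#' 2.5 SD), minimum object size 16 pixels (2D) / 64 voxels (3D), the 5 um^2
#' small-aggregate and 10 um^2 large-aggregate cutoffs, droplet circularity
#' minimum 0.8, and condensation SD-ratio minimum 1.5.
#'
#' @param threshold_k SD multiplier for the intensity threshold.
#' @param min_area_px minimum 2D object size in pixels.
#' @param min_vox minimum 3D object size in voxels.
#' @param small_agg_cutoff_um2 upper area bound of "small" aggregates (um^2).
#' @param large_agg_cutoff_um2 lower area bound of "large" aggregates (um^2).
#' @param circularity_min minimum circularity for droplet classification.
#' @param sd_ratio_min minimum coefficient-of-variation ratio for calling
#'   condensation.
#' @param rng_seed optional integer seed recorded with the configuration.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold_k = 2.5, min_area_px = 16L, min_vox = 64L,
                            small_agg_cutoff_um2 = 5.0,
                            large_agg_cutoff_um2 = 10.0,
                            circularity_min = 0.8, sd_ratio_min = 1.5,
                            rng_seed = NULL) {
  cfg <- list(threshold_k = threshold_k, min_area_px = as.integer(min_area_px),
              min_vox = as.integer(min_vox),
              small_agg_cutoff_um2 = small_agg_cutoff_um2,
              large_agg_cutoff_um2 = large_agg_cutoff_um2,
              circularity_min = circularity_min, sd_ratio_min = sd_ratio_min,
              rng_seed = rng_seed)
  num <- cfg[setdiff(names(cfg), "rng_seed")]
  if (any(vapply(num, function(v) !is.numeric(v) || v <= 0, TRUE))) {
    stop("all pipeline_config thresholds must be positive numbers")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys present in the file override the defaults of [pipeline_config()];
#' unknown keys are an error.
#'
#' @param path YAML file path.
#' @param ... further overrides applied after the file (e.g. from a command
#'   line), highest precedence.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}
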