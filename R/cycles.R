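#' Coarsening statistics across condensation/dissolution cycles
#'
#' Segments the aggregate channel at the first frame of each condensation
#' (light-on) interval — the point where the previous cycle's dissolution
#' and merging are complete — and reports the mean area of small aggregates
#' (area below `config$small_agg_cutoff_um2`) per cycle. Interface-mediated
#' coarsening shows as a non-decreasing sequence of means.
#'
#' The intensity threshold is estimated once (reference frame + automatic
#' background region + mean plus `k` SD) and applied to every analyzed frame.
#'
#' @param stack an [image_stack()] whose `light_schedule` holds >= 2
#'   condensation intervals.
#' @param roi a [cell_roi()].
#' @param channel aggregate channel name or index (default `"polyQ"`).
#' @param config a [pipeline_config()].
#' @param schedule optionally override the stack's light schedule.
#' @return data.frame with `cycle`, `frame`, `mean_small_area_um2`,
#'   `n_small`, `n_objects`.
#' @export
cycle_coarsening <- function(stack, roi, channel = "polyQ",
                             config = pipeline_config(), schedule = NULL) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "cell_roi"))
  sched <- schedule %||% stack$light_schedule
  if (length(sched) < 2L) stop("need >= 2 condensation intervals")
  starts <- vapply(sched, `[`, 0, 1L)
  if (any(starts > n_frames(stack))) {
    stop("light schedule extends past the end of the stack")
  }
  seg <- segment_stack(stack, roi, channel, frames = starts, config = config)
  out <- lapply(seq_along(starts), function(i) {
    obj <- seg$objects[seg$objects$frame == starts[i], , drop = FALSE]
    small <- obj$area_um2[obj$area_um2 < config$small_agg_cutoff_um2]
    data.frame(cycle = i, frame = starts[i],
               mean_small_area_um2 = if (length(small)) mean(small) else NA_real_,
               n_small = length(small), n_objects = nrow(obj))
  })
  do.call(rbind, out)
}

#' Average per-cycle coarsening across cells
#'
#' @param reports list of [cycle_coarsening()] outputs (>= 2 cells).
#' @return data.frame with `cycle`, `mean_small_area_um2` (cross-cell mean),
#'   `se`, `n_cells`.
#' @export
cycle_report <- function(reports) {
  if (length(reports) < 2L) stop("need >= 2 cells for an SE")
  cycles <- sort(unique(unlist(lapply(reports, function(r) r$cycle))))
  out <- lapply(cycles, function(cy) {
    vals <- vapply(reports, function(r) {
      v <- r$mean_small_area_um2[r$cycle == cy]
      if (length(v)) v else NA_real_
    }, 0)
    vals <- vals[!is.na(vals)]
    data.frame(cycle = cy, mean_small_area_um2 = mean(vals),
               se = sd(vals) / sqrt(length(vals)), n_cells = length(vals))
  })
  do.call(rbind, out)
}
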