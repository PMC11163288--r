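#' Parameters of the synthetic-microscopy generator
#'
#' Defaults describe one cell imaged through repeated blue-light
#' condensation/dissolution cycles: an elliptical cell over Gaussian detector
#' background; small solid aggregates with a broad lognormal size
#' distribution in the "polyQ" channel; light-inducible condensates in the
#' "p62" channel that nucleate at each light-on interval, grow during
#' activation and dissolve exponentially when the light goes off. Aggregates
#' within `capture_dist_um` of a condensate rim adsorb onto it; when a
#' condensate dissolves, its rim aggregates merge into a single aggregate of
#' summed area (intensity conserved), the interface-mediated coarsening
#' mechanism the downstream statistics are designed to detect.
#'
#' The default light schedule mirrors the standard protocol: three
#' condensation/dissolution cycles followed by one final condensation, here
#' 5 light-on and 3 light-off frames per cycle. The default pixel size
#' (0.0851 um) makes the two printed minimum-size filters mutually
#' consistent: 16 px = 0.116 um^2 and, with 0.25 um sections,
#' 64 voxels = 0.116 um^3.
#'
#' @param image_shape `(y, x)` image size in pixels.
#' @param pixel_size_um micrometres per pixel edge.
#' @param z_step_um micrometres per optical section (metadata only; the
#'   generator renders single-section stacks).
#' @param frame_interval_s seconds between frames.
#' @param bg_mean,bg_sd additive Gaussian detector background (bg_sd = 0
#'   gives a noise-free stack).
#' @param cell_axes_frac ellipse semi-axes of the cell as fractions of the
#'   image half-size.
#' @param n_aggregates number of aggregates to place.
#' @param agg_area_meanlog,agg_area_sdlog lognormal parameters of true
#'   aggregate areas (um^2).
#' @param aggregate_intensity per-pixel brightness of aggregates above
#'   background (arbitrary units).
#' @param cytoplasm_level diffuse "p62" channel level inside the cell.
#' @param n_condensates condensates nucleated per light-on interval.
#' @param condensate_r0_um initial condensate radius at nucleation.
#' @param condensate_growth_um growth in radius per light-on frame.
#' @param condensate_dissolve_tau dissolution time constant in frames.
#' @param condensate_intensity per-pixel condensate brightness above the
#'   cytoplasm level.
#' @param capture_dist_um maximum rim distance for aggregate adsorption.
#' @param min_gap_um minimum clearance between rendered object boundaries at
#'   placement; distinct solid aggregates must be resolvable (two touching
#'   solids are a single aggregate).
#' @param max_rim_occupancy maximum aggregates one condensate interface can
#'   hold (default unbounded; no measured value exists).
#' @param merge_on_dissolution merge rim aggregates when their condensate
#'   dissolves?
#' @param adsorption enable interface adsorption at all?
#' @param psf_sigma_um Gaussian point-spread-function width.
#' @param n_cycles number of condensation/dissolution cycle pairs before the
#'   final condensation.
#' @param frames_on,frames_off frames per light-on / light-off interval.
#' @param frap_events list of `list(frame, center_um = c(y, x), radius_um,
#'   depth)` bleach events applied to the "p62" channel.
#' @param seed integer RNG seed; identical parameters and seed give an
#'   identical stack.
#' @return a `sim_params` list.
#' @export
sim_params <- function(image_shape = c(224L, 224L),
                       pixel_size_um = 0.0851,
                       z_step_um = 0.25,
                       frame_interval_s = 60,
                       bg_mean = 200, bg_sd = 20,
                       cell_axes_frac = c(0.84, 0.78),
                       n_aggregates = 25L,
                       agg_area_meanlog = log(0.3), agg_area_sdlog = 0.5,
                       aggregate_intensity = 800,
                       cytoplasm_level = 100,
                       n_condensates = 3L,
                       condensate_r0_um = 0.4,
                       condensate_growth_um = 0.15,
                       condensate_dissolve_tau = 1.0,
                       condensate_intensity = 600,
                       capture_dist_um = 1.5,
                       min_gap_um = 0.8,
                       max_rim_occupancy = Inf,
                       merge_on_dissolution = TRUE,
                       adsorption = TRUE,
                       psf_sigma_um = 0.1,
                       n_cycles = 3L, frames_on = 5L, frames_off = 3L,
                       frap_events = list(),
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$bg_sd >= 0, p$capture_dist_um >= 0, p$pixel_size_um > 0,
            p$agg_area_sdlog >= 0, p$aggregate_intensity > 0,
            p$condensate_r0_um > 0, p$condensate_growth_um >= 0,
            p$condensate_dissolve_tau > 0, p$n_aggregates >= 0,
            p$frames_on >= 1, p$frames_off >= 1, p$n_cycles >= 0)
  structure(p, class = "sim_params")
}

# Light schedule implied by the cycle structure: n_cycles on/off pairs plus a
# final on interval.
sim_schedule <- function(p) {
  sched <- list()
  t <- 1L
  for (i in seq_len(p$n_cycles)) {
    sched[[length(sched) + 1L]] <- c(t, t + p$frames_on - 1L)
    t <- t + p$frames_on + p$frames_off
  }
  sched[[length(sched) + 1L]] <- c(t, t + p$frames_on - 1L)
  sched
}

sim_n_frames <- function(p) {
  p$n_cycles * (p$frames_on + p$frames_off) + p$frames_on
}

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

ellipse_mask <- function(shape, axes_frac) {
  cy <- (shape[1L] + 1) / 2; cx <- (shape[2L] + 1) / 2
  ay <- axes_frac[1L] * shape[1L] / 2; ax <- axes_frac[2L] * shape[2L] / 2
  yy <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  xx <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  ((yy - cy) / ay)^2 + ((xx - cx) / ax)^2 <= 1
}

# Add a disk of total integrated intensity `amplitude * area_px` to `img`.
# The rasterized pixel values are scaled so the disk's sum is exact, making
# total intensity independent of sub-pixel position (and hence conserved
# under repositioning and merging).
add_disk <- function(img, cy_um, cx_um, r_um, amplitude, px) {
  target <- amplitude * pi * r_um^2 / px^2
  d <- dim(img)
  r_px <- r_um / px
  cy <- cy_um / px + 0.5; cx <- cx_um / px + 0.5
  y0 <- max(1L, floor(cy - r_px - 1)); y1 <- min(d[1L], ceiling(cy + r_px + 1))
  x0 <- max(1L, floor(cx - r_px - 1)); x1 <- min(d[2L], ceiling(cx + r_px + 1))
  ys <- y0:y1; xs <- x0:x1
  sub <- outer(ys - cy, xs - cx, function(a, b) a^2 + b^2) <= r_px^2
  n <- sum(sub)
  if (n == 0L) {
    # sub-pixel object: deposit the whole intensity in the nearest pixel
    iy <- min(max(1L, round(cy)), d[1L]); ix <- min(max(1L, round(cx)), d[2L])
    img[iy, ix] <- img[iy, ix] + target
    return(img)
  }
  img[ys, xs][sub] <- img[ys, xs][sub] + target / n
  img
}

# Uniform rejection sampling of points inside the (slightly shrunk) cell.
sample_in_cell <- function(n, shape_um, axes_frac, margin_um, max_rounds = 50L) {
  cy <- shape_um[1L] / 2; cx <- shape_um[2L] / 2
  ay <- axes_frac[1L] * shape_um[1L] / 2 - margin_um
  ax <- axes_frac[2L] * shape_um[2L] / 2 - margin_um
  if (ay <= 0 || ax <= 0) stop("cell too small for requested margin")
  # a cell of ~30 um diameter holds at most a few hundred distinct objects
  capacity <- 400L
  if (n > capacity) {
    stop(sprintf("could not place %d objects in cell mask (placed %d)",
                 n, capacity))
  }
  out <- matrix(NA_real_, 0L, 2L)
  for (round in seq_len(max_rounds)) {
    if (nrow(out) >= n) break
    m <- 2L * (n - nrow(out))
    y <- runif(m, cy - ay, cy + ay); x <- runif(m, cx - ax, cx + ax)
    ok <- ((y - cy) / ay)^2 + ((x - cx) / ax)^2 <= 1
    out <- rbind(out, cbind(y[ok], x[ok]))
  }
  if (nrow(out) < n) {
    stop(sprintf("could not place %d objects in cell mask (placed %d)",
                 n, nrow(out)))
  }
  out[seq_len(n), , drop = FALSE]
}

# Place n disks of given radii with pairwise clearance: center distance at
# least r_i + r_j + min_gap. Distinct solid aggregates must be resolvable —
# two touching solids are one aggregate, and the ground truth counts objects.
sample_separated <- function(radii, shape_um, axes_frac, margin_um,
                             min_gap, max_tries = 4000L) {
  n <- length(radii)
  out <- matrix(NA_real_, n, 2L)
  placed <- 0L
  for (i in seq_len(max_tries)) {
    if (placed >= n) break
    cand <- sample_in_cell(1L, shape_um, axes_frac, margin_um)
    if (placed > 0L) {
      dd <- sqrt((out[seq_len(placed), 1L] - cand[1L])^2 +
                   (out[seq_len(placed), 2L] - cand[2L])^2)
      if (any(dd < radii[seq_len(placed)] + radii[placed + 1L] + min_gap)) next
    }
    placed <- placed + 1L
    out[placed, ] <- cand
  }
  if (placed < n) {
    stop(sprintf("could not place %d objects in cell mask (placed %d)",
                 n, placed))
  }
  out
}

#' Simulate one cell through condensation/dissolution cycles
#'
#' Renders a calibrated two-channel ("p62", "polyQ") time-lapse embodying
#' interface-mediated coarsening, together with the cell ROI and a full
#' ground-truth record. Per frame: condensates nucleate at each light-on
#' interval, grow while the light is on, and shrink exponentially when it is
#' off; unattached aggregates within `capture_dist_um` of a rim are
#' repositioned onto the nearest rim point and subsequently track the rim;
#' when a condensate dissolves (radius below half its nucleation radius),
#' its attached aggregates merge into one aggregate whose area is the sum of
#' the merged areas, placed at their area- (intensity-) weighted centroid.
#' Rendering applies the Gaussian PSF first and additive Gaussian background
#' noise last. Aggregate disks are drawn with exactly conserved integrated
#' intensity, so in a noise-free stack the bulk "polyQ" signal is constant
#' over time by construction.
#'
#' @param params a [sim_params()].
#' @return list with `stack` (an [image_stack()]), `roi` (a [cell_roi()]),
#'   and `truth`: list of `objects` (per-frame object table), `merges`
#'   (merge lineage), and `totals` (per-frame true integrated aggregate
#'   intensity).
#' @export
simulate_cell <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  with_seed(p$seed, {
    shape <- as.integer(p$image_shape)
    px <- p$pixel_size_um
    shape_um <- shape * px
    T <- sim_n_frames(p)
    sched <- sim_schedule(p)
    mask <- ellipse_mask(shape, p$cell_axes_frac)

    # --- initial aggregates -------------------------------------------------
    agg <- data.frame(id = integer(), y = numeric(), x = numeric(),
                      area = numeric(), attached = integer(),
                      angle = numeric())
    if (p$n_aggregates > 0L) {
      areas <- rlnorm(p$n_aggregates, p$agg_area_meanlog, p$agg_area_sdlog)
      pos <- sample_separated(sqrt(areas / pi), shape_um, p$cell_axes_frac,
                              margin_um = 1.5, min_gap = p$min_gap_um)
      agg <- data.frame(id = seq_len(p$n_aggregates), y = pos[, 1L],
                        x = pos[, 2L], area = areas,
                        attached = NA_integer_, angle = NA_real_)
    }
    next_id <- p$n_aggregates + 1L

    cond <- data.frame(id = integer(), y = numeric(), x = numeric(),
                       r = numeric())
    next_cond_id <- 1L

    data <- array(0, dim = c(T, 1L, 2L, shape[1L], shape[2L]))
    objects <- vector("list", T)
    merges <- list()
    totals <- numeric(T)
    sigma_px <- p$psf_sigma_um / px
    bleach_mult <- matrix(1, shape[1L], shape[2L])

    light_on <- function(t) any(vapply(sched, function(iv)
      t >= iv[1L] && t <= iv[2L], TRUE))
    interval_start <- function(t) any(vapply(sched, function(iv)
      t == iv[1L], TRUE))

    for (t in seq_len(T)) {
      # --- condensate dynamics ---------------------------------------------
      if (interval_start(t) && p$n_condensates > 0L) {
        r_max <- p$condensate_r0_um + p$condensate_growth_um * p$frames_on
        ctr <- sample_separated(rep(r_max, p$n_condensates), shape_um,
                                p$cell_axes_frac, margin_um = r_max + 1,
                                min_gap = 2 * p$capture_dist_um)
        cond <- rbind(cond, data.frame(
          id = seq.int(next_cond_id, length.out = p$n_condensates),
          y = ctr[, 1L], x = ctr[, 2L], r = p$condensate_r0_um))
        next_cond_id <- next_cond_id + p$n_condensates
      } else if (light_on(t)) {
        cond$r <- cond$r + p$condensate_growth_um
      } else if (nrow(cond)) {
        cond$r <- cond$r * exp(-1 / p$condensate_dissolve_tau)
        dissolved <- which(cond$r < 0.5 * p$condensate_r0_um)
        for (di in dissolved) {
          cid <- cond$id[di]
          on_rim <- which(!is.na(agg$attached) & agg$attached == cid)
          if (p$merge_on_dissolution && length(on_rim) >= 2L) {
            w <- agg$area[on_rim]
            merged <- data.frame(
              id = next_id,
              y = sum(agg$y[on_rim] * w) / sum(w),
              x = sum(agg$x[on_rim] * w) / sum(w),
              area = sum(w), attached = NA_integer_, angle = NA_real_)
            merges[[length(merges) + 1L]] <- data.frame(
              frame = t, child_id = next_id,
              parent_ids = paste(agg$id[on_rim], collapse = ";"),
              area_um2 = sum(w))
            next_id <- next_id + 1L
            agg <- rbind(agg[-on_rim, , drop = FALSE], merged)
          } else if (length(on_rim)) {
            agg$attached[on_rim] <- NA_integer_
            agg$angle[on_rim] <- NA_real_
          }
        }
        if (length(dissolved)) cond <- cond[-dissolved, , drop = FALSE]
      }

      # --- adsorption onto rims --------------------------------------------
      # interfacial accumulation takes minutes: no capture on the nucleation
      # frame itself, so the first frame of each cycle shows free aggregates
      if (p$adsorption && nrow(cond) && light_on(t) && !interval_start(t) &&
          nrow(agg)) {
        for (i in which(is.na(agg$attached))) {
          dc <- sqrt((cond$y - agg$y[i])^2 + (cond$x - agg$x[i])^2)
          rim_dist <- abs(dc - cond$r)
          j <- which.min(rim_dist)
          occupancy <- sum(!is.na(agg$attached) & agg$attached == cond$id[j])
          if (rim_dist[j] <= p$capture_dist_um &&
              occupancy < p$max_rim_occupancy) {
            agg$attached[i] <- cond$id[j]
            agg$angle[i] <- atan2(agg$y[i] - cond$y[j], agg$x[i] - cond$x[j])
          }
        }
      }
      # attached aggregates sit on the (possibly moving) rim
      att <- which(!is.na(agg$attached))
      for (i in att) {
        j <- match(agg$attached[i], cond$id)
        if (is.na(j)) { agg$attached[i] <- NA_integer_; next }
        agg$y[i] <- cond$y[j] + cond$r[j] * sin(agg$angle[i])
        agg$x[i] <- cond$x[j] + cond$r[j] * cos(agg$angle[i])
      }

      # --- render -----------------------------------------------------------
      p62 <- matrix(0, shape[1L], shape[2L])
      p62[mask] <- p$cytoplasm_level
      for (j in seq_len(nrow(cond))) {
        p62 <- add_disk(p62, cond$y[j], cond$x[j], cond$r[j],
                        p$condensate_intensity, px)
      }
      polyq <- matrix(0, shape[1L], shape[2L])
      for (i in seq_len(nrow(agg))) {
        polyq <- add_disk(polyq, agg$y[i], agg$x[i],
                          sqrt(agg$area[i] / pi), p$aggregate_intensity, px)
      }
      if (sigma_px > 0.05) {
        # FFT-based blur leaves float dust of order -1e-13; clip it
        p62 <- pmax(EBImage::gblur(p62, sigma = sigma_px), 0)
        polyq <- pmax(EBImage::gblur(polyq, sigma = sigma_px), 0)
      }
      for (ev in p$frap_events) {
        if (ev$frame == t) {
          yy <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
          xx <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
          hit <- ((yy - 0.5) * px - ev$center_um[1L])^2 +
            ((xx - 0.5) * px - ev$center_um[2L])^2 <= ev$radius_um^2
          bleach_mult[hit] <- bleach_mult[hit] * (1 - ev$depth)
        }
      }
      p62 <- p62 * bleach_mult
      if (p$bg_mean > 0 || p$bg_sd > 0) {
        p62 <- p62 + p$bg_mean + rnorm(length(p62), 0, p$bg_sd)
        polyq <- polyq + p$bg_mean + rnorm(length(polyq), 0, p$bg_sd)
        p62[p62 < 0] <- 0
        polyq[polyq < 0] <- 0
      }
      data[t, 1L, 1L, , ] <- p62
      data[t, 1L, 2L, , ] <- polyq

      # --- ground truth ------------------------------------------------------
      rows <- list()
      if (nrow(agg)) {
        rows$agg <- data.frame(frame = t, object_id = agg$id,
                               type = "aggregate", y_um = agg$y, x_um = agg$x,
                               area_um2 = agg$area, radius_um = NA_real_,
                               attached_to = agg$attached)
      }
      if (nrow(cond)) {
        rows$cond <- data.frame(frame = t, object_id = cond$id,
                                type = "condensate", y_um = cond$y,
                                x_um = cond$x, area_um2 = NA_real_,
                                radius_um = cond$r, attached_to = NA_integer_)
      }
      objects[[t]] <- do.call(rbind, rows)
      totals[t] <- sum(agg$area) * p$aggregate_intensity / px^2
    }

    stack <- image_stack(data, pixel_size_um = px, z_step_um = NULL,
                         channel_names = c("p62", "polyQ"),
                         frame_interval_s = p$frame_interval_s,
                         light_schedule = sched)
    roi <- cell_roi("sim", mask, "synthetic_truth")
    truth <- list(
      objects = if (length(objects)) do.call(rbind, objects) else NULL,
      merges = if (length(merges)) do.call(rbind, merges) else
        data.frame(frame = integer(), child_id = integer(),
                   parent_ids = character(), area_um2 = numeric()),
      totals = data.frame(frame = seq_len(T), polyq_integrated = totals))
    rownames(truth$objects) <- NULL
    list(stack = stack, roi = roi, truth = truth)
  })
}

#' Simulate a FRAP recovery trace
#'
#' Pre-bleach samples sit at 1; after the bleach the signal follows
#' `F(t) = (1 - d) + d * (1 - f_immobile) * (1 - exp(-k t))`, i.e. a
#' single-exponential recovery of the mobile fraction towards full recovery,
#' plus optional Gaussian noise.
#'
#' @param f_immobile immobile fraction in \[0, 1\].
#' @param k recovery rate per second (>= 0).
#' @param bleach_depth fraction of signal removed by the bleach, in (0, 1\].
#' @param t post-bleach time grid in seconds, starting at 0.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param n_pre number of pre-bleach samples (>= 2).
#' @return a `frap_trace`: list with `time`, `intensity`, `bleach_index`.
#' @export
simulate_frap_trace <- function(f_immobile, k, bleach_depth = 0.8,
                                t = seq(0, 120, by = 1), noise_sd = 0,
                                n_pre = 5L) {
  stopifnot(f_immobile >= 0, f_immobile <= 1, k >= 0,
            bleach_depth > 0, bleach_depth <= 1, n_pre >= 2L)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  dt <- if (length(t) > 1L) t[2L] - t[1L] else 1
  time <- c(seq(-n_pre * dt, -dt, by = dt), t)
  post <- (1 - bleach_depth) +
    bleach_depth * (1 - f_immobile) * (1 - exp(-k * t))
  intensity <- c(rep(1, n_pre), post)
  if (noise_sd > 0) intensity <- intensity + rnorm(length(intensity), 0, noise_sd)
  frap_trace(time, intensity, bleach_index = n_pre + 1L)
}

#' Simulate a titration of cells across the phase diagram
#'
#' Cells are sampled log-uniformly in (core concentration `C`, valence `V`);
#' the true phase boundary is the hyperbola `V * C = K`, with a cell labeled
#' condensed iff `V * C > K`. This is the ground-truth generator for
#' [fit_phase_boundary()] recovery experiments.
#'
#' @param n_cells number of cells (>= 2).
#' @param c_range,v_range positive `(min, max)` ranges of core concentration
#'   (uM) and valence.
#' @param K true boundary constant (> 0).
#' @param condition label attached to every cell.
#' @return data.frame with `cell_id`, `c_core`, `valence`, `condensed`,
#'   `condition`.
#' @export
simulate_titration <- function(n_cells, c_range = c(0.01, 10),
                               v_range = c(0.1, 100), K = 1,
                               condition = "control") {
  if (n_cells < 2L) stop("n_cells must be >= 2")
  stopifnot(all(c_range > 0), all(v_range > 0), K > 0)
  C <- exp(runif(n_cells, log(c_range[1L]), log(c_range[2L])))
  V <- exp(runif(n_cells, log(v_range[1L]), log(v_range[2L])))
  data.frame(cell_id = sprintf("cell%04d", seq_len(n_cells)),
             c_core = C, valence = V, condensed = V * C > K,
             condition = condition)
}

#' Render a minimal pre/post activation stack for condensation classification
#'
#' Two-frame, one-channel stack: frame 1 is the pre-activation cytoplasm;
#' frame 2 shows the end of a light-on interval, either with `n_droplets`
#' bright circular condensates (condensed cell) or unchanged (non-condensing
#' cell). Used for end-to-end tests of [classify_condensation()] and
#' [classify_cellwide()].
#'
#' @param condensed render droplets in frame 2?
#' @param n_droplets droplet count when condensed.
#' @param droplet_r_um droplet radius (um).
#' @param irregular if `TRUE`, render low-circularity (elongated) objects
#'   instead of circular droplets.
#' @param params a [sim_params()] for geometry/noise settings.
#' @return list with `stack` and `roi`.
#' @export
simulate_phase_stack <- function(condensed, n_droplets = 4L,
                                 droplet_r_um = 0.8, irregular = FALSE,
                                 params = sim_params()) {
  p <- params
  with_seed(p$seed, {
    shape <- as.integer(p$image_shape)
    px <- p$pixel_size_um
    mask <- ellipse_mask(shape, p$cell_axes_frac)
    mk_frame <- function(with_droplets) {
      img <- matrix(0, shape[1L], shape[2L])
      img[mask] <- p$cytoplasm_level
      if (with_droplets) {
        # bars may still touch at this spacing; a fused bar stays irregular
        gap <- if (irregular) 2.5 else 1.5
        ctr <- sample_separated(rep(droplet_r_um, n_droplets), shape * px,
                                p$cell_axes_frac,
                                margin_um = droplet_r_um * 4 + 1,
                                min_gap = gap)
        for (i in seq_len(n_droplets)) {
          if (irregular) {
            # a thin bar: same area, circularity far below the droplet gate
            len <- droplet_r_um * 6
            for (s in seq(-len / 2, len / 2, by = px / 2)) {
              img <- add_disk(img, ctr[i, 1L], ctr[i, 2L] + s,
                              droplet_r_um / 3.5, p$condensate_intensity, px)
            }
          } else {
            img <- add_disk(img, ctr[i, 1L], ctr[i, 2L], droplet_r_um,
                            p$condensate_intensity, px)
          }
        }
      }
      sigma_px <- p$psf_sigma_um / px
      if (sigma_px > 0.05) img <- pmax(EBImage::gblur(img, sigma = sigma_px), 0)
      img <- img + p$bg_mean + rnorm(length(img), 0, p$bg_sd)
      img[img < 0] <- 0
      img
    }
    data <- array(0, dim = c(2L, 1L, 1L, shape[1L], shape[2L]))
    data[1L, 1L, 1L, , ] <- mk_frame(FALSE)
    data[2L, 1L, 1L, , ] <- mk_frame(condensed)
    stack <- image_stack(data, pixel_size_um = px,
                         channel_names = "p62",
                         frame_interval_s = p$frame_interval_s,
                         light_schedule = list(c(2L, 2L)))
    list(stack = stack, roi = cell_roi("sim", mask, "synthetic_truth"))
  })
}
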