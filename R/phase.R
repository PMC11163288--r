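#' Convert fluorescence intensity to protein concentration
#'
#' Linear FCS-derived conversion: `uM = (I - offset) / slope` for the given
#' channel.
#'
#' @param I mean intensity (>= channel offset).
#' @param channel channel name present in `calib`.
#' @param calib a [calibration_factors()].
#' @return concentration in micromolar.
#' @export
intensity_to_concentration <- function(I, channel, calib) {
  stopifnot(inherits(calib, "calibration_factors"))
  if (!channel %in% names(calib$slope)) {
    stop("no calibration for channel '", channel, "'")
  }
  if (any(I < calib$offset[[channel]])) {
    stop("intensity below the channel offset")
  }
  (I - calib$offset[[channel]]) / calib$slope[[channel]]
}

#' Pre-activation cytoplasmic intensity
#'
#' Mean per-channel intensity in an automatically selected cytoplasmic patch
#' of about `region_area_um2` (default ~10 um^2), measured on the last frame
#' preceding the first light-on interval (before any condensate nucleates).
#' The patch is chosen with the same clean-region rule as the segmentation
#' background.
#'
#' @param stack an [image_stack()] with a non-empty light schedule whose
#'   first interval does not start at frame 1.
#' @param roi a [cell_roi()].
#' @param region_area_um2 target patch area (um^2).
#' @return named numeric vector of mean intensities, one per channel, with
#'   attributes `frame` and `region` (the patch mask).
#' @export
cytoplasm_intensity <- function(stack, roi, region_area_um2 = 10) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "cell_roi"),
            region_area_um2 > 0)
  if (!length(stack$light_schedule)) stop("stack has no light schedule")
  first_on <- stack$light_schedule[[1L]][1L]
  if (first_on <= 1L) stop("no pre-activation frame before the first light-on")
  t <- first_on - 1L
  frame1 <- get_frame(stack, t, 1L)
  patch <- select_background_region(frame1, roi, stack$pixel_size_um,
                                    tile_um = sqrt(region_area_um2))
  out <- vapply(stack$channel_names, function(ch) {
    mean(get_frame(stack, t, ch)[patch])
  }, 0)
  attr(out, "frame") <- t
  attr(out, "region") <- patch
  out
}

#' Phase-diagram coordinates of one cell
#'
#' `c_core = c_ilid_monomer / 24` (concentration of 24-mer scaffolds from
#' the monomer-calibrated intensity) and `valence = c_sspb / c_core` (the
#' average number of sspB-fused clients per core).
#'
#' @param c_ilid_monomer scaffold monomer concentration (uM, > 0).
#' @param c_sspb client concentration (uM, > 0).
#' @return named list with `c_core` and `valence`.
#' @export
phase_point <- function(c_ilid_monomer, c_sspb) {
  if (any(c_ilid_monomer <= 0) || any(c_sspb <= 0)) {
    stop("concentrations must be positive")
  }
  c_core <- c_ilid_monomer / 24
  list(c_core = c_core, valence = c_sspb / c_core)
}

#' Classify whether a cell condensed during light activation
#'
#' A cell is called condensed when (1) the coefficient of variation
#' (SD / mean) of the ROI intensity at the end of the first activation
#' interval is at least `config$sd_ratio_min` times its pre-activation
#' value — texture appearing where there was none, robust to illumination
#' gain — and (2) at least one detected object at that frame has
#' circularity >= `config$circularity_min` (a droplet, not an irregular
#' aggregate). Both numbers are returned as evidence.
#'
#' @param stack an [image_stack()] with >= 1 light-on interval and at least
#'   one pre-activation frame.
#' @param roi a [cell_roi()].
#' @param channel condensate channel name or index.
#' @param config a [pipeline_config()].
#' @return list with `condensed` (logical), `cv_ratio`, `n_droplets`,
#'   `n_objects`, `frame_pre`, `frame_post`.
#' @export
classify_condensation <- function(stack, roi, channel = "p62",
                                  config = pipeline_config()) {
  ev <- condensation_evidence(stack, roi, channel, config)
  ev$condensed <- ev$cv_ratio >= config$sd_ratio_min && ev$n_droplets >= 1L
  ev[c("condensed", "cv_ratio", "n_droplets", "n_objects",
       "frame_pre", "frame_post")]
}

#' Classify cell-wide response: droplet condensation or not
#'
#' `droplet_condensation` when at least two detected objects with
#' circularity >= `config$circularity_min` appear during activation —
#' multiple de novo spherical condensates; `no_droplet_condensation`
#' otherwise (including p62 recruitment onto irregular aggregates only).
#' Raw droplet counts are attached so either labeling convention can be
#' applied downstream.
#'
#' @inheritParams classify_condensation
#' @return list with `class` (factor of the two labels), `n_droplets`,
#'   `n_objects`, `cv_ratio`.
#' @export
classify_cellwide <- function(stack, roi, channel = "p62",
                              config = pipeline_config()) {
  ev <- condensation_evidence(stack, roi, channel, config)
  cls <- if (ev$n_droplets >= 2L) "droplet_condensation" else
    "no_droplet_condensation"
  list(class = cls, n_droplets = ev$n_droplets, n_objects = ev$n_objects,
       cv_ratio = ev$cv_ratio)
}

condensation_evidence <- function(stack, roi, channel, config) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "cell_roi"))
  if (!length(stack$light_schedule)) stop("stack has no light schedule")
  iv <- stack$light_schedule[[1L]]
  if (iv[1L] <= 1L) stop("no pre-activation frames")
  pre_t <- iv[1L] - 1L
  post_t <- iv[2L]
  pre <- get_frame(stack, pre_t, channel)
  post <- get_frame(stack, post_t, channel)
  cv <- function(fr) {
    v <- fr[roi$mask]
    sd(v) / mean(v)
  }
  cv_ratio <- cv(post) / cv(pre)

  bg_region <- select_background_region(pre, roi, stack$pixel_size_um)
  bg <- estimate_background(pre, bg_region)
  thr <- compute_threshold(bg$mean, bg$sd, config$threshold_k)
  seg <- segment_2d(post, roi, thr, config$min_area_px)
  n_droplets <- 0L
  n_objects <- seg$n_objects
  if (n_objects > 0L) {
    rec <- measure_objects(seg, pixel_size_um = stack$pixel_size_um)
    n_droplets <- sum(rec$circularity >= config$circularity_min)
  }
  list(cv_ratio = cv_ratio, n_droplets = n_droplets, n_objects = n_objects,
       frame_pre = pre_t, frame_post = post_t)
}

#' Fit the phase boundary from classified cells
#'
#' Logistic decision boundary in `(log c_core, log valence)`:
#' `P(condensed) = logit^-1(b0 + b1 log C + b2 log V)`. When the two slopes
#' agree to within 20% the boundary is the hyperbola `V * C = K` and the
#' implied `K_hat = exp(-2 b0 / (b1 + b2))` is reported. Training accuracy
#' at the 0.5 probability cut is included. Complete separation (the
#' well-resolved-binodal case) is expected and handled: glm's
#' fitted-probabilities warnings are suppressed and the boundary ratio,
#' which remains stable, is reported.
#'
#' @param points data.frame with `c_core`, `valence`, `condensed` (>= 10
#'   rows, both classes present).
#' @return object of class `phase_boundary`: list with `coef` (b0, b1, b2),
#'   `K_hat` (or `NA` when the slopes disagree), `accuracy`, `n`,
#'   `slope_agreement`.
#' @export
fit_phase_boundary <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("c_core", "valence", "condensed") %in% names(points)))
  if (nrow(points) < 10L) stop("need >= 10 points")
  y <- as.logical(points$condensed)
  if (length(unique(y)) < 2L) {
    stop("both condensed and non-condensed cells are required")
  }
  df <- data.frame(y = y, lc = log(points$c_core), lv = log(points$valence))
  fit <- suppressWarnings(glm(y ~ lc + lv, family = binomial(), data = df))
  b <- unname(coef(fit))
  pred <- predict(fit, type = "response") >= 0.5
  acc <- mean(pred == y)
  agree <- abs(b[2L] - b[3L]) / max(abs(b[2L]), 1e-12)
  K_hat <- if (agree < 0.2) exp(-2 * b[1L] / (b[2L] + b[3L])) else NA_real_
  structure(list(coef = c(b0 = b[1L], b1 = b[2L], b2 = b[3L]),
                 K_hat = K_hat, accuracy = acc, n = nrow(points),
                 slope_agreement = agree),
            class = "phase_boundary")
}

#' @export
print.phase_boundary <- function(x, ...) {
  cat(sprintf("<phase_boundary> n = %d, accuracy %.3f, K_hat %s\n", x$n,
              x$accuracy,
              if (is.na(x$K_hat)) "NA (slopes disagree)" else
                sprintf("%.4g", x$K_hat)))
  invisible(x)
}

#' Compare phase boundaries between two conditions
#'
#' Fits each condition's boundary, then bootstraps cells within each
#' condition (`B` resamples, seeded by the caller's RNG state) to put a
#' percentile confidence interval on `log(K_b / K_a)`. The boundary is
#' declared shifted when the CI excludes 0. Resamples that lose a class or
#' fail to fit are dropped; if more than 10% of resamples degenerate the
#' comparison is flagged.
#'
#' @param a,b data.frames of classified cells (as for
#'   [fit_phase_boundary()]).
#' @param B number of bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @return list with `K_a`, `K_b`, `log_ratio`, `ci` (length 2), `shifted`,
#'   `degenerate_rate`, `flagged`.
#' @export
compare_boundaries <- function(a, b, B = 1000L, conf = 0.95) {
  fa <- fit_phase_boundary(a)
  fb <- fit_phase_boundary(b)
  boot_logK <- function(pts) {
    idx <- sample.int(nrow(pts), replace = TRUE)
    r <- pts[idx, , drop = FALSE]
    if (length(unique(as.logical(r$condensed))) < 2L) return(NA_real_)
    f <- tryCatch(fit_phase_boundary(r), error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    bb <- f$coef
    # boundary ratio regardless of slope agreement, for resampling stability
    -2 * bb[["b0"]] / (bb[["b1"]] + bb[["b2"]])
  }
  la <- replicate(B, boot_logK(a))
  lb <- replicate(B, boot_logK(b))
  diff <- lb - la
  degenerate <- mean(is.na(diff))
  diff <- diff[!is.na(diff)]
  alpha <- (1 - conf) / 2
  ci <- quantile(diff, c(alpha, 1 - alpha), names = FALSE)
  logK <- function(f) if (!is.na(f$K_hat)) log(f$K_hat) else
    -2 * f$coef[["b0"]] / (f$coef[["b1"]] + f$coef[["b2"]])
  list(K_a = exp(logK(fa)), K_b = exp(logK(fb)),
       log_ratio = logK(fb) - logK(fa), ci = ci,
       shifted = ci[1L] > 0 || ci[2L] < 0,
       degenerate_rate = degenerate, flagged = degenerate > 0.1)
}
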