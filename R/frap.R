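#' FRAP trace container and normalization
#'
#' A FRAP trace holds a strictly increasing time grid (seconds), normalized
#' intensities, and the index of the first post-bleach sample.
#' `normalize_trace()` divides every raw sample by the first pre-bleach
#' value, the standard fractional-recovery normalization.
#'
#' @param time numeric vector of times (s), strictly increasing.
#' @param intensity numeric vector, same length.
#' @param bleach_index 1-based index of the first post-bleach sample.
#' @return a `frap_trace` object.
#' @export
frap_trace <- function(time, intensity, bleach_index) {
  stopifnot(length(time) == length(intensity), bleach_index >= 2L,
            bleach_index <= length(time))
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  structure(list(time = as.numeric(time), intensity = as.numeric(intensity),
                 bleach_index = as.integer(bleach_index)),
            class = "frap_trace")
}

#' @rdname frap_trace
#' @param raw raw intensity vector.
#' @export
normalize_trace <- function(raw, time = seq_along(raw) - 1, bleach_index) {
  if (raw[1L] <= 0) stop("first pre-bleach intensity must be > 0")
  frap_trace(time, raw / raw[1L], bleach_index)
}

#' Fit a single-exponential FRAP recovery
#'
#' Least-squares fit of
#' `F(t) = (1 - d) + d * m * (1 - exp(-k (t - t0)))` to the post-bleach
#' samples, with the bleach depth `d` fixed from the first post-bleach point
#' (`d = 1 - F(t0)`). Returns the mobile fraction `m`, the rate `k`
#' (per second), and the residual RMS. A flat (no-recovery) trace — the
#' solid-aggregate regime — yields `m = 0` with `k` flagged unidentifiable
#' (`NA`).
#'
#' @param trace a [frap_trace()] with >= 2 pre-bleach and >= 5 post-bleach
#'   samples.
#' @return object of class `frap_fit`: list with `mobile_fraction`, `k`,
#'   `bleach_depth`, `rms`, `plateau`, `k_identifiable`.
#' @export
fit_recovery <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  bi <- trace$bleach_index
  if (bi < 3L) stop("need >= 2 pre-bleach samples")
  post <- seq(bi, length(trace$time))
  if (length(post) < 5L) stop("need >= 5 post-bleach samples")
  t <- trace$time[post] - trace$time[bi]
  y <- trace$intensity[post]
  d <- 1 - y[1L]
  if (d <= 0) {
    stop("no bleach detected: first post-bleach value is not below 1")
  }

  # flat-trace guard: recovery amplitude indistinguishable from noise
  amp <- mean(tail(y, max(3L, length(y) %/% 5L))) - y[1L]
  scatter <- sd(diff(y)) / sqrt(2)
  if (!is.finite(scatter)) scatter <- 0
  if (amp <= max(2 * scatter / sqrt(length(y)), 1e-12)) {
    return(new_frap_fit(0, NA_real_, d, sqrt(mean((y - mean(y))^2)), FALSE))
  }

  m0 <- min(max(amp / d, 0.05), 1)
  thalf <- t[which.min(abs((y - y[1L]) - amp / 2))]
  k0 <- if (thalf > 0) log(2) / thalf else 1 / max(t[2L], 1e-6)
  fit <- minpack.lm::nlsLM(
    y ~ (1 - d) + d * m * (1 - exp(-k * t)),
    start = list(m = m0, k = k0),
    lower = c(m = 0, k = 1e-8), upper = c(m = 1.5, k = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- coef(fit)
  rms <- sqrt(mean(residuals(fit)^2))
  new_frap_fit(unname(co["m"]), unname(co["k"]), d, rms, TRUE)
}

new_frap_fit <- function(m, k, d, rms, k_ok) {
  structure(list(mobile_fraction = min(max(m, 0), 1), k = k,
                 bleach_depth = d, rms = rms,
                 plateau = (1 - d) + d * min(max(m, 0), 1),
                 k_identifiable = k_ok),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> mobile fraction %.3f, k %s /s, bleach depth %.3f, RMS %.2g\n",
              x$mobile_fraction,
              if (x$k_identifiable) sprintf("%.4g", x$k) else "unidentifiable",
              x$bleach_depth, x$rms))
  invisible(x)
}

#' Average FRAP traces with a standard error
#'
#' Traces are aligned on the common time grid (bleach at `t = 0`); traces on
#' different grids are linearly interpolated onto the first trace's grid.
#' Returns the pointwise mean and SE across traces.
#'
#' @param traces list of >= 2 [frap_trace()] objects.
#' @return data.frame with `time`, `mean`, `se`, `n`.
#' @export
average_traces <- function(traces) {
  if (length(traces) < 2L) stop("need >= 2 traces")
  stopifnot(all(vapply(traces, inherits, TRUE, "frap_trace")))
  align <- function(tr) tr$time - tr$time[tr$bleach_index]
  grid <- align(traces[[1L]])
  mat <- vapply(traces, function(tr) {
    tt <- align(tr)
    if (min(tt) > max(grid) || max(tt) < min(grid)) {
      stop("trace time supports are disjoint; cannot average")
    }
    approx(tt, tr$intensity, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  data.frame(time = grid, mean = rowMeans(mat),
             se = apply(mat, 1L, sd) / sqrt(ncol(mat)),
             n = ncol(mat))
}
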