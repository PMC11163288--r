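#' Per-cell complementary cumulative size distribution
#'
#' Empirical survival function `P(S >= s)` of one cell's aggregate sizes,
#' evaluated at the sorted unique observed sizes. The value at the smallest
#' observed size is 1 by construction.
#'
#' @param sizes numeric vector of aggregate areas (um^2); must be non-empty.
#' @return data.frame with `size_um2` (ascending) and `survival`.
#' @export
ccdf_per_cell <- function(sizes) {
  if (!length(sizes)) stop("a cell with no aggregates contributes no CCDF")
  stopifnot(is.numeric(sizes), all(is.finite(sizes)))
  s <- sort(unique(sizes))
  surv <- vapply(s, function(x) mean(sizes >= x), 0)
  data.frame(size_um2 = s, survival = surv)
}

#' Average single-cell CCDFs across cells
#'
#' Each cell's empirical survival function is evaluated (as a step function)
#' on the union grid of all observed sizes; the cross-cell pointwise mean and
#' standard error (SD / sqrt(n_cells)) are reported. Averaging is over cells,
#' not over pooled aggregates, so every cell carries equal weight.
#'
#' @param cells list of per-cell size vectors, or of [ccdf_per_cell()]
#'   outputs; at least 2 cells.
#' @return object of class `ccdf_curve`: data.frame with `size_um2`, `mean`,
#'   `se`, and attribute `n_cells`.
#' @export
ccdf_average <- function(cells) {
  if (length(cells) < 2L) stop("need >= 2 cells for an SE")
  sizes_of <- function(x) if (is.data.frame(x)) x$size_um2 else x
  per_cell <- lapply(cells, function(x) {
    s <- sizes_of(x)
    if (is.data.frame(x)) {
      # recover the sample only through its survival steps: evaluate directly
      x
    } else {
      ccdf_per_cell(s)
    }
  })
  grid <- sort(unique(unlist(lapply(per_cell, function(d) d$size_um2))))
  # right-continuous step evaluation of P(S >= s): survival drops just above
  # each observed size, so at grid point g use the survival of the smallest
  # observed size >= g (1 below the support, 0 above it).
  eval_cell <- function(d, g) {
    vapply(g, function(s) {
      i <- which(d$size_um2 >= s)
      if (!length(i)) 0 else if (s <= d$size_um2[1L]) 1 else d$survival[min(i)]
    }, 0)
  }
  mat <- vapply(per_cell, eval_cell, numeric(length(grid)), g = grid)
  mat <- matrix(mat, nrow = length(grid))
  out <- data.frame(size_um2 = grid,
                    mean = rowMeans(mat),
                    se = apply(mat, 1L, sd) / sqrt(ncol(mat)))
  structure(out, n_cells = length(cells), class = c("ccdf_curve", "data.frame"))
}

#' Aggregation propensity versus concentration
#'
#' Fraction of cells showing at least one detected aggregate, binned by
#' cytoplasmic protein concentration. Bins without cells are reported as
#' `NA` (undefined), never as 0.
#'
#' @param cells data.frame with columns `concentration_uM` and
#'   `n_aggregates`.
#' @param breaks ascending bin edges covering the data.
#' @return data.frame with `bin_lo_uM`, `bin_hi_uM`, `fraction`, `n`.
#' @export
aggregation_propensity <- function(cells, breaks) {
  stopifnot(is.data.frame(cells),
            all(c("concentration_uM", "n_aggregates") %in% names(cells)),
            length(breaks) >= 2L, !is.unsorted(breaks, strictly = TRUE))
  if (any(cells$concentration_uM < breaks[1L] |
            cells$concentration_uM > breaks[length(breaks)])) {
    stop("bin edges must cover all concentrations")
  }
  bin <- cut(cells$concentration_uM, breaks, include.lowest = TRUE)
  n <- as.integer(table(bin))
  frac <- vapply(levels(bin), function(b) {
    i <- bin == b
    if (!any(i)) NA_real_ else mean(cells$n_aggregates[i] >= 1L)
  }, 0)
  data.frame(bin_lo_uM = breaks[-length(breaks)], bin_hi_uM = breaks[-1L],
             fraction = unname(frac), n = n)
}

#' Normalized bulk intensity over time
#'
#' Sum of one channel's intensity within the ROI per frame, divided by the
#' frame-1 value. Conservation of aggregate material shows as a flat trace at
#' 1 ("little to no change" in bulk signal), whatever the spatial
#' rearrangement of the aggregates.
#'
#' @param stack an [image_stack()] with >= 2 frames.
#' @param roi a [cell_roi()].
#' @param channel channel name or index.
#' @return numeric vector of length `n_frames(stack)`, first element 1.
#' @export
bulk_intensity_trace <- function(stack, roi, channel) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "cell_roi"))
  if (n_frames(stack) < 2L) stop("need >= 2 frames")
  sums <- vapply(seq_len(n_frames(stack)), function(t) {
    sum(get_frame(stack, t, channel)[roi$mask])
  }, 0)
  if (sums[1L] == 0) stop("frame-1 bulk intensity is zero; cannot normalize")
  sums / sums[1L]
}
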