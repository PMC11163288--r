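#' Pearson colocalization of an object pair in contact
#'
#' Pearson correlation coefficient between two channels over the union of
#' the two object masks, each dilated by one pixel. "Physical contact" is
#' operationalized as the dilated masks overlapping or touching; pairs not
#' in contact are an error. If either channel has zero variance over the
#' region the PCC is undefined and returned as `NA` with a flag (never 0).
#'
#' @param imgA,imgB `(y, x)` intensity matrices of the two channels.
#' @param maskA,maskB logical object masks congruent with the images.
#' @param radius_um optional aggregate equivalent radius carried through to
#'   the result (for size-binned curves).
#' @param min_px minimum admissible contact-region size (default 8; smaller
#'   regions are too few pixels for a meaningful correlation).
#' @return data.frame row with `radius_um`, `pcc`, `n_px`, `undefined`.
#' @export
pair_pcc <- function(imgA, imgB, maskA, maskB, radius_um = NA_real_,
                     min_px = 8L) {
  stopifnot(is.matrix(imgA), all(dim(imgA) == dim(imgB)),
            all(dim(maskA) == dim(imgA)), all(dim(maskB) == dim(imgA)))
  dA <- dilate1(maskA != 0)
  dB <- dilate1(maskB != 0)
  if (!any(dA & dB)) {
    stop("objects are not in physical contact (1-px dilated masks disjoint)")
  }
  region <- dA | dB
  n <- sum(region)
  if (n < min_px) stop("contact region has fewer than ", min_px, " pixels")
  a <- imgA[region]; b <- imgB[region]
  va <- sum((a - mean(a))^2); vb <- sum((b - mean(b))^2)
  if (va == 0 || vb == 0) {
    return(data.frame(radius_um = radius_um, pcc = NA_real_, n_px = n,
                      undefined = TRUE))
  }
  rho <- sum((a - mean(a)) * (b - mean(b))) / sqrt(va * vb)
  data.frame(radius_um = radius_um, pcc = rho, n_px = n, undefined = FALSE)
}

# one-pixel 8-neighborhood binary dilation
dilate1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- seq_len(d[1L]); xs <- seq_len(d[2L])
    sy <- ys - dy; sx <- xs - dx
    oky <- sy >= 1 & sy <= d[1L]; okx <- sx >= 1 & sx <= d[2L]
    out[ys[oky], xs[okx]] <- out[ys[oky], xs[okx]] | mask[sy[oky], sx[okx]]
  }
  out
}

#' Bin pairwise PCC values by aggregate radius
#'
#' @param pairs data.frame of [pair_pcc()] rows (with `radius_um`).
#' @param breaks ascending radius bin edges.
#' @return data.frame with `bin_center_um`, `mean_pcc`, `se`, `n`; empty
#'   bins are omitted (with a message), single-pair bins carry `se = NA`.
#' @export
pcc_vs_size <- function(pairs, breaks) {
  stopifnot(is.data.frame(pairs), all(c("radius_um", "pcc") %in% names(pairs)),
            length(breaks) >= 2L, !is.unsorted(breaks, strictly = TRUE))
  pairs <- pairs[!is.na(pairs$pcc), , drop = FALSE]
  if (!nrow(pairs)) stop("no defined PCC values to bin")
  bin <- cut(pairs$radius_um, breaks, include.lowest = TRUE)
  centers <- (breaks[-length(breaks)] + breaks[-1L]) / 2
  rows <- lapply(seq_along(centers), function(i) {
    v <- pairs$pcc[as.integer(bin) == i]
    if (!length(v)) return(NULL)
    data.frame(bin_center_um = centers[i], mean_pcc = mean(v),
               se = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  })
  empty <- sum(vapply(rows, is.null, TRUE))
  if (empty) message(empty, " empty radius bin(s) omitted")
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("all bins empty")
  out
}

#' Integrated intensity versus size, normalized per channel
#'
#' For each intensity channel of a measured-object table, returns
#' `(size, integrated intensity / channel maximum)` sorted by size, so every
#' channel's maximum is exactly 1. Used to relate per-object content (e.g.
#' polyubiquitin, p62) to aggregate size.
#'
#' @param objects data.frame from [measure_objects()] with >= 2 rows and at
#'   least one `intensity_*` column.
#' @param size_col column to use as size (default `"area_um2"`).
#' @return data.frame with `size`, one `norm_<channel>` column per channel.
#' @export
integrated_intensity_vs_size <- function(objects, size_col = "area_um2") {
  stopifnot(is.data.frame(objects), size_col %in% names(objects))
  if (nrow(objects) < 1L) stop("need >= 1 object")
  ich <- grep("^intensity_", names(objects), value = TRUE)
  if (!length(ich)) stop("no intensity_* columns present")
  ord <- order(objects[[size_col]])
  out <- data.frame(size = objects[[size_col]][ord])
  for (ch in ich) {
    mx <- max(objects[[ch]])
    if (mx == 0) stop("channel ", ch, " has zero maximum; cannot normalize")
    out[[sub("^intensity_", "norm_", ch)]] <- objects[[ch]][ord] / mx
  }
  out
}
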