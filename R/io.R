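#' Read and write image stacks as multi-page TIFF plus YAML sidecar
#'
#' Stacks are stored as multi-page 32-bit float TIFF (pages ordered
#' t-major, then z, then channel) with a YAML sidecar carrying the geometry
#' the TIFF cannot: `pixel_size_um`, `z_step_um`, `frame_interval_s`,
#' `light_schedule`, `channel_names`, the array dimensions and an
#' `intensity_scale`. Raw intensities are divided by `intensity_scale` for
#' storage (TIFF float samples live in \[0, 1\]) and restored on read, so a
#' write/read round trip reproduces the data to 32-bit float precision.
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path.
#' @param meta sidecar YAML path; defaults to `paste0(path, ".yaml")`.
#' @return `read_stack()` returns an [image_stack()]; `write_stack()` returns
#'   `path` invisibly.
#' @export
write_stack <- function(stack, path, meta = paste0(path, ".yaml")) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  scale <- max(stack$data, 1e-12)
  pages <- vector("list", d[1L] * d[2L] * d[3L])
  i <- 1L
  for (t in seq_len(d[1L])) for (z in seq_len(d[2L])) for (c in seq_len(d[3L])) {
    pages[[i]] <- matrix(stack$data[t, z, c, , ] / scale, d[4L], d[5L])
    i <- i + 1L
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  if (!ok) stop("failed to write TIFF to '", path, "'")
  side <- list(pixel_size_um = stack$pixel_size_um,
               z_step_um = stack$z_step_um,
               frame_interval_s = stack$frame_interval_s,
               light_schedule = lapply(stack$light_schedule, as.integer),
               channel_names = as.list(stack$channel_names),
               dims = as.list(as.integer(d)),
               intensity_scale = scale)
  yaml::write_yaml(side[!vapply(side, is.null, TRUE)], meta)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, meta = paste0(path, ".yaml")) {
  if (!file.exists(path)) stop("cannot read image file '", path, "'")
  if (!file.exists(meta)) {
    stop("missing sidecar metadata '", meta,
         "': pixel_size_um is required and TIFF alone does not carry it")
  }
  side <- yaml::read_yaml(meta)
  if (is.null(side$pixel_size_um)) {
    stop("sidecar '", meta, "' lacks required field pixel_size_um")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- if (!is.null(side$dims)) as.integer(unlist(side$dims)) else
    c(length(pages), 1L, 1L, dim(pages[[1L]]))
  if (prod(d[1:3]) != length(pages)) {
    stop("sidecar dims disagree with TIFF page count")
  }
  scale <- if (!is.null(side$intensity_scale)) side$intensity_scale else 1
  data <- array(0, dim = d)
  i <- 1L
  for (t in seq_len(d[1L])) for (z in seq_len(d[2L])) for (c in seq_len(d[3L])) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]  # tolerate grey-as-RGB readers
    data[t, z, c, , ] <- pg * scale
    i <- i + 1L
  }
  image_stack(data,
              pixel_size_um = side$pixel_size_um,
              z_step_um = side$z_step_um,
              channel_names = if (!is.null(side$channel_names))
                unlist(side$channel_names) else NULL,
              frame_interval_s = side$frame_interval_s %||% 1,
              light_schedule = lapply(side$light_schedule %||% list(), unlist))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read result tables as CSV
#'
#' Column order is preserved, floats are written at full precision, and units
#' are encoded in column names (e.g. `area_um2`). An empty table produces a
#' header-only CSV.
#'
#' @param records a data.frame (possibly 0-row).
#' @param path CSV file path.
#' @return `read_results()` returns a data.frame; `write_results()` returns
#'   `path` invisibly.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  old <- options(digits = 17)
  on.exit(options(old))
  write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("cannot read results file '", path, "'")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a boolean or label mask as TIFF
#'
#' Label images are stored as 16-bit grey TIFF (labels up to 65535); boolean
#' masks as 0/1.
#'
#' @param mask integer or logical matrix.
#' @param path TIFF file path.
#' @return `read_mask()` returns an integer matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (max(m) > 65535) stop("label values exceed 16-bit TIFF range")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask file '", path, "'")
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
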