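#' Physical-unit conversions between pixels/voxels and micrometres
#'
#' All geometry reported by the pipeline is in micrometres; these helpers are
#' the single place where pixel counts and physical sizes are interconverted.
#' `area_to_px()` / `volume_to_vox()` return the integer pixel/voxel count
#' equivalent to a physical size (rounded to the nearest integer, as minimum
#' size filters are integer counts); `px_to_area()` / `vox_to_volume()` are
#' the exact inverse maps on counts.
#'
#' With the default pixel size of 0.0851 um and 0.25 um optical sections, the
#' standard diffraction-limit filters are mutually consistent:
#' 0.116 um^2 corresponds to 16 pixels and 0.116 um^3 to 64 voxels.
#'
#' @param area_um2 area in square micrometres.
#' @param volume_um3 volume in cubic micrometres.
#' @param n_px,n_vox integer pixel / voxel counts.
#' @param pixel_size_um edge length of a pixel in micrometres (> 0).
#' @param z_step_um spacing of optical sections in micrometres (> 0).
#' @return a numeric scalar (count or physical size).
#' @examples
#' area_to_px(0.116, 0.0851)          # 16
#' volume_to_vox(0.116, 0.0851, 0.25) # 64
#' @export
area_to_px <- function(area_um2, pixel_size_um) {
  stopifnot(pixel_size_um > 0, area_um2 >= 0)
  round(area_um2 / pixel_size_um^2)
}

#' @rdname area_to_px
#' @export
px_to_area <- function(n_px, pixel_size_um) {
  stopifnot(pixel_size_um > 0)
  n_px * pixel_size_um^2
}

#' @rdname area_to_px
#' @export
volume_to_vox <- function(volume_um3, pixel_size_um, z_step_um) {
  stopifnot(pixel_size_um > 0, z_step_um > 0, volume_um3 >= 0)
  round(volume_um3 / (pixel_size_um^2 * z_step_um))
}

#' @rdname area_to_px
#' @export
vox_to_volume <- function(n_vox, pixel_size_um, z_step_um) {
  stopifnot(pixel_size_um > 0, z_step_um > 0)
  n_vox * pixel_size_um^2 * z_step_um
}
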