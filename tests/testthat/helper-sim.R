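# Shared fixtures, all built in code.

# A small uniform test frame with bright rectangles burned in.
toy_frame <- function(shape = c(32L, 32L), bg = 0) {
  matrix(bg, shape[1L], shape[2L])
}

# Rasterize a disk mask (pixel centers within radius), 1-based center coords.
disk_mask <- function(shape, cy, cx, r) {
  yy <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  xx <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# Full-frame ROI helper.
full_roi <- function(shape) cell_roi("all", matrix(TRUE, shape[1L], shape[2L]))

# Noise-free, blur-free generator settings: detected geometry should match
# ground truth almost exactly under these conditions.
clean_params <- function(...) {
  sim_params(bg_mean = 50, bg_sd = 0, psf_sigma_um = 0, ...)
}
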