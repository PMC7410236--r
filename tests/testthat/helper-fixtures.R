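# Shared fixture builders (everything is generated in code at test time).

# circular roll of a 3D array by integer offsets (oracle-side shift model)
roll3 <- function(a, d) {
  dm <- dim(a)
  idx <- lapply(1:3, function(k) ((seq_len(dm[k]) - 1 - d[k]) %% dm[k]) + 1)
  a[idx[[1]], idx[[2]], idx[[3]]]
}

# Sierpinski triangle raster at depth k (2^k x 2^k): cells where x AND y == 0
sierpinski_mask <- function(depth) {
  n <- 2^depth
  outer(0:(n - 1), 0:(n - 1), function(y, x) bitwAnd(y, x) == 0)
}

# a straight horizontal process attached to a disk soma, as a segmentation
line_cell_image <- function(n = 160, soma_cx = 130, soma_cy = 79,
                            soma_r = 8, x0 = 22, x1 = 124) {
  img <- matrix(0, n, n)
  img[(soma_cy - 1):soma_cy, x0:x1] <- 0.8
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  img[(xx - soma_cx)^2 + (yy - soma_cy)^2 <= soma_r^2] <- 1
  img
}

# small, fast time-lapse spec used across dynamics/pipeline tests
fast_tl_spec <- function(motility_level = 0.1, seed = 1, drift = c(0, 0, 0),
                         noise = 0, n_frames = 3, cell_seed = 1,
                         n_slices = 4) {
  timelapse_spec(cell = cell_spec(n_roots = 4, branch_prob = 0.7,
                                  max_depth = 2, img_size_px = 64,
                                  segment_len_um = 6, pixel_size_um = 0.8,
                                  seed = cell_seed),
                 n_frames = n_frames, n_slices = n_slices,
                 motility_level = motility_level, drift_px = drift,
                 noise_sigma = noise, seed = seed)
}
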