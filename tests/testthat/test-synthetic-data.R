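test_that("deterministic branch topologies match closed-form expectations", {
  # unbranched single process
  c1 <- generate_cell_image(cell_spec(n_roots = 1, branch_prob = 0,
                                      max_depth = 1, seed = 3))
  expect_equal(c1$truth$n_roots, 1L)
  expect_equal(c1$truth$n_segments, 1L)
  expect_equal(nrow(c1$truth$nodes), 0L)
  expect_equal(nrow(c1$truth$endpoints), 1L)

  # full dichotomous expansion: every root branches once
  c2 <- generate_cell_image(cell_spec(n_roots = 4, branch_prob = 1,
                                      max_depth = 2, segment_len_um = 8,
                                      pixel_size_um = 0.5,
                                      img_size_px = 128, seed = 5))
  expect_equal(c2$truth$n_roots, 4L)
  expect_equal(c2$truth$n_segments, 12L) # 4 x (1 + 2)
  expect_equal(nrow(c2$truth$nodes), 4L)
  expect_true(all(c2$truth$nodes$rank == 1))
  expect_equal(nrow(c2$truth$endpoints), 8L)

  # general closed form: n_roots * (2^max_depth - 1) segments at branch_prob 1
  c3 <- generate_cell_image(cell_spec(n_roots = 3, branch_prob = 1,
                                      max_depth = 3, segment_len_um = 6,
                                      pixel_size_um = 0.5,
                                      img_size_px = 160, seed = 2))
  expect_equal(c3$truth$n_segments, 3L * (2^3 - 1))
  expect_equal(sum(c3$truth$nodes$rank == 1), 3L)
  expect_equal(sum(c3$truth$nodes$rank == 2), 6L)
})

test_that("generators are bit-reproducible under a fixed seed", {
  s <- cell_spec(n_roots = 4, branch_prob = 0.6, seed = 11)
  expect_identical(generate_cell_image(s)$image, generate_cell_image(s)$image)

  tsp <- fast_tl_spec(motility_level = 0.15, seed = 7, noise = 0.02)
  expect_identical(generate_timelapse(tsp)$stack$data,
                   generate_timelapse(tsp)$stack$data)

  p <- eeg_preset("pentobarbital", duration_s = 20, seed = 9)
  expect_identical(generate_eeg(p)$samples, generate_eeg(p)$samples)
})

test_that("cell specs are validated and oversized cells are rejected", {
  expect_error(cell_spec(n_roots = 0))
  expect_error(cell_spec(branch_prob = 1.5))
  expect_error(generate_cell_image(
    cell_spec(max_depth = 6, segment_len_um = 30, img_size_px = 64)),
    "raster")
})

test_that("a motility-free drift-free noise-free time lapse is static", {
  tl <- generate_timelapse(fast_tl_spec(motility_level = 0, seed = 4))
  for (t in 2:dim(tl$stack$data)[1])
    expect_identical(tl$stack$data[t, , , ], tl$stack$data[1, , , ])
})

test_that("injected drift is the cross-correlation shift of consecutive frames", {
  tl <- generate_timelapse(fast_tl_spec(motility_level = 0, seed = 6,
                                        drift = c(0, 2, 3)))
  d <- dim(tl$stack$data)
  v1 <- array(tl$stack$data[1, , , ], d[2:4])
  v2 <- array(tl$stack$data[2, , , ], d[2:4])
  expect_equal(gliamorphdyn:::estimate_shift_fft(v1, v2), c(0L, 2L, 3L))
  # SD projections of consecutive volumes carry the same (y, x) shift
  p1 <- sd_projection(v1)$data
  p2 <- sd_projection(v2)$data
  cc <- Re(stats::fft(stats::fft(p2) * Conj(stats::fft(p1)), inverse = TRUE))
  peak <- arrayInd(which.max(cc), dim(cc)) - 1L
  expect_equal(as.integer(peak), c(2L, 3L))
})

test_that("drift that would push the cell off the raster errors", {
  expect_error(generate_timelapse(fast_tl_spec(drift = c(0, 40, 0),
                                               n_frames = 3)),
               "off the raster")
})

test_that("higher programmed motility yields a higher recovered index", {
  idx <- function(level, r) {
    tl <- generate_timelapse(fast_tl_spec(motility_level = level,
                                          seed = 100 + r, cell_seed = r))
    analyze_stack_dynamics(tl$stack, register = FALSE,
                           metrics = "motility")$motility$normalized_index
  }
  lo <- vapply(1:6, function(r) idx(0.05, r), numeric(1))
  hi <- vapply(1:6, function(r) idx(0.20, r), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("EEG presets carry their state signatures", {
  kx <- generate_eeg(eeg_preset("ketamine_xylazine", duration_s = 60,
                                seed = 21))
  pk <- spectral_peaks(power_spectrum(kx), n = 2, max_hz = 10)
  expect_equal(pk$freq_hz, c(0.5, 2.0), tolerance = 0.13)

  wake <- generate_eeg(eeg_preset("wake", duration_s = 60, seed = 21))
  pb <- generate_eeg(eeg_preset("pentobarbital", duration_s = 60, seed = 21))
  expect_gt(amplitude_distribution(pb)$excess_kurtosis,
            amplitude_distribution(wake)$excess_kurtosis)
  expect_error(eeg_preset("halothane"))
})

test_that("paired cohorts honour the size and effect contracts", {
  spec <- fast_tl_spec(motility_level = 0.4)
  coh <- generate_paired_cohort(2, spec, effect = -0.5, seed = 1)
  expect_length(coh, 2)
  expect_s3_class(coh[[1]]$pre$stack, "timelapse_stack")
  expect_equal(coh[[2]]$post$spec$motility_level, 0.2)
  expect_error(generate_paired_cohort(3, spec, effect = 2, seed = 1),
               "outside")
})
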