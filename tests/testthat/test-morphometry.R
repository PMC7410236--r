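test_that("segmentation round-trips the generator and orders its masks", {
  cl <- generate_cell_image(cell_spec(n_roots = 4, branch_prob = 0.5,
                                      max_depth = 2, segment_len_um = 8,
                                      soma_radius_um = 5,
                                      pixel_size_um = 0.4,
                                      img_size_px = 128, seed = 3))
  segs <- segment_cells(cl$image, pixel_um = c(0.4, 0.4))
  expect_length(segs, 1)
  s <- segs[[1]]
  expect_true(all(s$soma_mask <= s$cytoplasm_mask))
  expect_true(all(s$cytoplasm_mask <= s$arbor_mask))
  expect_lt(max(abs(s$soma_centroid_px - cl$truth$soma_center_px)), 2)
  expect_false(s$border_touching)
})

test_that("a blank image yields no segmentations", {
  expect_length(segment_cells(matrix(0, 64, 64)), 0)
})

test_that("two non-overlapping cells are segmented disjointly", {
  a <- generate_cell_image(cell_spec(n_roots = 3, branch_prob = 0,
                                     max_depth = 1, segment_len_um = 6,
                                     pixel_size_um = 0.5,
                                     img_size_px = 64, seed = 1))
  b <- generate_cell_image(cell_spec(n_roots = 4, branch_prob = 0,
                                     max_depth = 1, segment_len_um = 6,
                                     pixel_size_um = 0.5,
                                     img_size_px = 64, seed = 2))
  mosaic <- matrix(0, 80, 150)
  mosaic[9:72, 5:68] <- a$image
  mosaic[9:72, 81:144] <- b$image
  segs <- segment_cells(mosaic, pixel_um = c(0.5, 0.5))
  expect_length(segs, 2)
  expect_false(any(segs[[1]]$arbor_mask & segs[[2]]$arbor_mask))
})

test_that("skeleton graphs recover deterministic generator topologies", {
  # three unbranched processes
  cl <- generate_cell_image(cell_spec(n_roots = 3, branch_prob = 0,
                                      max_depth = 2, segment_len_um = 10,
                                      pixel_size_um = 0.5,
                                      img_size_px = 128, seed = 5))
  g <- extract_graph(segment_cells(cl$image, pixel_um = c(0.5, 0.5))[[1]])
  expect_equal(g$n_roots, 3L)
  expect_equal(g$n_segments, 3L)
  expect_equal(g$n_junctions, 0L)

  # two roots, each branching once: 6 segments, 2 rank-1 junctions
  cl2 <- generate_cell_image(cell_spec(n_roots = 2, branch_prob = 1,
                                       max_depth = 2, segment_len_um = 9,
                                       pixel_size_um = 0.5,
                                       img_size_px = 128, seed = 8))
  g2 <- extract_graph(segment_cells(cl2$image, pixel_um = c(0.5, 0.5))[[1]])
  expect_equal(g2$n_roots, 2L)
  expect_equal(g2$n_segments, 6L)
  expect_equal(g2$n_nodes_rank1, 2L)
  expect_equal(g2$n_nodes_rank2, 0L)
})

test_that("a straight 50 um process measures 50 um", {
  img <- line_cell_image() # 103 px of process at 0.5 um/px, minus soma overlap
  segs <- segment_cells(img, pixel_um = c(0.5, 0.5))
  g <- extract_graph(segs[[1]])
  expect_equal(g$n_roots, 1L)
  expect_equal(g$n_segments, 1L)
  expect_equal(g$total_length_um, 50, tolerance = 1 / 50)
})

test_that("complexity index follows its defining formula", {
  expect_equal(complexity_index(list(n_segments = 6, n_nodes_rank1 = 2,
                                     n_nodes_rank2 = 1, n_roots = 2)), 9)
  # unbranched cell: no ranked nodes, CI = 0
  expect_equal(complexity_index(list(n_segments = 4, n_nodes_rank1 = 0,
                                     n_nodes_rank2 = 0, n_roots = 4)), 0)
  expect_error(complexity_index(list(n_segments = 3, n_nodes_rank1 = 1,
                                     n_nodes_rank2 = 0, n_roots = 0)),
               "roots")
  # dual-route check on random count vectors
  set.seed(15)
  for (i in 1:50) {
    ns <- sample(1:40, 1); n1 <- sample(0:10, 1); n2 <- sample(0:10, 1)
    nr <- sample(1:8, 1)
    g <- list(n_segments = ns, n_nodes_rank1 = n1, n_nodes_rank2 = n2,
              n_roots = nr)
    expect_equal(complexity_index(g), ns * (n1 + n2) / nr)
  }
})

test_that("covered environment area matches closed forms and an exhaustive hull oracle", {
  sq <- cbind(y = c(0, 0, 1, 1), x = c(0, 1, 0, 1))
  expect_equal(covered_environment_area(sq), 1)
  tri <- cbind(y = c(0, 0, 3), x = c(0, 4, 0))
  expect_equal(covered_environment_area(tri), 6)
  expect_warning(a2 <- covered_environment_area(cbind(y = c(0, 1),
                                                      x = c(0, 1))),
                 "fewer")
  expect_equal(a2, 0)
  expect_warning(a3 <- covered_environment_area(cbind(y = c(0, 1, 2),
                                                      x = c(0, 1, 2))),
                 "collinear")
  expect_equal(a3, 0)

  # oracle: find hull edges exhaustively (all points on one side), then
  # integrate the enclosed area on a fine grid membership test
  set.seed(19)
  pts <- cbind(y = stats::runif(20, 0, 10), x = stats::runif(20, 0, 10))
  area <- covered_environment_area(pts)
  inside <- function(py, px) {
    for (i in 1:19) for (j in (i + 1):20) {
      ny <- pts[j, 2] - pts[i, 2]; nx <- -(pts[j, 1] - pts[i, 1])
      s <- (pts[, 1] - pts[i, 1]) * ny + (pts[, 2] - pts[i, 2]) * nx
      if (all(s <= 1e-9)) { # supporting edge; test the query point
        if ((py - pts[i, 1]) * ny + (px - pts[i, 2]) * nx > 1e-9) return(FALSE)
      }
      if (all(s >= -1e-9)) {
        if ((py - pts[i, 1]) * ny + (px - pts[i, 2]) * nx < -1e-9) return(FALSE)
      }
    }
    TRUE
  }
  h <- 0.25
  gy <- seq(h / 2, 10, by = h)
  hits <- 0L
  for (py in gy) for (px in gy) if (inside(py, px)) hits <- hits + 1L
  expect_equal(area, hits * h^2, tolerance = 0.05)
})

test_that("morphometric records carry areas, lengths and counts", {
  cl <- generate_cell_image(cell_spec(n_roots = 2, branch_prob = 1,
                                      max_depth = 2, segment_len_um = 9,
                                      soma_radius_um = 5,
                                      pixel_size_um = 0.5,
                                      img_size_px = 128, seed = 8))
  s <- segment_cells(cl$image, pixel_um = c(0.5, 0.5))[[1]]
  g <- extract_graph(s)
  rec <- morphometrics(s, g, region = "cortex", condition = "control")
  expect_equal(rec$cell_body_area_um2, pi * 25, tolerance = 0.05)
  expect_equal(rec$n_segments, cl$truth$n_segments)
  expect_equal(rec$complexity_index, complexity_index(g))
  expect_equal(rec$region, "cortex")
  expect_gt(rec$total_ramification_length_um, 0)
  expect_gte(rec$cytoplasm_area_um2, rec$cell_body_area_um2)
})

test_that("a soma-only cell yields an empty graph and zero ramification", {
  img <- matrix(0, 64, 64)
  yy <- matrix(1:64, 64, 64); xx <- t(yy)
  img[(xx - 32)^2 + (yy - 32)^2 <= 10^2] <- 1
  s <- segment_cells(img, pixel_um = c(0.5, 0.5))[[1]]
  expect_warning(g <- extract_graph(s), "empty graph")
  expect_equal(g$n_segments, 0L)
  rec <- suppressWarnings(morphometrics(s, g))
  expect_equal(rec$total_ramification_length_um, 0)
  expect_true(is.na(rec$complexity_index))
})

test_that("CEA scales with the pixel area while CI is scale-invariant", {
  cl <- generate_cell_image(cell_spec(n_roots = 3, branch_prob = 1,
                                      max_depth = 2, segment_len_um = 9,
                                      pixel_size_um = 0.5,
                                      img_size_px = 128, seed = 4))
  s <- segment_cells(cl$image, pixel_um = c(0.5, 0.5))[[1]]
  g1 <- extract_graph(s)
  s2 <- s; s2$pixel_um <- c(1, 1)
  g2 <- extract_graph(s2)
  expect_equal(complexity_index(g1), complexity_index(g2))
  expect_equal(covered_environment_area(g2),
               4 * covered_environment_area(g1), tolerance = 1e-6)
  expect_equal(g2$total_length_um, 2 * g1$total_length_um, tolerance = 1e-6)
})
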