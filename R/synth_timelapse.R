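#' Specification of a synthetic motile time-lapse acquisition
#'
#' Describes a T x Z x Y x X two-photon-style acquisition of one cell:
#' consecutive z-stack volumes at a fixed frame interval, with programmed
#' process-tip motility, rigid field drift, and additive intensity noise.
#'
#' @param cell a [cell_spec()] for the imaged cell.
#' @param n_frames number of volumes (>= 2).
#' @param n_slices number of optical z-sections per volume.
#' @param frame_interval_s seconds between consecutive volumes.
#' @param motility_level expected fraction of arbor pixels toggled
#'   (extended/retracted) per frame, in [0, 1]. Toggling is restricted to the
#'   terminal 30\% of each process, where microglial dynamics concentrate.
#' @param drift_px integer (dz, dy, dx) rigid drift applied per frame;
#'   frame t carries cumulative drift t * drift_px.
#' @param noise_sigma additive Gaussian intensity noise SD (intensities are
#'   clipped at 0).
#' @param seed RNG seed.
#'
#' @return An object of class \code{timelapse_spec}.
#' @export
timelapse_spec <- function(cell = cell_spec(), n_frames = 4, n_slices = 8,
                           frame_interval_s = 30, motility_level = 0.05,
                           drift_px = c(0L, 0L, 0L), noise_sigma = 0,
                           seed = 1) {
  stopifnot(inherits(cell, "cell_spec"), n_frames >= 2, n_slices >= 1,
            frame_interval_s > 0, motility_level >= 0, motility_level <= 1,
            length(drift_px) == 3, all(drift_px == round(drift_px)),
            noise_sigma >= 0)
  structure(list(cell = cell, n_frames = as.integer(n_frames),
                 n_slices = as.integer(n_slices),
                 frame_interval_s = frame_interval_s,
                 motility_level = motility_level,
                 drift_px = as.integer(drift_px), noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "timelapse_spec")
}

# Pixels lying in the terminal 30% (by arc length) of every terminal branch:
# the pool from which motility toggles are drawn.
tip_pixel_pool <- function(truth, img_size_px) {
  c0 <- truth$soma_center_px[["x"]]
  px_of <- function(u) round(u / truth$pixel_size_um + c0)
  segs <- truth$segments
  term <- segs[segs$seg_id %in% truth$endpoints$seg_id, , drop = FALSE]
  pts <- list()
  for (i in seq_len(nrow(term))) {
    s <- term[i, ]
    tt <- seq(0.7, 1, length.out = 40) # terminal 30% of the branch
    xs <- px_of(s$x0 + tt * (s$x1 - s$x0))
    ys <- px_of(s$y0 + tt * (s$y1 - s$y0))
    for (dx in 0:1) for (dy in 0:1)
      pts[[length(pts) + 1L]] <- cbind(y = ys + dy, x = xs + dx)
  }
  m <- unique(do.call(rbind, pts))
  m[m[, 1] >= 1 & m[, 1] <= img_size_px &
      m[, 2] >= 1 & m[, 2] <= img_size_px, , drop = FALSE]
}

# Place a 2D cell image into a z-stack with a Gaussian axial intensity profile.
render_volume <- function(img2d, n_slices) {
  z <- seq_len(n_slices)
  prof <- exp(-((z - (n_slices + 1) / 2)^2) / (2 * (n_slices / 4)^2))
  vol <- array(0, c(n_slices, nrow(img2d), ncol(img2d)))
  for (k in z) vol[k, , ] <- prof[k] * img2d
  vol
}

#' Generate a drifting, motile synthetic time-lapse stack
#'
#' Builds a T x Z x Y x X acquisition of one synthetic cell. Frame t is frame
#' t-1 with a random set of process-tip pixels toggled (the expected toggled
#' fraction of arbor pixels per frame equals \code{motility_level}), then
#' rigidly shifted by the cumulative drift \code{t * drift_px} with zero fill,
#' then corrupted with additive Gaussian noise clipped at zero.
#'
#' @param spec a [timelapse_spec()].
#' @return A list with \code{stack} (a [timelapse_stack()]), and \code{truth}
#'   (the cell's ground-truth graph plus the injected \code{drift_px} and the
#'   programmed \code{motility_level}).
#' @export
generate_timelapse <- function(spec) {
  stopifnot(inherits(spec, "timelapse_spec"))
  cell <- generate_cell_image(spec$cell)
  set.seed(spec$seed + 1000003L)

  img0 <- cell$image
  n <- spec$cell$img_size_px
  pool <- tip_pixel_pool(cell$truth, n)
  n_arbor <- sum(img0 > 0)
  n_tog <- round(spec$motility_level * n_arbor)
  state <- rep(TRUE, nrow(pool)) # TRUE = tip pixel currently extended

  # drift must not push the cell off the raster
  occ <- which(img0 > 0, arr.ind = TRUE)
  tmax <- spec$n_frames - 1L
  if (any(c(occ[, 1] + tmax * spec$drift_px[2], occ[, 2] + tmax * spec$drift_px[3]) < 1) ||
      any(occ[, 1] + tmax * spec$drift_px[2] > n) ||
      any(occ[, 2] + tmax * spec$drift_px[3] > n) ||
      abs(tmax * spec$drift_px[1]) >= spec$n_slices)
    stop("programmed drift drives the cell off the raster")

  frames <- vector("list", spec$n_frames)
  for (t in seq_len(spec$n_frames)) {
    if (t > 1 && n_tog > 0 && nrow(pool) > 0) {
      flip <- sample.int(nrow(pool), min(n_tog, nrow(pool)))
      state[flip] <- !state[flip]
    }
    img <- img0
    off <- pool[!state, , drop = FALSE]
    if (nrow(off) > 0) img[off] <- 0
    vol <- render_volume(img, spec$n_slices)
    d <- (t - 1L) * spec$drift_px
    vol <- shift_volume(vol, d)
    if (spec$noise_sigma > 0)
      vol <- pmax(vol + stats::rnorm(length(vol), 0, spec$noise_sigma), 0)
    frames[[t]] <- vol
  }
  data <- array(0, c(spec$n_frames, spec$n_slices, n, n))
  for (t in seq_len(spec$n_frames)) data[t, , , ] <- frames[[t]]

  truth <- cell$truth
  truth$drift_px <- spec$drift_px
  truth$motility_level <- spec$motility_level
  stack <- timelapse_stack(data,
                           voxel_um = c(1, spec$cell$pixel_size_um,
                                        spec$cell$pixel_size_um),
                           frame_interval_s = spec$frame_interval_s)
  list(stack = stack, truth = truth, spec = spec)
}

#' Generate a paired pre/post cohort of synthetic time-lapse stacks
#'
#' Emulates a paired anesthesia experiment: each cell is imaged once at the
#' pre-condition motility level and once at \code{pre * (1 + effect)}, with an
#' independent arbor per cell (cell seeds are derived from \code{seed}).
#'
#' @param n_cells number of cells (>= 2).
#' @param pre_spec a [timelapse_spec()] describing the pre-condition
#'   acquisition; per-cell specs differ only in seed.
#' @param effect fractional change of motility level in the post condition
#'   (e.g. -0.17 for a 17\% reduction). The post level must stay in [0, 1].
#' @param seed cohort RNG seed.
#' @return A list of \code{n_cells} elements, each with \code{pre} and
#'   \code{post} (results of [generate_timelapse()]) and \code{cell_id}.
#' @export
generate_paired_cohort <- function(n_cells, pre_spec, effect, seed = 1) {
  stopifnot(n_cells >= 2, inherits(pre_spec, "timelapse_spec"))
  post_level <- pre_spec$motility_level * (1 + effect)
  if (post_level < 0 || post_level > 1)
    stop("effect pushes motility_level outside [0, 1]")
  set.seed(seed)
  cell_seeds <- sample.int(2^30, n_cells)
  pair_seeds <- matrix(sample.int(2^30, 2 * n_cells), ncol = 2)
  lapply(seq_len(n_cells), function(i) {
    cs <- pre_spec$cell; cs$seed <- cell_seeds[i]
    pre <- pre_spec; pre$cell <- cs; pre$seed <- pair_seeds[i, 1]
    post <- pre; post$motility_level <- post_level
    post$seed <- pair_seeds[i, 2]
    list(cell_id = i,
         pre = generate_timelapse(pre),
         post = generate_timelapse(post))
  })
}
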