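#' Time-lapse stack container
#'
#' A 4D fluorescence acquisition: T volumes of Z optical sections of Y x X
#' pixels, with physical voxel dimensions and the inter-volume interval.
#'
#' @param data numeric array of dimension T x Z x Y x X.
#' @param voxel_um voxel dimensions (z, y, x) in micrometres.
#' @param frame_interval_s seconds between consecutive volumes.
#' @return An object of class \code{timelapse_stack}.
#' @export
timelapse_stack <- function(data, voxel_um = c(1, 0.4, 0.4),
                            frame_interval_s = 30) {
  stopifnot(is.array(data), length(dim(data)) == 4, all(voxel_um > 0),
            frame_interval_s > 0)
  structure(list(data = data, voxel_um = as.numeric(voxel_um),
                 frame_interval_s = frame_interval_s),
            class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<timelapse_stack> %d frames x %d slices x %d x %d px, voxel %s um, dt %gs\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_um, 3), collapse = "x"),
              x$frame_interval_s))
  invisible(x)
}

#' Physical volume of the imaged field in cubic micrometres
#' @param stack a [timelapse_stack()].
#' @return Field volume (Z extent x Y extent x X extent) in um^3.
#' @export
stack_volume_um3 <- function(stack) {
  d <- dim(stack$data)
  prod(d[2:4] * stack$voxel_um)
}

#' Rigidly shift a volume by an integer voxel offset with zero fill
#'
#' Content at voxel (z, y, x) moves to (z + dz, y + dy, x + dx); voxels
#' shifted in from outside the field are zero-filled, never wrapped.
#'
#' @param vol numeric Z x Y x X array.
#' @param d integer shift (dz, dy, dx).
#' @return Shifted array of the same dimension.
#' @export
shift_volume <- function(vol, d) {
  stopifnot(length(dim(vol)) == 3, length(d) == 3, all(d == round(d)))
  d <- as.integer(d)
  if (all(d == 0L)) return(vol)
  dm <- dim(vol)
  out <- array(0, dm)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    src[[k]] <- max(1L, 1L - d[k]):min(dm[k], dm[k] - d[k])
    dst[[k]] <- src[[k]] + d[k]
    if (length(src[[k]]) == 0 || src[[k]][1] > dm[k]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

# Integer shift estimate from the peak of the circular FFT cross-correlation.
# Returns d such that mov ~= shift_volume(ref, d); peak indices above the
# Nyquist fold are wrapped to negative shifts.
estimate_shift_fft <- function(ref, mov) {
  if (all(ref == 0) || all(mov == 0))
    stop("cross-correlation undefined for an all-zero volume")
  cc <- Re(stats::fft(stats::fft(mov) * Conj(stats::fft(ref)),
                      inverse = TRUE))
  dm <- dim(ref)
  idx <- arrayInd(which.max(cc), dm) - 1L
  d <- ifelse(idx > dm / 2, idx - dm, idx)
  as.integer(d)
}

#' Register a time-lapse stack to a reference volume
#'
#' Estimates, for every frame, the integer 3D displacement relative to the
#' reference volume from the peak of their FFT-based cross-correlation, and
#' translates each frame by the negative of its displacement (zero-filling
#' voxels shifted in from outside the field). No subpixel refinement is
#' applied by default: the drift in this kind of acquisition is well
#' approximated by whole-voxel offsets and integer shifts avoid
#' interpolation artefacts in the downstream pixel-change metrics.
#'
#' @param stack a [timelapse_stack()].
#' @param reference_index 1-based index of the reference frame (default the
#'   first volume).
#' @return A list with \code{stack} (the registered [timelapse_stack()]) and
#'   \code{shifts} (a data frame with one row per frame: frame, dz, dy, dx —
#'   the estimated displacement of that frame relative to the reference).
#' @export
register_stack <- function(stack, reference_index = 1L) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$data)
  stopifnot(reference_index >= 1, reference_index <= d[1])
  ref <- stack$data[reference_index, , , , drop = TRUE]
  if (d[2] == 1L) ref <- array(ref, d[2:4])
  shifts <- matrix(0L, d[1], 3)
  out <- stack$data
  for (t in seq_len(d[1])) {
    if (t == reference_index) next
    mov <- array(stack$data[t, , , ], d[2:4])
    s <- estimate_shift_fft(ref, mov)
    shifts[t, ] <- s
    out[t, , , ] <- shift_volume(mov, -s)
  }
  res <- stack
  res$data <- out
  list(stack = res,
       shifts = data.frame(frame = seq_len(d[1]), dz = shifts[, 1],
                           dy = shifts[, 2], dx = shifts[, 3]))
}

#' Standard-deviation z-projection of a volume
#'
#' Collapses a Z x Y x X volume to a 2D image by taking, per pixel, the
#' population standard deviation (divisor Z) of intensity across the z axis.
#' Structured signal present in several sections survives; flat background
#' projects to zero.
#'
#' @param volume numeric Z x Y x X array (Z >= 1).
#' @param pixel_um pixel dimensions (y, x) in micrometres.
#' @return An object of class \code{projection2d}: list(data, pixel_um).
#' @export
sd_projection <- function(volume, pixel_um = c(1, 1)) {
  stopifnot(is.array(volume), length(dim(volume)) == 3, dim(volume)[1] >= 1)
  d <- dim(volume)
  flat <- matrix(volume, d[1], d[2] * d[3]) # z in rows, pixels in columns
  m <- matrix(colMeans(flat), d[2], d[3])
  m2 <- matrix(colMeans(flat^2), d[2], d[3])
  sd2 <- pmax(m2 - m^2, 0) # population variance, divisor Z
  structure(list(data = sqrt(sd2), pixel_um = as.numeric(pixel_um)),
            class = "projection2d")
}

#' Binarize a 2D projection
#'
#' Thresholds a standard-deviation projection into a foreground mask. The
#' default Otsu method picks, per image, the threshold maximizing
#' between-class variance of the intensity histogram; a fixed threshold can
#' be supplied instead. The threshold actually used is recorded in the mask.
#'
#' @param projection a [sd_projection()] result, or a plain numeric matrix.
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param fixed_threshold threshold intensity, required for
#'   \code{method = "fixed"}.
#' @return An object of class \code{binary_mask}: list(data — logical matrix,
#'   pixel_um, threshold_used). Foreground = strictly above threshold.
#' @export
binarize <- function(projection, method = c("otsu", "fixed"),
                     fixed_threshold = NULL) {
  method <- match.arg(method)
  if (inherits(projection, "projection2d")) {
    img <- projection$data; pixel_um <- projection$pixel_um
  } else {
    stopifnot(is.matrix(projection))
    img <- projection; pixel_um <- c(1, 1)
  }
  rng <- range(img)
  if (method == "fixed") {
    if (is.null(fixed_threshold)) stop("fixed method requires fixed_threshold")
    thr <- fixed_threshold
  } else {
    if (diff(rng) == 0) {
      warning("constant image: empty mask returned")
      return(structure(list(data = matrix(FALSE, nrow(img), ncol(img)),
                            pixel_um = pixel_um, threshold_used = rng[1]),
                       class = "binary_mask"))
    }
    scaled <- (img - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(t(scaled)), levels = 256) *
      diff(rng) + rng[1]
  }
  structure(list(data = img > thr, pixel_um = pixel_um,
                 threshold_used = thr),
            class = "binary_mask")
}
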