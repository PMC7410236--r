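#' Box-counting (Hausdorff) fractal dimension of a binary mask
#'
#' Estimates shape complexity as the box-counting dimension: for each box
#' size s, the number N(s) of occupied s x s boxes on a grid anchored at the
#' image origin is counted, and the dimension is the negative slope of the
#' least-squares fit of log N(s) on log s. For 2D masks the estimate lies in
#' [0, 2]; ramified cell silhouettes fall between the line (1) and the
#' filled plane (2), which is what makes the dimension a complexity measure.
#'
#' @param mask a [binarize()] result or a logical matrix.
#' @param box_sizes integer box edge lengths in pixels; default powers of two
#'   from 2 up to a quarter of the shorter image side. At least 3 distinct
#'   sizes are required for a meaningful fit.
#' @return A list with \code{dimension}, \code{fit_r2}, and the per-size
#'   counts (\code{box_sizes}, \code{counts}).
#' @export
#' @examples
#' m <- matrix(TRUE, 64, 64)
#' fractal_dimension(m)$dimension # ~2 for a filled square
fractal_dimension <- function(mask, box_sizes = NULL) {
  m <- if (inherits(mask, "binary_mask")) mask$data else mask
  stopifnot(is.matrix(m))
  m <- m > 0
  if (!any(m)) stop("empty mask: fractal dimension undefined")
  if (is.null(box_sizes)) {
    smax <- floor(min(dim(m)) / 4)
    box_sizes <- 2^(1:max(1, floor(log2(smax))))
    box_sizes <- box_sizes[box_sizes <= smax]
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (length(box_sizes) < 3) stop("need at least 3 distinct box sizes")
  fg <- which(m, arr.ind = TRUE) - 1L # 0-based pixel coordinates
  counts <- vapply(box_sizes, function(s) {
    nrow(unique(cbind(fg[, 1] %/% s, fg[, 2] %/% s)))
  }, integer(1))
  fit <- stats::lm(log(counts) ~ log(box_sizes))
  ss_tot <- sum((log(counts) - mean(log(counts)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(dimension = -unname(stats::coef(fit)[2]),
       fit_r2 = r2,
       box_sizes = box_sizes, counts = counts)
}

#' Mean fractal complexity of a time-ordered mask series
#'
#' Computes the box-counting dimension of every frame of a binarized
#' time-lapse series and averages them into a single per-cell complexity
#' value, the in vivo morphology readout of the pipeline.
#'
#' @param masks list of [binarize()] results or logical matrices.
#' @param box_sizes forwarded to [fractal_dimension()].
#' @return An object of class \code{fractal_result}:
#'   list(per_frame_dimension, mean_dimension, fit_r2).
#' @export
series_complexity <- function(masks, box_sizes = NULL) {
  stopifnot(length(masks) >= 1)
  per <- lapply(masks, fractal_dimension, box_sizes = box_sizes)
  structure(list(per_frame_dimension = vapply(per, `[[`, numeric(1), "dimension"),
                 mean_dimension = mean(vapply(per, `[[`, numeric(1), "dimension")),
                 fit_r2 = vapply(per, `[[`, numeric(1), "fit_r2")),
            class = "fractal_result")
}

#' Frame-subtraction motility index of a binarized time-lapse series
#'
#' Subtracts consecutive binarized projections and counts the changed pixels
#' (symmetric difference). The per-pair counts are the pairwise motility
#' coefficients (arbitrary unit); their sum is the global motility
#' coefficient, which is normalized to the physical volume of the imaged
#' stack to give the motility index (index per um^3).
#'
#' @param masks time-ordered list (>= 2) of [binarize()] results or logical
#'   matrices, all of identical dimension.
#' @param stack_volume_um3 physical volume of the imaged field in um^3.
#' @return An object of class \code{motility_series}:
#'   list(pairwise_coefficients, global_coefficient, normalized_index,
#'   stack_volume_um3).
#' @export
#' @examples
#' a <- matrix(FALSE, 8, 8); b <- a; b[1, 1:4] <- TRUE
#' motility_index(list(a, b), stack_volume_um3 = 100)$global_coefficient # 4
motility_index <- function(masks, stack_volume_um3) {
  stopifnot(length(masks) >= 2, stack_volume_um3 > 0)
  ms <- lapply(masks, function(m) {
    x <- if (inherits(m, "binary_mask")) m$data else m
    stopifnot(is.matrix(x))
    x > 0
  })
  d1 <- dim(ms[[1]])
  if (!all(vapply(ms, function(x) identical(dim(x), d1), logical(1))))
    stop("all masks must share the same dimensions")
  pair <- vapply(seq_len(length(ms) - 1), function(i) {
    sum(xor(ms[[i]], ms[[i + 1]]))
  }, numeric(1))
  g <- sum(pair)
  structure(list(pairwise_coefficients = pair, global_coefficient = g,
                 normalized_index = g / stack_volume_um3,
                 stack_volume_um3 = stack_volume_um3),
            class = "motility_series")
}

#' @export
print.motility_series <- function(x, ...) {
  cat(sprintf("<motility_series> %d frame pairs, global %g, index %.4g /um^3\n",
              length(x$pairwise_coefficients), x$global_coefficient,
              x$normalized_index))
  invisible(x)
}

#' In vivo dynamics of one registered time-lapse stack
#'
#' The full per-cell in vivo chain: register to the first volume, produce
#' per-frame standard-deviation z-projections, binarize each (Otsu by
#' default), then compute the mean fractal complexity and the
#' volume-normalized motility index.
#'
#' @param stack a [timelapse_stack()].
#' @param register apply FFT drift registration first (default TRUE).
#' @param binarize_method forwarded to [binarize()].
#' @param fixed_threshold forwarded to [binarize()].
#' @param metrics which readouts to compute (\code{"complexity"},
#'   \code{"motility"}, or both).
#' @return A list with \code{complexity} ([series_complexity()] result),
#'   \code{motility} ([motility_index()] result), \code{shifts}, and
#'   \code{volume_um3}; omitted metrics are NULL.
#' @export
analyze_stack_dynamics <- function(stack, register = TRUE,
                                   binarize_method = "otsu",
                                   fixed_threshold = NULL,
                                   metrics = c("complexity", "motility")) {
  stopifnot(inherits(stack, "timelapse_stack"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  shifts <- NULL
  if (register && dim(stack$data)[1] > 1) {
    reg <- register_stack(stack)
    stack <- reg$stack
    shifts <- reg$shifts
  }
  d <- dim(stack$data)
  masks <- lapply(seq_len(d[1]), function(t) {
    proj <- sd_projection(array(stack$data[t, , , ], d[2:4]),
                          pixel_um = stack$voxel_um[2:3])
    binarize(proj, method = binarize_method, fixed_threshold = fixed_threshold)
  })
  vol <- stack_volume_um3(stack)
  list(complexity = if ("complexity" %in% metrics)
         series_complexity(masks) else NULL,
       motility = if ("motility" %in% metrics)
         motility_index(masks, vol) else NULL,
       shifts = shifts, volume_um3 = vol)
}
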