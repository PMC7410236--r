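#' Specification of a synthetic branched microglial cell
#'
#' Parameters of the recursive arbor generator used to emulate single
#' microglia in 2D confocal-style images. Each primary branch (root) leaves
#' the soma and branches dichotomously with probability \code{branch_prob}
#' at the end of every segment, up to \code{max_depth} branch orders.
#'
#' @param n_roots number of primary branches leaving the soma (>= 1).
#' @param branch_prob probability that a segment branches into two children,
#'   in [0, 1].
#' @param max_depth maximal branch order (a cell with \code{max_depth = 1}
#'   has only unbranched primary processes).
#' @param segment_len_um mean segment length in micrometres.
#' @param soma_radius_um soma radius in micrometres.
#' @param pixel_size_um image sampling, micrometres per pixel.
#' @param img_size_px side length of the square raster, pixels.
#' @param seed RNG seed; the generator is bit-reproducible under a fixed seed.
#'
#' @return An object of class \code{cell_spec}.
#' @export
cell_spec <- function(n_roots = 5, branch_prob = 0.7, max_depth = 4,
                      segment_len_um = 9, soma_radius_um = 4,
                      pixel_size_um = 0.4, img_size_px = 256, seed = 1) {
  stopifnot(n_roots >= 1, branch_prob >= 0, branch_prob <= 1,
            max_depth >= 1, segment_len_um > 0, soma_radius_um > 0,
            pixel_size_um > 0, img_size_px >= 16)
  structure(list(n_roots = as.integer(n_roots), branch_prob = branch_prob,
                 max_depth = as.integer(max_depth),
                 segment_len_um = segment_len_um,
                 soma_radius_um = soma_radius_um,
                 pixel_size_um = pixel_size_um,
                 img_size_px = as.integer(img_size_px),
                 seed = as.integer(seed)),
            class = "cell_spec")
}

#' @export
print.cell_spec <- function(x, ...) {
  cat(sprintf(
    "<cell_spec> %d roots, branch_prob %.2f, max_depth %d, %g um segments, %g um/px\n",
    x$n_roots, x$branch_prob, x$max_depth, x$segment_len_um, x$pixel_size_um))
  invisible(x)
}

# Recursively grow the arbor in micrometre coordinates centred on the soma.
# Returns data frames of segments (with branch depth), junction nodes (with
# topological rank = depth of the branching junction) and process endpoints.
grow_arbor <- function(spec) {
  segs <- list(); nodes <- list(); tips <- list()
  si <- 0L; ni <- 0L; ti <- 0L

  grow <- function(x0, y0, angle, depth, parent_seg) {
    len <- spec$segment_len_um * stats::runif(1, 0.8, 1.2)
    x1 <- x0 + len * cos(angle); y1 <- y0 + len * sin(angle)
    si <<- si + 1L
    id <- si
    segs[[id]] <<- data.frame(seg_id = id, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                              depth = depth, length_um = len,
                              parent = parent_seg)
    branches <- depth < spec$max_depth && stats::runif(1) < spec$branch_prob
    if (branches) {
      ni <<- ni + 1L
      nodes[[ni]] <<- data.frame(node_id = ni, x = x1, y = y1, rank = depth)
      # children deviate from the parent direction by a uniform angle in +/-60 deg
      a1 <- angle + stats::runif(1, pi / 12, pi / 3)
      a2 <- angle - stats::runif(1, pi / 12, pi / 3)
      grow(x1, y1, a1, depth + 1L, id)
      grow(x1, y1, a2, depth + 1L, id)
    } else {
      ti <<- ti + 1L
      tips[[ti]] <<- data.frame(tip_id = ti, x = x1, y = y1, seg_id = id)
    }
    invisible(NULL)
  }

  # quasi-even angular spacing: jitter bounded to a quarter of the spacing so
  # arbors of different roots cannot collide at the angular level
  root_angles <- 2 * pi * (seq_len(spec$n_roots) - 1) / spec$n_roots +
    stats::runif(spec$n_roots, -pi / spec$n_roots / 4, pi / spec$n_roots / 4)
  r0 <- spec$soma_radius_um
  for (k in seq_len(spec$n_roots)) {
    a <- root_angles[k]
    grow(r0 * cos(a), r0 * sin(a), a, 1L, 0L)
  }
  list(segments = do.call(rbind, segs),
       nodes = if (ni > 0) do.call(rbind, nodes) else
         data.frame(node_id = integer(), x = numeric(), y = numeric(),
                    rank = integer()),
       endpoints = do.call(rbind, tips))
}

# Stamp a 2-px-thick polyline into a matrix (row = y, col = x), 1-based px.
draw_polyline <- function(img, xs, ys, value) {
  n <- max(2L, ceiling(max(abs(diff(range(xs))), abs(diff(range(ys)))) * 3))
  t <- seq(0, 1, length.out = n)
  px <- round(xs[1] + t * (xs[2] - xs[1]))
  py <- round(ys[1] + t * (ys[2] - ys[1]))
  for (dx in 0:1) for (dy in 0:1) {
    ix <- px + dx; iy <- py + dy
    ok <- ix >= 1 & ix <= ncol(img) & iy >= 1 & iy <= nrow(img)
    img[cbind(iy[ok], ix[ok])] <- pmax(img[cbind(iy[ok], ix[ok])], value)
  }
  img
}

#' Render a synthetic microglial cell with known branch topology
#'
#' Generates one connected cell (filled-disk soma plus a recursively branched
#' process arbor) on a square intensity raster, together with the exact
#' ground-truth graph: number of roots, every segment with its branch depth,
#' every junction node with its topological rank (first junction out from the
#' soma = rank 1), and every process endpoint.
#'
#' @param spec a [cell_spec()].
#' @return A list with \code{image} (Y x X intensity matrix in [0, 1]),
#'   \code{truth} (ground-truth graph: \code{n_roots}, \code{segments},
#'   \code{nodes}, \code{endpoints}, all in micrometre coordinates relative
#'   to the soma centre, plus \code{soma_center_px} and
#'   \code{motility_level = NA}), and \code{spec}.
#' @export
#' @examples
#' cell <- generate_cell_image(cell_spec(n_roots = 3, branch_prob = 0, seed = 7))
#' cell$truth$n_segments
generate_cell_image <- function(spec) {
  stopifnot(inherits(spec, "cell_spec"))
  set.seed(spec$seed)
  arbor <- grow_arbor(spec)

  # reject cells whose maximal possible reach exceeds the raster
  reach_um <- spec$soma_radius_um +
    spec$max_depth * spec$segment_len_um * 1.2
  half_um <- (spec$img_size_px / 2 - 2) * spec$pixel_size_um
  if (reach_um > half_um)
    stop("rendered cell would exceed the raster; enlarge img_size_px or shrink the arbor")

  n <- spec$img_size_px
  img <- matrix(0, n, n)
  c0 <- n / 2 # soma centre in px
  to_px <- function(u) u / spec$pixel_size_um + c0

  for (i in seq_len(nrow(arbor$segments))) {
    s <- arbor$segments[i, ]
    img <- draw_polyline(img, to_px(c(s$x0, s$x1)), to_px(c(s$y0, s$y1)), 0.8)
  }
  rr <- spec$soma_radius_um / spec$pixel_size_um
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  img[(xx - c0)^2 + (yy - c0)^2 <= rr^2] <- 1

  truth <- list(n_roots = spec$n_roots,
                n_segments = nrow(arbor$segments),
                segments = arbor$segments,
                nodes = arbor$nodes,
                endpoints = arbor$endpoints,
                soma_center_px = c(y = c0, x = c0),
                soma_radius_um = spec$soma_radius_um,
                pixel_size_um = spec$pixel_size_um,
                motility_level = NA_real_)
  list(image = img, truth = truth, spec = spec)
}
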