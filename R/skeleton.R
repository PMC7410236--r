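# Morphological thinning (Zhang & Suen 1984) to a 1-px-wide, 8-connected
# skeleton. Vectorized over the image; matrices are (row = y, col = x).

shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  ys <- max(1, 1 - dy):min(nr, nr - dy)
  xs <- max(1, 1 - dx):min(nc, nc - dx)
  if (length(ys) && length(xs)) out[ys + dy, xs + dx] <- m[ys, xs]
  out
}

#' Thin a binary mask to a one-pixel skeleton
#'
#' Iterative Zhang-Suen thinning: boundary pixels are peeled in two
#' alternating sub-iterations until the mask is reduced to its 8-connected
#' medial skeleton. Connectivity and endpoints are preserved.
#'
#' @param mask logical matrix (row = y, col = x).
#' @return Logical matrix of the same size containing the skeleton.
#' @export
thin_mask <- function(mask) {
  img <- mask != 0
  # neighbours clockwise from north: P2..P9
  off <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
              c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- lapply(off, function(d) shift_mat(img, d[1], d[2]))
      b <- Reduce(`+`, p)
      seq9 <- c(p, p[1])
      a <- Reduce(`+`, lapply(1:8, function(i) !seq9[[i]] & seq9[[i + 1]]))
      if (sub == 1) {
        cond <- !(p[[1]] & p[[3]] & p[[5]]) & !(p[[3]] & p[[5]] & p[[7]])
      } else {
        cond <- !(p[[1]] & p[[3]] & p[[7]]) & !(p[[1]] & p[[5]] & p[[7]])
      }
      del <- img & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) {
        img <- img & !del
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}
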