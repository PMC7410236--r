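# EBImage stores images as (x, y); package matrices are (row = y, col = x).
as_ebi <- function(m) EBImage::Image(t(m * 1))
from_ebi <- function(im) t(EBImage::imageData(im))

#' Segment microglial cells in a 2D intensity image
#'
#' Dual-threshold segmentation: the soma is the bright core above a high
#' intensity threshold (morphologically opened to drop speckle), the arbor is
#' the connected component above a low (Otsu) threshold that contains that
#' soma, and the cytoplasm is the soma geodesically dilated along the
#' proximal primary branches. Cells whose arbor touches the image border are
#' flagged.
#'
#' @param image numeric Y x X intensity matrix.
#' @param pixel_um pixel dimensions (y, x) in micrometres.
#' @param soma_frac high threshold as a fraction of the image maximum.
#' @param min_soma_px minimum soma area in pixels after opening.
#' @param cytoplasm_reach_um geodesic reach of the proximal cytoplasm along
#'   primary branches, micrometres.
#' @return A list of \code{cell_segmentation} objects, each with
#'   \code{soma_mask}, \code{cytoplasm_mask}, \code{arbor_mask} (logical,
#'   soma \eqn{\subseteq} cytoplasm \eqn{\subseteq} arbor), \code{pixel_um},
#'   \code{soma_centroid_px} (y, x) and \code{border_touching}. Empty list if
#'   no soma is detected.
#' @export
segment_cells <- function(image, pixel_um = c(0.4, 0.4), soma_frac = 0.9,
                          min_soma_px = 12, cytoplasm_reach_um = 5) {
  stopifnot(is.matrix(image), all(pixel_um > 0))
  if (diff(range(image)) == 0) return(list())

  arbor_all <- binarize(image, method = "otsu")$data
  arbor_lab <- from_ebi(EBImage::bwlabel(as_ebi(arbor_all)))

  soma_raw <- image >= soma_frac * max(image)
  brush <- EBImage::makeBrush(5, shape = "disc")
  soma_open <- from_ebi(EBImage::opening(as_ebi(soma_raw), brush)) > 0
  soma_lab <- from_ebi(EBImage::bwlabel(as_ebi(soma_open)))
  n_soma <- max(soma_lab)
  if (n_soma == 0) return(list())

  kern <- EBImage::makeBrush(3, shape = "box")
  out <- list()
  for (k in seq_len(n_soma)) {
    soma <- soma_lab == k
    if (sum(soma) < min_soma_px) next
    cen <- which(soma, arr.ind = TRUE)
    cy <- mean(cen[, 1]); cx <- mean(cen[, 2])
    lab <- arbor_lab[round(cy), round(cx)]
    if (lab == 0) {
      labs <- arbor_lab[soma]
      labs <- labs[labs > 0]
      if (!length(labs)) next
      lab <- as.integer(names(sort(table(labs), decreasing = TRUE))[1])
    }
    arbor <- arbor_lab == lab | soma
    soma <- soma & arbor
    # proximal cytoplasm: geodesic dilation of the soma inside the arbor
    n_iter <- max(1L, round(cytoplasm_reach_um / mean(pixel_um)))
    cyto <- soma
    for (i in seq_len(n_iter))
      cyto <- (from_ebi(EBImage::dilate(as_ebi(cyto), kern)) > 0) & arbor
    border <- any(arbor[1, ]) || any(arbor[nrow(arbor), ]) ||
      any(arbor[, 1]) || any(arbor[, ncol(arbor)])
    out[[length(out) + 1L]] <- structure(
      list(soma_mask = soma, cytoplasm_mask = cyto, arbor_mask = arbor,
           pixel_um = as.numeric(pixel_um),
           soma_centroid_px = c(y = cy, x = cx),
           border_touching = border),
      class = "cell_segmentation")
  }
  out
}

# 8-neighbour offsets and step lengths (px)
.nbr8 <- cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
.nbr8_w <- sqrt(.nbr8[, 1]^2 + .nbr8[, 2]^2)

# Adjacency structure of a skeleton: for each skeleton pixel, its 8-connected
# skeleton neighbours, with diagonal shortcuts removed (a diagonal contact is
# dropped when the two pixels already share an orthogonal skeleton
# neighbour), so the pixel graph is locally thin and degrees classify
# pixels reliably.
skeleton_adjacency <- function(skel) {
  idx <- which(skel)
  np <- length(idx)
  nr <- nrow(skel); nc <- ncol(skel)
  pos <- arrayInd(idx, dim(skel))
  id_of <- integer(length(skel)); id_of[idx] <- seq_len(np)
  nbrs <- vector("list", np)
  wts <- vector("list", np)
  for (i in seq_len(np)) {
    y <- pos[i, 1]; x <- pos[i, 2]
    ids <- integer(0); ws <- numeric(0)
    for (k in seq_len(8)) {
      ny <- y + .nbr8[k, 1]; nx <- x + .nbr8[k, 2]
      if (ny < 1 || ny > nr || nx < 1 || nx > nc || !skel[ny, nx]) next
      if (.nbr8_w[k] > 1) { # diagonal: skip if an orthogonal relay exists
        if (skel[y, nx] || skel[ny, x]) next
      }
      ids <- c(ids, id_of[(nx - 1L) * nr + ny])
      ws <- c(ws, .nbr8_w[k])
    }
    nbrs[[i]] <- ids; wts[[i]] <- ws
  }
  list(pixels = pos, nbrs = nbrs, wts = wts,
       deg = lengths(nbrs), id_of = id_of)
}

#' Extract the skeleton graph of a segmented cell
#'
#' Thins the arbor mask to a one-pixel centerline, removes the soma
#' interior, and converts the remaining skeleton into a topological graph:
#' roots are skeleton branches incident to the soma boundary, junction nodes
#' are ranked by topological order outward from the soma (first junction on
#' a path from a root = rank 1, next = rank 2; deeper junctions keep higher
#' ranks), and segments are maximal skeleton paths between nodes/endpoints
#' with geodesic length in micrometres (8-connected steps of 1 or sqrt(2)
#' pixels). Short terminal spurs, a known thinning artefact, are pruned and
#' the pass-through pseudo-junctions they leave behind are dissolved.
#'
#' @param seg a \code{cell_segmentation} from [segment_cells()] (or a list
#'   with \code{arbor_mask}, \code{soma_mask}, \code{pixel_um}).
#' @param prune_um terminal spurs shorter than this are removed.
#' @return An object of class \code{morphology_graph}: list(nodes — data
#'   frame (id, type in root/junction/endpoint, rank, y_px, x_px),
#'   segments — data frame (from, to, length_um), n_roots, n_segments,
#'   n_nodes_rank1, n_nodes_rank2, n_junctions, total_length_um,
#'   endpoints_um — endpoint coordinates in micrometres).
#' @export
extract_graph <- function(seg, prune_um = 1.5) {
  arbor <- seg$arbor_mask; soma <- seg$soma_mask
  px_um <- mean(seg$pixel_um)
  skel <- thin_mask(arbor)
  skel_out <- skel & !soma
  if (!any(skel_out)) {
    warning("no skeleton outside the soma: returning an empty graph")
    return(structure(list(
      nodes = data.frame(id = integer(), type = character(),
                         rank = numeric(), y_px = numeric(),
                         x_px = numeric()),
      segments = data.frame(from = integer(), to = integer(),
                            length_um = numeric()),
      n_roots = 0L, n_segments = 0L, n_nodes_rank1 = 0L,
      n_nodes_rank2 = 0L, n_junctions = 0L, total_length_um = 0,
      endpoints_um = cbind(y = numeric(), x = numeric()),
      pixel_um = seg$pixel_um), class = "morphology_graph"))
  }

  adj <- skeleton_adjacency(skel_out)
  pos <- adj$pixels
  np <- nrow(pos)

  # pixels touching the soma; one attachment (closest to the soma centroid)
  # per adjacency cluster becomes a root, the rest stay ordinary pixels
  touches <- vapply(seq_len(np), function(i) {
    ys <- pos[i, 1] + .nbr8[, 1]; xs <- pos[i, 2] + .nbr8[, 2]
    ok <- ys >= 1 & ys <= nrow(soma) & xs >= 1 & xs <= ncol(soma)
    any(soma[cbind(ys[ok], xs[ok])])
  }, logical(1))
  if (!any(touches)) stop("skeleton has no attachment to the soma")
  sc <- colMeans(which(soma, arr.ind = TRUE))
  tset <- which(touches)
  troot <- rep(NA_integer_, np)
  seed_cl <- 0L
  visited <- rep(FALSE, np)
  for (s in tset) {
    if (visited[s]) next
    seed_cl <- seed_cl + 1L
    queue <- s
    members <- integer(0)
    visited[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      members <- c(members, v)
      for (u in adj$nbrs[[v]]) if (touches[u] && !visited[u]) {
        visited[u] <- TRUE; queue <- c(queue, u)
      }
    }
    d2 <- (pos[members, 1] - sc[1])^2 + (pos[members, 2] - sc[2])^2
    troot[members[which.min(d2)]] <- seed_cl
  }
  is_root <- !is.na(troot)

  # junction clustering: adjacent junction pixels collapse into one node
  is_junc <- adj$deg >= 3 & !is_root
  is_endp <- adj$deg <= 1 & !is_root
  node_cl <- integer(np) # 0 = chain pixel
  n_cl <- 0L
  for (i in which(is_root | is_endp)) {
    n_cl <- n_cl + 1L; node_cl[i] <- n_cl
  }
  seen <- rep(FALSE, np)
  for (i in which(is_junc)) {
    if (seen[i]) next
    n_cl <- n_cl + 1L
    queue <- i; seen[i] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      node_cl[v] <- n_cl
      for (u in adj$nbrs[[v]]) if (is_junc[u] && !seen[u]) {
        seen[u] <- TRUE; queue <- c(queue, u)
      }
    }
  }
  cl_type <- character(n_cl)
  cl_type[node_cl[is_root]] <- "root"
  cl_type[node_cl[is_endp]] <- "endpoint"
  cl_type[node_cl[is_junc]] <- "junction"
  cl_pos <- matrix(0, n_cl, 2)
  for (k in seq_len(n_cl)) {
    m <- which(node_cl == k)
    cl_pos[k, ] <- colMeans(pos[m, , drop = FALSE])
  }

  # walk from every node pixel along each chain until the next node pixel;
  # chain pixels are claimed on first traversal so each segment is traced once
  segs <- list()
  claimed <- rep(FALSE, np)
  for (i in which(node_cl > 0)) {
    for (j in seq_along(adj$nbrs[[i]])) {
      nb <- adj$nbrs[[i]][j]
      if (node_cl[nb] > 0) {
        if (node_cl[nb] != node_cl[i] && i < nb) # direct node-node contact
          segs[[length(segs) + 1L]] <- c(node_cl[i], node_cl[nb],
                                         adj$wts[[i]][j])
        next
      }
      if (claimed[nb]) next
      len <- adj$wts[[i]][j]
      prev <- i; cur <- nb
      while (node_cl[cur] == 0) {
        claimed[cur] <- TRUE
        nxt <- setdiff(adj$nbrs[[cur]], prev)
        if (!length(nxt)) break # dead-end chain pixel (isolated artefact)
        wsel <- which(adj$nbrs[[cur]] == nxt[1])[1]
        len <- len + adj$wts[[cur]][wsel]
        prev <- cur; cur <- nxt[1]
      }
      if (node_cl[cur] == 0) next
      segs[[length(segs) + 1L]] <- c(node_cl[i], node_cl[cur], len)
    }
  }
  if (!length(segs)) stop("no segments traced")
  sm <- do.call(rbind, segs)

  # node-level graph
  ng <- igraph::make_empty_graph(n = n_cl, directed = FALSE)
  ng <- igraph::add_edges(ng, as.vector(t(sm[, 1:2, drop = FALSE])),
                          attr = list(length_px = sm[, 3]))

  # drop unreachable leftovers (disconnected skeleton fragments)
  comp <- igraph::components(ng)
  keep_comp <- unique(comp$membership[cl_type == "root"])
  drop_v <- which(!(comp$membership %in% keep_comp))
  if (length(drop_v)) {
    warning("skeleton disconnected after soma removal; keeping the soma-attached part")
    ng <- igraph::delete_vertices(ng, drop_v)
    cl_type <- cl_type[-drop_v]; cl_pos <- cl_pos[-drop_v, , drop = FALSE]
    n_cl <- length(cl_type)
  }

  # prune short terminal spurs attached to junctions, then dissolve
  # pass-through junctions left with exactly two incident segments
  repeat {
    degs <- igraph::degree(ng)
    drop_v <- integer(0)
    for (v in which(cl_type == "endpoint" & degs == 1)) {
      e <- igraph::incident(ng, v)
      if (igraph::E(ng)$length_px[e] * px_um < prune_um) {
        other <- setdiff(as.integer(igraph::ends(ng, e)), v)
        if (length(other) && cl_type[other] == "junction")
          drop_v <- c(drop_v, v)
      }
    }
    if (length(drop_v)) {
      ng <- igraph::delete_vertices(ng, drop_v)
      cl_type <- cl_type[-drop_v]
      cl_pos <- cl_pos[-drop_v, , drop = FALSE]
      n_cl <- length(cl_type)
    }
    dissolved <- FALSE
    repeat {
      degs <- igraph::degree(ng)
      j2 <- which(cl_type == "junction" & degs == 2)
      if (!length(j2)) break
      v <- j2[1]
      es <- igraph::incident(ng, v)
      vend <- igraph::ends(ng, es)
      nbrs <- as.integer(t(vend))
      nbrs <- nbrs[nbrs != v]
      len <- sum(igraph::E(ng)$length_px[es])
      ng <- igraph::delete_vertices(ng, v)
      cl_type <- cl_type[-v]; cl_pos <- cl_pos[-v, , drop = FALSE]
      nbrs <- nbrs - (nbrs > v)
      if (length(nbrs) == 2)
        ng <- igraph::add_edges(ng, nbrs, attr = list(length_px = len))
      n_cl <- n_cl - 1L
      dissolved <- TRUE
    }
    if (!length(drop_v) && !dissolved) break
  }

  # topological rank of a junction: hop count from the nearest root over the
  # node graph (endpoints are leaves and never intermediates, so hops count
  # the junction order outward from the soma)
  roots <- which(cl_type == "root")
  if (!length(roots)) stop("no root attachments survived pruning")
  dmat <- igraph::distances(ng, v = roots, weights = NA)
  hop <- apply(dmat, 2, min)
  rank <- ifelse(cl_type == "junction", hop, NA)

  nodes <- data.frame(id = seq_len(n_cl), type = cl_type,
                      rank = as.numeric(rank),
                      y_px = cl_pos[, 1], x_px = cl_pos[, 2])
  el <- igraph::as_edgelist(ng)
  segments <- data.frame(from = el[, 1], to = el[, 2],
                         length_um = igraph::E(ng)$length_px * px_um)
  epi <- nodes$type == "endpoint"
  endpoints_um <- cbind(y = nodes$y_px[epi] * seg$pixel_um[1],
                        x = nodes$x_px[epi] * seg$pixel_um[2])
  structure(list(
    nodes = nodes, segments = segments,
    n_roots = sum(cl_type == "root"),
    n_segments = nrow(segments),
    n_nodes_rank1 = sum(nodes$rank == 1, na.rm = TRUE),
    n_nodes_rank2 = sum(nodes$rank == 2, na.rm = TRUE),
    n_junctions = sum(cl_type == "junction"),
    total_length_um = sum(segments$length_um),
    endpoints_um = endpoints_um,
    pixel_um = seg$pixel_um), class = "morphology_graph")
}

#' @export
print.morphology_graph <- function(x, ...) {
  cat(sprintf(
    "<morphology_graph> %d roots, %d segments, %d junctions (rank1 %d, rank2 %d), %.1f um total\n",
    x$n_roots, x$n_segments, x$n_junctions, x$n_nodes_rank1,
    x$n_nodes_rank2, x$total_length_um))
  invisible(x)
}

#' Ramification complexity index (CI)
#'
#' CI = n_segments x (n rank-1 nodes + n rank-2 nodes) / n_roots: the
#' per-cell ramification statistic relating branching density to the number
#' of primary branches. Topological, hence scale-invariant.
#'
#' @param graph a [extract_graph()] result, or a list with \code{n_segments},
#'   \code{n_nodes_rank1}, \code{n_nodes_rank2}, \code{n_roots}.
#' @return The dimensionless complexity index.
#' @export
#' @examples
#' complexity_index(list(n_segments = 6, n_nodes_rank1 = 2,
#'                       n_nodes_rank2 = 1, n_roots = 2)) # 9
complexity_index <- function(graph) {
  if (is.null(graph$n_roots) || graph$n_roots < 1) stop("graph has no roots")
  graph$n_segments * (graph$n_nodes_rank1 + graph$n_nodes_rank2) / graph$n_roots
}

# Shoelace polygon area for vertices in order
shoelace_area <- function(y, x) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Covered environment area (CEA)
#'
#' The 2D surveillance territory of a cell: the area of the convex polygon
#' linking the extremities of its processes, in square micrometres
#' (convex hull of the endpoint coordinates, shoelace formula).
#'
#' @param graph a [extract_graph()] result, or a 2-column matrix of endpoint
#'   coordinates (y, x) in micrometres.
#' @return Area in um^2; 0 with a warning when fewer than 3 non-collinear
#'   endpoints exist.
#' @export
#' @examples
#' covered_environment_area(cbind(y = c(0, 0, 3), x = c(0, 4, 0))) # 6
covered_environment_area <- function(graph) {
  pts <- if (inherits(graph, "morphology_graph")) graph$endpoints_um else graph
  pts <- unique(as.matrix(pts))
  if (nrow(pts) < 3) {
    warning("fewer than 3 process endpoints: CEA set to 0")
    return(0)
  }
  h <- grDevices::chull(pts[, 2], pts[, 1])
  if (length(h) < 3) {
    warning("collinear process endpoints: CEA set to 0")
    return(0)
  }
  shoelace_area(pts[h, 1], pts[h, 2])
}

#' Full morphometric record of one segmented cell
#'
#' Collects the per-cell morphology metrics: cell-body and cytoplasm areas
#' (pixel count x pixel area), complexity index, covered environment area,
#' segment and ranked-node counts, and total ramification length.
#'
#' @param seg a \code{cell_segmentation} from [segment_cells()].
#' @param graph the matching [extract_graph()] result.
#' @param region optional region label carried into the record.
#' @param condition optional condition label.
#' @return A one-row data frame (class \code{morphometric_record}).
#' @export
morphometrics <- function(seg, graph, region = NA_character_,
                          condition = NA_character_) {
  if (!isTRUE(all.equal(seg$pixel_um, graph$pixel_um)))
    stop("segmentation and graph pixel scales differ")
  pxa <- prod(seg$pixel_um)
  rec <- data.frame(
    cell_body_area_um2 = sum(seg$soma_mask) * pxa,
    cytoplasm_area_um2 = sum(seg$cytoplasm_mask) * pxa,
    complexity_index = if (graph$n_roots >= 1) complexity_index(graph) else
      NA_real_, # soma-only cell: ramification statistics undefined
    cea_um2 = suppressWarnings(covered_environment_area(graph)),
    n_roots = graph$n_roots,
    n_segments = graph$n_segments,
    n_nodes_rank1 = graph$n_nodes_rank1,
    n_nodes_rank2 = graph$n_nodes_rank2,
    total_ramification_length_um = graph$total_length_um,
    border_touching = isTRUE(seg$border_touching),
    region = region, condition = condition,
    stringsAsFactors = FALSE)
  class(rec) <- c("morphometric_record", class(rec))
  rec
}
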