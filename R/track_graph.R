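# Track topology: 2D graph representation of the environment, HMM/Viterbi
# linearization of 2D positions, discretized position grids (1D and 2D), and
# graph shortest-path distances.

#' Build a track graph
#'
#' A track graph represents the environment as segments (edges) between 2D
#' node coordinates. Edges are laid out on a 1D axis arm by arm, with
#' `gap_size` cm inserted between arms so that smoothing across the 1D layout
#' cannot bridge physically separate segments. Distances, however, are always
#' topological (shortest path along the graph), never layout distances.
#'
#' @param nodes data.frame with columns `x`, `y` (cm); row order defines node
#'   ids `1..n`.
#' @param edges data.frame with integer columns `from`, `to` and optionally
#'   `arm` (a grouping label; edges of the same arm are laid out contiguously
#'   in order, and a gap separates distinct arms). Default: every edge its own
#'   arm.
#' @param gap_size 1D layout gap between arms in cm (default 15).
#' @param origin node id to place at linear position 0 (default 1; for a
#'   W-track, the center well).
#' @return object of class `track_graph`.
#' @export
track_graph <- function(nodes, edges, gap_size = 15, origin = 1L) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (!all(c("x", "y") %in% names(nodes)))
    stop_param("`nodes` needs columns x, y")
  if (!all(c("from", "to") %in% names(edges)))
    stop_param("`edges` needs columns from, to")
  if (nrow(edges) < 1L) stop_param("track graph needs at least one edge")
  if (is.null(edges$arm)) edges$arm <- seq_len(nrow(edges))
  len <- sqrt((nodes$x[edges$to] - nodes$x[edges$from])^2 +
              (nodes$y[edges$to] - nodes$y[edges$from])^2)
  if (any(len <= 0)) stop_param("zero-length edge")
  edges$length <- len
  # 1D layout: edges in row order; contiguous within an arm, gap between arms
  start_1d <- numeric(nrow(edges))
  pos <- 0
  for (i in seq_len(nrow(edges))) {
    if (i > 1L && !identical(edges$arm[i], edges$arm[i - 1L])) pos <- pos + gap_size
    start_1d[i] <- pos
    pos <- pos + edges$length[i]
  }
  edges$start_1d <- start_1d
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$from, to = edges$to, weight = edges$length),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(nodes))))
  node_dist <- igraph::distances(g)
  ord <- as.integer(igraph::V(g)$name)
  node_dist <- node_dist[order(ord), order(ord), drop = FALSE]
  dimnames(node_dist) <- NULL
  if (!all(is.finite(node_dist))) stop_param("track graph must be connected")
  structure(list(nodes = nodes, edges = edges, gap_size = gap_size,
                 origin = as.integer(origin), node_dist = node_dist),
            class = "track_graph")
}

#' @export
print.track_graph <- function(x, ...) {
  cat(sprintf("Track graph: %d nodes, %d edges, total length %.1f cm (%d arms, %g cm gaps)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length),
              length(unique(x$edges$arm)), x$gap_size))
  invisible(x)
}

#' A straight linear track
#'
#' @param length track length in cm.
#' @return a [track_graph()] with one edge from (0,0) to (length,0).
#' @export
linear_track <- function(length = 180) {
  check_positive(length, "length")
  track_graph(nodes = data.frame(x = c(0, length), y = c(0, 0)),
              edges = data.frame(from = 1L, to = 2L, arm = "track"))
}

#' A W-shaped track
#'
#' Three parallel arms joined by a crossbar: center well at the origin (node
#' 1, linear position 0), center arm up to the center junction, then left and
#' right arms each consisting of a crossbar segment plus a descending arm to
#' the outer well.
#'
#' @param arm_length length of the three parallel arms in cm.
#' @param arm_spacing lateral distance between adjacent arms in cm.
#' @param gap_size 1D layout gap between arms in cm.
#' @return a [track_graph()]. Node order: center well, center junction, left
#'   junction, left well, right junction, right well.
#' @export
w_track <- function(arm_length = 77, arm_spacing = 40, gap_size = 15) {
  nodes <- data.frame(
    x = c(0, 0, -arm_spacing, -arm_spacing, arm_spacing, arm_spacing),
    y = c(0, arm_length, arm_length, 0, arm_length, 0))
  edges <- data.frame(
    from = c(1L, 2L, 3L, 2L, 5L),
    to   = c(2L, 3L, 4L, 5L, 6L),
    arm  = c("center", "left", "left", "right", "right"))
  track_graph(nodes, edges, gap_size = gap_size, origin = 1L)
}

# ---- point/segment geometry helpers -------------------------------------

#' Project a 2D point onto every edge of the track
#' @return list(offset, dist, px, py): vectors over edges; offset measured
#'   from each edge's `from` node.
#' @noRd
project_all_edges <- function(track, p) {
  e <- track$edges; nd <- track$nodes
  ax <- nd$x[e$from]; ay <- nd$y[e$from]
  bx <- nd$x[e$to];   by <- nd$y[e$to]
  vx <- bx - ax; vy <- by - ay
  tt <- ((p[1L] - ax) * vx + (p[2L] - ay) * vy) / (vx^2 + vy^2)
  tt <- pmin(pmax(tt, 0), 1)
  px <- ax + tt * vx; py <- ay + tt * vy
  list(offset = tt * e$length,
       dist = sqrt((p[1L] - px)^2 + (p[2L] - py)^2),
       px = px, py = py)
}

#' Shortest-path distance between two points on the track
#'
#' Points are given as (edge id, offset from the edge's `from` node).
#' @noRd
track_point_distance <- function(track, edge1, off1, edge2, off2) {
  e <- track$edges
  if (edge1 == edge2) return(abs(off1 - off2))
  d <- track$node_dist
  ends1 <- c(e$from[edge1], e$to[edge1])
  w1 <- c(off1, e$length[edge1] - off1)
  ends2 <- c(e$from[edge2], e$to[edge2])
  w2 <- c(off2, e$length[edge2] - off2)
  min(outer(w1, w2, "+") + d[ends1, ends2])
}

#' Map a (edge, offset) point to its 1D layout coordinate
#' @noRd
layout_position <- function(track, edge, offset) {
  track$edges$start_1d[edge] + offset
}

#' Map a 1D layout coordinate back to 2D track coordinates
#'
#' @param track a [track_graph()].
#' @param linear_position 1D layout positions in cm.
#' @return data.frame x, y, edge_id.
#' @export
linear_to_2d <- function(track, linear_position) {
  e <- track$edges; nd <- track$nodes
  n <- length(linear_position)
  x <- rep(NA_real_, n); y <- rep(NA_real_, n); edge <- rep(NA_integer_, n)
  for (j in seq_len(nrow(e))) {
    inside <- is.na(edge) & !is.na(linear_position) &
      linear_position >= e$start_1d[j] - 1e-9 &
      linear_position <= e$start_1d[j] + e$length[j] + 1e-9
    if (!any(inside)) next
    f <- (linear_position[inside] - e$start_1d[j]) / e$length[j]
    f <- pmin(pmax(f, 0), 1)
    x[inside] <- nd$x[e$from[j]] + f * (nd$x[e$to[j]] - nd$x[e$from[j]])
    y[inside] <- nd$y[e$from[j]] + f * (nd$y[e$to[j]] - nd$y[e$from[j]])
    edge[inside] <- j
  }
  data.frame(x = x, y = y, edge_id = edge)
}

# ---- linearization -------------------------------------------------------

#' Linearize 2D positions onto a track graph
#'
#' Assigns each video frame to a track segment with a hidden Markov model and
#' the Viterbi algorithm, then projects the frame orthogonally onto that
#' segment. The observation model is Gaussian in the point-to-segment
#' distance (SD `obs_sd`). The frame-to-frame segment transition weight
#' favors segment pairs whose along-graph distance between the successive
#' projections matches the Euclidean displacement (a Gaussian penalty on the
#' mismatch, SD `obs_sd`), with an additive `diag_bias` on staying on the
#' same segment; rows are normalized. This prevents single-frame segment
#' flips near junctions that a nearest-segment rule would produce.
#'
#' Frames with missing coordinates are linearly interpolated when the gap is
#' shorter than `max_gap` frames, otherwise flagged invalid.
#'
#' @param track a [track_graph()].
#' @param xy matrix or data.frame of 2D positions (cm), one row per frame.
#' @param time_s optional frame times (default 30 Hz frame index).
#' @param obs_sd Gaussian observation SD in cm (default 5).
#' @param diag_bias additive bias toward staying on the current segment
#'   (default 0.1).
#' @param max_gap longest interpolatable run of missing frames.
#' @return data.frame of class `linearized_position` with columns `time_s`,
#'   `segment_id`, `linear_position`, `x_proj`, `y_proj`, `valid`, `speed`
#'   (cm/s, from smoothed projected displacement).
#' @export
linearize <- function(track, xy, time_s = NULL, obs_sd = 5, diag_bias = 0.1,
                      max_gap = 5L) {
  stopifnot(inherits(track, "track_graph"))
  check_positive(obs_sd, "obs_sd")
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  n <- nrow(xy)
  if (is.null(time_s)) time_s <- (seq_len(n) - 1L) / 30
  dt <- if (n > 1L) stats::median(diff(time_s)) else 1 / 30
  # interpolate short gaps of missing samples
  valid <- complete.cases(xy)
  if (!all(valid)) {
    runs <- rle_runs(valid)
    for (r in which(runs$value == "FALSE")) {
      if (runs$end[r] - runs$start[r] + 1L < max_gap &&
          runs$start[r] > 1L && runs$end[r] < n) {
        idx <- runs$start[r]:runs$end[r]
        for (d in 1:2)
          xy[idx, d] <- approx(time_s[valid], xy[valid, d],
                               xout = time_s[idx])$y
        valid[idx] <- TRUE
      }
    }
  }
  ne <- nrow(track$edges)
  proj <- vector("list", n)
  obs_ll <- matrix(-Inf, n, ne)
  for (k in which(valid)) {
    pr <- project_all_edges(track, xy[k, ])
    proj[[k]] <- pr
    obs_ll[k, ] <- dnorm(pr$dist, 0, obs_sd, log = TRUE)
  }
  seg <- rep(NA_integer_, n)
  ok <- which(valid)
  if (length(ok)) {
    # Viterbi over segments, frame-dependent transitions
    delta <- matrix(-Inf, n, ne)
    psi <- matrix(0L, n, ne)
    k0 <- ok[1L]
    delta[k0, ] <- log(1 / ne) + obs_ll[k0, ]
    prev <- k0
    for (k in ok[-1L]) {
      eucl <- sqrt(sum((xy[k, ] - xy[prev, ])^2))
      A <- matrix(0, ne, ne)
      for (a in seq_len(ne)) for (b in seq_len(ne)) {
        gd <- track_point_distance(track, a, proj[[prev]]$offset[a],
                                   b, proj[[k]]$offset[b])
        A[a, b] <- dnorm(gd - eucl, 0, obs_sd)
      }
      diag(A) <- diag(A) + diag_bias
      A <- A / rowSums(A)
      cand <- delta[prev, ] + log(A)          # ne x ne
      delta[k, ] <- apply(cand, 2L, max) + obs_ll[k, ]
      psi[k, ] <- apply(cand, 2L, which.max)
      prev <- k
    }
    kk <- rev(ok)
    seg[kk[1L]] <- which.max(delta[kk[1L], ])
    for (i in seq_along(kk)[-1L])
      seg[kk[i]] <- psi[kk[i - 1L], seg[kk[i - 1L]]]
  }
  lin <- rep(NA_real_, n); xp <- rep(NA_real_, n); yp <- rep(NA_real_, n)
  for (k in ok) {
    lin[k] <- layout_position(track, seg[k], proj[[k]]$offset[seg[k]])
    xp[k] <- proj[[k]]$px[seg[k]]
    yp[k] <- proj[[k]]$py[seg[k]]
  }
  disp <- c(0, sqrt(diff(xp)^2 + diff(yp)^2))
  speed <- gaussian_smooth(disp / dt, sd = 0.1 / dt)  # ~100 ms smoothing
  out <- data.frame(time_s = time_s, segment_id = seg,
                    linear_position = lin, x_proj = xp, y_proj = yp,
                    valid = valid, speed = speed)
  class(out) <- c("linearized_position", "data.frame")
  attr(out, "track") <- track
  out
}

#' Wrap an already 1D position series as a linearized position
#'
#' For simulated data whose latent position is natively 1D: assigns each
#' sample to the track edge containing its layout coordinate and computes
#' speed from the smoothed absolute derivative if not supplied.
#'
#' @param track a [track_graph()].
#' @param time_s sample times (seconds).
#' @param linear_position 1D positions (cm, layout coordinates).
#' @param speed optional speeds (cm/s).
#' @return a `linearized_position` data.frame.
#' @export
linearized_from_1d <- function(track, time_s, linear_position, speed = NULL) {
  stopifnot(inherits(track, "track_graph"))
  p2 <- linear_to_2d(track, linear_position)
  if (is.null(speed)) {
    dt <- stats::median(diff(time_s))
    speed <- abs(gaussian_smooth(gradient1d(linear_position, dt),
                                 sd = max(1, 0.1 / dt)))
  }
  out <- data.frame(time_s = time_s, segment_id = p2$edge_id,
                    linear_position = linear_position,
                    x_proj = p2$x, y_proj = p2$y,
                    valid = !is.na(p2$edge_id), speed = speed)
  class(out) <- c("linearized_position", "data.frame")
  attr(out, "track") <- track
  out
}

# ---- position grids ------------------------------------------------------

#' Discretize a track graph into 1D position bins
#'
#' Each edge is partitioned into bins no wider than `bin_size`, anchored at
#' the edge's `from` node (the final bin of an edge may be narrower). Bin
#' centers are inserted as nodes into the track graph and all-pairs shortest
#' path distances between bin centers are computed.
#'
#' @param track a [track_graph()].
#' @param bin_size maximum bin width in cm (default 3).
#' @return object of class `position_grid` with fields `bin_centers` (1D
#'   layout cm), `widths`, `edge_id`, `centers_2d`, `graph_distance`
#'   (n_bins x n_bins cm), `bin_size`, `kind = "1d"`, `track`.
#' @export
make_grid_1d <- function(track, bin_size = 3) {
  stopifnot(inherits(track, "track_graph"))
  check_positive(bin_size, "bin_size")
  e <- track$edges
  bins <- do.call(rbind, lapply(seq_len(nrow(e)), function(j) {
    n <- ceiling(e$length[j] / bin_size - 1e-9)
    w <- rep(bin_size, n)
    w[n] <- e$length[j] - (n - 1L) * bin_size
    start <- c(0, cumsum(w))[seq_len(n)]
    data.frame(edge_id = j, offset = start + w / 2, width = w,
               start_offset = start)
  }))
  nb <- nrow(bins)
  centers_1d <- e$start_1d[bins$edge_id] + bins$offset
  # augmented graph: original nodes 1..nn, bin centers nn+1..nn+nb
  nn <- nrow(track$nodes)
  ef <- list(); k <- 1L
  for (j in seq_len(nrow(e))) {
    idx <- which(bins$edge_id == j)
    off <- bins$offset[idx]
    ids <- nn + idx
    chain_from <- c(e$from[j], ids)
    chain_to <- c(ids, e$to[j])
    wts <- c(off[1L], diff(off), e$length[j] - off[length(off)])
    ef[[k]] <- data.frame(from = chain_from, to = chain_to, weight = wts)
    k <- k + 1L
  }
  ef <- do.call(rbind, ef)
  g <- igraph::graph_from_data_frame(ef, directed = FALSE,
                                     vertices = data.frame(name = seq_len(nn + nb)))
  d <- igraph::distances(g)
  ord <- order(as.integer(igraph::V(g)$name))
  d <- d[ord, ord, drop = FALSE]
  gd <- d[nn + seq_len(nb), nn + seq_len(nb), drop = FALSE]
  dimnames(gd) <- NULL
  frac <- bins$offset / e$length[bins$edge_id]
  centers_2d <- cbind(
    x = track$nodes$x[e$from[bins$edge_id]] + frac *
      (track$nodes$x[e$to[bins$edge_id]] - track$nodes$x[e$from[bins$edge_id]]),
    y = track$nodes$y[e$from[bins$edge_id]] + frac *
      (track$nodes$y[e$to[bins$edge_id]] - track$nodes$y[e$from[bins$edge_id]]))
  structure(list(bin_centers = centers_1d, widths = bins$width,
                 edge_id = bins$edge_id, edge_offset = bins$offset,
                 centers_2d = centers_2d, graph_distance = gd,
                 bin_size = bin_size, kind = "1d", track = track),
            class = "position_grid")
}

#' @export
print.position_grid <- function(x, ...) {
  cat(sprintf("Position grid (%s): %d bins of <= %g cm\n",
              x$kind, length(x$widths), x$bin_size))
  invisible(x)
}

#' Morphological opening of a logical matrix (4-connected cross kernel)
#'
#' Erosion treats off-grid neighbors as occupied (so an occupancy mask that
#' fills the grid is left intact) while dilation treats them as empty;
#' isolated occupied bins are still removed.
#' @noRd
morph_open <- function(m) {
  pad <- function(mm, fill) {
    out <- matrix(fill, nrow(mm) + 2L, ncol(mm) + 2L)
    out[2:(nrow(mm) + 1L), 2:(ncol(mm) + 1L)] <- mm
    out
  }
  shift4 <- function(mm, f, fill) {
    p <- pad(mm, fill); nr <- nrow(mm); nc <- ncol(mm)
    ctr <- p[2:(nr + 1L), 2:(nc + 1L)]
    up <- p[1:nr, 2:(nc + 1L)]; dn <- p[3:(nr + 2L), 2:(nc + 1L)]
    lf <- p[2:(nr + 1L), 1:nc]; rt <- p[2:(nr + 1L), 3:(nc + 2L)]
    f(ctr, up, dn, lf, rt)
  }
  er <- shift4(m, function(c, u, d, l, r) c & u & d & l & r, TRUE)
  shift4(er, function(c, u, d, l, r) c | u | d | l | r, FALSE)
}

#' Discretize occupied 2D space into a grid
#'
#' Bins the occupied 2D positions with square bins of `bin_size`, applies a
#' morphological opening to remove isolated occupied bins / holes smaller
#' than the bin size, and computes shortest-path distances on the
#' 4-connected adjacency graph of valid bins.
#'
#' @param xy matrix/data.frame of occupied 2D positions (cm).
#' @param bin_size bin width and height in cm (default 3).
#' @return object of class `position_grid` with `kind = "2d"`, fields
#'   `centers_2d`, `widths` (bin areas are `bin_size^2`; widths here are the
#'   linear bin size used for Riemann sums), `valid_mask`, `graph_distance`.
#' @export
make_grid_2d <- function(xy, bin_size = 3) {
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  xy <- xy[complete.cases(xy), , drop = FALSE]
  if (nrow(xy) < 1L) stop_param("need at least one 2D position")
  check_positive(bin_size, "bin_size")
  x0 <- floor(min(xy[, 1L]) / bin_size) * bin_size
  y0 <- floor(min(xy[, 2L]) / bin_size) * bin_size
  nx <- max(1L, ceiling((max(xy[, 1L]) - x0) / bin_size + 1e-9))
  ny <- max(1L, ceiling((max(xy[, 2L]) - y0) / bin_size + 1e-9))
  ix <- pmin(pmax(floor((xy[, 1L] - x0) / bin_size) + 1L, 1L), nx)
  iy <- pmin(pmax(floor((xy[, 2L] - y0) / bin_size) + 1L, 1L), ny)
  mask <- matrix(FALSE, nx, ny)
  mask[cbind(ix, iy)] <- TRUE
  opened <- morph_open(mask)
  if (!any(opened)) opened <- mask  # degenerate occupancy: keep raw bins
  idx <- which(opened, arr.ind = TRUE)
  nb <- nrow(idx)
  centers_2d <- cbind(x = x0 + (idx[, 1L] - 0.5) * bin_size,
                      y = y0 + (idx[, 2L] - 0.5) * bin_size)
  id_of <- matrix(NA_integer_, nx, ny)
  id_of[idx] <- seq_len(nb)
  ef <- list(); k <- 1L
  for (b in seq_len(nb)) {
    r <- idx[b, 1L]; c <- idx[b, 2L]
    if (r < nx && !is.na(id_of[r + 1L, c]))
      { ef[[k]] <- c(b, id_of[r + 1L, c]); k <- k + 1L }
    if (c < ny && !is.na(id_of[r, c + 1L]))
      { ef[[k]] <- c(b, id_of[r, c + 1L]); k <- k + 1L }
  }
  if (length(ef)) {
    em <- do.call(rbind, ef)
    g <- igraph::graph_from_data_frame(
      data.frame(from = em[, 1L], to = em[, 2L], weight = bin_size),
      directed = FALSE, vertices = data.frame(name = seq_len(nb)))
    d <- igraph::distances(g)
    ord <- order(as.integer(igraph::V(g)$name))
    gd <- d[ord, ord, drop = FALSE]
    dimnames(gd) <- NULL
  } else gd <- matrix(0, nb, nb)
  structure(list(bin_centers = seq_len(nb), widths = rep(bin_size, nb),
                 centers_2d = centers_2d, valid_mask = opened,
                 graph_distance = gd, bin_size = bin_size, kind = "2d",
                 origin = c(x0, y0), dims = c(nx, ny)),
            class = "position_grid")
}

#' Distance along the track between a decoded bin and the animal
#'
#' Projects the animal's 2D position onto the track graph and returns the
#' shortest-path distance (cm) to the decoded bin's center. Distances of at
#' least 30 cm mark a non-local representation.
#'
#' @param grid a 1D [make_grid_1d()] grid.
#' @param decoded_bin bin index (may be a vector).
#' @param animal_xy length-2 numeric 2D position of the animal (cm).
#' @param max_project maximum allowed point-to-track distance before the
#'   position is flagged unprojectable (default 30 cm).
#' @return distances in cm (NA if unprojectable).
#' @export
distance_from_animal <- function(grid, decoded_bin, animal_xy,
                                 max_project = 30) {
  stopifnot(inherits(grid, "position_grid"))
  if (grid$kind != "1d") stop_param("distance_from_animal needs a 1D grid")
  track <- grid$track
  pr <- project_all_edges(track, as.numeric(animal_xy))
  e <- which.min(pr$dist)
  if (pr$dist[e] > max_project) {
    warning("animal position too far from every track segment; flagged NA")
    return(rep(NA_real_, length(decoded_bin)))
  }
  if (any(decoded_bin < 1L | decoded_bin > length(grid$bin_centers)))
    stop_param("decoded bin index out of range")
  vapply(decoded_bin, function(b)
    track_point_distance(track, e, pr$offset[e],
                         grid$edge_id[b], grid$edge_offset[b]),
    numeric(1))
}
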