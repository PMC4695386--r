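# Track geometry: linearization, along-track distances, candidate replay
# paths, and reward regions.
#
# A track is a set of directed segments with a global linear coordinate
# formed by adjoining them. The end-to-end T-maze ("swm") has 5 segments
# adjoined in the order force reward sites -> force point -> choice point ->
# choice reward sites; the linear track has one. Both graphs are trees, so
# the along-track distance between any two points is the length of the
# unique node path between them.

#' Construct a track
#'
#' @param type `"linear"` (single 200 cm segment, reward well at each end)
#'   or `"swm"` (end-to-end T-maze: two force arms, central arm, two choice
#'   arms; four reward wells).
#' @param length_cm linear track length (cm).
#' @param arm_cm segment length for the SWM maze (cm); individual
#'   reward-to-reward trajectories are `3 * arm_cm`.
#' @param bin_width spatial bin width (cm), default 10.
#' @param reward_halfwidth_cm reward region half-width around each well (cm).
#' @return an object of class `track`.
#' @export
make_track <- function(type = c("linear", "swm"), length_cm = 200,
                       arm_cm = 100, bin_width = 10,
                       reward_halfwidth_cm = 10) {
  type <- match.arg(type)
  if (length_cm <= 0 || arm_cm <= 0 || bin_width <= 0)
    stop("make_track: invalid geometry")
  if (type == "linear") {
    segs <- data.frame(id = 1L, from = "A", to = "B", length = length_cm,
                       x0 = 0, y0 = 0, x1 = length_cm, y1 = 0)
    nodes <- c("A", "B")
    wells <- data.frame(node = c("A", "B"), global = c(0, length_cm))
    paths <- list(list(id = "full", segs = 1L, dirs = 1L, length = length_cm))
  } else {
    a <- arm_cm
    segs <- data.frame(
      id = 1:5,
      from = c("R3", "R4", "fp", "cp", "cp"),
      to   = c("fp", "fp", "cp", "R1", "R2"),
      length = rep(a, 5),
      x0 = c(0, 2 * a, a, a, a), y0 = c(0, 0, 0, a, a),
      x1 = c(a, a, a, 0, 2 * a), y1 = c(0, 0, a, a, a))
    nodes <- c("R3", "R4", "fp", "cp", "R1", "R2")
    # R1 sits at the end of segment 4; nudge inside the segment so the
    # global coordinate does not resolve to the start of segment 5 (cp)
    wells <- data.frame(node = c("R3", "R4", "R1", "R2"),
                        global = c(0, a, 4 * a - 1e-9, 5 * a))
    path_def <- list(
      c("f3c4" = NA, s1 = 1L, s2 = 3L, s3 = 4L),  # R3 -> fp -> cp -> R1
      c(s1 = 1L, s2 = 3L, s3 = 5L),               # R3 -> R2
      c(s1 = 2L, s2 = 3L, s3 = 4L),               # R4 -> R1
      c(s1 = 2L, s2 = 3L, s3 = 5L))               # R4 -> R2
    paths <- lapply(seq_along(path_def), function(i) {
      ss <- unname(path_def[[i]][!is.na(path_def[[i]])])
      list(id = c("R3-R1", "R3-R2", "R4-R1", "R4-R2")[i],
           segs = ss, dirs = rep(1L, length(ss)), length = 3 * a)
    })
  }
  seg_start <- cumsum(c(0, segs$length[-nrow(segs)]))
  total <- sum(segs$length)
  tr <- structure(list(type = type, segments = segs, seg_start = seg_start,
                       nodes = nodes, wells = wells, paths = paths,
                       total_cm = total, bin_width = bin_width,
                       reward_halfwidth = reward_halfwidth_cm),
                  class = "track")
  tr$node_dist <- node_distance_matrix(tr)
  tr
}

# All-pairs node distances on the segment graph (Floyd-Warshall; the graphs
# are tiny). Kept independent of igraph, which the tests use as an oracle.
node_distance_matrix <- function(track) {
  nn <- track$nodes
  D <- matrix(Inf, length(nn), length(nn), dimnames = list(nn, nn))
  diag(D) <- 0
  for (i in seq_len(nrow(track$segments))) {
    s <- track$segments[i, ]
    D[s$from, s$to] <- min(D[s$from, s$to], s$length)
    D[s$to, s$from] <- D[s$from, s$to]
  }
  for (k in nn) for (i in nn) for (j in nn)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

#' Segment and offset of a global linear coordinate
#' @keywords internal
global_to_seg <- function(track, g) {
  g <- pmin(pmax(g, 0), track$total_cm - 1e-9)
  si <- findInterval(g, track$seg_start, rightmost.closed = FALSE)
  list(seg = si, off = g - track$seg_start[si])
}

#' Along-track distance between global linear coordinates
#'
#' Distances respect the track graph: points on different arms are separated
#' by the path through the junctions, not by naive subtraction of linear
#' coordinates.
#'
#' @param track a `track`.
#' @param a,b numeric global linear coordinates (cm), recycled.
#' @return numeric distances (cm).
#' @export
track_distance <- function(track, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  pa <- global_to_seg(track, a); pb <- global_to_seg(track, b)
  segs <- track$segments
  f <- match(segs$from, track$nodes); t2 <- match(segs$to, track$nodes)
  nd <- track$node_dist
  f1 <- f[pa$seg]; t1 <- t2[pa$seg]; f2 <- f[pb$seg]; tb <- t2[pb$seg]
  df1 <- pa$off; dt1 <- segs$length[pa$seg] - pa$off
  df2 <- pb$off; dtb <- segs$length[pb$seg] - pb$off
  out <- pmin(df1 + nd[cbind(f1, f2)] + df2,
              df1 + nd[cbind(f1, tb)] + dtb,
              dt1 + nd[cbind(t1, f2)] + df2,
              dt1 + nd[cbind(t1, tb)] + dtb)
  same <- pa$seg == pb$seg
  out[same] <- pmin(out[same], abs(pa$off[same] - pb$off[same]))
  out
}

#' Spatial bins of a track
#' @param track a `track`.
#' @return data frame with `bin` (0-based index), `center` (global cm),
#'   `reward` (logical: center within a reward region).
#' @export
track_bins <- function(track) {
  S <- ceiling(track$total_cm / track$bin_width)
  centers <- (seq_len(S) - 0.5) * track$bin_width
  rw <- reward_region_mask(track, centers)
  data.frame(bin = seq_len(S) - 1L, center = centers, reward = rw)
}

#' Reward-region membership of positions
#' @param track a `track`.
#' @param g global linear coordinates (cm).
#' @return logical vector: within `reward_halfwidth` of a reward well
#'   (along-track distance).
#' @export
reward_region_mask <- function(track, g) {
  m <- rep(FALSE, length(g))
  for (w in track$wells$global)
    m <- m | track_distance(track, g, w) <= track$reward_halfwidth
  m
}

#' Map path coordinate to global linear coordinate
#' @param track a `track`; `path_id` index into `track$paths`.
#' @param s path coordinate (cm from path start); values outside the path
#'   are clamped.
#' @export
path_to_global <- function(track, path_id, s) {
  p <- track$paths[[path_id]]
  lens <- track$segments$length[p$segs]
  cum <- cumsum(c(0, lens))
  s <- pmin(pmax(s, 0), p$length - 1e-9)
  k <- findInterval(s, cum, rightmost.closed = FALSE)
  local <- s - cum[k]
  seg <- p$segs[k]
  off <- ifelse(p$dirs[k] > 0, local, lens[k] - local)
  track$seg_start[seg] + off
}

#' Project 2-D positions onto the track (linearize)
#'
#' Each sample is projected to the nearest point on any segment. Samples
#' farther than `tolerance` from the track are flagged and replaced by
#' linear interpolation of neighboring on-track coordinates.
#'
#' @param track a `track`.
#' @param xy two-column matrix of positions (cm).
#' @param tolerance off-track distance flag threshold (cm).
#' @return list with `linear` (global cm), `off_track` (logical),
#'   `dist` (projection residual, cm).
#' @export
linearize <- function(track, xy, tolerance = 5) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  best_d <- rep(Inf, n); best_g <- numeric(n)
  for (i in seq_len(nrow(track$segments))) {
    s <- track$segments[i, ]
    vx <- s$x1 - s$x0; vy <- s$y1 - s$y0
    L2 <- vx^2 + vy^2
    tproj <- pmin(pmax(((xy[, 1] - s$x0) * vx + (xy[, 2] - s$y0) * vy) / L2, 0), 1)
    px <- s$x0 + tproj * vx; py <- s$y0 + tproj * vy
    d <- sqrt((xy[, 1] - px)^2 + (xy[, 2] - py)^2)
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_g[upd] <- track$seg_start[i] + tproj[upd] * s$length
  }
  off <- best_d > tolerance
  if (any(off)) {
    ok <- which(!off)
    if (length(ok) >= 2L)
      best_g[off] <- stats::approx(ok, best_g[ok], xout = which(off),
                                   rule = 2)$y
  }
  list(linear = best_g, off_track = off, dist = best_d)
}
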