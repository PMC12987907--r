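#' Extract the centreline of a semicircular-canal mesh
#'
#' Voxelizes the canal lumen on a regular grid (`voxel_pitch`, default
#' 0.1 mm), computes the medial path through the interior -- voxels weighted
#' by their distance to the canal wall, endpoints found as the geodesically
#' farthest voxel pair, path by Dijkstra through the 26-connected voxel graph
#' -- and smooths it into an arc-length-parameterized spline curve.
#'
#' @param canal a closed `scc_mesh` of one canal.
#' @param voxel_pitch voxelization pitch in mm.
#' @param resample_step spacing of the returned samples (mm, <= 0.2).
#' @param smooth_sigma Gaussian smoothing bandwidth along the path (mm).
#' @return A `centreline` tibble with columns `s` (arc length from one end,
#'   mm), `x`, `y`, `z` and unit tangents `tx`, `ty`, `tz`.
#' @export
extract_centreline <- function(canal, voxel_pitch = 0.1, resample_step = 0.1,
                               smooth_sigma = 0.25) {
  bb <- mesh_bounds(canal)
  xs <- seq(bb[1, 1] - voxel_pitch, bb[2, 1] + voxel_pitch, by = voxel_pitch)
  ys <- seq(bb[1, 2] - voxel_pitch, bb[2, 2] + voxel_pitch, by = voxel_pitch)
  zs <- seq(bb[1, 3] - voxel_pitch, bb[2, 3] + voxel_pitch, by = voxel_pitch)
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dist <- mesh_distance(canal, g, signed = TRUE)$distance
  inside <- dist < 0
  if (!any(inside)) stop("voxelization produced no interior voxels")
  dims <- c(length(xs), length(ys), length(zs))
  idx <- which(inside)
  depth <- -dist[idx]                    # distance to the canal wall
  # 26-neighbourhood adjacency among interior voxels
  key <- integer(prod(dims))
  key[idx] <- seq_along(idx)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
                (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  ii <- (idx - 1) %% dims[1]
  jj <- ((idx - 1) %/% dims[1]) %% dims[2]
  kk <- (idx - 1) %/% (dims[1] * dims[2])
  ef <- list(); et <- list(); ew <- list()
  for (o in seq_len(nrow(offs))) {
    ni <- ii + offs[o, 1]; nj <- jj + offs[o, 2]; nk <- kk + offs[o, 3]
    ok <- ni >= 0 & ni < dims[1] & nj >= 0 & nj < dims[2] & nk >= 0 & nk < dims[3]
    nidx <- ni[ok] + nj[ok] * dims[1] + nk[ok] * dims[1] * dims[2] + 1
    to <- key[nidx]
    from <- seq_along(idx)[ok]
    keep <- to > 0
    len <- sqrt(sum(offs[o, ]^2)) * voxel_pitch
    ef[[o]] <- from[keep]; et[[o]] <- to[keep]
    dmid <- (depth[from[keep]] + depth[to[keep]]) / 2
    ew[[o]] <- len / (dmid + 0.05)^2     # medial penalty: hug the deep axis
  }
  ef <- unlist(ef); et <- unlist(et); ew <- unlist(ew)
  gr <- igraph::graph_from_edgelist(cbind(ef, et), directed = FALSE)
  gr <- igraph::set_edge_attr(gr, "weight", value = ew)
  if (igraph::vcount(gr) < length(idx))
    gr <- igraph::add_vertices(gr, length(idx) - igraph::vcount(gr))
  comp <- igraph::components(gr)
  main <- which.max(comp$csize)
  if (comp$csize[main] < 0.5 * length(idx))
    stop("no dominant connected lumen component; canal topology is broken")
  sub <- which(comp$membership == main)
  # geodesic endpoints by two sweeps (unit path lengths)
  d0 <- igraph::distances(gr, v = sub[1], to = sub, weights = NA)
  e1 <- sub[which.max(d0)]
  d1 <- igraph::distances(gr, v = e1, to = sub, weights = NA)
  e2 <- sub[which.max(d1)]
  # the farthest voxels sit on the end-cap rim; snap each endpoint to the
  # deepest (most medial) voxel in its Euclidean neighbourhood
  snap <- function(e) {
    p <- g[idx[e], ]
    near <- which(sqrt(rowSums(sweep(g[idx, , drop = FALSE], 2, p, "-")^2)) <
                  max(5 * voxel_pitch, 0.5))
    near <- intersect(near, sub)
    near[which.max(depth[near])]
  }
  e1 <- snap(e1); e2 <- snap(e2)
  path <- igraph::shortest_paths(gr, from = e1, to = e2)$vpath[[1]]
  pv <- g[idx[as.integer(path)], , drop = FALSE]
  if (nrow(pv) < 4) stop("medial path degenerate")
  # Gaussian kernel smoothing along the path, then spline resampling
  s <- c(0, cumsum(sqrt(rowSums(diff(pv)^2))))
  w <- exp(-outer(s, s, "-")^2 / (2 * smooth_sigma^2))
  sm <- (w %*% pv) / rowSums(w)
  # extend both ends to the end-cap surface (the medial endpoints sit roughly
  # half a lumen radius inside the caps); quadratic extrapolation follows the
  # local curvature instead of overshooting tangentially
  extend_end <- function(sm, head_end) {
    ss <- c(0, cumsum(sqrt(rowSums(diff(sm)^2))))
    if (head_end) { sel <- which(ss <= ss[1] + 2); sgn <- -1; s0 <- ss[1] }
    else { sel <- which(ss >= ss[length(ss)] - 2); sgn <- 1; s0 <- ss[length(ss)] }
    if (length(sel) < 5) return(sm)
    X <- cbind(1, ss[sel] - s0, (ss[sel] - s0)^2)
    beta <- qr.solve(X, sm[sel, , drop = FALSE])
    steps <- sgn * seq(0.1, 1.2, by = 0.1)
    ext <- cbind(1, steps, steps^2) %*% beta
    d <- mesh_distance(canal, ext, signed = TRUE)$distance
    k <- which(d >= -1e-3)[1]
    if (is.na(k)) return(sm) # no cap crossing found; leave the end alone
    ext <- ext[seq_len(k), , drop = FALSE]
    if (head_end) rbind(ext[rev(seq_len(nrow(ext))), , drop = FALSE], sm)
    else rbind(sm, ext)
  }
  sm <- extend_end(extend_end(sm, TRUE), FALSE)
  s2 <- c(0, cumsum(sqrt(rowSums(diff(sm)^2))))
  n_out <- max(4, ceiling(s2[length(s2)] / resample_step) + 1)
  ss <- seq(0, s2[length(s2)], length.out = n_out)
  out <- sapply(1:3, function(j) spline(s2, sm[, j], xout = ss, method = "natural")$y)
  s3 <- c(0, cumsum(sqrt(rowSums(diff(out)^2))))
  # symmetric-difference tangents over a ~0.5 mm window: unbiased on circular
  # arcs, and robust to residual sub-voxel wiggle of the medial path
  n <- nrow(out)
  k <- max(1L, min(round(0.5 / max(mean(diff(s3)), 1e-9)), (n - 1) %/% 2))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  tg <- out[hi, , drop = FALSE] - out[lo, , drop = FALSE]
  tg <- tg / sqrt(rowSums(tg^2))
  structure(tibble::tibble(s = s3, x = out[, 1], y = out[, 2], z = out[, 3],
                           tx = tg[, 1], ty = tg[, 2], tz = tg[, 3]),
            class = c("centreline", class(tibble::tibble())))
}

centreline_total_length <- function(centreline) centreline$s[nrow(centreline)]

# linear interpolation of position and tangent at arc length s
centreline_at <- function(centreline, s) {
  p <- sapply(c("x", "y", "z"), function(cc) approx(centreline$s, centreline[[cc]],
                                                    xout = s, rule = 2)$y)
  tg <- sapply(c("tx", "ty", "tz"), function(cc) approx(centreline$s, centreline[[cc]],
                                                        xout = s, rule = 2)$y)
  list(point = unname(p), tangent = unname(tg / sqrt(sum(tg^2))))
}

#' Place the electrode target and fenestration site on a canal centreline
#'
#' The electrode target is the centreline point closest to the annotated
#' nerve-stimulation target; the fenestration site lies `fenestration_offset`
#' mm from it along the centreline, in the direction away from the ampullary
#' end (the end nearer the nerve target). The returned tangent points from
#' the fenestration site towards the electrode target (ampulla-directed).
#'
#' @param centreline a [extract_centreline()] result.
#' @param nerve_target length-3 point (mm).
#' @param fenestration_offset arc-length offset in mm (default 2).
#' @return A `canal_targets` list: `electrode_target`, `fenestration_site`,
#'   `tangent`, `offset`, and the arc positions `s_electrode`,
#'   `s_fenestration`.
#' @export
locate_targets <- function(centreline, nerve_target, fenestration_offset = 2) {
  if (fenestration_offset < 0) stop("`fenestration_offset` must be >= 0")
  L <- centreline_total_length(centreline)
  if (fenestration_offset >= L)
    stop("fenestration offset exceeds the canal arc length")
  p <- cbind(centreline$x, centreline$y, centreline$z)
  d2 <- rowSums(sweep(p, 2, as.double(nerve_target), "-")^2)
  ie <- which.min(d2)
  s_e <- centreline$s[ie]
  # ampullary end: the centreline end nearer the nerve target
  amp_at_start <- s_e <= L - s_e
  s_f <- if (amp_at_start) s_e + fenestration_offset else s_e - fenestration_offset
  if (s_f < 0 || s_f > L)
    stop("fenestration offset exceeds the remaining arc length")
  fen <- centreline_at(centreline, s_f)
  tangent <- fen$tangent * if (s_e >= s_f) 1 else -1
  structure(list(electrode_target = p[ie, ], fenestration_site = fen$point,
                 tangent = tangent, offset = fenestration_offset,
                 s_electrode = s_e, s_fenestration = s_f,
                 ampulla_at_start = amp_at_start),
            class = "canal_targets")
}
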