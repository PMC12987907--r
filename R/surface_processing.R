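#' Extract the sub-mesh whose faces are kept
#' @param mesh a `scc_mesh`.
#' @param faces_keep integer or logical index of faces to keep.
#' @return a `scc_mesh` with unused vertices dropped.
#' @export
mesh_subset <- function(mesh, faces_keep) {
  f <- mesh$faces[faces_keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  mesh_new(mesh$vertices[used, , drop = FALSE],
           matrix(remap[f], ncol = 3))
}

#' Crop a temporal-bone mesh to the region of interest
#'
#' Keeps the faces inside a vertical triangular prism (equilateral footprint
#' in the axial plane, unbounded vertically) centred near the region of
#' interest, standardizing mesh extent across cases.
#'
#' @param temporal_bone a `scc_mesh`.
#' @param inner_ear_centre length-3 point (mm).
#' @param circumradius circumradius of the triangular footprint (mm).
#' @param center_offset offset of the prism centre from the inner-ear centre.
#' @return the cropped `scc_mesh`.
#' @export
crop_roi <- function(temporal_bone, inner_ear_centre,
                     circumradius = 60, center_offset = c(0, -10, 0)) {
  bb <- mesh_bounds(temporal_bone)
  if (nrow(temporal_bone$faces) == 0) stop("empty mesh")
  if (any(inner_ear_centre < bb["lo", ] - 1e-9) ||
      any(inner_ear_centre > bb["hi", ] + 1e-9))
    stop("inner-ear centre outside the mesh bounding box")
  ctr <- inner_ear_centre[1:2] + center_offset[1:2]
  ang <- c(90, 210, 330) * pi / 180
  tri <- cbind(ctr[1] + circumradius * cos(ang), ctr[2] + circumradius * sin(ang))
  inside <- rep(TRUE, nrow(temporal_bone$vertices))
  for (e in 1:3) {
    a <- tri[e, ]; b <- tri[e %% 3 + 1, ]
    edge <- b - a
    nrm <- c(-edge[2], edge[1])           # rotate 90 degrees
    if (sum(nrm * (ctr - a)) < 0) nrm <- -nrm # point inward
    inside <- inside &
      ((temporal_bone$vertices[, 1] - a[1]) * nrm[1] +
       (temporal_bone$vertices[, 2] - a[2]) * nrm[2] >= 0)
  }
  keep <- inside[temporal_bone$faces[, 1]] & inside[temporal_bone$faces[, 2]] &
    inside[temporal_bone$faces[, 3]]
  if (!any(keep)) stop("region-of-interest prism does not intersect the mesh")
  mesh_subset(temporal_bone, keep)
}

# vertex 1-ring neighbour averaging (uniform Laplacian), vectorized
laplacian_smooth <- function(vertices, faces, lambda = 0.5) {
  idx <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)],
               faces[, c(2, 1)], faces[, c(3, 2)], faces[, c(1, 3)])
  sums <- rowsum(vertices[idx[, 2], , drop = FALSE], idx[, 1])
  cnt <- as.vector(rowsum(rep(1, nrow(idx)), idx[, 1]))
  at <- as.integer(rownames(sums))
  out <- vertices
  out[at, ] <- (1 - lambda) * vertices[at, , drop = FALSE] + lambda * sums / cnt
  out
}

# one global 1-to-4 midpoint subdivision
subdivide_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  ukey <- unique(ekey)
  mid_id <- nrow(v) + match(ekey, ukey)
  ue <- edges[!duplicated(ekey), , drop = FALSE]
  v <- rbind(v, (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2)
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m31 <- mid_id[2 * nf + seq_len(nf)]
  mesh_new(v, rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
                    cbind(f[, 3], m31, m23), cbind(m12, m23, m31)))
}

#' Extract the cavity-free outer surface of a bone mesh
#'
#' Shrink-wraps the bone with an enclosing sphere mesh: iterated tangential
#' relaxation towards uniform vertex spacing followed by projection of every
#' vertex onto the nearest point of the original surface, until the maximum
#' per-iteration vertex displacement falls below `tol`. Because projection
#' always proceeds from outside, interior cavities (mastoid air cells, carved
#' channels) are excluded. The wrap is subdivided until the median face area
#' is within a factor 2 of `target_face_area`.
#'
#' @param temporal_bone a `scc_mesh`.
#' @param target_face_area target face area in mm^2.
#' @param tol convergence tolerance on the max vertex displacement (mm).
#' @param max_iter iteration cap per resolution level.
#' @return a `scc_mesh`; attribute `"displacement_trace"` records the max
#'   displacement per iteration of the final level.
#' @export
extract_outer_surface <- function(temporal_bone, target_face_area = 0.1,
                                  tol = 0.02, max_iter = 50) {
  if (nrow(temporal_bone$faces) == 0) stop("empty mesh")
  ctr <- colMeans(temporal_bone$vertices)
  rad <- 1.05 * sqrt(max(rowSums(sweep(temporal_bone$vertices, 2, ctr, "-")^2)))
  wrap <- mesh_icosphere(3, radius = rad, center = ctr)
  repeat {
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      # annealed tangential relaxation: strong early uniformization, then a
      # contracting step size so the relax/project cycle reaches a fixed point
      lambda <- 0.5 * 0.7^(it - 1)
      sm <- laplacian_smooth(wrap$vertices, wrap$faces, lambda = lambda)
      prj <- mesh_distance(temporal_bone, sm)$closest
      disp <- max(sqrt(rowSums((prj - wrap$vertices)^2)))
      wrap$vertices <- prj
      trace <- c(trace, disp)
      if (disp < tol) break
    }
    if (trace[length(trace)] >= tol)
      stop(sprintf("outer-surface extraction did not converge: last displacement %.4f mm",
                   trace[length(trace)]))
    if (median(face_areas(wrap)) <= 2 * target_face_area) break
    wrap <- subdivide_mesh(wrap)
  }
  attr(wrap, "displacement_trace") <- trace
  wrap
}

# faces connected to `seed_face` through shared edges, within `candidate` set
connected_faces <- function(mesh, seed_face, candidate) {
  cand <- which(candidate)
  if (!(seed_face %in% cand)) return(integer(0))
  f <- mesh$faces[cand, , drop = FALSE]
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  fid <- rep(seq_along(cand), 3)
  grp <- split(fid, ekey)
  pairs <- do.call(rbind, lapply(grp[lengths(grp) > 1], function(g)
    cbind(g[-length(g)], g[-1])))
  g <- igraph::graph_from_edgelist(
    rbind(pairs, cbind(seq_along(cand), seq_along(cand))), directed = FALSE)
  comp <- igraph::components(g)$membership
  cand[comp == comp[match(seed_face, cand)]]
}

#' Extract the lateral skull base from a temporal-bone mesh
#'
#' Casts a ray straight superior from the inner-ear centre, takes the first
#' face it hits, and floods outward across shared edges over all
#' superior-facing faces (normal within `max_normal_angle` of vertical) whose
#' centroids lie inside a bounding box around the region of interest.
#'
#' @param temporal_bone a `scc_mesh`.
#' @param inner_ear_centre length-3 point (mm).
#' @param roi_box 2 x 3 matrix (rows lo, hi) clipping box; default the
#'   inner-ear centre +/- (20, 25, 30) mm with the floor at the centre.
#' @param max_normal_angle maximum angle (degrees) between a face normal and
#'   the superior axis.
#' @return the skull-base `scc_mesh` (one edge-connected component).
#' @export
extract_skull_base <- function(temporal_bone, inner_ear_centre, roi_box = NULL,
                               max_normal_angle = 60) {
  if (is.null(roi_box))
    roi_box <- rbind(lo = inner_ear_centre + c(-20, -25, 0),
                     hi = inner_ear_centre + c(20, 25, 30))
  hit <- mesh_raycast(temporal_bone, rbind(inner_ear_centre), rbind(c(0, 0, 1)))
  if (is.na(hit$face[1])) stop("no face directly superior to the inner-ear centre")
  n <- face_normals(temporal_bone)
  cen <- face_centroids(temporal_bone)
  candidate <- n[, 3] >= cos(max_normal_angle * pi / 180) &
    cen[, 1] >= roi_box[1, 1] & cen[, 1] <= roi_box[2, 1] &
    cen[, 2] >= roi_box[1, 2] & cen[, 2] <= roi_box[2, 2] &
    cen[, 3] >= roi_box[1, 3] & cen[, 3] <= roi_box[2, 3]
  candidate[hit$face[1]] <- TRUE
  keep <- connected_faces(temporal_bone, hit$face[1], candidate)
  mesh_subset(temporal_bone, keep)
}

# quasi-uniform directions on the unit sphere (Fibonacci lattice)
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Bounding surface of the sigmoid sinus
#'
#' From samples along the sinus centreline, casts rays uniformly in all
#' directions, intersects them with the temporal-bone surface, and
#' reconstructs a bounding surface of the hit-point cloud: morphological
#' closing with a ball of radius `1/alpha`, isosurfaced on a regular grid.
#' For the tube-like clouds this produces, the result matches an alpha-shape
#' hull with shape parameter `alpha` at the tolerances used downstream.
#'
#' @param sinus_centreline ordered centreline points (k x 3 matrix, mm).
#' @param temporal_bone a `scc_mesh` containing the sinus channel.
#' @param alpha shape parameter (1/mm); the closing ball radius is `1/alpha`.
#' @param n_dirs rays per centreline sample.
#' @param sample_step centreline resampling step (mm).
#' @param grid_pitch reconstruction grid pitch (mm).
#' @return a closed `scc_mesh` enclosing the centreline; attribute
#'   `"hit_points"` holds the ray-hit cloud.
#' @export
build_sigmoid_surface <- function(sinus_centreline, temporal_bone, alpha = 0.1,
                                  n_dirs = 256, sample_step = 0.5,
                                  grid_pitch = 0.7) {
  sinus_centreline <- as.matrix(sinus_centreline)
  if (nrow(sinus_centreline) < 2) stop("centreline needs at least 2 points")
  r_ball <- 1 / alpha
  samples <- resample_polyline(sinus_centreline, sample_step)
  dirs <- fibonacci_directions(n_dirs)
  # only bone faces near the channel can be hit: prefilter for speed
  pad <- r_ball + 3
  lo <- apply(samples, 2, min) - pad
  hi <- apply(samples, 2, max) + pad
  cen <- face_centroids(temporal_bone)
  nearby <- cen[, 1] > lo[1] & cen[, 1] < hi[1] & cen[, 2] > lo[2] &
    cen[, 2] < hi[2] & cen[, 3] > lo[3] & cen[, 3] < hi[3]
  bone <- mesh_subset(temporal_bone, nearby)
  o <- samples[rep(seq_len(nrow(samples)), each = n_dirs), , drop = FALSE]
  d <- dirs[rep(seq_len(n_dirs), times = nrow(samples)), , drop = FALSE]
  hit <- mesh_raycast(bone, o, d)
  pts <- hit$point[!is.na(hit$t), , drop = FALSE]
  if (nrow(pts) < 4) stop("fewer than 4 ray hits; cannot reconstruct surface")

  # the grid must reach beyond the dilated cloud so its complement is non-empty
  lo <- apply(pts, 2, min) - (r_ball + 2 * grid_pitch)
  hi <- apply(pts, 2, max) + (r_ball + 2 * grid_pitch)
  xs <- seq(lo[1], hi[1], by = grid_pitch)
  ys <- seq(lo[2], hi[2], by = grid_pitch)
  zs <- seq(lo[3], hi[3], by = grid_pitch)
  dims <- c(length(xs), length(ys), length(zs))
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  d_pts <- FNN::get.knnx(pts, g, k = 1)$nn.dist[, 1]
  D <- array(d_pts <= r_ball, dims)
  # exterior nodes with a dilated neighbour = boundary of the complement
  shift_or <- function(a) {
    out <- array(FALSE, dim(a))
    out[-1, , ] <- out[-1, , ] | a[-dims[1], , ]
    out[-dims[1], , ] <- out[-dims[1], , ] | a[-1, , ]
    out[, -1, ] <- out[, -1, ] | a[, -dims[2], ]
    out[, -dims[2], ] <- out[, -dims[2], ] | a[, -1, ]
    out[, , -1] <- out[, , -1] | a[, , -dims[3]]
    out[, , -dims[3]] <- out[, , -dims[3]] | a[, , -1]
    out
  }
  B <- !D & shift_or(D)
  if (!any(B)) stop("degenerate dilation; increase grid extent")
  d_b <- FNN::get.knnx(g[as.vector(B), , drop = FALSE], g, k = 1)$nn.dist[, 1]
  f <- ifelse(as.vector(D), r_ball - d_b, pmax(d_pts - r_ball, 1e-6))
  out <- mesh_isosurface(f, dims, lo, grid_pitch)
  attr(out, "hit_points") <- pts
  out
}

#' Remove the faces of a mesh enclosed by another surface
#'
#' Containment-based subtraction: faces of `mesh` whose centroids have
#' negative signed distance to the closed surface `enclosure` are dropped.
#'
#' @param mesh an open or closed `scc_mesh` (e.g. the lateral skull base).
#' @param enclosure a closed `scc_mesh` (e.g. the sigmoid surface).
#' @return `mesh` without the enclosed faces.
#' @export
subtract_enclosed_faces <- function(mesh, enclosure) {
  d <- mesh_distance(enclosure, face_centroids(mesh), signed = TRUE)$distance
  mesh_subset(mesh, d >= 0)
}

#' Drill entry-point region on the mastoid surface
#'
#' Defines the retroauricular planar domain -- a `size` x `size` mm sagittal
#' square whose anterior edge aligns with the ear-canal centre and which is
#' vertically centred on it, plus an `ext_size` x `ext_size` mm extension at
#' the anterosuperior corner (towards the zygomatic process) -- generates
#' `n_points` evenly spaced samples over the domain, and projects each
#' laterally onto the outer mastoid surface.
#'
#' @param outer_surface the outer mastoid `scc_mesh` (from
#'   `extract_outer_surface()`).
#' @param eac_centre ear-canal reference point (mm).
#' @param n_points number of samples over the planar domain.
#' @param size,ext_size side lengths of the main square and the extension (mm).
#' @param max_miss_frac maximum tolerated fraction of samples whose lateral
#'   projection misses the surface.
#' @return An `entry_region`: a tibble with one row per surface point
#'   (`point`, `x`, `y`, `z`, `u`, `v`, `nx`, `ny`, `nz`), with attributes
#'   `domain` (rectangles in (u,v)), `area` (mm^2) and `eac_centre`. The
#'   chart coordinates are `u = y - y_EAC` (anterior positive) and
#'   `v = z - z_EAC` (superior positive).
#' @export
build_entry_region <- function(outer_surface, eac_centre, n_points = 5000,
                               size = 30, ext_size = 10, max_miss_frac = 0.01) {
  yE <- eac_centre[2]; zE <- eac_centre[3]
  main <- c(u0 = -size, u1 = 0, v0 = -size / 2, v1 = size / 2)
  ext <- c(u0 = 0, u1 = ext_size, v0 = size / 2 - ext_size, v1 = size / 2)
  area <- size^2 + ext_size^2
  n_main <- round(n_points * size^2 / area)
  n_ext <- n_points - n_main
  grid_rect <- function(r, m) {
    if (m == 0) return(matrix(0, 0, 2))
    W <- r["u1"] - r["u0"]; H <- r["v1"] - r["v0"]
    nr <- max(1, round(sqrt(m * H / W)))
    per <- rep(floor(m / nr), nr)
    extra <- m - sum(per)
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
    do.call(rbind, lapply(seq_len(nr), function(i) {
      if (per[i] == 0) return(matrix(0, 0, 2))
      cbind(r["u0"] + (seq_len(per[i]) - 0.5) / per[i] * W,
            r["v0"] + (i - 0.5) / nr * H)
    }))
  }
  uv <- rbind(grid_rect(main, n_main), grid_rect(ext, n_ext))
  x_hi <- max(outer_surface$vertices[, 1]) + 5
  o <- cbind(x_hi, yE + uv[, 1], zE + uv[, 2])
  d <- matrix(rep(c(-1, 0, 0), each = nrow(o)), ncol = 3)
  hit <- mesh_raycast(outer_surface, o, d)
  miss <- is.na(hit$t)
  if (mean(miss) > max_miss_frac)
    stop(sprintf("lateral projection misses the outer surface for %.1f%% of samples",
                 100 * mean(miss)))
  nrm <- face_normals(outer_surface)[hit$face[!miss], , drop = FALSE]
  flip <- nrm[, 1] < 0
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  out <- tibble::tibble(
    point = seq_len(sum(!miss)),
    x = hit$point[!miss, 1], y = hit$point[!miss, 2], z = hit$point[!miss, 3],
    u = uv[!miss, 1], v = uv[!miss, 2],
    nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3])
  structure(out, domain = list(main = main, ext = ext), area = area,
            eac_centre = eac_centre,
            class = c("entry_region", class(out)))
}

#' Normalize a case to the right-ear convention
#'
#' Left-ear cases are reflected about the sagittal plane through the
#' inner-ear centre (triangle winding re-flipped so outward normals are
#' preserved); right-ear cases are returned unchanged.
#'
#' @param case an `anatomy_case`.
#' @return an `anatomy_case` with `side == "right"`.
#' @export
normalize_side <- function(case) {
  if (case$side == "right") return(case)
  mirror_case(case, to_side = "right")
}
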