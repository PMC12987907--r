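#' Triangular surface meshes
#'
#' A `scc_mesh` is a minimal triangular surface mesh: a numeric vertex matrix
#' (`n x 3`, millimetres) and an integer face matrix (`m x 3`, 1-based,
#' counter-clockwise seen from outside). All geometry handled by the package
#' uses this representation.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z) in mm.
#' @param faces integer matrix, one row per triangle (1-based vertex indices).
#' @return A `scc_mesh` object.
#' @export
mesh_new <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns")
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  structure(list(vertices = vertices, faces = faces), class = "scc_mesh")
}

#' @export
print.scc_mesh <- function(x, ...) {
  cat(sprintf("<scc_mesh: %d vertices, %d faces>\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

is_mesh <- function(x) inherits(x, "scc_mesh")

#' Per-face and total surface areas
#' @param mesh a `scc_mesh`.
#' @return `face_areas()`: numeric vector of triangle areas (mm^2);
#'   `mesh_area()`: total area.
#' @export
face_areas <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  cr <- vec_cross(b - a, c - a)
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname face_areas
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Signed enclosed volume (divergence theorem; positive for outward winding)
#' @param mesh a closed `scc_mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

face_normals <- function(mesh, unit = TRUE) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  n <- vec_cross(b - a, c - a)
  if (unit) n / pmax(sqrt(rowSums(n^2)), 1e-300) else n
}

face_centroids <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
}

vec_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

#' Distance from points to a mesh surface
#'
#' Exact point-to-triangle distances accelerated by a uniform grid. With
#' `signed = TRUE` the sign is taken from the angle-weighted pseudonormal of
#' the closest feature: negative inside a closed, outward-wound mesh.
#'
#' @param mesh a `scc_mesh`.
#' @param points numeric matrix of query points (k x 3, mm).
#' @param signed logical; return signed distances (meaningful only for closed
#'   meshes).
#' @return list with `distance` (k), `closest` (k x 3) and `face` (k).
#' @export
mesh_distance <- function(mesh, points, signed = FALSE) {
  points <- rbind(points)
  storage.mode(points) <- "double"
  cpp_mesh_distance(mesh$vertices, mesh$faces, points, isTRUE(signed))
}

#' First ray-mesh intersections
#'
#' @param mesh a `scc_mesh`.
#' @param origins,directions matrices (k x 3) of ray origins and directions.
#' @return list with `t` (ray parameter of first hit, `NA` if none), `face`,
#'   and `point` (k x 3 hit coordinates).
#' @export
mesh_raycast <- function(mesh, origins, directions) {
  origins <- rbind(origins); directions <- rbind(directions)
  storage.mode(origins) <- "double"
  storage.mode(directions) <- "double"
  cpp_ray_mesh(mesh$vertices, mesh$faces, origins, directions)
}

#' Isosurface of a scalar grid by marching tetrahedra
#'
#' Extracts the `iso` level set of values sampled on a regular grid (values
#' below `iso` are inside). Output triangles are wound outward.
#'
#' @param values numeric array or vector (x fastest) of grid samples.
#' @param dims integer grid dimensions (nx, ny, nz); inferred from an array.
#' @param origin,spacing grid origin and spacing per axis (mm).
#' @param iso iso-level (default 0).
#' @return a `scc_mesh`.
#' @export
mesh_isosurface <- function(values, dims = dim(values), origin, spacing, iso = 0) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  r <- cpp_marching_tets(as.double(values), as.integer(dims),
                         as.double(origin), as.double(spacing), iso)
  mesh_new(r$vertices, r$faces)
}

#' Rigid and mirror transforms
#'
#' `mesh_translate()` shifts all vertices; `mesh_mirror()` reflects a mesh
#' about a plane orthogonal to one axis and flips triangle winding so outward
#' normals are preserved.
#'
#' @param mesh a `scc_mesh`.
#' @param offset length-3 translation (mm).
#' @param axis axis index (1 = x) orthogonal to the mirror plane.
#' @param center coordinate of the mirror plane on that axis.
#' @return a transformed `scc_mesh`.
#' @export
mesh_translate <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, as.double(offset), "+")
  mesh
}

#' @rdname mesh_translate
#' @export
mesh_mirror <- function(mesh, axis = 1, center = 0) {
  mesh$vertices[, axis] <- 2 * center - mesh$vertices[, axis]
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

mirror_points <- function(p, axis = 1, center = 0) {
  p <- rbind(p)
  p[, axis] <- 2 * center - p[, axis]
  p
}

#' Flip winding so the enclosed signed volume is positive
#' @param mesh a closed `scc_mesh`.
#' @return a `scc_mesh` with outward-wound faces.
#' @export
mesh_orient_outward <- function(mesh) {
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

mesh_bounds <- function(mesh) {
  rbind(lo = apply(mesh$vertices, 2, min), hi = apply(mesh$vertices, 2, max))
}

# ---- primitive constructors -------------------------------------------------

#' Geodesic sphere mesh
#' @param subdivisions number of icosahedron midpoint subdivisions.
#' @param radius sphere radius (mm).
#' @param center length-3 centre.
#' @return a `scc_mesh` (watertight, outward-wound).
#' @export
mesh_icosphere <- function(subdivisions = 3, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    ukey <- unique(ekey)
    mids <- match(ekey, ukey)
    ue <- edges[!duplicated(ekey), , drop = FALSE]
    mv <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    mv <- mv / sqrt(rowSums(mv^2))
    v <- rbind(v, mv)
    m12 <- nv + mids[seq_len(nrow(f))]
    m23 <- nv + mids[nrow(f) + seq_len(nrow(f))]
    m31 <- nv + mids[2 * nrow(f) + seq_len(nrow(f))]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  mesh_new(sweep(v * radius, 2, center, "+"), f)
}

#' Axis-aligned box mesh
#' @param lo,hi length-3 opposite corners (mm).
#' @return a `scc_mesh` (12 triangles, outward-wound).
#' @export
mesh_box <- function(lo, hi) {
  g <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # corners indexed 1..8 with x fastest
  quads <- rbind(
    c(1, 3, 4, 2),  # z = lo, normal -z
    c(5, 6, 8, 7),  # z = hi, normal +z
    c(1, 2, 6, 5),  # y = lo
    c(3, 7, 8, 4),  # y = hi
    c(1, 5, 7, 3),  # x = lo
    c(2, 4, 8, 6))  # x = hi
  f <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  # orient every triangle outward from the box centre
  ctr <- (as.double(lo) + as.double(hi)) / 2
  m <- mesh_new(g, f)
  n <- face_normals(m, unit = FALSE)
  out <- sweep(face_centroids(m), 2, ctr, "-")
  flip <- rowSums(n * out) < 0
  m$faces[flip, ] <- m$faces[flip, c(1, 3, 2), drop = FALSE]
  m
}

#' Tube mesh swept along a polyline
#'
#' Sweeps a circular cross-section of (possibly varying) radius along a 3-D
#' path using parallel-transport frames; optionally closes the ends with
#' triangle fans, yielding a watertight capsule-like surface.
#'
#' @param path numeric matrix (k x 3) of ordered path points (mm).
#' @param radius scalar or length-k vector of section radii (mm).
#' @param n_theta number of vertices per cross-section ring.
#' @param caps close the tube ends.
#' @return a `scc_mesh`.
#' @export
mesh_tube <- function(path, radius, n_theta = 14, caps = TRUE) {
  path <- as.matrix(path)
  k <- nrow(path)
  if (k < 2) stop("`path` needs at least 2 points")
  radius <- rep_len(radius, k)
  if (any(radius <= 0)) stop("`radius` must be positive")
  # central-difference tangents
  tg <- matrix(0, k, 3)
  tg[1, ] <- path[2, ] - path[1, ]
  tg[k, ] <- path[k, ] - path[k - 1, ]
  if (k > 2) tg[2:(k - 1), ] <- path[3:k, , drop = FALSE] - path[1:(k - 2), , drop = FALSE]
  tg <- tg / pmax(sqrt(rowSums(tg^2)), 1e-300)
  # parallel transport frame
  ref <- if (abs(tg[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- unit(ref - sum(ref * tg[1, ]) * tg[1, ])
  frames_u <- matrix(0, k, 3); frames_v <- matrix(0, k, 3)
  frames_u[1, ] <- n1
  frames_v[1, ] <- vec_cross(rbind(tg[1, ]), rbind(n1))
  for (i in 2:k) {
    a <- tg[i - 1, ]; b <- tg[i, ]
    axis <- vec_cross(rbind(a), rbind(b))[1, ]
    s <- sqrt(sum(axis^2)); cth <- sum(a * b)
    u <- frames_u[i - 1, ]
    if (s > 1e-12) {
      ax <- axis / s
      ang <- atan2(s, cth)
      u <- u * cos(ang) + vec_cross(rbind(ax), rbind(u))[1, ] * sin(ang) +
        ax * sum(ax * u) * (1 - cos(ang))
    }
    u <- unit(u - sum(u * b) * b)
    frames_u[i, ] <- u
    frames_v[i, ] <- vec_cross(rbind(b), rbind(u))
  }
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  verts <- matrix(0, k * n_theta, 3)
  for (i in seq_len(k)) {
    ring <- path[rep(i, n_theta), ] +
      radius[i] * (outer(cos(th), frames_u[i, ]) + outer(sin(th), frames_v[i, ]))
    verts[(i - 1) * n_theta + seq_len(n_theta), ] <- ring
  }
  fcs <- vector("list", k - 1)
  for (i in seq_len(k - 1)) {
    a <- (i - 1) * n_theta + seq_len(n_theta)
    b <- a + n_theta
    an <- c(a[-1], a[1]); bn <- c(b[-1], b[1])
    fcs[[i]] <- rbind(cbind(a, an, bn), cbind(a, bn, b))
  }
  f <- do.call(rbind, fcs)
  if (caps) {
    verts <- rbind(verts, path[1, ], path[k, ])
    c1 <- nrow(verts) - 1; c2 <- nrow(verts)
    a <- seq_len(n_theta); an <- c(a[-1], a[1])
    b <- (k - 1) * n_theta + seq_len(n_theta); bn <- c(b[-1], b[1])
    f <- rbind(f, cbind(an, a, rep(c1, n_theta)), cbind(b, bn, rep(c2, n_theta)))
  }
  mesh_orient_outward(mesh_new(verts, f))
}

#' Torus-arc tube mesh (semicircular-canal model)
#'
#' A circular arc of given major radius swept with a circular cross-section;
#' the last `ampulla_arc_deg` degrees at the start of the arc can be widened
#' into an ampullary bulge.
#'
#' @param center arc centre (mm).
#' @param normal unit normal of the arc plane.
#' @param major_radius arc radius (mm).
#' @param lumen_radius tube cross-section radius (mm).
#' @param span_deg arc span in degrees.
#' @param start_dir in-plane unit vector pointing at the arc start.
#' @param ampulla_scale cross-section radius multiplier at the ampullary end.
#' @param ampulla_arc_deg arc length (degrees) of the ampullary widening.
#' @param step_deg angular sampling step.
#' @param n_theta vertices per cross-section ring.
#' @return a `scc_mesh`; attribute `"arc"` holds the analytic centreline.
#' @export
mesh_torus_arc <- function(center, normal, major_radius, lumen_radius,
                           span_deg = 270, start_dir = NULL,
                           ampulla_scale = 1, ampulla_arc_deg = 25,
                           step_deg = 6, n_theta = 14) {
  normal <- unit(normal)
  if (is.null(start_dir)) {
    ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
    start_dir <- unit(ref - sum(ref * normal) * normal)
  } else start_dir <- unit(start_dir - sum(start_dir * normal) * normal)
  e2 <- vec_cross(rbind(normal), rbind(start_dir))[1, ]
  ang <- seq(0, span_deg, by = step_deg) * pi / 180
  path <- sweep(major_radius * (outer(cos(ang), start_dir) + outer(sin(ang), e2)),
                2, center, "+")
  rad <- rep(lumen_radius, length(ang))
  if (ampulla_scale > 1) {
    w <- pmax(0, 1 - (ang * 180 / pi) / ampulla_arc_deg)
    rad <- lumen_radius * (1 + (ampulla_scale - 1) * w^2)
  }
  m <- mesh_tube(path, rad, n_theta = n_theta, caps = TRUE)
  attr(m, "arc") <- list(center = center, normal = normal, start_dir = start_dir,
                         major_radius = major_radius, span_deg = span_deg,
                         path = path)
  m
}

# ---- file I/O ---------------------------------------------------------------

#' Read and write surface meshes (ASCII STL / PLY)
#'
#' Plain-text readers and writers for the two interchange formats the package
#' uses. The format is chosen from the file extension.
#'
#' @param mesh a `scc_mesh`.
#' @param path file path ending in `.stl` or `.ply`.
#' @return `read_mesh()` returns a `scc_mesh`; `write_mesh()` returns `path`
#'   invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    n <- face_normals(mesh)
    v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
    v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
    v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
    fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
    lines <- c("solid mesh",
               as.vector(rbind(
                 sprintf("facet normal %s", fmt(n)),
                 "outer loop",
                 sprintf("vertex %s", fmt(v1)),
                 sprintf("vertex %s", fmt(v2)),
                 sprintf("vertex %s", fmt(v3)),
                 "endloop",
                 "endfacet")),
               "endsolid mesh")
    writeLines(lines, path)
  } else if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(mesh$vertices)),
             "property double x", "property double y", "property double z",
             sprintf("element face %d", nrow(mesh$faces)),
             "property list uchar int vertex_indices", "end_header")
    vl <- sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                  mesh$vertices[, 3])
    fl <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                  mesh$faces[, 3] - 1L)
    writeLines(c(hdr, vl, fl), path)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "stl") {
    vl <- grep("^\\s*vertex ", lines, value = TRUE)
    xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(t)
      as.double(t[2:4])))
    key <- paste(xyz[, 1], xyz[, 2], xyz[, 3])
    uid <- match(key, unique(key))
    verts <- xyz[!duplicated(key), , drop = FALSE]
    mesh_new(verts, matrix(uid, ncol = 3, byrow = TRUE))
  } else if (ext == "ply") {
    endh <- which(lines == "end_header")[1]
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
    vl <- lines[endh + seq_len(nv)]
    fl <- lines[endh + nv + seq_len(nf)]
    verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(t)
      as.double(t[1:3])))
    faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(t)
      as.integer(t[2:4]) + 1L))
    mesh_new(verts, faces)
  } else stop("unsupported mesh format: ", ext)
}
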