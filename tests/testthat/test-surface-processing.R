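test_that("ROI cropping keeps exactly the faces inside the prism", {
  tu <- mesh_tube(cbind(seq(-20, 20, by = 1), 0, 0), 2, n_theta = 12)
  ctr <- c(0, 0, 0)
  # prism fully containing the mesh: identity
  out <- crop_roi(tu, ctr, circumradius = 200, center_offset = c(0, 0, 0))
  expect_equal(nrow(out$faces), nrow(tu$faces))
  # disjoint prism: error
  expect_error(crop_roi(tu, ctr, circumradius = 5, center_offset = c(0, 500, 0)),
               "intersect")
  # partial crop: every kept vertex satisfies the three half-plane predicates
  out2 <- crop_roi(tu, ctr, circumradius = 15, center_offset = c(0, 0, 0))
  expect_gt(nrow(out2$faces), 0)
  ang <- c(90, 210, 330) * pi / 180
  tri <- cbind(15 * cos(ang), 15 * sin(ang))
  for (e in 1:3) {
    a <- tri[e, ]; b <- tri[e %% 3 + 1, ]
    nrm <- c(-(b - a)[2], (b - a)[1])
    if (sum(nrm * (c(0, 0) - a)) < 0) nrm <- -nrm
    expect_true(all((out2$vertices[, 1] - a[1]) * nrm[1] +
                    (out2$vertices[, 2] - a[2]) * nrm[2] >= -1e-9))
  }
})

test_that("outer surface of a convex body reproduces the body", {
  s <- mesh_icosphere(3, radius = 5)
  out <- extract_outer_surface(s, target_face_area = 1.0)
  # Hausdorff-style check in both directions
  expect_lt(max(abs(mesh_distance(s, out$vertices)$distance)), 0.05)
  expect_lt(max(abs(mesh_distance(out, s$vertices)$distance)), 0.05)
  expect_lt(median(face_areas(out)), 2.0)
})

test_that("outer surface excludes interior cavities", {
  # box with a concentric spherical cavity: build implicitly so the cavity
  # wall is part of the same mesh
  pitch <- 0.5
  xs <- seq(-6, 6, by = pitch)
  g <- as.matrix(expand.grid(xs, xs, xs))
  fbox <- pmax(abs(g[, 1]) - 5, abs(g[, 2]) - 5, abs(g[, 3]) - 5)
  fcav <- 2.5 - sqrt(rowSums(g^2))
  m <- mesh_isosurface(pmax(fbox, fcav), rep(length(xs), 3), rep(-6, 3), pitch)
  out <- extract_outer_surface(m, target_face_area = 1.0)
  # no output vertex projects onto the cavity wall (radius 2.5 sphere)
  r <- sqrt(rowSums(mesh_distance(m, out$vertices)$closest^2))
  expect_true(all(r > 3.5))
  # displacement trace converged and is non-increasing after the start
  tr <- attr(out, "displacement_trace")
  expect_lt(tr[length(tr)], 0.02)
  if (length(tr) > 2) expect_true(all(diff(tr[-1]) <= 1e-6))
})

test_that("outer-surface extraction is idempotent within tolerance", {
  s <- mesh_icosphere(3, radius = 5)
  out1 <- extract_outer_surface(s, target_face_area = 1.0)
  out2 <- extract_outer_surface(out1, target_face_area = 1.0)
  expect_lt(max(abs(mesh_distance(out1, out2$vertices)$distance)), 0.05)
})

test_that("skull base extraction returns the flat superior plate", {
  b <- mesh_box(c(-10, -10, -10), c(10, 10, 5))
  sb <- extract_skull_base(b, c(0, 0, 0))
  # exactly the two top triangles
  expect_equal(nrow(sb$faces), 2)
  expect_true(all(abs(sb$vertices[, 3] - 5) < 1e-9))
  # seeded from the first superior ray hit
  hit <- mesh_raycast(b, rbind(c(0, 0, 0)), rbind(c(0, 0, 1)))
  expect_false(is.na(hit$face[1]))
  # connectivity: one edge-connected component by construction
  expect_error(extract_skull_base(b, c(0, 0, 20)), "superior")
})

test_that("skull base of the synthetic bone is one superior-facing component", {
  ctx <- demo_context()
  sb <- ctx$skull_base
  expect_gt(nrow(sb$faces), 10)
  n <- canalaccess:::face_normals(sb)
  expect_true(all(n[, 3] > 0))
  # connectedness: flood from face 1 reaches every face
  comp <- canalaccess:::connected_faces(sb, 1, rep(TRUE, nrow(sb$faces)))
  expect_equal(length(comp), nrow(sb$faces))
})

test_that("sigmoid surface reconstruction matches a cylindrical channel", {
  # block with a capped cylindrical channel of radius 4
  pitch <- 0.8
  xs <- seq(-12, 12, by = pitch); zs <- seq(-22, 22, by = pitch)
  g <- as.matrix(expand.grid(xs, xs, zs))
  fbox <- pmax(abs(g[, 1]) - 10, abs(g[, 2]) - 10, -20 - g[, 3], g[, 3] - 20)
  dz <- pmax(abs(g[, 3]) - 15, 0)
  fch <- 4 - sqrt(g[, 1]^2 + g[, 2]^2 + dz^2)
  block <- mesh_isosurface(pmax(fbox, fch), c(length(xs), length(xs), length(zs)),
                           c(-12, -12, -22), pitch)
  cl <- cbind(0, 0, seq(-15, 15, by = 1))
  surf <- build_sigmoid_surface(cl, block, n_dirs = 128, grid_pitch = 0.8)
  analytic <- pi * 16 * 30 + 4 / 3 * pi * 64   # capsule: cylinder + caps
  expect_lt(abs(mesh_volume(surf) - analytic) / analytic, 0.15)
  # the generating centreline is enclosed
  d <- mesh_distance(surf, cl, signed = TRUE)$distance
  expect_true(all(d <= 0))
  expect_error(build_sigmoid_surface(cl[1, , drop = FALSE], block), "2 points")
})

test_that("sigmoid subtraction removes exactly the enclosed skull-base faces", {
  plate <- mesh_box(c(-10, -10, 4.8), c(10, 10, 5))
  ball <- mesh_icosphere(3, radius = 6, center = c(0, 0, 5))
  sub <- subtract_enclosed_faces(plate, ball)
  cen <- canalaccess:::face_centroids(sub)
  d <- mesh_distance(ball, cen, signed = TRUE)$distance
  expect_true(all(d >= 0))
  expect_lt(nrow(sub$faces), nrow(plate$faces))
})

test_that("entry region has the stated planar area and sample count", {
  ctx <- demo_context()
  reg <- ctx$region
  expect_equal(attr(reg, "area"), 30 * 30 + 10 * 10)
  expect_equal(nrow(reg), 200)       # all samples hit the synthetic mastoid
  # every point lies on the outer surface
  d <- mesh_distance(ctx$outer, cbind(reg$x, reg$y, reg$z))$distance
  expect_lt(max(abs(d)), 1e-6)
  # back-projection: each (u, v) is inside the main square or the extension
  dom <- attr(reg, "domain")
  in_rect <- function(u, v, r) u >= r["u0"] - 1e-9 & u <= r["u1"] + 1e-9 &
    v >= r["v0"] - 1e-9 & v <= r["v1"] + 1e-9
  expect_true(all(in_rect(reg$u, reg$v, dom$main) | in_rect(reg$u, reg$v, dom$ext)))
})

test_that("default region sampling returns exactly 5000 evenly spaced points", {
  # flat lateral plate phantom: projection cannot miss
  plate <- mesh_box(c(0, -40, -40), c(2, 40, 40))
  reg <- build_entry_region(plate, eac_centre = c(2, 5, 0))
  expect_equal(nrow(reg), 5000)
  nn <- FNN::get.knn(cbind(reg$u, reg$v), k = 1)$nn.dist[, 1]
  expect_lt(stats::sd(nn) / mean(nn), 0.2)
})

test_that("projection misses beyond the tolerated fraction raise an error", {
  small <- mesh_box(c(0, -3, -3), c(2, 3, 3))
  expect_error(build_entry_region(small, eac_centre = c(2, 5, 0), n_points = 100),
               "misses")
})

test_that("side normalization is the identity on right ears, involutive on left", {
  r <- generate_case(anatomy_params(side = "right"))
  expect_identical(normalize_side(r)$meshes$SCC_lateral$vertices,
                   r$meshes$SCC_lateral$vertices)
  l <- generate_case(anatomy_params(side = "left"))
  n <- normalize_side(l)
  expect_identical(n$side, "right")
  expect_identical(n$meshes$SCC_lateral$vertices, r$meshes$SCC_lateral$vertices)
  # mirror twice restores coordinates exactly
  back <- canalaccess:::mirror_case(n, "left")
  expect_equal(back$meshes$SCC_lateral$vertices, l$meshes$SCC_lateral$vertices,
               tolerance = 1e-12)
})
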