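test_that("primitive meshes have correct analytic area and volume", {
  s <- mesh_icosphere(3, radius = 2)
  expect_lt(abs(mesh_area(s) - 4 * pi * 4) / (4 * pi * 4), 0.01)
  expect_lt(abs(mesh_volume(s) - 4 / 3 * pi * 8) / (4 / 3 * pi * 8), 0.02)

  b <- mesh_box(c(0, 0, 0), c(2, 3, 4))
  expect_equal(mesh_volume(b), 24)
  expect_equal(mesh_area(b), 52)

  path <- cbind(0, 0, seq(0, 10, by = 0.5))
  tu <- mesh_tube(path, 0.5, n_theta = 24)
  # inscribed-polygon cross-section: area factor (n/2pi) sin(2pi/n)
  shrink <- 24 / (2 * pi) * sin(2 * pi / 24)
  expect_lt(abs(mesh_volume(tu) - pi * 0.25 * 10 * shrink) / (pi * 0.25 * 10 * shrink),
            0.01)
})

test_that("signed mesh distance matches the brute-force oracle", {
  meshes <- list(mesh_icosphere(2, radius = 1.5, center = c(0.3, -0.2, 0.1)),
                 mesh_box(c(-1, -2, -0.5), c(1.5, 0.5, 2)),
                 mesh_torus_arc(c(0, 0, 0), c(0, 0, 1), 3, 0.6, span_deg = 250))
  set.seed(11)
  for (m in meshes) {
    q <- matrix(runif(60, -3, 3), ncol = 3)
    got <- mesh_distance(m, q, signed = TRUE)$distance
    ref <- vapply(seq_len(nrow(q)), function(i) oracle_point_mesh_dist(m, q[i, ]),
                  numeric(1))
    expect_equal(abs(got), ref, tolerance = 1e-9)
  }
})

test_that("signed distance is negative inside closed meshes", {
  s <- mesh_icosphere(3, radius = 1)
  d <- mesh_distance(s, rbind(c(0, 0, 0), c(0.5, 0, 0), c(2, 0, 0)),
                     signed = TRUE)$distance
  expect_lt(d[1], 0)
  expect_lt(d[2], 0)
  expect_gt(d[3], 0)
})

test_that("ray casting returns the first hit", {
  s <- mesh_icosphere(3, radius = 1)
  h <- mesh_raycast(s, rbind(c(5, 0, 0), c(5, 0, 0), c(0, 0, 5)),
                    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, 0, -1)))
  expect_equal(h$t[1], 4, tolerance = 0.02)
  expect_true(is.na(h$t[2]))          # pointing away
  expect_equal(h$point[3, 3], 1, tolerance = 0.02)
})

test_that("marching tetrahedra reconstructs an implicit sphere", {
  n <- 41
  xs <- seq(-1.5, 1.5, length.out = n)
  g <- expand.grid(x = xs, y = xs, z = xs)
  vals <- sqrt(g$x^2 + g$y^2 + g$z^2) - 1
  m <- mesh_isosurface(vals, c(n, n, n), rep(-1.5, 3), diff(xs)[1])
  expect_lt(abs(mesh_volume(m) - 4 / 3 * pi) / (4 / 3 * pi), 0.02)
  expect_lt(max(abs(sqrt(rowSums(m$vertices^2)) - 1)), 0.01)
  # closed and outward-wound: interior point has negative signed distance
  expect_lt(mesh_distance(m, rbind(c(0, 0, 0)), signed = TRUE)$distance, 0)
})

test_that("mirroring is an involution that preserves outward normals", {
  tu <- mesh_tube(rbind(c(0, 0, 0), c(3, 1, 2), c(5, -1, 4)), 0.4)
  m1 <- mesh_mirror(tu, axis = 1, center = 0.5)
  expect_gt(mesh_volume(m1), 0)       # winding flipped with coordinates
  m2 <- mesh_mirror(m1, axis = 1, center = 0.5)
  expect_equal(m2$vertices, tu$vertices, tolerance = 1e-12)
  expect_equal(m2$faces, tu$faces)
})

test_that("STL and PLY round-trips preserve geometry", {
  tu <- mesh_tube(rbind(c(0, 0, 0), c(2, 1, 3), c(4, 0, 5)), 0.7, n_theta = 10)
  for (ext in c(".stl", ".ply")) {
    f <- tempfile(fileext = ext)
    write_mesh(tu, f)
    back <- read_mesh(f)
    expect_equal(nrow(back$faces), nrow(tu$faces))
    expect_lt(max(abs(mesh_distance(tu, back$vertices)$distance)), 1e-6)
    expect_lt(abs(mesh_volume(back) - mesh_volume(tu)), 1e-6)
  }
})
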