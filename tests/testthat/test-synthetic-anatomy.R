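test_that("generation is deterministic: same params give identical geometry", {
  a <- generate_case()
  b <- generate_case()
  for (nm in names(a$meshes))
    expect_identical(a$meshes[[nm]]$vertices, b$meshes[[nm]]$vertices)
  expect_identical(a$nerve_targets, b$nerve_targets)
})

test_that("a left ear is the exact mirror of its right-ear twin", {
  r <- generate_case(anatomy_params(side = "right"))
  l <- generate_case(anatomy_params(side = "left"))
  for (nm in names(r$meshes)) {
    expect_identical(mesh_mirror(l$meshes[[nm]], 1, 0)$vertices,
                     r$meshes[[nm]]$vertices)
  }
  expect_identical(mirror_points(l$nerve_targets, 1, 0), r$nerve_targets)
})

test_that("invalid parameters raise errors naming the offending field", {
  expect_error(anatomy_params(lumen_diameter = 0.5), "lumen_diameter")
  expect_error(anatomy_params(lumen_diameter = 2.0), "lumen_diameter")
  expect_error(anatomy_params(facial_nerve_radius = -1), "facial_nerve_radius")
  expect_error(anatomy_params(side = "up"), "side")
  p <- anatomy_params()
  p$canal_normals[1, ] <- c(2, 0, 0)
  expect_error(generate_case(p), "canal_normals")
})

test_that("critical structures do not intersect in the default case", {
  case <- demo_case()
  # exact closest-point oracle, independent of the C++ kernels
  for (nm in c("SCC_superior", "SCC_lateral", "SCC_posterior")) {
    d <- oracle_mesh_mesh_dist(case$meshes$facial_nerve, case$meshes[[nm]])
    expect_gt(d, 0)
  }
  expect_gt(oracle_mesh_mesh_dist(case$meshes$SCC_superior,
                                  case$meshes$SCC_lateral), 0)
  expect_gt(oracle_mesh_mesh_dist(case$meshes$SCC_superior,
                                  case$meshes$SCC_posterior), 0)
  expect_gt(oracle_mesh_mesh_dist(case$meshes$SCC_lateral,
                                  case$meshes$SCC_posterior), 0)
})

test_that("generated canal lumen matches the requested diameter within 5%", {
  case <- demo_case()
  arc <- attr(case$meshes$SCC_lateral, "arc")
  # cross-section at mid-arc, away from the ampulla: intersect mesh edges
  # with the plane through the arc point, normal to the local tangent
  path <- arc$path
  i <- nrow(path) %/% 2
  p0 <- path[i, ]
  tg <- unit(path[i + 1, ] - path[i - 1, ])
  v <- case$meshes$SCC_lateral$vertices
  f <- case$meshes$SCC_lateral$faces
  edges <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]))
  h <- (v %*% tg) - sum(p0 * tg)
  cross <- h[edges[, 1]] * h[edges[, 2]] < 0
  e <- edges[cross, , drop = FALSE]
  tt <- h[e[, 1]] / (h[e[, 1]] - h[e[, 2]])
  pts <- v[e[, 1], ] + tt * (v[e[, 2], ] - v[e[, 1], ])
  radii <- sqrt(rowSums(sweep(pts, 2, p0, "-")^2))
  lumen <- case$params$lumen_diameter
  expect_lt(abs(2 * mean(radii) - lumen) / lumen, 0.05)
})

test_that("nerve targets sit at the ampullary canal ends", {
  case <- demo_case()
  for (nm in c("superior", "lateral", "posterior")) {
    d <- mesh_distance(case$meshes[[paste0("SCC_", nm)]],
                       rbind(case$nerve_targets[nm, ]))$distance
    expect_lt(abs(d), 3)
  }
})

test_that("cohorts are reproducible, validated, and mix sides", {
  coh1 <- generate_cohort(6, seed = 3)
  coh2 <- generate_cohort(6, seed = 3)
  for (i in seq_along(coh1))
    expect_identical(coh1[[i]]$meshes$SCC_lateral$vertices,
                     coh2[[i]]$meshes$SCC_lateral$vertices)
  for (cs in coh1) expect_true(validate_case(cs))
  expect_gt(length(unique(vapply(coh1, function(x) x$side, character(1)))), 1)
  # scales stay within the +/-10% envelope
  sc <- vapply(coh1, function(x) x$params$size_scale, numeric(1))
  expect_true(all(sc >= 0.9 & sc <= 1.1))
  expect_error(generate_cohort(0), "n")
})

test_that("a cohort of one equals generate_case on the derived seed", {
  coh <- generate_cohort(1, seed = 42)
  single <- generate_case(canalaccess:::derive_case_params(anatomy_params(), 42, 1))
  expect_identical(coh[[1]]$meshes$temporal_bone$vertices,
                   single$meshes$temporal_bone$vertices)
})

test_that("case directories round-trip through STL + JSON + YAML", {
  case <- demo_case()
  dir <- withr::local_tempdir()
  write_case(case, dir)
  expect_true(file.exists(file.path(dir, "landmarks.json")))
  expect_true(file.exists(file.path(dir, "params.yaml")))
  back <- read_case(dir)
  expect_identical(back$side, case$side)
  expect_equal(back$nerve_targets, case$nerve_targets, tolerance = 1e-9)
  expect_equal(back$ci$direction, case$ci$direction, tolerance = 1e-9)
  # geometry preserved (vertex order may change in STL deduplication)
  for (nm in names(case$meshes)) {
    expect_equal(nrow(back$meshes[[nm]]$faces), nrow(case$meshes[[nm]]$faces))
    expect_lt(max(abs(mesh_distance(case$meshes[[nm]],
                                    back$meshes[[nm]]$vertices)$distance)), 1e-6)
  }
  expect_true(validate_case(back))
})
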