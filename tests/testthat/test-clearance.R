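test_that("drill radius follows the half-open stepped profile", {
  expect_equal(drill_radius(0), 0.5)
  expect_equal(drill_radius(3.999), 0.5)
  expect_equal(drill_radius(4), 0.6)
  expect_equal(drill_radius(5), 0.6)
  expect_equal(drill_radius(13.999), 0.6)
  expect_equal(drill_radius(14), 1.25)
  expect_equal(drill_radius(20), 1.25)
  expect_error(drill_radius(-0.1), ">= 0")
  expect_error(drill_profile(step_radius = c(0.6, 0.55)), "increasing")
})

test_that("interpolated distance fields match exact distances", {
  s <- mesh_icosphere(4, radius = 1)
  fld <- build_distance_field(s, rbind(c(-2.2, -2.2, -2.2), c(2.2, 2.2, 2.2)),
                              spacing = 0.125)
  # analytic point at distance 2 from the centre
  expect_equal(field_interp(fld, rbind(c(2, 0, 0))), 1, tolerance = 0.13)
  # on the zero level set
  expect_lt(abs(field_interp(fld, rbind(c(0, 1, 0)))), 0.13)
  # random queries vs exact closest-point computation
  set.seed(4)
  q <- matrix(runif(1500, -2, 2), ncol = 3)
  err <- abs(field_interp(fld, q) - mesh_distance(s, q, signed = TRUE)$distance)
  expect_lt(max(err), 2 * fld$spacing)
})

test_that("field queries outside the grid raise an out-of-bounds error", {
  s <- mesh_icosphere(2, radius = 1)
  fld <- build_distance_field(s, rbind(c(-2, -2, -2), c(2, 2, 2)), spacing = 0.25)
  expect_error(field_interp(fld, rbind(c(3, 0, 0))), "bounds")
})

test_that("stepped-profile clearance reproduces the sphere-obstacle closed form", {
  # obstacle: sphere r = 2 whose centre sits 3.5 mm perpendicular from the
  # path at more than 14 mm from the tip -> margin = 3.5 - 2 - 1.25
  obs <- mesh_icosphere(4, radius = 2, center = c(10, 5.5, 0))
  fld <- build_distance_field(obs, rbind(c(-1, -2, -2), c(31, 9, 3)),
                              spacing = 0.125)
  traj <- trajectory(c(0, 0, 0), c(30, 0, 0))
  rep <- trajectory_clearance(traj, list(sphere = fld))
  expect_equal(rep$safety_margin, 5.5 - 2 - 1.25, tolerance = 0.15)
  expect_equal(rep$per_obstacle$s_tip[1], 20, tolerance = 0.5)
})

test_that("the safety margin is the minimum over obstacles", {
  near <- mesh_icosphere(3, radius = 1, center = c(15, 3, 0))
  far <- mesh_icosphere(3, radius = 1, center = c(15, 8, 0))
  b <- rbind(c(-1, -3, -3), c(31, 10, 3))
  f_near <- build_distance_field(near, b, spacing = 0.25)
  f_far <- build_distance_field(far, b, spacing = 0.25)
  traj <- trajectory(c(0, 0, 0), c(30, 0, 0))
  r2 <- trajectory_clearance(traj, list(near = f_near, far = f_far),
                             sample_step = 0.25)
  expect_equal(r2$safety_margin, min(r2$per_obstacle$min_clearance))
  expect_equal(r2$per_obstacle$min_clearance[1], r2$safety_margin)
  # duplicating an obstacle leaves the margin unchanged
  r3 <- trajectory_clearance(traj, list(a = f_near, b = f_near, c = f_far),
                             sample_step = 0.25)
  expect_equal(r3$safety_margin, r2$safety_margin)
})

test_that("clearance decreases with drill radius; stepped <= uniform tip", {
  obs <- mesh_icosphere(3, radius = 1.5, center = c(20, 4, 0))
  fld <- build_distance_field(obs, rbind(c(-1, -3, -3), c(31, 7, 3)),
                              spacing = 0.25)
  traj <- trajectory(c(0, 0, 0), c(30, 0, 0))
  margins <- vapply(c(0.3, 0.5, 0.8, 1.2), function(r)
    trajectory_clearance(traj, list(o = fld),
                         profile = drill_profile(tip_radius = r,
                                                 step_at = numeric(0),
                                                 step_radius = numeric(0)),
                         sample_step = 0.25)$safety_margin, numeric(1))
  expect_true(all(diff(margins) < 0))
  stepped <- trajectory_clearance(traj, list(o = fld), sample_step = 0.25)
  uniform <- trajectory_clearance(traj, list(o = fld),
                                  profile = drill_profile(0.5, numeric(0),
                                                          numeric(0)),
                                  sample_step = 0.25)
  expect_lte(stepped$safety_margin, uniform$safety_margin)
})

test_that("negative clearance flags collisions and is never clipped", {
  obs <- mesh_icosphere(3, radius = 2, center = c(15, 0, 0)) # on the path
  fld <- build_distance_field(obs, rbind(c(-1, -3, -3), c(31, 3, 3)),
                              spacing = 0.25)
  rep <- trajectory_clearance(trajectory(c(0, 0, 0), c(30, 0, 0)),
                              list(o = fld), sample_step = 0.25)
  expect_lt(rep$safety_margin, -2)
})

test_that("entry angles agree with the closed form", {
  expect_equal(entry_angle(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(entry_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(entry_angle(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_error(entry_angle(c(0, 0, 0), c(1, 0, 0)), "degenerate")
  set.seed(5)
  for (i in 1:100) {
    d <- canalaccess:::unit(rnorm(3))
    tg <- canalaccess:::unit(rnorm(3))
    got <- entry_angle(d, tg)
    ref <- acos(max(-1, min(1, sum(d * tg)))) * 180 / pi
    expect_lt(abs(got - ref), 0.5)
  }
})

test_that("trajectory objects validate their construction", {
  tr <- trajectory(c(0, 0, 0), c(3, 4, 0))
  expect_equal(tr$length, 5)
  expect_equal(tr$direction, c(0.6, 0.8, 0))
  expect_error(trajectory(c(1, 1, 1), c(1, 1, 1)), "zero-length")
})

test_that("exposed area decreases strictly with the entry angle", {
  curve <- exposed_area_curve(seq(10, 90, by = 10))
  expect_true(all(diff(curve$area) < 0))
  expect_error(exposed_area(0), "theta")
  expect_error(exposed_area(91), "theta")
})

test_that("exposed area scales quadratically with geometry", {
  a1 <- as.numeric(exposed_area(40, lumen_diameter = 1.1, tip_radius = 0.5))
  a2 <- as.numeric(exposed_area(40, lumen_diameter = 2.2, tip_radius = 1.0))
  expect_equal(a2 / a1, 4, tolerance = 0.02)
})

test_that("perpendicular exposed area matches independent oracles", {
  got <- exposed_area(90)
  # 1D closed form: strip of the cylinder wall within the drill half-line
  rc <- 0.55; rd <- 0.5
  f <- function(phi) ifelse(rc^2 * sin(phi)^2 <= rd^2,
                            2 * sqrt(pmax(rd^2 - rc^2 * sin(phi)^2, 0)), 0)
  closed <- 2 * rc * integrate(f, 0, pi / 2, subdivisions = 2000)$value
  expect_lt(abs(got - closed) / closed, 0.02)
  # voxel-boolean oracle: boolean swept-volume grid sampled by wall facets
  h <- 0.02
  phi <- seq(-pi / 2, pi / 2, by = h / rc)   # upper wall half (z > 0)
  xx <- seq(-1.6, 1.6, by = h)
  gp <- expand.grid(phi = phi, x = xx)
  p <- cbind(gp$x, rc * sin(gp$phi), rc * cos(gp$phi))
  vox <- floor(p / h)                        # containing voxel of each facet
  vc <- (vox + 0.5) * h                      # voxel centre
  tt <- pmax(0, vc[, 3])                     # half-line along +z
  inside <- (vc[, 1]^2 + vc[, 2]^2 + (vc[, 3] - tt)^2) <= rd^2
  oracle <- sum(inside) * (h / rc * rc) * h  # facet area = h^2
  expect_lt(abs(got - oracle) / oracle, 0.05)
})
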