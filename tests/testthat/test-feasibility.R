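test_that("accessibility classification applies both strict thresholds", {
  expect_true(classify_access(1.2, 45, 1.0))
  expect_false(classify_access(0.9, 30, 1.0))
  expect_false(classify_access(1.5, 80.0, 1.0))   # strict angle inequality
  expect_false(classify_access(1.0, 30, 1.0))     # strict margin inequality
  expect_equal(classify_access(c(2, 0.5), c(10, 10)), c(TRUE, FALSE))
})

test_that("the optimizer matches exhaustive search on random toy instances", {
  for (seed in 1:20) {
    maps <- toy_maps(n_per_canal = 8, seed = seed)
    plan <- optimize_mutual(maps)
    ref <- brute_force_plan(maps)
    if (is.null(ref)) {
      expect_false(plan$feasible)
    } else {
      expect_equal(plan$objective, ref$obj, tolerance = 1e-9)
      # every printed constraint re-verified on the returned plan
      expect_true(all(plan$trajectories$margin > 1))
      expect_true(all(plan$trajectories$angle < 80))
      expect_lt(plan$max_pairwise_distance, 12.5)
      expect_lte(plan$enclosing_circle_diameter, 15)
    }
  }
})

test_that("a forced unique triple is returned", {
  maps <- toy_maps(5, seed = 99)
  for (cn in names(maps)) {
    maps[[cn]]$accessible <- FALSE
    maps[[cn]]$accessible[3] <- TRUE
    maps[[cn]]$u <- maps[[cn]]$x <- rep(c(0, 1, 2, 3, 4), length.out = 5)
    maps[[cn]]$v <- maps[[cn]]$y <- 0
    maps[[cn]]$z <- 0
  }
  plan <- optimize_mutual(maps)
  expect_true(plan$feasible)
  expect_equal(plan$trajectories$point, c(3, 3, 3))
})

test_that("triples farther apart than the pairwise bound are infeasible", {
  maps <- toy_maps(4, seed = 7)
  maps[[1]]$x <- maps[[1]]$u <- 0
  maps[[2]]$x <- maps[[2]]$u <- 50
  maps[[3]]$x <- maps[[3]]$u <- 100
  for (cn in names(maps)) maps[[cn]]$accessible <- TRUE
  plan <- optimize_mutual(maps)
  expect_false(plan$feasible)
  expect_match(plan$diagnostics$reason, "pairwise")
})

test_that("the enclosing circle respects the equilateral worst-case bound", {
  # max pairwise 12.4 -> minimal enclosing circle <= 12.4 * 2 / sqrt(3)
  p <- 12.4 * rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  mec <- canalaccess:::enclosing_circle(p)
  expect_equal(2 * mec$radius, 12.4 * 2 / sqrt(3), tolerance = 1e-9)
  expect_lte(2 * mec$radius, 14.43)
  # two-point case: diameter equals the distance
  mec2 <- canalaccess:::enclosing_circle(rbind(c(0, 0), c(3, 4)))
  expect_equal(2 * mec2$radius, 5)
})

test_that("an obstacle-free phantom is fully accessible, a wall blocks all", {
  # straight tube target below a flat entry plate; obstacle far away
  plate <- mesh_box(c(10, -15, -15), c(12, 15, 15))
  reg <- build_entry_region(plate, eac_centre = c(12, 10, 0), n_points = 100,
                            size = 20, ext_size = 5)
  tube <- mesh_tube(cbind(seq(-4, 4, by = 0.25), 0, 0), 0.55, n_theta = 16)
  cl <- extract_centreline(tube)
  tg <- locate_targets(cl, c(-4, 0, 0), 2)
  far <- mesh_icosphere(2, radius = 1, center = c(0, 50, 0))
  bounds <- rbind(c(-6, -22, -16), c(13, 16, 16))
  f_far <- build_distance_field(far, bounds, spacing = 0.5)
  m <- compute_access_map(reg, tg, list(far = f_far), sample_step = 0.5)
  expect_true(all(m$angle < 80))
  expect_equal(accessibility(m), 100)
  # wall inserted between region and canal
  wall <- mesh_box(c(6, -20, -14), c(7, 14, 14))
  f_wall <- build_distance_field(wall, bounds, spacing = 0.5)
  m2 <- compute_access_map(reg, tg, list(far = f_far, wall = f_wall),
                           sample_step = 0.5)
  expect_equal(accessibility(m2), 0)
})

test_that("access map flags agree with a grid-free closest-point oracle", {
  ctx <- demo_context()
  map <- access_map(ctx, "lateral")
  set.seed(8)
  idx <- sample(nrow(map), 10)
  structures <- list(
    superior_canal = ctx$case$meshes$SCC_superior,
    posterior_canal = ctx$case$meshes$SCC_posterior,
    facial_nerve = ctx$case$meshes$facial_nerve,
    chorda_tympani = ctx$case$meshes$chorda_tympani,
    lateral_skull_base = ctx$skull_base,
    sigmoid_sinus = ctx$sigmoid,
    external_auditory_canal = ctx$case$meshes$external_auditory_canal)
  fen <- ctx$targets$lateral$fenestration_site
  for (i in idx) {
    entry <- c(map$x[i], map$y[i], map$z[i])
    len <- sqrt(sum((fen - entry)^2))
    ss <- seq(0, len, length.out = ceiling(len) + 1)
    pts <- t(entry + outer(fen - entry, ss / len))
    rad <- drill_radius(len - ss)
    margin_oracle <- min(vapply(structures, function(m) {
      d <- vapply(seq_len(nrow(pts)), function(k)
        oracle_point_mesh_dist(m, pts[k, ]), numeric(1))
      min(d - rad)
    }, numeric(1)))
    thr <- attr(map, "margin_threshold")
    # exact agreement outside a band around the threshold
    if (abs(margin_oracle - thr) > 0.25 && map$angle[i] < 79.5) {
      expect_equal(map$accessible[i], margin_oracle > thr,
                   info = sprintf("entry %d: oracle %.2f map %.2f", i,
                                  margin_oracle, map$margin[i]))
    }
  }
})

test_that("fenestration sweeps are consistent with single maps", {
  ctx <- demo_context()
  fields <- ctx$fields[setdiff(names(ctx$fields), "lateral_canal")]
  sw <- fenestration_sweep(ctx$centrelines$lateral,
                           ctx$case$nerve_targets["lateral", ], fields,
                           ctx$region, offsets = c(0, 2, 2),
                           sample_step = 0.5, canal = "lateral")
  # duplicate offsets give duplicate identical rows
  expect_equal(sw[2, ], sw[3, ])
  # offset 0 equals a direct map at the electrode target
  tg0 <- locate_targets(ctx$centrelines$lateral,
                        ctx$case$nerve_targets["lateral", ], 0)
  m0 <- compute_access_map(ctx$region, tg0, fields, sample_step = 0.5,
                           canal = "lateral")
  expect_equal(sw$accessibility[1], accessibility(m0))
  expect_error(fenestration_sweep(ctx$centrelines$lateral,
                                  ctx$case$nerve_targets["lateral", ], fields,
                                  ctx$region, offsets = c(0, 99)), "arc length")
})

test_that("steeper approaches appear as the fenestration leaves the ampulla", {
  # straight tube angled so that larger offsets force steeper approaches:
  # entry plate faces the tube end; moving the target away increases the
  # angle between the (fixed) entry->target direction and the tube axis
  plate <- mesh_box(c(14, -15, -15), c(16, 15, 15))
  reg <- build_entry_region(plate, eac_centre = c(16, 10, 0), n_points = 60,
                            size = 20, ext_size = 5)
  tube <- mesh_tube(cbind(seq(-5, 5, by = 0.25), 0, 0), 0.55, n_theta = 16)
  cl <- extract_centreline(tube)
  far <- mesh_icosphere(2, radius = 1, center = c(0, 60, 0))
  f_far <- build_distance_field(far, rbind(c(-7, -22, -16), c(17, 16, 16)),
                                spacing = 1)
  # ampulla at the far (-x) end: growing offsets move the fenestration
  # towards the plate, steepening every approach
  sw <- fenestration_sweep(cl, c(-5, 0, 0), list(far = f_far), reg,
                           offsets = c(0, 2, 4, 6), sample_step = 1)
  expect_true(all(diff(sw$min_accessible_angle) >= -1e-6))
})

test_that("case reports nest thresholds and handle CI references", {
  rep <- demo_report()
  cn <- rep$canals
  expect_true(all(cn$accessibility_0.5 >= cn$accessibility_1))
  expect_true(all(cn$accessibility_1 >= cn$accessibility_2))
  # CI offsets are angles in [0, 180]; entry distances positive
  ok <- !is.na(cn$lowest_ci_angular_offset)
  expect_true(all(cn$lowest_ci_angular_offset[ok] >= 0))
  expect_true(all(cn$lowest_ci_entry_distance[ok] > 0))
  # a CI direction equal to a plan direction gives zero angular offset
  plan <- attr(rep, "plan")
  tr <- plan$trajectories[1, ]
  ci <- list(entry = c(tr$x, tr$y, tr$z), direction = c(tr$dx, tr$dy, tr$dz))
  maps <- attr(rep, "maps")
  rep2 <- case_report(maps, plan, ci = ci)
  expect_equal(rep2$canals$plan_ci_angular_offset[1], 0, tolerance = 1e-6)
  # without a CI trajectory the metrics are marked absent
  rep3 <- case_report(maps, plan, ci = NULL)
  expect_true(all(is.na(rep3$canals$lowest_ci_angular_offset)))
})

test_that("cohort summaries are correct and permutation invariant", {
  rep <- demo_report()
  # single report: median = value, zero-width IQR and range
  s1 <- cohort_summary(list(rep))
  row <- s1[s1$metric == "accessibility_1" & s1$canal == "lateral", ]
  expect_equal(row$median, rep$canals$accessibility_1[rep$canals$canal == "lateral"])
  expect_equal(row$q25, row$q75)
  expect_equal(row$min, row$max)
  # textbook median on a constructed set of reports
  mk <- function(v) {
    r <- rep
    r$canals$accessibility_1 <- v
    r
  }
  reps <- lapply(c(1, 2, 3, 4, 5), mk)
  s <- cohort_summary(reps)
  expect_true(all(s$median[s$metric == "accessibility_1"] == 3))
  # permutation invariance
  s_shuf <- cohort_summary(reps[c(4, 1, 5, 2, 3)])
  expect_equal(s, s_shuf)
  expect_error(cohort_summary(list()), "at least one")
})
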