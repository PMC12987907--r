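# Independent brute-force geometry oracles (pure R, no use of the package's
# C++ kernels) and shared small fixtures.

# closest distance from one point to every triangle of a mesh (Ericson's
# per-region closest-point-on-triangle, vectorized over faces)
oracle_point_mesh_dist <- function(mesh, p) {
  A <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  ab <- B - A; ac <- C - A
  ap <- sweep(-A, 2, p, "+")
  bp <- sweep(-B, 2, p, "+")
  cp <- sweep(-C, 2, p, "+")
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  m <- nrow(A)
  cpnt <- matrix(NA_real_, m, 3)
  done <- rep(FALSE, m)
  set <- function(mask, pts) {
    mask <- mask & !done
    cpnt[mask, ] <<- pts[mask, , drop = FALSE]
    done <<- done | mask
  }
  set(d1 <= 0 & d2 <= 0, A)
  set(d3 >= 0 & d4 <= d3, B)
  set(d6 >= 0 & d5 <= d6, C)
  t1 <- d1 / (d1 - d3)
  set(vc <= 0 & d1 >= 0 & d3 <= 0, A + t1 * ab)
  t2 <- d2 / (d2 - d6)
  set(vb <= 0 & d2 >= 0 & d6 <= 0, A + t2 * ac)
  t3 <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, B + t3 * (C - B))
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  set(rep(TRUE, m), A + v * ab + w * ac)
  min(sqrt(rowSums(sweep(-cpnt, 2, p, "+")^2)))
}

oracle_mesh_mesh_dist <- function(mesh_a, mesh_b) {
  min(vapply(seq_len(nrow(mesh_a$vertices)), function(i)
    oracle_point_mesh_dist(mesh_b, mesh_a$vertices[i, ]), numeric(1)))
}

# fast test-scale pipeline configuration (the methods vignette documents the
# paper-scale defaults; tests run the same code on smaller problem sizes)
quick_config <- function(...) {
  args <- list(field_spacing = 0.5, sample_step = 0.5, n_entry_points = 200,
               target_face_area = 2.0, sigmoid_n_dirs = 96,
               sigmoid_grid_pitch = 1.0)
  over <- list(...)
  args[names(over)] <- over
  do.call(pipeline_config, args)
}

# shared demo case/context, computed once per test session
demo_cache <- function() {
  if (!exists(".canalaccess_test_cache", envir = globalenv()))
    assign(".canalaccess_test_cache", new.env(), envir = globalenv())
  get(".canalaccess_test_cache", envir = globalenv())
}

demo_case <- function() {
  cache <- demo_cache()
  if (is.null(cache$case)) cache$case <- generate_case()
  cache$case
}

demo_context <- function() {
  cache <- demo_cache()
  if (is.null(cache$ctx)) cache$ctx <- case_context(demo_case(), quick_config())
  cache$ctx
}

demo_report <- function() {
  cache <- demo_cache()
  if (is.null(cache$report))
    cache$report <- run_case(demo_case(), quick_config(), case_id = "demo")
  cache$report
}

# torus-arc phantom used by the centreline oracle tests
torus_phantom <- function(major = 3.2, lumen = 0.55, span = 270)
  mesh_torus_arc(c(0, 0, 0), c(0, 0, 1), major, lumen, span_deg = span,
                 step_deg = 4, n_theta = 18)

# toy access maps over an explicit entry-point set, for optimizer tests
toy_maps <- function(n_per_canal, seed, spread = 20) {
  set.seed(seed)
  lapply(stats::setNames(nm = c("superior", "lateral", "posterior")), function(cn) {
    u <- runif(n_per_canal, -spread, spread)
    v <- runif(n_per_canal, -spread, spread)
    margin <- runif(n_per_canal, 0, 3)
    angle <- runif(n_per_canal, 0, 120)
    tibble::tibble(canal = cn, point = seq_len(n_per_canal), u = u, v = v,
                   x = u, y = v, z = 0,
                   dx = 1, dy = 0, dz = 0, length = 25,
                   margin = margin, angle = angle,
                   accessible = classify_access(margin, angle))
  })
}

# exhaustive reference optimizer
brute_force_plan <- function(maps, max_pairwise = 12.5, ideal = 30) {
  acc <- lapply(maps, function(m) which(m$accessible))
  if (any(lengths(acc) == 0)) return(NULL)
  best <- NULL
  for (i in acc[[1]]) for (j in acc[[2]]) for (k in acc[[3]]) {
    p1 <- c(maps[[1]]$x[i], maps[[1]]$y[i], maps[[1]]$z[i])
    p2 <- c(maps[[2]]$x[j], maps[[2]]$y[j], maps[[2]]$z[j])
    p3 <- c(maps[[3]]$x[k], maps[[3]]$y[k], maps[[3]]$z[k])
    dmax <- max(sqrt(sum((p1 - p2)^2)), sqrt(sum((p1 - p3)^2)),
                sqrt(sum((p2 - p3)^2)))
    if (dmax >= max_pairwise) next
    obj <- (maps[[1]]$angle[i] - ideal)^2 + (maps[[2]]$angle[j] - ideal)^2 +
      (maps[[3]]$angle[k] - ideal)^2
    if (is.null(best) || obj < best$obj) best <- list(obj = obj)
  }
  best
}

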