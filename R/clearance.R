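#' Stepped drill profile
#'
#' Piecewise-constant drill radius as a function of the distance from the
#' drill tip, matching the stepped burr geometry of image-guided keyhole
#' drilling systems: a 0.5 mm tip radius, widening to 0.6 mm beyond 4 mm
#' from the tip and to 1.25 mm beyond 14 mm.
#'
#' @param tip_radius tip radius in mm.
#' @param step_at distances from the tip (mm) at which the radius steps up.
#' @param step_radius radii (mm) after each step.
#' @return a `drill_profile` object.
#' @export
drill_profile <- function(tip_radius = 0.5, step_at = c(4, 14),
                          step_radius = c(0.6, 1.25)) {
  if (length(step_at) != length(step_radius))
    stop("`step_at` and `step_radius` must have equal length")
  r <- c(tip_radius, step_radius)
  if (any(r <= 0) || any(diff(r) <= 0))
    stop("radii must be positive and strictly increasing")
  if (length(step_at) && (any(step_at <= 0) || any(diff(step_at) <= 0)))
    stop("step distances must be positive and strictly increasing")
  structure(list(tip_radius = tip_radius, step_at = step_at,
                 step_radius = step_radius), class = "drill_profile")
}

#' @export
print.drill_profile <- function(x, ...) {
  cat(sprintf("<drill_profile: tip %.2f mm; steps %s>\n", x$tip_radius,
              paste(sprintf("%.2f mm @ %.0f mm", x$step_radius, x$step_at),
                    collapse = ", ")))
  invisible(x)
}

#' Drill radius at a distance from the tip
#'
#' Half-open convention: the radius steps up *at* each threshold, i.e. the
#' larger radius applies from the step distance onward (conservative for
#' safety margins).
#'
#' @param s distance from the drill tip (mm); vectorized.
#' @param profile a [drill_profile()].
#' @return radii in mm.
#' @export
drill_radius <- function(s, profile = drill_profile()) {
  if (any(s < 0)) stop("distance from tip must be >= 0")
  r <- rep(profile$tip_radius, length(s))
  for (i in seq_along(profile$step_at))
    r[s >= profile$step_at[i]] <- profile$step_radius[i]
  r
}

#' Signed distance field of a structure on a regular grid
#'
#' Samples the exact point-to-mesh distance of `structure` on a regular grid
#' (node values are exact, not approximated); queries between nodes use
#' trilinear interpolation via [field_interp()]. With `signed = TRUE`
#' (closed meshes) distances are negative inside the structure; open sheets
#' such as the lateral skull base use unsigned distances.
#'
#' @param structure a `scc_mesh`.
#' @param bounds 2 x 3 matrix (rows lo, hi) of the grid extent (mm).
#' @param spacing grid spacing in mm (default 0.125).
#' @param signed logical; use the interior sign convention.
#' @param name structure name carried into reports.
#' @return a `distance_field` object.
#' @export
build_distance_field <- function(structure, bounds, spacing = 0.125,
                                 signed = TRUE, name = "structure") {
  if (nrow(structure$faces) == 0) stop("empty structure mesh")
  if (spacing <= 0) stop("`spacing` must be > 0")
  lo <- as.double(bounds[1, ]); hi <- as.double(bounds[2, ])
  if (any(hi <= lo)) stop("degenerate bounds")
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  xs <- lo[1] + (seq_len(dims[1]) - 1) * spacing
  ys <- lo[2] + (seq_len(dims[2]) - 1) * spacing
  zs <- lo[3] + (seq_len(dims[3]) - 1) * spacing
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  d <- mesh_distance(structure, g, signed = signed)$distance
  structure(list(origin = lo, spacing = spacing, dims = dims,
                 values = array(d, dims), signed = signed, name = name),
            class = "distance_field")
}

#' @export
print.distance_field <- function(x, ...) {
  cat(sprintf("<distance_field '%s': %d x %d x %d @ %.3f mm, %s>\n", x$name,
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              if (x$signed) "signed" else "unsigned"))
  invisible(x)
}

#' Trilinear interpolation of a distance field
#'
#' @param field a [build_distance_field()] result.
#' @param points k x 3 matrix of query points (mm); all must lie inside the
#'   grid (no extrapolation).
#' @return numeric vector of interpolated distances.
#' @export
field_interp <- function(field, points) {
  points <- rbind(points)
  fr <- sweep(points, 2, field$origin, "-") / field$spacing
  hi <- field$dims - 1L
  if (any(fr < -1e-9) || any(sweep(fr, 2, hi, "-") > 1e-9))
    stop("query point outside the distance-field bounds")
  fr <- pmin(pmax(fr, 0), matrix(hi - 1e-12, nrow(fr), 3, byrow = TRUE))
  i0 <- pmin(floor(fr), matrix(hi - 1L, nrow(fr), 3, byrow = TRUE))
  tt <- fr - i0
  v <- field$values
  gidx <- function(dx, dy, dz)
    v[cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)]
  w000 <- (1 - tt[, 1]) * (1 - tt[, 2]) * (1 - tt[, 3])
  w100 <- tt[, 1] * (1 - tt[, 2]) * (1 - tt[, 3])
  w010 <- (1 - tt[, 1]) * tt[, 2] * (1 - tt[, 3])
  w110 <- tt[, 1] * tt[, 2] * (1 - tt[, 3])
  w001 <- (1 - tt[, 1]) * (1 - tt[, 2]) * tt[, 3]
  w101 <- tt[, 1] * (1 - tt[, 2]) * tt[, 3]
  w011 <- (1 - tt[, 1]) * tt[, 2] * tt[, 3]
  w111 <- tt[, 1] * tt[, 2] * tt[, 3]
  w000 * gidx(0, 0, 0) + w100 * gidx(1, 0, 0) + w010 * gidx(0, 1, 0) +
    w110 * gidx(1, 1, 0) + w001 * gidx(0, 0, 1) + w101 * gidx(1, 0, 1) +
    w011 * gidx(0, 1, 1) + w111 * gidx(1, 1, 1)
}

#' Drill trajectory from an entry point to a fenestration site
#'
#' @param entry entry point on the mastoid surface (mm).
#' @param fenestration fenestration site on the canal centreline (mm); the
#'   drill tip leads, so distances from the tip are measured from this end.
#' @return a `trajectory` object with unit `direction` and `length`.
#' @export
trajectory <- function(entry, fenestration) {
  entry <- as.double(entry); fenestration <- as.double(fenestration)
  len <- sqrt(sum((fenestration - entry)^2))
  if (len <= 0) stop("zero-length trajectory")
  structure(list(entry = entry, fenestration = fenestration,
                 direction = (fenestration - entry) / len, length = len),
            class = "trajectory")
}

#' Clearance of a trajectory against obstacle distance fields
#'
#' Samples the path from entry to fenestration at `sample_step` (both
#' endpoints included), interpolates each obstacle's distance field at every
#' sample, and subtracts the local drill radius (distance from the tip
#' measured from the fenestration end, where the tip leads). The safety
#' margin is the minimum clearance over all obstacles and samples; negative
#' values indicate collision and are never clipped.
#'
#' @param traj a [trajectory()].
#' @param fields named list of [build_distance_field()] objects (obstacles).
#' @param profile a [drill_profile()].
#' @param sample_step sampling step along the path (mm).
#' @return a `clearance_report`: list with `per_obstacle` (tibble of
#'   `obstacle`, `min_clearance`, `s_tip` of the minimum), `safety_margin`,
#'   and `n_samples`.
#' @export
trajectory_clearance <- function(traj, fields, profile = drill_profile(),
                                 sample_step = 0.125) {
  n <- max(2L, ceiling(traj$length / sample_step) + 1L)
  s_entry <- seq(0, traj$length, length.out = n)
  pts <- cbind(traj$entry[1] + s_entry * traj$direction[1],
               traj$entry[2] + s_entry * traj$direction[2],
               traj$entry[3] + s_entry * traj$direction[3])
  s_tip <- traj$length - s_entry
  radius <- drill_radius(s_tip, profile)
  mins <- numeric(length(fields)); locs <- numeric(length(fields))
  for (i in seq_along(fields)) {
    cl <- field_interp(fields[[i]], pts) - radius
    j <- which.min(cl)
    mins[i] <- cl[j]; locs[i] <- s_tip[j]
  }
  nm <- names(fields)
  if (is.null(nm)) nm <- paste0("obstacle_", seq_along(fields))
  structure(list(per_obstacle = tibble::tibble(obstacle = nm,
                                               min_clearance = mins,
                                               s_tip = locs),
                 safety_margin = min(mins), n_samples = n),
            class = "clearance_report")
}

#' Semicircular-canal entry angle of a trajectory
#'
#' The angle between the drill direction and the ampulla-directed tangent of
#' the canal centreline at the fenestration site: 0 degrees is a perfectly
#' tangential anterograde approach, 90 degrees perpendicular, and angles
#' towards 180 degrees indicate a retrograde direction.
#'
#' @param traj a [trajectory()], or a unit direction vector.
#' @param targets a [locate_targets()] result, or a unit tangent vector.
#' @return angle in degrees, in `[0, 180]`.
#' @export
entry_angle <- function(traj, targets) {
  d <- if (inherits(traj, "trajectory")) traj$direction else as.double(traj)
  tg <- if (inherits(targets, "canal_targets")) targets$tangent else as.double(targets)
  nd <- sqrt(sum(d^2)); nt <- sqrt(sum(tg^2))
  if (nd == 0 || nt == 0) stop("degenerate direction or tangent")
  acos(pmin(pmax(sum(d * tg) / (nd * nt), -1), 1)) * 180 / pi
}

#' Exposed canal-wall area of an idealized fenestration
#'
#' Models the canal as a straight cylindrical lumen and the drill as a
#' cylinder with a hemispherical tip whose centre stops exactly on the canal
#' axis, entering at `theta` degrees to the axis. The swept drill volume is
#' then the set of points within the tip radius of the backward drill
#' half-line, and the exposed area is the canal-wall surface removed by it,
#' computed by quadrature over the wall with an analytic containment test
#' and refined until the result changes by less than `tol`.
#'
#' @param theta SCC entry angle in degrees, in `(0, 90]`.
#' @param lumen_diameter canal lumen diameter (mm).
#' @param tip_radius drill tip radius (mm).
#' @param tol relative convergence tolerance of the refinement.
#' @return exposed area in mm^2.
#' @export
exposed_area <- function(theta, lumen_diameter = 1.1, tip_radius = 0.5,
                         tol = 0.01) {
  if (theta <= 0 || theta > 90) stop("`theta` must lie in (0, 90] degrees")
  r_c <- lumen_diameter / 2
  r_d <- tip_radius
  th <- theta * pi / 180
  # drill axis direction (towards the canal): angle theta to the +x canal axis
  d <- c(cos(th), 0, -sin(th))
  half_x <- r_d / sin(th) + r_d + r_c   # wall extent that can be exposed
  area_at <- function(n) {
    phi <- (seq_len(2 * n) - 0.5) / (2 * n) * 2 * pi
    xx <- seq(-half_x, half_x, length.out = n + 1)
    xx <- (xx[-1] + xx[-(n + 1)]) / 2
    gp <- expand.grid(phi = phi, x = xx)
    p <- cbind(gp$x, r_c * sin(gp$phi), r_c * cos(gp$phi))
    # distance to the backward half-line {-t d, t >= 0}
    tt <- pmax(0, -(p %*% d))
    dd2 <- rowSums((p + tt %*% t(d))^2)
    cell <- (2 * pi * r_c / (2 * n)) * (2 * half_x / n)
    sum(dd2 <= r_d^2) * cell
  }
  n <- 64
  a0 <- area_at(n)
  repeat {
    n <- n * 2
    a1 <- area_at(n)
    if (abs(a1 - a0) <= tol * a1 || n >= 1024) break
    a0 <- a1
  }
  structure(a1, n_refine = n)
}

#' Exposed-area curve over entry angles
#'
#' @param theta vector of SCC entry angles (degrees).
#' @param lumen_diameter,tip_radius,tol passed to [exposed_area()].
#' @return tibble with `theta` and `area` (mm^2).
#' @export
exposed_area_curve <- function(theta = seq(10, 90, by = 5), lumen_diameter = 1.1,
                               tip_radius = 0.5, tol = 0.01) {
  tibble::tibble(theta = theta,
                 area = vapply(theta, exposed_area, numeric(1),
                               lumen_diameter = lumen_diameter,
                               tip_radius = tip_radius, tol = tol))
}
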