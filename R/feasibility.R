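#' Accessibility of a single trajectory
#'
#' A trajectory is accessible when its safety margin strictly exceeds the
#' margin threshold and its SCC entry angle is strictly below `max_angle`
#' (default 80 degrees, above which electrode insertion risks a retrograde
#' course).
#'
#' @param margin safety margin(s) in mm.
#' @param angle SCC entry angle(s) in degrees.
#' @param margin_threshold threshold in mm (default 1).
#' @param max_angle maximum admissible entry angle (degrees).
#' @return logical vector.
#' @export
classify_access <- function(margin, angle, margin_threshold = 1, max_angle = 80) {
  margin > margin_threshold & angle < max_angle
}

#' Accessibility map of one canal over an entry region
#'
#' Evaluates one candidate trajectory per entry point (entry point to the
#' canal's fenestration site): per-obstacle minimum clearances for the
#' stepped drill, the safety margin (minimum over obstacles), the SCC entry
#' angle, and the accessibility flag at the stated margin threshold.
#'
#' @param region an `entry_region`.
#' @param targets a [locate_targets()] result for the canal.
#' @param fields named list of obstacle [build_distance_field()] objects
#'   (the target canal itself must not be included).
#' @param profile a [drill_profile()].
#' @param sample_step path sampling step (mm).
#' @param margin_threshold accessibility margin threshold (mm).
#' @param max_angle maximum admissible SCC entry angle (degrees).
#' @param canal canal name carried into the map.
#' @return An `access_map` tibble: one row per entry point with entry
#'   coordinates, chart coordinates `u`, `v`, unit direction, trajectory
#'   `length`, one `clearance_*` column per obstacle, `margin`, `angle` and
#'   `accessible`.
#' @export
compute_access_map <- function(region, targets, fields,
                               profile = drill_profile(), sample_step = 0.125,
                               margin_threshold = 1, max_angle = 80,
                               canal = "canal") {
  if (length(fields) == 0) stop("no obstacle distance fields supplied")
  entry <- cbind(region$x, region$y, region$z)
  fen <- as.double(targets$fenestration_site)
  dvec <- cbind(fen[1] - entry[, 1], fen[2] - entry[, 2], fen[3] - entry[, 3])
  len <- sqrt(rowSums(dvec^2))
  if (any(len <= 0)) stop("entry point coincides with the fenestration site")
  dvec <- dvec / len
  n_traj <- nrow(entry)
  n_max <- max(2L, ceiling(max(len) / sample_step) + 1L)
  frac <- matrix(seq(0, 1, length.out = n_max), n_traj, n_max, byrow = TRUE)
  s_entry <- frac * len                    # n_traj x n_max, includes both ends
  px <- entry[, 1] + s_entry * dvec[, 1]
  py <- entry[, 2] + s_entry * dvec[, 2]
  pz <- entry[, 3] + s_entry * dvec[, 3]
  s_tip <- len - s_entry
  radius <- matrix(drill_radius(as.vector(s_tip), profile), n_traj, n_max)
  pts <- cbind(as.vector(px), as.vector(py), as.vector(pz))
  row_min <- function(m) do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
  clearances <- lapply(fields, function(fld) {
    cl <- matrix(field_interp(fld, pts), n_traj, n_max) - radius
    row_min(cl)
  })
  names(clearances) <- paste0("clearance_", names(fields))
  margin <- do.call(pmin, clearances)
  angle <- acos(pmin(pmax(dvec %*% as.double(targets$tangent), -1), 1)) * 180 / pi
  out <- tibble::tibble(canal = canal, point = region$point,
                        u = region$u, v = region$v,
                        x = entry[, 1], y = entry[, 2], z = entry[, 3],
                        dx = dvec[, 1], dy = dvec[, 2], dz = dvec[, 3],
                        length = len, !!!clearances, margin = margin,
                        angle = as.vector(angle),
                        accessible = classify_access(margin, as.vector(angle),
                                                     margin_threshold, max_angle))
  structure(out, margin_threshold = margin_threshold, max_angle = max_angle,
            fenestration_site = fen,
            class = c("access_map", class(out)))
}

#' Accessibility percentage of an access map
#' @param map an `access_map`.
#' @return percentage of accessible entry points (0--100).
#' @export
accessibility <- function(map) 100 * mean(map$accessible)

#' Sweep of fenestration sites along a canal
#'
#' Recomputes the canal targets and access map for a set of arc-length
#' offsets of the fenestration site from the electrode target, reporting the
#' accessibility and the lowest accessible SCC entry angle per offset.
#'
#' @param centreline the canal [extract_centreline()] result.
#' @param nerve_target the canal's nerve-stimulation target (mm).
#' @param fields named list of obstacle distance fields for this canal.
#' @param region an `entry_region`.
#' @param offsets fenestration offsets in mm (default 0--6).
#' @param ... passed to [compute_access_map()].
#' @return tibble with `offset`, `accessibility` (%), `min_accessible_angle`
#'   (degrees; `NA` if nothing is accessible).
#' @export
fenestration_sweep <- function(centreline, nerve_target, fields, region,
                               offsets = 0:6, ...) {
  L <- centreline_total_length(centreline)
  if (any(offsets < 0 | offsets >= L))
    stop("fenestration offsets must lie within the canal arc length")
  rows <- lapply(offsets, function(off) {
    tg <- locate_targets(centreline, nerve_target, off)
    map <- compute_access_map(region, tg, fields, ...)
    acc <- map$angle[map$accessible]
    tibble::tibble(offset = off, accessibility = accessibility(map),
                   min_accessible_angle = if (length(acc)) min(acc) else NA_real_)
  })
  dplyr::bind_rows(rows)
}

# minimal enclosing circle of <= 3 planar points
enclosing_circle <- function(p) {
  p <- rbind(p)
  if (nrow(p) == 1) return(list(center = p[1, ], radius = 0))
  best <- NULL
  contains <- function(c, r) all(sqrt((p[, 1] - c[1])^2 + (p[, 2] - c[2])^2) <= r + 1e-9)
  for (i in seq_len(nrow(p) - 1)) for (j in (i + 1):nrow(p)) {
    c <- (p[i, ] + p[j, ]) / 2
    r <- sqrt(sum((p[i, ] - p[j, ])^2)) / 2
    if (contains(c, r) && (is.null(best) || r < best$radius))
      best <- list(center = c, radius = r)
  }
  if (is.null(best) && nrow(p) == 3) {
    a <- p[1, ]; b <- p[2, ]; c <- p[3, ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d) > 1e-12) {
      ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
             sum(c^2) * (a[2] - b[2])) / d
      uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
             sum(c^2) * (b[1] - a[1])) / d
      best <- list(center = c(ux, uy), radius = sqrt((a[1] - ux)^2 + (a[2] - uy)^2))
    }
  }
  best
}

#' Mutually optimized three-canal trajectory plan
#'
#' Over all triples of accessible entry points (one per canal) whose pairwise
#' 3-D distances are below `max_pairwise`, minimizes the objective
#' `sum((angle_i - ideal_angle)^2)`. Ties are broken by the smaller maximum
#' pairwise distance, then lexicographically by entry index, so the result is
#' deterministic. The feasibility flag additionally requires the minimal
#' enclosing circle of the three entry points (in the entry-region chart) to
#' stay within `circle_diameter`.
#'
#' @param maps named list of three `access_map` tibbles over the same entry
#'   point set (names = canal names).
#' @param max_pairwise maximum pairwise entry distance (mm, default 12.5).
#' @param ideal_angle ideal SCC entry angle (degrees, default 30).
#' @param circle_diameter mastoidectomy diameter bound (mm, default 15).
#' @return a `mutual_plan`: list with `trajectories` (tibble, one row per
#'   canal), `objective`, `feasible`, `max_pairwise_distance`,
#'   `enclosing_circle_diameter` and `diagnostics`.
#' @export
optimize_mutual <- function(maps, max_pairwise = 12.5, ideal_angle = 30,
                            circle_diameter = 15) {
  if (length(maps) != 3) stop("exactly three access maps are required")
  ns <- vapply(maps, nrow, integer(1))
  if (length(unique(ns)) != 1 ||
      !all(vapply(maps, function(m) identical(m$point, maps[[1]]$point), logical(1))))
    stop("access maps must share the same entry-point set")
  cand <- lapply(maps, function(m) {
    k <- which(m$accessible)
    list(idx = k, pos = cbind(m$x, m$y, m$z)[k, , drop = FALSE],
         uv = cbind(m$u, m$v)[k, , drop = FALSE],
         w = (m$angle[k] - ideal_angle)^2, angle = m$angle[k],
         margin = m$margin[k])
  })
  diagnostics <- list(n_accessible = vapply(cand, function(cc) length(cc$idx),
                                            integer(1)))
  empty_plan <- function(reason) {
    diagnostics$reason <- reason
    structure(list(trajectories = NULL, objective = Inf, feasible = FALSE,
                   max_pairwise_distance = NA_real_,
                   enclosing_circle_diameter = NA_real_,
                   ideal_angle = ideal_angle, diagnostics = diagnostics),
              class = "mutual_plan")
  }
  if (any(diagnostics$n_accessible == 0))
    return(empty_plan("no accessible entry point for at least one canal"))
  # search order: canals by ascending candidate count; candidates by objective
  ord <- order(diagnostics$n_accessible)
  c1 <- cand[[ord[1]]]; c2 <- cand[[ord[2]]]; c3 <- cand[[ord[3]]]
  o1 <- order(c1$w); o2 <- order(c2$w)
  minw2 <- min(c2$w); minw3 <- min(c3$w)
  pd <- function(a, b)
    sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b), 0))
  d12 <- pd(c1$pos, c2$pos); d13 <- pd(c1$pos, c3$pos); d23 <- pd(c2$pos, c3$pos)
  best <- NULL
  for (i in o1) {
    if (!is.null(best) && c1$w[i] + minw2 + minw3 > best$obj + 1e-12) break
    ok2 <- which(d12[i, ] < max_pairwise)
    if (!length(ok2)) next
    for (j in ok2[order(c2$w[ok2])]) {
      if (!is.null(best) && c1$w[i] + c2$w[j] + minw3 > best$obj + 1e-12) break
      ok3 <- which(d13[i, ] < max_pairwise & d23[j, ] < max_pairwise)
      if (!length(ok3)) next
      w3 <- c3$w[ok3]
      obj3 <- c1$w[i] + c2$w[j] + w3
      maxd <- pmax(d12[i, j], d13[i, ok3], d23[j, ok3])
      # deterministic selection: objective, then max pairwise, then index
      sel <- order(obj3, maxd, c3$idx[ok3])[1]
      k <- ok3[sel]
      candbest <- list(i = i, j = j, k = k, obj = obj3[sel], maxd = maxd[sel])
      if (is.null(best) || candbest$obj < best$obj - 1e-12 ||
          (abs(candbest$obj - best$obj) <= 1e-12 &&
           (candbest$maxd < best$maxd - 1e-12 ||
            (abs(candbest$maxd - best$maxd) <= 1e-12 &&
             paste(c1$idx[candbest$i], c2$idx[candbest$j], c3$idx[candbest$k]) <
             paste(c1$idx[best$i], c2$idx[best$j], c3$idx[best$k])))))
        best <- candbest
    }
  }
  if (is.null(best))
    return(empty_plan("no accessible triple satisfies the pairwise distance constraint"))
  picks <- list(c1, c2, c3); sel <- c(best$i, best$j, best$k)
  canals_ordered <- names(maps)[ord]
  rows <- lapply(1:3, function(m) {
    cc <- picks[[m]]; s <- sel[m]
    map <- maps[[canals_ordered[m]]]
    r <- map[cc$idx[s], ]
    tibble::tibble(canal = canals_ordered[m], point = r$point, u = r$u, v = r$v,
                   x = r$x, y = r$y, z = r$z, dx = r$dx, dy = r$dy, dz = r$dz,
                   length = r$length, margin = r$margin, angle = r$angle)
  })
  traj <- dplyr::bind_rows(rows)[match(names(maps), canals_ordered), ]
  mec <- enclosing_circle(cbind(traj$u, traj$v))
  feasible <- 2 * mec$radius <= circle_diameter
  structure(list(trajectories = traj,
                 objective = sum((traj$angle - ideal_angle)^2),
                 feasible = feasible,
                 max_pairwise_distance = best$maxd,
                 enclosing_circle_diameter = 2 * mec$radius,
                 ideal_angle = ideal_angle, diagnostics = diagnostics),
            class = "mutual_plan")
}

#' @export
print.mutual_plan <- function(x, ...) {
  if (!x$feasible && is.null(x$trajectories)) {
    cat("<mutual_plan: infeasible -", x$diagnostics$reason, ">\n")
  } else {
    cat(sprintf("<mutual_plan: objective %.1f, angles %s deg, circle %.1f mm%s>\n",
                x$objective,
                paste(sprintf("%.0f", x$trajectories$angle), collapse = "/"),
                x$enclosing_circle_diameter,
                if (x$feasible) "" else " (infeasible)"))
  }
  invisible(x)
}

#' @export
tidy.mutual_plan <- function(x, ...) {
  if (is.null(x$trajectories)) return(tibble::tibble())
  x$trajectories
}

#' @export
glance.mutual_plan <- function(x, ...) {
  tibble::tibble(feasible = x$feasible, objective = x$objective,
                 max_pairwise_distance = x$max_pairwise_distance,
                 enclosing_circle_diameter = x$enclosing_circle_diameter,
                 ideal_angle = x$ideal_angle)
}

angle_between <- function(a, b) {
  acos(pmin(pmax(sum(unit(a) * unit(b)), -1), 1)) * 180 / pi
}

#' Per-case feasibility report
#'
#' Collects the per-canal metrics of a case: accessibility at each margin
#' threshold, the lowest accessible SCC entry angle, angular offsets and
#' entry-point distances to the cochlear-implant (CI) reference trajectory
#' (omitted when no CI trajectory is given), and the mutually optimized plan
#' metrics. The case is feasible when three accessible trajectories originate
#' within the mastoidectomy circle, i.e. when the mutual plan is feasible.
#'
#' @param maps_by_threshold named list (one element per margin threshold, e.g.
#'   `"1"`) of named lists of `access_map`s per canal.
#' @param plan a [optimize_mutual()] result computed at the reference
#'   threshold.
#' @param ci optional CI trajectory: list with `entry` and unit `direction`.
#' @param reference_threshold threshold (mm) whose maps feed the "lowest
#'   accessible" metrics.
#' @param case_id optional case label.
#' @return a `case_report`: list with `canals` (tibble), `feasible`, `plan`,
#'   `case_id`.
#' @export
case_report <- function(maps_by_threshold, plan, ci = NULL,
                        reference_threshold = 1, case_id = NA_character_) {
  thr_names <- names(maps_by_threshold)
  ref <- maps_by_threshold[[as.character(reference_threshold)]]
  canals <- names(ref)
  rows <- lapply(canals, function(cn) {
    acc <- setNames(lapply(thr_names, function(tn)
      accessibility(maps_by_threshold[[tn]][[cn]])), paste0("accessibility_", thr_names))
    m <- ref[[cn]]
    am <- m[m$accessible, ]
    lowest_angle <- if (nrow(am)) min(am$angle) else NA_real_
    ci_offset <- ci_dist <- NA_real_
    if (!is.null(ci) && nrow(am)) {
      dirs <- cbind(am$dx, am$dy, am$dz)
      offs <- acos(pmin(pmax(dirs %*% unit(ci$direction), -1), 1)) * 180 / pi
      ci_offset <- min(offs)
      ci_dist <- min(sqrt((am$x - ci$entry[1])^2 + (am$y - ci$entry[2])^2 +
                          (am$z - ci$entry[3])^2))
    }
    pr <- if (!is.null(plan$trajectories)) plan$trajectories[plan$trajectories$canal == cn, ] else NULL
    has_plan <- !is.null(pr) && nrow(pr) == 1
    tibble::tibble(canal = cn, !!!acc,
                   lowest_accessible_angle = lowest_angle,
                   lowest_ci_angular_offset = ci_offset,
                   lowest_ci_entry_distance = ci_dist,
                   plan_angle = if (has_plan) pr$angle else NA_real_,
                   plan_margin = if (has_plan) pr$margin else NA_real_,
                   plan_drill_length = if (has_plan) pr$length else NA_real_,
                   plan_ci_angular_offset = if (has_plan && !is.null(ci))
                     angle_between(c(pr$dx, pr$dy, pr$dz), ci$direction) else NA_real_,
                   plan_ci_entry_distance = if (has_plan && !is.null(ci))
                     sqrt(sum((c(pr$x, pr$y, pr$z) - ci$entry)^2)) else NA_real_)
  })
  structure(list(canals = dplyr::bind_rows(rows), feasible = plan$feasible,
                 plan = plan, case_id = case_id),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf("<case_report %s: %s>\n",
              ifelse(is.na(x$case_id), "", x$case_id),
              if (x$feasible) "feasible" else "not feasible"))
  print(x$canals)
  invisible(x)
}

#' @export
tidy.case_report <- function(x, ...) x$canals

#' @export
glance.case_report <- function(x, ...) {
  tibble::tibble(case_id = x$case_id, feasible = x$feasible,
                 objective = x$plan$objective,
                 enclosing_circle_diameter = x$plan$enclosing_circle_diameter)
}

#' Cohort summary statistics
#'
#' Median, interquartile range and range of every per-canal metric across a
#' list of case reports, in the layout of a cohort summary table.
#'
#' @param reports list of [case_report()] results.
#' @return tibble with `metric`, `canal`, `n`, `median`, `q25`, `q75`,
#'   `min`, `max`.
#' @export
cohort_summary <- function(reports) {
  if (length(reports) == 0) stop("at least one case report is required")
  long <- dplyr::bind_rows(lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    dplyr::mutate(tidyr::pivot_longer(r$canals, -"canal", names_to = "metric",
                                      values_to = "value"),
                  case = i)
  }))
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$metric, .data$canal),
    n = sum(is.finite(.data$value)),
    median = median(.data$value, na.rm = TRUE),
    q25 = unname(quantile(.data$value, 0.25, na.rm = TRUE)),
    q75 = unname(quantile(.data$value, 0.75, na.rm = TRUE)),
    min = suppressWarnings(min(.data$value, na.rm = TRUE)),
    max = suppressWarnings(max(.data$value, na.rm = TRUE)),
    .groups = "drop")
  feas <- vapply(reports, function(r) isTRUE(r$feasible), logical(1))
  attr(out, "n_cases") <- length(reports)
  attr(out, "feasible_fraction") <- mean(feas)
  out
}
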