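#' Parameters of the synthetic temporal-bone generator
#'
#' Describes one synthetic ear in the package's canonical frame: a right-ear
#' coordinate system with axes (x = lateral, y = anterior, z = superior) and
#' the origin at the inner-ear centre, all lengths in millimetres. The three
#' semicircular canals are modelled as torus-arc tubes with an ampullary
#' widening, nerves as swept tubes, the external auditory canal as a cylinder,
#' the temporal bone as an implicit solid (two overlapping blocks with a domed
#' lateral surface) from which the sigmoid-sinus channel and optional air-cell
#' cavities are carved.
#'
#' @param side `"right"` or `"left"`; left ears are generated by exact mirror
#'   imaging of the right-ear geometry about the sagittal plane.
#' @param lumen_diameter canal lumen diameter in mm; anatomically 1.0--1.2 mm,
#'   accepted range 0.8--1.5 mm.
#' @param canal_major_radius named numeric (superior, lateral, posterior):
#'   torus major radii in mm.
#' @param canal_span_deg arc span of each canal in degrees.
#' @param canal_normals 3 x 3 matrix of unit canal-plane normals (rows named
#'   superior, lateral, posterior).
#' @param canal_centers 3 x 3 matrix of canal-torus centres (mm).
#' @param canal_gap_rotation_deg named numeric (superior, lateral, posterior):
#'   rotation of each canal's arc gap about its plane normal, away from the
#'   default vestibule-facing placement; orients the ampullary arm (and hence
#'   the fenestration-site tangent) relative to the mastoid surface.
#' @param ampulla_scale,ampulla_arc_deg relative widening and angular extent
#'   of the ampullary bulge at the canal's ampullary end.
#' @param facial_nerve_radius,chorda_radius nerve tube radii (mm).
#' @param facial_nerve_path,chorda_path control polylines of the mastoid
#'   facial-nerve segment and the chorda tympani (mm).
#' @param eac_radius,eac_axis external-auditory-canal radius and axis
#'   (2 x 3 matrix: medial and lateral axis points).
#' @param skull_base_offset vertical offset (mm) added to the flat
#'   middle-fossa plate of the bone model.
#' @param sigmoid_points control points of the sigmoid-sinus centreline (mm).
#' @param sigmoid_radius radius of the sigmoid channel carved into the bone.
#' @param sigmoid_shift length-3 translation applied to the sigmoid
#'   centreline (used e.g. to probe directional sensitivity).
#' @param n_air_cells,air_cell_radius number and radius range (mm) of
#'   spherical mastoid air-cell cavities carved into the bone interior.
#' @param bone_pitch grid pitch (mm) of the implicit-surface extraction for
#'   the temporal bone.
#' @param size_scale global isotropic scale factor applied to the finished
#'   geometry (1 = canonical size).
#' @param seed integer random seed; fixes the air-cell layout and makes
#'   generation fully deterministic.
#' @return A validated `anatomy_params` list.
#' @export
anatomy_params <- function(side = "right",
                           lumen_diameter = 1.1,
                           canal_major_radius = c(superior = 3.4, lateral = 3.2,
                                                  posterior = 3.3),
                           canal_span_deg = 250,
                           canal_normals = NULL,
                           canal_centers = NULL,
                           canal_gap_rotation_deg = c(superior = 10, lateral = 0,
                                                      posterior = -105),
                           ampulla_scale = 1.6,
                           ampulla_arc_deg = 25,
                           facial_nerve_radius = 0.6,
                           chorda_radius = 0.25,
                           facial_nerve_path = NULL,
                           chorda_path = NULL,
                           eac_radius = 4,
                           eac_axis = rbind(c(3, 10.5, -1), c(17, 12, 0.5)),
                           skull_base_offset = 0,
                           sigmoid_points = NULL,
                           sigmoid_radius = 4,
                           sigmoid_shift = c(0, 0, 0),
                           n_air_cells = 6,
                           air_cell_radius = c(0.8, 1.6),
                           bone_pitch = 0.9,
                           size_scale = 1,
                           seed = 1L) {
  if (is.null(canal_normals))
    canal_normals <- rbind(superior  = unit(c(0.70, 0.70, 0.10)),
                           lateral   = unit(c(-0.15, 0.35, 0.92)),
                           posterior = unit(c(0.68, -0.72, 0.10)))
  if (is.null(canal_centers))
    canal_centers <- rbind(superior  = c(-0.2, 0.6, 3.6),
                           lateral   = c(1.5, 0.6, -0.4),
                           posterior = c(-0.8, -2.2, 1.2))
  if (is.null(facial_nerve_path))
    facial_nerve_path <- rbind(c(1.6, 4.8, 1.2), c(2.9, 5.2, -1.5),
                               c(3.3, 4.6, -4.5), c(3.1, 3.4, -8.5),
                               c(2.7, 2.4, -13.0))
  if (is.null(chorda_path))
    chorda_path <- rbind(c(3.1, 3.4, -8.5), c(2.7, 4.9, -5.6), c(2.2, 6.3, -3.2))
  if (is.null(sigmoid_points))
    sigmoid_points <- rbind(c(8.5, -13.0, 5.0), c(7.0, -14.5, 0.0),
                            c(5.5, -15.0, -5.0), c(5.0, -14.0, -10.0),
                            c(5.5, -12.5, -14.0))
  p <- structure(list(
    side = side, lumen_diameter = lumen_diameter,
    canal_major_radius = canal_major_radius, canal_span_deg = canal_span_deg,
    canal_normals = canal_normals, canal_centers = canal_centers,
    canal_gap_rotation_deg = canal_gap_rotation_deg,
    ampulla_scale = ampulla_scale, ampulla_arc_deg = ampulla_arc_deg,
    facial_nerve_radius = facial_nerve_radius, chorda_radius = chorda_radius,
    facial_nerve_path = facial_nerve_path, chorda_path = chorda_path,
    eac_radius = eac_radius, eac_axis = eac_axis,
    skull_base_offset = skull_base_offset,
    sigmoid_points = sigmoid_points, sigmoid_radius = sigmoid_radius,
    sigmoid_shift = sigmoid_shift,
    n_air_cells = n_air_cells, air_cell_radius = air_cell_radius,
    bone_pitch = bone_pitch, size_scale = size_scale,
    seed = as.integer(seed)), class = "anatomy_params")
  validate_anatomy_params(p)
}

validate_anatomy_params <- function(p) {
  bad <- function(field, why) stop(sprintf("invalid `%s`: %s", field, why),
                                   call. = FALSE)
  if (!p$side %in% c("left", "right")) bad("side", "must be 'left' or 'right'")
  if (!is.finite(p$lumen_diameter) || p$lumen_diameter < 0.8 ||
      p$lumen_diameter > 1.5)
    bad("lumen_diameter", "must lie in [0.8, 1.5] mm")
  if (any(p$canal_major_radius <= 0)) bad("canal_major_radius", "must be > 0")
  if (p$canal_span_deg <= 180 || p$canal_span_deg > 330)
    bad("canal_span_deg", "must lie in (180, 330] degrees")
  nn <- sqrt(rowSums(p$canal_normals^2))
  if (any(abs(nn - 1) > 1e-6)) bad("canal_normals", "rows must be unit vectors")
  for (f in c("facial_nerve_radius", "chorda_radius", "eac_radius",
              "sigmoid_radius", "bone_pitch", "size_scale"))
    if (p[[f]] <= 0) bad(f, "must be > 0")
  if (p$ampulla_scale < 1) bad("ampulla_scale", "must be >= 1")
  if (p$n_air_cells < 0) bad("n_air_cells", "must be >= 0")
  if (any(p$air_cell_radius <= 0) || diff(p$air_cell_radius) < 0)
    bad("air_cell_radius", "must be an increasing positive range")
  if (length(p$seed) != 1 || is.na(p$seed)) bad("seed", "must be one integer")
  p
}

# direction used to pick the ampullary end of each canal arc
ampulla_selectors <- rbind(superior = c(0, 1, 0), lateral = c(0, 1, 0),
                           posterior = c(0, 0, -1))

canal_names <- c("superior", "lateral", "posterior")

rotate_about <- function(v, axis, angle_rad) {
  axis <- unit(axis)
  v * cos(angle_rad) + vec_cross(rbind(axis), rbind(v))[1, ] * sin(angle_rad) +
    axis * sum(axis * v) * (1 - cos(angle_rad))
}

# resample a control polyline into a smooth curve with ~`step` spacing
resample_polyline <- function(points, step = 0.5) {
  points <- as.matrix(points)
  if (nrow(points) == 2) {
    len <- sqrt(sum((points[2, ] - points[1, ])^2))
    tt <- seq(0, 1, length.out = max(2, ceiling(len / step) + 1))
    return(cbind(points[1, 1] + tt * (points[2, 1] - points[1, 1]),
                 points[1, 2] + tt * (points[2, 2] - points[1, 2]),
                 points[1, 3] + tt * (points[2, 3] - points[1, 3])))
  }
  s <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  n <- max(3, ceiling(s[length(s)] / step) + 1)
  ss <- seq(0, s[length(s)], length.out = n)
  sapply(1:3, function(j) spline(s, points[, j], xout = ss, method = "natural")$y)
}

canal_mesh <- function(params, which) {
  ctr <- params$canal_centers[which, ]
  nrm <- unit(params$canal_normals[which, ])
  R <- params$canal_major_radius[[which]]
  # arc gap faces the vestibule (origin); candidate endpoints sit 45 degrees
  # either side of the gap direction, the ampullary end selected per canal
  d <- -ctr
  d <- d - sum(d * nrm) * nrm
  d <- if (sqrt(sum(d^2)) < 1e-9) {
    ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
    unit(ref - sum(ref * nrm) * nrm)
  } else unit(d)
  rot <- params$canal_gap_rotation_deg
  if (!is.null(rot) && is.finite(rot[[which]]) && rot[[which]] != 0)
    d <- rotate_about(d, nrm, rot[[which]] * pi / 180)
  gap <- 360 - params$canal_span_deg
  e1 <- rotate_about(d, nrm, gap / 2 * pi / 180)
  e2 <- rotate_about(d, nrm, -gap / 2 * pi / 180)
  sel <- ampulla_selectors[which, ]
  # sweep from the ampullary end away from the gap: +nrm from e1, -nrm from e2
  if (sum(e1 * sel) >= sum(e2 * sel)) {
    start_dir <- e1; nrm_eff <- nrm
  } else {
    start_dir <- e2; nrm_eff <- -nrm
  }
  mesh_torus_arc(ctr, nrm_eff, R, params$lumen_diameter / 2,
                 span_deg = params$canal_span_deg, start_dir = start_dir,
                 ampulla_scale = params$ampulla_scale,
                 ampulla_arc_deg = params$ampulla_arc_deg)
}

bone_mesh <- function(params, air_centers, air_radii) {
  pitch <- params$bone_pitch
  top1 <- 10 + params$skull_base_offset
  b1 <- list(lo = c(-6, -24, -20), hi = c(12, 12, top1))
  b2 <- list(lo = c(8, -24, -20), hi = c(15.5, 24, 16))
  dome_k <- 0.004; dome_c <- c(-6, -1) # (y, z) centre of the lateral dome
  lo <- pmin(b1$lo, b2$lo) - 1.5
  hi <- pmax(b1$hi, b2$hi) + 1.5
  xs <- seq(lo[1], hi[1], by = pitch)
  ys <- seq(lo[2], hi[2], by = pitch)
  zs <- seq(lo[3], hi[3], by = pitch)
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  boxf <- function(b) pmax(b$lo[1] - g[, 1], g[, 1] - b$hi[1],
                           b$lo[2] - g[, 2], g[, 2] - b$hi[2],
                           b$lo[3] - g[, 3], g[, 3] - b$hi[3])
  f1 <- boxf(b1)
  xlat <- 15.5 - dome_k * ((g[, 2] - dome_c[1])^2 + (g[, 3] - dome_c[2])^2)
  f2 <- pmax(b2$lo[1] - g[, 1], g[, 1] - xlat,
             b2$lo[2] - g[, 2], g[, 2] - b2$hi[2],
             b2$lo[3] - g[, 3], g[, 3] - b2$hi[3])
  f <- pmin(f1, f2)
  # carve the sigmoid channel
  sig <- resample_polyline(sweep(params$sigmoid_points, 2,
                                 as.double(params$sigmoid_shift), "+"),
                           step = 0.25)
  dsig <- FNN::get.knnx(sig, g, k = 1)$nn.dist[, 1]
  f <- pmax(f, params$sigmoid_radius - dsig)
  # carve air cells
  if (length(air_radii))
    for (i in seq_along(air_radii)) {
      d <- sqrt((g[, 1] - air_centers[i, 1])^2 + (g[, 2] - air_centers[i, 2])^2 +
                (g[, 3] - air_centers[i, 3])^2)
      f <- pmax(f, air_radii[i] - d)
    }
  mesh_isosurface(f, c(length(xs), length(ys), length(zs)),
                  c(lo[1], lo[2], lo[3]), pitch)
}

#' Generate one synthetic temporal-bone case
#'
#' Builds the full per-ear geometry the trajectory analysis consumes: surface
#' meshes of the three semicircular canals, facial nerve, chorda tympani,
#' external auditory canal and temporal bone, the sigmoid-sinus centreline,
#' one nerve-stimulation target per canal, the inner-ear centre, the
#' ear-canal reference point for entry-region placement, and a cochlear
#' implant (CI) reference trajectory. Generation is fully deterministic for a
#' fixed parameter set, and left ears are exact mirror images of the
#' right-ear geometry from the same seed.
#'
#' @param params an [anatomy_params()] list.
#' @return An `anatomy_case`: list with `side`, named `meshes`,
#'   `sigmoid_centreline`, `nerve_targets` (3 x 3 matrix), `inner_ear_centre`,
#'   `eac_centre`, `ci` (entry + unit direction) and the generating `params`.
#' @export
generate_case <- function(params = anatomy_params()) {
  params <- validate_anatomy_params(params)
  case <- withr::with_seed(params$seed, {
    air_centers <- matrix(0, 0, 3); air_radii <- numeric(0)
    if (params$n_air_cells > 0) {
      air_centers <- cbind(stats::runif(params$n_air_cells, 9, 11.5),
                           stats::runif(params$n_air_cells, -12, 6),
                           stats::runif(params$n_air_cells, -10, 4))
      air_radii <- stats::runif(params$n_air_cells, params$air_cell_radius[1],
                                params$air_cell_radius[2])
    }
    canals <- lapply(canal_names, function(nm) canal_mesh(params, nm))
    names(canals) <- canal_names
    fn_path <- resample_polyline(params$facial_nerve_path, 0.5)
    ct_path <- resample_polyline(params$chorda_path, 0.5)
    facial <- mesh_tube(fn_path, params$facial_nerve_radius, n_theta = 12)
    chorda <- mesh_tube(ct_path, params$chorda_radius, n_theta = 10)
    eac_path <- resample_polyline(params$eac_axis, 1.0)
    eac <- mesh_tube(eac_path, params$eac_radius, n_theta = 20)
    bone <- bone_mesh(params, air_centers, air_radii)
    sig <- resample_polyline(sweep(params$sigmoid_points, 2,
                                   as.double(params$sigmoid_shift), "+"),
                             step = 0.5)
    targets <- do.call(rbind, lapply(canals, function(m) attr(m, "arc")$path[1, ]))
    rownames(targets) <- canal_names
    # ear-canal reference: EAC axis point at the lateral bone surface depth
    ax <- params$eac_axis
    tt <- (14 - ax[1, 1]) / (ax[2, 1] - ax[1, 1])
    eac_centre <- ax[1, ] + tt * (ax[2, ] - ax[1, ])
    # CI reference trajectory: lateral surface entry aimed at the cochlea
    ci_hit <- mesh_raycast(bone, rbind(c(40, 3, -2)), rbind(c(-1, 0, 0)))
    ci_entry <- if (is.na(ci_hit$t[1])) c(15, 3, -2) else ci_hit$point[1, ]
    ci_dir <- unit(c(-1, 6, -4) - ci_entry)
    list(side = "right",
         meshes = list(SCC_superior = canals$superior,
                       SCC_lateral = canals$lateral,
                       SCC_posterior = canals$posterior,
                       facial_nerve = facial,
                       chorda_tympani = chorda,
                       external_auditory_canal = eac,
                       temporal_bone = bone),
         sigmoid_centreline = sig,
         nerve_targets = targets,
         inner_ear_centre = c(0, 0, 0),
         eac_centre = eac_centre,
         ci = list(entry = ci_entry, direction = ci_dir),
         params = params)
  })
  s <- params$size_scale
  if (s != 1) {
    case$meshes <- lapply(case$meshes, function(m) { m$vertices <- m$vertices * s; m })
    case$sigmoid_centreline <- case$sigmoid_centreline * s
    case$nerve_targets <- case$nerve_targets * s
    case$eac_centre <- case$eac_centre * s
    case$ci$entry <- case$ci$entry * s
  }
  if (params$side == "left") case <- mirror_case(case, to_side = "left")
  structure(case, class = "anatomy_case")
}

# mirror a case about the sagittal plane through its inner-ear centre
mirror_case <- function(case, to_side) {
  x0 <- case$inner_ear_centre[1]
  case$meshes <- lapply(case$meshes, mesh_mirror, axis = 1, center = x0)
  case$sigmoid_centreline <- mirror_points(case$sigmoid_centreline, 1, x0)
  case$nerve_targets <- mirror_points(case$nerve_targets, 1, x0)
  case$eac_centre <- mirror_points(case$eac_centre, 1, x0)[1, ]
  case$ci$entry <- mirror_points(case$ci$entry, 1, x0)[1, ]
  case$ci$direction <- case$ci$direction * c(-1, 1, 1)
  case$side <- to_side
  case
}

#' @export
print.anatomy_case <- function(x, ...) {
  cat(sprintf("<anatomy_case: %s ear, %d structures, seed %d>\n", x$side,
              length(x$meshes), x$params$seed))
  invisible(x)
}

#' Validate the structural invariants of an anatomy case
#'
#' Checks that every mesh is finite and triangular, that exactly three canals
#' and three nerve targets are present, and that each nerve target lies
#' within 3 mm of its canal surface.
#'
#' @param case an `anatomy_case`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_case <- function(case) {
  need <- c("SCC_superior", "SCC_lateral", "SCC_posterior", "facial_nerve",
            "chorda_tympani", "external_auditory_canal", "temporal_bone")
  if (!all(need %in% names(case$meshes))) stop("missing structure meshes")
  for (nm in names(case$meshes)) {
    m <- case$meshes[[nm]]
    if (!is_mesh(m)) stop("not a mesh: ", nm)
    if (!all(is.finite(m$vertices))) stop("non-finite vertices in ", nm)
    if (ncol(m$faces) != 3) stop("non-triangular faces in ", nm)
  }
  if (nrow(case$nerve_targets) != 3) stop("exactly three nerve targets required")
  for (nm in canal_names) {
    d <- mesh_distance(case$meshes[[paste0("SCC_", nm)]],
                       rbind(case$nerve_targets[nm, ]))$distance
    if (abs(d) > 3) stop("nerve target more than 3 mm from the ", nm, " canal")
  }
  if (!case$side %in% c("left", "right")) stop("unknown side")
  invisible(TRUE)
}

#' Generate a seeded cohort of synthetic cases
#'
#' Draws `n` cases around `base_params` with seeded inter-case variation:
#' +/-10% isotropic size scaling, +/-10 degree canal-orientation jitter,
#' +/-3 mm sigmoid-sinus position jitter, and a random mixture of left and
#' right ears. Case `i` is fully reproducible from `(base_params, seed)`.
#'
#' @param n number of cases (>= 1).
#' @param base_params an [anatomy_params()] list used as the cohort centre.
#' @param seed cohort-level integer seed.
#' @return list of `anatomy_case` objects.
#' @export
generate_cohort <- function(n, base_params = anatomy_params(), seed = 1L) {
  if (n < 1) stop("`n` must be >= 1")
  lapply(seq_len(n), function(i) generate_case(derive_case_params(base_params, seed, i)))
}

# per-case parameter draw for the cohort
derive_case_params <- function(base, seed, i) {
  case_seed <- (as.integer(seed) + 7919L * as.integer(i)) %% 2147483647L
  withr::with_seed(case_seed, {
    p <- base
    p$seed <- case_seed
    p$side <- if (i %% 2 == 0) "left" else "right"
    p$size_scale <- base$size_scale * stats::runif(1, 0.9, 1.1)
    for (nm in canal_names) {
      ax <- unit(stats::rnorm(3))
      ang <- stats::runif(1, -10, 10) * pi / 180
      p$canal_normals[nm, ] <- rotate_about(base$canal_normals[nm, ], ax, ang)
      p$canal_centers[nm, ] <- rotate_about(base$canal_centers[nm, ], ax, ang)
    }
    p$sigmoid_points <- base$sigmoid_points +
      matrix(stats::runif(3, -3, 3), nrow(base$sigmoid_points), 3, byrow = TRUE)
    p
  })
}

#' Write and read a case directory
#'
#' Serializes an `anatomy_case` as one ASCII STL file per structure, a JSON
#' file with all landmarks (sigmoid centreline, nerve targets, inner-ear
#' centre, ear-canal reference, CI trajectory, side) and a YAML file with the
#' generating parameters.
#'
#' @param case an `anatomy_case`.
#' @param dir directory to create/read.
#' @return `write_case()` returns `dir` invisibly; `read_case()` an
#'   `anatomy_case`.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(case$meshes))
    write_mesh(case$meshes[[nm]], file.path(dir, paste0(nm, ".stl")))
  lm <- list(side = case$side,
             sigmoid_centreline = case$sigmoid_centreline,
             nerve_targets = case$nerve_targets,
             nerve_target_names = rownames(case$nerve_targets),
             inner_ear_centre = case$inner_ear_centre,
             eac_centre = case$eac_centre,
             ci_entry = case$ci$entry, ci_direction = case$ci$direction)
  jsonlite::write_json(lm, file.path(dir, "landmarks.json"), digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor")
  pl <- case$params
  pl$canal_normals <- apply(pl$canal_normals, 1, identity, simplify = FALSE)
  pl$canal_centers <- apply(pl$canal_centers, 1, identity, simplify = FALSE)
  for (f in c("facial_nerve_path", "chorda_path", "eac_axis", "sigmoid_points"))
    pl[[f]] <- apply(pl[[f]], 1, identity, simplify = FALSE)
  yaml::write_yaml(unclass(pl), file.path(dir, "params.yaml"))
  invisible(dir)
}

#' @rdname write_case
#' @export
read_case <- function(dir) {
  lm <- jsonlite::read_json(file.path(dir, "landmarks.json"), simplifyVector = TRUE)
  meshes <- list()
  for (f in list.files(dir, pattern = "\\.stl$")) {
    nm <- sub("\\.stl$", "", f)
    meshes[[nm]] <- read_mesh(file.path(dir, f))
  }
  targets <- as.matrix(lm$nerve_targets)
  rownames(targets) <- lm$nerve_target_names
  params <- NULL
  pf <- file.path(dir, "params.yaml")
  if (file.exists(pf)) {
    pl <- yaml::read_yaml(pf)
    for (f in c("canal_normals", "canal_centers"))
      pl[[f]] <- do.call(rbind, lapply(pl[[f]], unlist))
    rownames(pl$canal_normals) <- rownames(pl$canal_centers) <- canal_names
    for (f in c("facial_nerve_path", "chorda_path", "eac_axis", "sigmoid_points"))
      pl[[f]] <- do.call(rbind, lapply(pl[[f]], unlist))
    params <- structure(pl, class = "anatomy_params")
  }
  structure(list(side = lm$side, meshes = meshes,
                 sigmoid_centreline = as.matrix(lm$sigmoid_centreline),
                 nerve_targets = targets,
                 inner_ear_centre = as.double(lm$inner_ear_centre),
                 eac_centre = as.double(lm$eac_centre),
                 ci = list(entry = as.double(lm$ci_entry),
                           direction = as.double(lm$ci_direction)),
                 params = params), class = "anatomy_case")
}
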