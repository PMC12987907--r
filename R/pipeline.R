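#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis, with defaults matching
#' the published planning setup: 0.1 mm centreline voxelization, 0.125 mm
#' distance-field spacing and path sampling, the stepped drill profile,
#' margin thresholds of 0.5/1/2 mm, an 80 degree maximum and 30 degree ideal
#' SCC entry angle, a 2 mm fenestration offset, a 12.5 mm pairwise
#' entry-distance constraint with a 15 mm mastoidectomy circle, a
#' 30 x 30 mm entry region with a 10 x 10 mm extension sampled at 5000
#' points, and a 0.1 mm^2 outer-surface face area.
#'
#' @param voxel_pitch canal voxelization pitch (mm).
#' @param field_spacing distance-field grid spacing (mm).
#' @param sample_step trajectory sampling step (mm).
#' @param profile a [drill_profile()].
#' @param margin_thresholds accessibility thresholds (mm).
#' @param reference_threshold threshold (mm) used for optimization and
#'   "lowest accessible" metrics.
#' @param max_angle maximum admissible SCC entry angle (degrees).
#' @param ideal_angle ideal SCC entry angle (degrees).
#' @param fenestration_offset arc offset of the fenestration site from the
#'   electrode target (mm).
#' @param max_pairwise pairwise entry-distance constraint (mm).
#' @param circle_diameter mastoidectomy diameter (mm).
#' @param entry_size,entry_ext_size entry-region side lengths (mm).
#' @param n_entry_points entry-region sample count.
#' @param target_face_area outer-surface remeshing target (mm^2).
#' @param sigmoid_alpha shape parameter of the sigmoid surface reconstruction.
#' @param sigmoid_n_dirs rays per sigmoid centreline sample.
#' @param sigmoid_grid_pitch reconstruction grid pitch (mm).
#' @param field_padding padding of the distance-field bounds around the
#'   trajectories (mm).
#' @param seed integer seed recorded with the run.
#' @param output_dir optional directory for per-case artifacts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(voxel_pitch = 0.1,
                            field_spacing = 0.125,
                            sample_step = 0.125,
                            profile = drill_profile(),
                            margin_thresholds = c(0.5, 1, 2),
                            reference_threshold = 1,
                            max_angle = 80,
                            ideal_angle = 30,
                            fenestration_offset = 2,
                            max_pairwise = 12.5,
                            circle_diameter = 15,
                            entry_size = 30,
                            entry_ext_size = 10,
                            n_entry_points = 5000,
                            target_face_area = 0.1,
                            sigmoid_alpha = 0.1,
                            sigmoid_n_dirs = 256,
                            sigmoid_grid_pitch = 0.7,
                            field_padding = 4,
                            seed = 1L,
                            output_dir = NULL) {
  cfg <- list(voxel_pitch = voxel_pitch, field_spacing = field_spacing,
              sample_step = sample_step, profile = profile,
              margin_thresholds = sort(margin_thresholds),
              reference_threshold = reference_threshold,
              max_angle = max_angle, ideal_angle = ideal_angle,
              fenestration_offset = fenestration_offset,
              max_pairwise = max_pairwise, circle_diameter = circle_diameter,
              entry_size = entry_size, entry_ext_size = entry_ext_size,
              n_entry_points = n_entry_points,
              target_face_area = target_face_area,
              sigmoid_alpha = sigmoid_alpha, sigmoid_n_dirs = sigmoid_n_dirs,
              sigmoid_grid_pitch = sigmoid_grid_pitch,
              field_padding = field_padding, seed = as.integer(seed),
              output_dir = output_dir)
  for (f in c("voxel_pitch", "field_spacing", "sample_step", "max_angle",
              "ideal_angle", "max_pairwise", "circle_diameter", "entry_size",
              "n_entry_points", "target_face_area", "sigmoid_alpha",
              "field_padding"))
    if (cfg[[f]] <= 0) stop(sprintf("invalid `%s`: must be > 0", f))
  if (!cfg$reference_threshold %in% cfg$margin_thresholds)
    cfg$margin_thresholds <- sort(c(cfg$margin_thresholds, cfg$reference_threshold))
  structure(cfg, class = "pipeline_config")
}

#' Serialize a pipeline configuration to YAML
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$profile <- unclass(cfg$profile)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Prepare the derived geometry of a case
#'
#' Runs the geometric stages shared by every downstream analysis:
#' side normalization, ROI cropping, outer-surface extraction, skull-base and
#' sigmoid-surface construction (with the sigmoid subtracted from the skull
#' base), entry-region sampling, per-canal centrelines and targets, and the
#' obstacle distance fields.
#'
#' @param case an `anatomy_case` (or a case directory for [read_case()]).
#' @param config a [pipeline_config()].
#' @return a `case_context` list with all derived objects plus a stage-timing
#'   log tibble.
#' @export
case_context <- function(case, config = pipeline_config()) {
  if (is.character(case)) case <- read_case(case)
  log <- list()
  tic <- function() Sys.time()
  lap <- function(stage, t0)
    log[[length(log) + 1]] <<- tibble::tibble(stage = stage,
                                              seconds = as.numeric(Sys.time() - t0,
                                                                   units = "secs"))
  t0 <- tic(); case <- normalize_side(case); lap("normalize_side", t0)
  t0 <- tic()
  bone <- crop_roi(case$meshes$temporal_bone, case$inner_ear_centre)
  lap("crop_roi", t0)
  t0 <- tic()
  outer <- extract_outer_surface(bone, target_face_area = config$target_face_area)
  lap("outer_surface", t0)
  t0 <- tic()
  skull_base <- extract_skull_base(bone, case$inner_ear_centre)
  lap("skull_base", t0)
  t0 <- tic()
  sigmoid <- build_sigmoid_surface(case$sigmoid_centreline, bone,
                                   alpha = config$sigmoid_alpha,
                                   n_dirs = config$sigmoid_n_dirs,
                                   grid_pitch = config$sigmoid_grid_pitch)
  skull_base <- subtract_enclosed_faces(skull_base, sigmoid)
  lap("sigmoid_surface", t0)
  t0 <- tic()
  region <- build_entry_region(outer, case$eac_centre,
                               n_points = config$n_entry_points,
                               size = config$entry_size,
                               ext_size = config$entry_ext_size)
  lap("entry_region", t0)
  t0 <- tic()
  centrelines <- lapply(canal_names, function(nm)
    extract_centreline(case$meshes[[paste0("SCC_", nm)]],
                       voxel_pitch = config$voxel_pitch))
  names(centrelines) <- canal_names
  targets <- lapply(canal_names, function(nm)
    locate_targets(centrelines[[nm]], case$nerve_targets[nm, ],
                   config$fenestration_offset))
  names(targets) <- canal_names
  lap("centrelines", t0)
  t0 <- tic()
  fens <- do.call(rbind, lapply(targets, function(t) t$fenestration_site))
  pts <- rbind(cbind(region$x, region$y, region$z), fens)
  bounds <- rbind(lo = apply(pts, 2, min) - config$field_padding,
                  hi = apply(pts, 2, max) + config$field_padding)
  structures <- list(
    superior_canal = case$meshes$SCC_superior,
    lateral_canal = case$meshes$SCC_lateral,
    posterior_canal = case$meshes$SCC_posterior,
    facial_nerve = case$meshes$facial_nerve,
    chorda_tympani = case$meshes$chorda_tympani,
    lateral_skull_base = skull_base,
    sigmoid_sinus = sigmoid,
    external_auditory_canal = case$meshes$external_auditory_canal)
  fields <- lapply(names(structures), function(nm)
    build_distance_field(structures[[nm]], bounds,
                         spacing = config$field_spacing,
                         signed = nm != "lateral_skull_base", name = nm))
  names(fields) <- names(structures)
  lap("distance_fields", t0)
  structure(list(case = case, config = config, bone = bone, outer = outer,
                 skull_base = skull_base, sigmoid = sigmoid, region = region,
                 centrelines = centrelines, targets = targets,
                 fields = fields, bounds = bounds,
                 log = dplyr::bind_rows(log)),
            class = "case_context")
}

# the obstacle set of a canal: every structure except the target canal itself
obstacle_fields <- function(ctx, canal, extra = NULL) {
  drop <- paste0(canal, "_canal")
  f <- ctx$fields[setdiff(names(ctx$fields), drop)]
  if (!is.null(extra)) f <- c(f, extra)
  f
}

#' Accessibility maps of one prepared case
#'
#' @param ctx a [case_context()].
#' @param canal canal name (`"superior"`, `"lateral"` or `"posterior"`).
#' @param margin_threshold accessibility threshold (mm).
#' @param extra_fields optional named list of additional obstacle fields.
#' @return an `access_map` tibble.
#' @export
access_map <- function(ctx, canal, margin_threshold = 1, extra_fields = NULL) {
  compute_access_map(ctx$region, ctx$targets[[canal]],
                     obstacle_fields(ctx, canal, extra_fields),
                     profile = ctx$config$profile,
                     sample_step = ctx$config$sample_step,
                     margin_threshold = margin_threshold,
                     max_angle = ctx$config$max_angle, canal = canal)
}

#' Run the full analysis of one case
#'
#' Executes the pipeline end to end -- [case_context()], accessibility maps
#' per canal and margin threshold, mutual trajectory optimization, and the
#' per-case report. If `config$output_dir` is set, writes the report
#' (JSON), the access maps (CSV), the resolved configuration (YAML) and the
#' stage log (CSV) under `output_dir/<case_id>/`.
#'
#' @param case an `anatomy_case` or a case directory path.
#' @param config a [pipeline_config()].
#' @param case_id label used in reports and output paths.
#' @return a `case_report`; the maps, plan and context are attached as
#'   attributes `maps`, `plan` and `context`.
#' @export
run_case <- function(case, config = pipeline_config(), case_id = "case") {
  ctx <- case_context(case, config)
  thrs <- config$margin_thresholds
  maps_by_threshold <- lapply(thrs, function(th) {
    m <- lapply(canal_names, function(cn) access_map(ctx, cn, th))
    names(m) <- canal_names
    m
  })
  names(maps_by_threshold) <- as.character(thrs)
  ref_maps <- maps_by_threshold[[as.character(config$reference_threshold)]]
  plan <- optimize_mutual(ref_maps, max_pairwise = config$max_pairwise,
                          ideal_angle = config$ideal_angle,
                          circle_diameter = config$circle_diameter)
  report <- case_report(maps_by_threshold, plan, ci = ctx$case$ci,
                        reference_threshold = config$reference_threshold,
                        case_id = case_id)
  if (!is.null(config$output_dir)) {
    dir <- file.path(config$output_dir, case_id)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(case_id = case_id, feasible = report$feasible,
           canals = report$canals, plan = glance(plan),
           plan_trajectories = plan$trajectories),
      file.path(dir, "report.json"), digits = NA, auto_unbox = TRUE)
    for (cn in canal_names)
      write.csv(ref_maps[[cn]], file.path(dir, paste0("access_map_", cn, ".csv")),
                row.names = FALSE)
    write_config(config, file.path(dir, "config.yaml"))
    write.csv(ctx$log, file.path(dir, "stages.csv"), row.names = FALSE)
  }
  attr(report, "maps") <- maps_by_threshold
  attr(report, "plan") <- plan
  attr(report, "context") <- ctx
  report
}

#' Run a cohort of cases
#'
#' Applies [run_case()] to every case; failures are isolated per case and
#' collected rather than aborting the cohort.
#'
#' @param cases list of `anatomy_case` objects, or a directory whose
#'   subdirectories are case directories.
#' @param config a [pipeline_config()].
#' @return list with `reports` (per successful case), `summary`
#'   ([cohort_summary()] tibble), and `failures` (named error messages).
#' @export
run_cohort <- function(cases, config = pipeline_config()) {
  if (is.character(cases)) {
    dirs <- list.dirs(cases, recursive = FALSE)
    if (length(dirs) == 0) stop("no case directories found in ", cases)
    names(dirs) <- basename(dirs)
    cases <- dirs
  }
  ids <- names(cases)
  if (is.null(ids)) ids <- sprintf("case_%02d", seq_along(cases))
  reports <- list(); failures <- character(0)
  for (i in seq_along(cases)) {
    r <- tryCatch(run_case(cases[[i]], config, case_id = ids[i]),
                  error = function(e) e)
    if (inherits(r, "error")) {
      failures[ids[i]] <- conditionMessage(r)
    } else {
      attr(r, "maps") <- NULL; attr(r, "context") <- NULL # keep cohorts light
      reports[[ids[i]]] <- r
    }
  }
  if (length(reports) == 0) stop("every case failed; first error: ", failures[1])
  list(reports = reports, summary = cohort_summary(reports), failures = failures)
}
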