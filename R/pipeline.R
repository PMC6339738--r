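# Pipeline stages: simulate -> measure -> analyze.  All interchange files are
# CSV (comma-separated, UTF-8, "." decimal, header row) with millimetres and
# degrees; meshes are PLY; every stage logs record counts at its boundary so
# the balanced-design audit is visible in the run log.

#' Pipeline configuration
#'
#' @param diameters_mm cylinder diameters to simulate (mm).
#' @param hand_length_mm anthropometric scale for the synthetic hand.
#' @param n_points,angular_jitter_deg,radial_noise_mm landmark noise model,
#'   see [sample_landmark_ring()].
#' @param n_subjects,subject_sd_fraction cohort model, see [cohort_spec()].
#' @param estimator end-center estimator: `"centroid"` or `"circle"`.
#' @param alpha significance level for the statistical stage.
#' @param seed integer seed; every stochastic stage derives from it.
#' @param output_dir directory for stage outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(diameters_mm = c(10, 60, 120),
                            hand_length_mm = 185.8,
                            n_points = 8, angular_jitter_deg = 10,
                            radial_noise_mm = 0.2,
                            n_subjects = 10, subject_sd_fraction = 0.5,
                            estimator = c("centroid", "circle"),
                            alpha = 0.05, seed = 1L,
                            output_dir = "gripangle-out") {
  estimator <- match.arg(estimator)
  if (is.null(seed)) stop("seed is mandatory for any stochastic run")
  structure(list(diameters_mm = as.numeric(diameters_mm),
                 hand_length_mm = hand_length_mm,
                 n_points = as.integer(n_points),
                 angular_jitter_deg = angular_jitter_deg,
                 radial_noise_mm = radial_noise_mm,
                 n_subjects = as.integer(n_subjects),
                 subject_sd_fraction = subject_sd_fraction,
                 estimator = estimator, alpha = alpha,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration (YAML)
#'
#' `load_config(save_config(cfg))` reproduces `cfg` exactly.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns the
#'   `pipeline_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

angle_csv_columns <- c("subject", "diameter_mm", "finger", "joint", "angle_deg")

#' Write / read joint angle records
#'
#' @param records data.frame of angle records.
#' @param path CSV path.
#' @return `path` / the records data.frame.
#' @export
write_angle_csv <- function(records, path) {
  utils::write.csv(records[angle_csv_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_angle_csv
#' @export
read_angle_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), angle_csv_columns))
    stop("angle CSV must have header exactly: ",
         paste(angle_csv_columns, collapse = ","))
  df
}

#' Simulation stage
#'
#' Writes, under `config$output_dir`: posed bone meshes (PLY) for every
#' diameter x finger x bone, the solver's ground-truth pose angles
#' (`ground_truth.csv`), a simulated cohort (`cohort.csv`) parameterized by
#' the published cell statistics, and a JSON manifest recording the seed and
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the manifest and file paths.
#' @export
grip_simulate <- function(config) {
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out)) stop("cannot create output directory: ", out)
  specs <- default_hand_specs(config$hand_length_mm)
  gt <- list(); mesh_files <- character()
  for (d in config$diameters_mm) {
    scen <- grip_scenario(d)
    pose <- solve_grip_poses(specs, scen)
    gt[[length(gt) + 1]] <- data.frame(subject = "model", diameter_mm = d,
                                       as.data.frame(pose)[c("finger", "joint", "angle_deg")])
    ddir <- file.path(out, "meshes", sprintf("d%03d", round(d)))
    dir.create(ddir, showWarnings = FALSE, recursive = TRUE)
    for (f in FINGERS) {
      chain <- pose_finger_chain(specs[[f]], pose, include_mesh = TRUE)
      for (b in BONES) {
        p <- file.path(ddir, sprintf("%s_%s.ply", f, b))
        write_ply(chain[[b]]$mesh, p)
        mesh_files <- c(mesh_files, p)
      }
    }
  }
  gt <- do.call(rbind, gt)
  gt_path <- file.path(out, "ground_truth.csv")
  write_angle_csv(gt, gt_path)

  cohort <- simulate_cohort(cohort_spec(config$n_subjects,
                                        subject_sd_fraction = config$subject_sd_fraction,
                                        seed = config$seed))
  cohort_path <- file.path(out, "cohort.csv")
  write_angle_csv(cohort, cohort_path)

  manifest <- list(stage = "simulate", seed = config$seed,
                   config = unclass(config),
                   n_meshes = length(mesh_files),
                   n_ground_truth_records = nrow(gt),
                   n_cohort_records = nrow(cohort))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("simulate: %d meshes, %d ground-truth records, %d cohort records -> %s",
                  length(mesh_files), nrow(gt), nrow(cohort), out))
  invisible(list(manifest = manifest, mesh_files = mesh_files,
                 ground_truth = gt_path, cohort = cohort_path))
}

# Orient per-bone end rings into a base->head chain by proximity matching.
chain_rings <- function(per_bone) {
  ctrs <- lapply(per_bone, function(x) attr(x, "axis_points"))
  n <- length(per_bone)
  oriented <- vector("list", n)
  # metacarpal base = end farther from the next bone
  d2 <- colMeans(rbind(ctrs[[2]]["end1", ], ctrs[[2]]["end2", ]))
  first_base <- if (vnorm(ctrs[[1]]["end1", ] - d2) > vnorm(ctrs[[1]]["end2", ] - d2))
    "end1" else "end2"
  prev_head_ctr <- NULL
  for (i in seq_len(n)) {
    if (i == 1) {
      base_end <- first_base
    } else {
      base_end <- if (vnorm(ctrs[[i]]["end1", ] - prev_head_ctr) <
                      vnorm(ctrs[[i]]["end2", ] - prev_head_ctr)) "end1" else "end2"
    }
    head_end <- setdiff(c("end1", "end2"), base_end)
    b <- per_bone[[i]][[base_end]]; b$end <- "base"
    h <- per_bone[[i]][[head_end]]; h$end <- "head"
    oriented[[i]] <- list(base = b, head = h)
    prev_head_ctr <- ctrs[[i]][head_end, ]
  }
  names(oriented) <- names(per_bone)
  oriented
}

#' Measurement stage
#'
#' Reads the posed bone meshes written by [grip_simulate()] (or any directory
#' with the same layout), picks landmark rings on every bone end, orients
#' base/head by chain proximity, and measures all joint angles.
#'
#' @param input_dir directory containing `meshes/d*/finger_bone.ply`.
#' @param config a [pipeline_config()] (estimator and ring size).
#' @return data.frame of angle records (also written to
#'   `geometric_angles.csv` in `input_dir`).
#' @export
grip_measure <- function(input_dir, config = pipeline_config(output_dir = input_dir)) {
  mesh_root <- file.path(input_dir, "meshes")
  ddirs <- list.dirs(mesh_root, recursive = FALSE)
  if (length(ddirs) == 0)
    stop("no-input: no mesh directories found under ", mesh_root)
  recs <- list()
  for (ddir in sort(ddirs)) {
    d <- as.numeric(sub("^d0*", "", basename(ddir)))
    rings <- list()
    for (f in FINGERS) {
      paths <- file.path(ddir, sprintf("%s_%s.ply", f, BONES))
      if (!all(file.exists(paths))) {
        rings[[f]] <- list()   # missing bones -> missing-data records
        next
      }
      per_bone <- lapply(seq_along(BONES), function(i)
        pick_end_rings(read_ply(paths[i]), n_points = config$n_points,
                       bone_id = c(f, BONES[i])))
      names(per_bone) <- BONES
      rings[[f]] <- chain_rings(per_bone)
    }
    recs[[length(recs) + 1]] <- measure_hand(rings, subject = "model",
                                             diameter_mm = d,
                                             method = config$estimator)
  }
  out <- do.call(rbind, recs)
  if (any(out$status == "missing-data"))
    stop("missing bones for: ",
         paste(unique(out$finger[out$status == "missing-data"]), collapse = ", "))
  write_angle_csv(out, file.path(input_dir, "geometric_angles.csv"))
  message(sprintf("measure: %d records from %d grips", nrow(out), length(ddirs)))
  out
}

#' Analysis stage
#'
#' From a balanced long-format angle table: cell summary, coupling ratios,
#' the three-way repeated-measures ANOVA with sphericity handling, simple
#' main effects, Bonferroni pairwise tables for each factor, and the two-way
#' CR ANOVA.  All tables are written as CSV (plus Markdown for the summary
#' tables) under `output_dir`.
#'
#' @param records data.frame or path to an angle CSV.
#' @param output_dir where to write the tables.
#' @param alpha significance level.
#' @return Invisibly, a named list of all result tables.
#' @export
grip_analyze <- function(records, output_dir, alpha = 0.05) {
  if (is.character(records)) records <- read_angle_csv(records)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  message(sprintf("analyze: %d records, %d subjects", nrow(records),
                  length(unique(records$subject))))
  angle_summary <- summarize_angles(records)
  crs <- cr_records(records)
  cr_summary <- summarize_cr(crs)
  fac <- c("diameter_mm", "finger", "joint")
  anova_table <- rm_anova(records, "angle_deg", fac, alpha = alpha)
  sphericity <- do.call(rbind, lapply(fac, function(f) {
    s <- mauchly_test(records, "angle_deg", fac, f)
    data.frame(effect = s$effect, mauchly_w = s$mauchly_w,
               chi_square = s$chi_square, df = s$df, p_value = s$p_value,
               epsilon_gg = s$epsilon_gg)
  }))
  simple_effects <- simple_main_effects(records, "angle_deg", "diameter_mm",
                                        c("finger", "joint"))
  pw <- list(
    diameter = pairwise_table(records, "angle_deg", "diameter_mm",
                              c("finger", "joint"), alpha),
    finger = pairwise_table(records, "angle_deg", "finger",
                            c("diameter_mm", "joint"), alpha),
    joint = pairwise_table(records, "angle_deg", "joint",
                           c("diameter_mm", "finger"), alpha))
  cr_anova <- rm_anova(crs, "cr", c("diameter_mm", "finger"), alpha = alpha)

  w <- function(x, name) utils::write.csv(as.data.frame(x),
                                          file.path(output_dir, paste0(name, ".csv")),
                                          row.names = FALSE)
  w(angle_summary, "angle_summary"); w(cr_summary, "cr_summary")
  w(anova_table, "anova_table"); w(sphericity, "sphericity")
  w(simple_effects, "simple_effects")
  w(pw$diameter, "pairwise_diameter"); w(pw$finger, "pairwise_finger")
  w(pw$joint, "pairwise_joint"); w(cr_anova, "cr_anova")
  writeLines(render_markdown(angle_summary),
             file.path(output_dir, "angle_summary.md"))
  writeLines(render_markdown(cr_summary),
             file.path(output_dir, "cr_summary.md"))
  invisible(list(angle_summary = angle_summary, cr_summary = cr_summary,
                 anova_table = anova_table, sphericity = sphericity,
                 simple_effects = simple_effects, pairwise = pw,
                 cr_anova = cr_anova))
}
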