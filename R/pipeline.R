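#' Default pipeline configuration
#'
#' All defaults mirror the method's standard settings: initialization
#' `A = 10`, `tau_out = 6` ms, `tau_close = 150` ms, constant initial
#' activation time `tau0`, RMSprop with `gamma = 0.9` and a 15-point
#' learning-rate grid over `[1e-5, 1e2]`.  The geometry/scenario block
#' defines the packaged synthetic benchmark: a 100-vertex epicardium-only
#' ventricle, 64 electrodes, a single pacing site, noiseless recording.
#'
#' @return A nested named list (the run configuration).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "ecginverse-output",
    geometry = list(semi_axes = c(30, 30, 60), wall_thickness = NULL,
                    n_target = 100, torso_radius = 100, torso_height = 240,
                    n_electrodes = 64),
    scenario = list(pacing_vertex = NULL, pacing_onset = 0,
                    conduction_velocity = 0.8, noise_snr_db = NULL,
                    mismatch = "none"),
    times = list(start = 0, end = 550, step = 1),
    optimizer = list(tau0 = 60, max_iterations = 300,
                     flat_tolerance = 1e-6, flat_window = 10,
                     dt_template = 0.05, verbose = 25),
    paths = list(mesh = NULL, electrodes = NULL, recording = NULL,
                 truth_tau = NULL)
  )
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file.
#' @return For `read_config`, the configuration list merged over
#'   [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# small stable FNV-1a hash of the serialized config, for the run manifest
config_hash <- function(config) {
  bytes <- as.integer(charToRaw(paste(deparse(config), collapse = "\n")))
  # polynomial rolling hash in double arithmetic (exact below 2^53)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^32
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

write_manifest <- function(config, dir, command) {
  jsonlite::write_json(
    list(command = command, config_hash = config_hash(config),
         seed = config$seed,
         package_version = as.character(utils::packageVersion("ecginverse")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = config),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
}

pipeline_geometry <- function(config) {
  g <- config$geometry
  if (!is.null(config$paths$mesh)) {
    list(mesh = read_mesh(config$paths$mesh),
         electrodes = read_electrodes(config$paths$electrodes))
  } else {
    make_synthetic_geometry(semi_axes = unlist(g$semi_axes),
                            wall_thickness = g$wall_thickness,
                            n_target = g$n_target,
                            torso_radius = g$torso_radius,
                            torso_height = g$torso_height,
                            n_electrodes = g$n_electrodes,
                            seed = config$seed)
  }
}

pipeline_times <- function(config) {
  with(config$times, seq(start, end, by = step))
}

pipeline_scenario <- function(config, mesh) {
  s <- config$scenario
  pv <- s$pacing_vertex
  if (is.null(pv)) {
    # default site: epicardial vertex nearest the mid free wall (largest x)
    epi <- which(mesh$surface_label == "EPI")
    pv <- epi[which.max(mesh$vertices[epi, 1])]
  }
  scenario(pacing = data.frame(vertex = pv, onset = s$pacing_onset),
           conduction_velocity = s$conduction_velocity,
           noise_snr_db = s$noise_snr_db,
           mismatch = s$mismatch,
           seed = config$seed)
}

#' Run an end-to-end pipeline command
#'
#' Orchestrates the package's workflow on disk:
#' * `"simulate"`: build (or load) the geometry, synthesize the scenario
#'   recording, and write recording + ground truth + manifest;
#' * `"invert"`: load geometry and recording, run [solve_inverse()], write
#'   the recovered fields (CSV + VTK) and diagnostics;
#' * `"evaluate"`: compare recovered fields with ground truth and write an
#'   [evaluation_report][evaluate_reconstruction()] (JSON + CSV);
#' * `"demo"`: the full synthetic round trip
#'   (simulate, invert, evaluate) with the packaged benchmark defaults.
#'
#' @param command one of `"simulate"`, `"invert"`, `"evaluate"`, `"demo"`.
#' @param config a configuration list ([default_config()] structure) or the
#'   path to a YAML file.
#' @return Invisibly, a list of produced artifacts (paths and, for
#'   `"invert"`/`"evaluate"`/`"demo"`, the in-memory results).
#' @export
run_pipeline <- function(command = c("simulate", "invert", "evaluate",
                                     "demo"),
                         config = default_config()) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_config(config)
  config <- merge_config(default_config(), config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- config$output_dir
  log_line <- function(...) message(format(Sys.time(), "[%H:%M:%S] "), ...)

  geom <- pipeline_geometry(config)
  times <- pipeline_times(config)
  artifacts <- list(output_dir = out)

  if (command %in% c("simulate", "demo")) {
    scn <- pipeline_scenario(config, geom$mesh)
    log_line("simulate: ", geom$mesh$n_vertices, " vertices, ",
             geom$electrodes$n_electrodes, " electrodes, pacing vertex ",
             scn$pacing$vertex[1])
    sim <- synthesize_recording(scn, geom$mesh, geom$electrodes, times,
                                config$optimizer$dt_template)
    write_bspm_csv(sim$recording, file.path(out, "recording.csv"))
    write_field_csv(sim$truth$field, file.path(out, "truth_field.csv"))
    write_mesh(geom$mesh, file.path(out, "mesh.vtk"),
               point_data = list(tau_true = sim$truth$tau,
                                 rt_true = ifelse(is.finite(sim$truth$rt),
                                                  sim$truth$rt, -1)))
    write_electrodes(geom$electrodes, file.path(out, "electrodes.txt"))
    write_manifest(config, out, command)
    artifacts$recording <- file.path(out, "recording.csv")
    artifacts$scenario <- scn
    if (command == "simulate") return(invisible(artifacts))
  }

  if (command == "invert" || command == "demo") {
    target <- if (command == "invert") {
      if (is.null(config$paths$recording))
        stop("config$paths$recording is required for 'invert'")
      read_bspm_csv(config$paths$recording)
    } else sim$recording
    if (nrow(target$phi) != geom$electrodes$n_electrodes)
      stop("recording has ", nrow(target$phi), " electrodes but the ",
           "electrode set has ", geom$electrodes$n_electrodes)
    opt <- config$optimizer
    log_line("invert: tau0 = ", opt$tau0, " ms, max ", opt$max_iterations,
             " iterations")
    sol <- solve_inverse(target, geom$mesh, geom$electrodes,
                         tau0 = opt$tau0,
                         stop = stopping_rule(opt$max_iterations,
                                              opt$flat_tolerance,
                                              opt$flat_window),
                         dt_template = opt$dt_template,
                         verbose = opt$verbose)
    log_line("invert: finished after ", sol$diagnostics$iterations,
             " iterations, J = ",
             signif(tail(sol$diagnostics$J_history, 1), 4))
    write_field_csv(sol$field, file.path(out, "recovered_field.csv"))
    write_field_vtk(sol$field, geom$mesh,
                    file.path(out, "recovered_field.vtk"))
    write_diagnostics_csv(sol, file.path(out, "diagnostics.csv"))
    write_manifest(config, out, command)
    artifacts$solution <- sol
    if (command == "invert") return(invisible(artifacts))
  }

  # evaluate (stand-alone or as the tail of demo)
  if (command == "evaluate") {
    fields <- read.csv(file.path(out, "recovered_field.csv"))
    sol <- parameter_field(A = fields$A[1], tau_out = fields$tau_out_ms,
                           tau_close = fields$tau_close_ms,
                           tau = fields$tau_ms)
    truth_fields <- read.csv(file.path(out, "truth_field.csv"))
    target <- read_bspm_csv(file.path(out, "recording.csv"))
    truth <- list(tau = truth_fields$tau_ms,
                  field = parameter_field(A = truth_fields$A[1],
                                          tau_out = truth_fields$tau_out_ms,
                                          tau_close = truth_fields$tau_close_ms,
                                          tau = truth_fields$tau_ms),
                  rt = rep(NaN, nrow(truth_fields)))
    pacing_vertex <- NULL
  } else {
    truth <- sim$truth
    target <- sim$recording
    pacing_vertex <- artifacts$scenario$pacing$vertex[1]
  }
  report <- evaluate_reconstruction(sol, truth, geom$mesh, geom$electrodes,
                                    target, pacing_vertex = pacing_vertex,
                                    dt_template = config$optimizer$dt_template)
  log_line(sprintf("evaluate: CC(AT) = %.3f, RE(AT) = %.3f",
                   report$cc_at, report$re_at))
  write_report_json(report, file.path(out, "report.json"))
  write_report_csv(report, file.path(out, "report.csv"))
  artifacts$report <- report
  invisible(artifacts)
}
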