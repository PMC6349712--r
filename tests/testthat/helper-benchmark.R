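# The packaged inverse-crime benchmark: 100-vertex epicardium-only ventricle,
# 64 electrodes, single epicardial pacing site, noiseless recording.  Solver
# runs are expensive, so results are memoised across test files.

.benchmark_env <- new.env()

benchmark_case <- function() {
  if (!is.null(.benchmark_env$case)) return(.benchmark_env$case)
  g <- make_synthetic_geometry(n_target = 100, n_electrodes = 64)
  epi <- which(g$mesh$surface_label == "EPI")
  pv <- epi[which.max(g$mesh$vertices[epi, 1])]
  scn <- scenario(pacing = data.frame(vertex = pv, onset = 0), seed = 1)
  times <- seq(0, 550, 1)
  sim <- synthesize_recording(scn, g$mesh, g$electrodes, times)
  .benchmark_env$case <- list(mesh = g$mesh, electrodes = g$electrodes,
                              pacing_vertex = pv, sim = sim, times = times)
  .benchmark_env$case
}

benchmark_solution <- function(tau0) {
  key <- paste0("sol_", tau0)
  if (!is.null(.benchmark_env[[key]])) return(.benchmark_env[[key]])
  case <- benchmark_case()
  sol <- solve_inverse(case$sim$recording, case$mesh, case$electrodes,
                       tau0 = tau0,
                       stop = stopping_rule(max_iterations = 300))
  .benchmark_env[[key]] <- sol
  sol
}
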