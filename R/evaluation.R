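#' Correlation and relative error between per-vertex maps
#'
#' Pearson correlation coefficient (CC) and relative L2 error
#' `RE = ||rec - ref|| / ||ref||` between a reconstructed and a reference
#' per-vertex map (activation or repolarization times), optionally restricted
#' per sub-surface (EPI / ENDO labels).
#'
#' @param reconstructed,reference numeric vectors of equal length (>= 3).
#' @param labels optional per-vertex labels (`"EPI"` / `"ENDO"`); when given,
#'   sub-surface CCs are added.
#' @return A list with `cc`, `re`, and (with labels) `cc_epi`, `cc_endo`.
#'   A zero-variance input yields `cc = NaN` with a warning.
#' @export
map_metrics <- function(reconstructed, reference, labels = NULL) {
  if (length(reconstructed) != length(reference))
    stop("map lengths differ")
  if (length(reference) < 3) stop("need at least 3 vertices")
  out <- list(cc = safe_cor(reconstructed, reference),
              re = sqrt(sum((reconstructed - reference)^2) /
                        sum(reference^2)))
  if (!is.null(labels)) {
    epi <- labels == "EPI"
    out$cc_epi <- safe_cor(reconstructed[epi], reference[epi])
    out$cc_endo <- if (any(!epi))
      safe_cor(reconstructed[!epi], reference[!epi]) else NA_real_
  }
  out
}

safe_cor <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2 || sd(a) == 0 || sd(b) == 0) {
    warning("zero variance (or too few finite values): CC undefined")
    return(NaN)
  }
  cor(a, b)
}

#' Per-time BSPM agreement metrics
#'
#' At each time sample, the Pearson correlation across electrodes and the
#' root-mean-square error between reconstructed and reference recordings,
#' plus their means and standard deviations over time.
#'
#' @param reconstructed,reference [bspm_recording()]s on the same electrode
#'   set and time grid.
#' @return A list with `cc` and `rmse` traces (length `T_max`), and scalars
#'   `cc_mean`, `cc_sd`, `rmse_mean`, `rmse_sd` (NaN-times excluded from the
#'   CC summary).
#' @export
bspm_metrics <- function(reconstructed, reference) {
  stopifnot(inherits(reconstructed, "bspm_recording"),
            inherits(reference, "bspm_recording"))
  if (!isTRUE(all.equal(reconstructed$times, reference$times)) ||
      nrow(reconstructed$phi) != nrow(reference$phi))
    stop("recordings must share electrode count and time grid")
  A <- reconstructed$phi; B <- reference$phi
  cc <- vapply(seq_len(ncol(A)), function(k) {
    if (sd(A[, k]) == 0 || sd(B[, k]) == 0) NaN else cor(A[, k], B[, k])
  }, numeric(1))
  rmse <- sqrt(colMeans((A - B)^2))
  list(cc = cc, rmse = rmse,
       cc_mean = mean(cc, na.rm = TRUE), cc_sd = sd(cc[is.finite(cc)]),
       rmse_mean = mean(rmse), rmse_sd = sd(rmse))
}

#' Repolarization times from extracellular potentials
#'
#' The repolarization time of a node is the time of the highest positive
#' slope of its extracellular potential during the repolarization phase.
#' The search window starts `plateau_guard` ms after the node's activation
#' time (excluding the depolarization upslope) and slopes are central
#' differences on the recording grid.  Nodes with an empty window or no
#' strictly positive slope get `NaN` with a warning.
#'
#' @param phi_e a `heart_potential_set` from [vm_to_extracellular()], or a
#'   plain `N_H x T_max` matrix.
#' @param tau per-vertex activation times in ms.
#' @param times recording time grid in ms.
#' @param plateau_guard guard interval in ms (default 50).
#' @return Numeric vector of per-vertex repolarization times (ms).
#' @export
extract_repolarization_times <- function(phi_e, tau, times,
                                         plateau_guard = 50) {
  M <- if (inherits(phi_e, "heart_potential_set")) phi_e$phi_e else
    as.matrix(phi_e)
  n <- nrow(M); T_max <- ncol(M)
  if (length(tau) != n) stop("tau length must match phi_e rows")
  # central-difference slope; one-sided at the ends
  slope <- M
  slope[, 2:(T_max - 1)] <- (M[, 3:T_max] - M[, 1:(T_max - 2)]) /
    (times[3:T_max] - times[1:(T_max - 2)])
  slope[, 1] <- (M[, 2] - M[, 1]) / (times[2] - times[1])
  slope[, T_max] <- (M[, T_max] - M[, T_max - 1]) /
    (times[T_max] - times[T_max - 1])
  rt <- rep(NaN, n)
  any_empty <- FALSE
  for (i in seq_len(n)) {
    win <- which(times >= tau[i] + plateau_guard)
    if (length(win) == 0) { any_empty <- TRUE; next }
    s <- slope[i, win]
    if (max(s) <= 0) { any_empty <- TRUE; next }
    rt[i] <- times[win[which.max(s)]]
  }
  if (any_empty)
    warning("repolarization time undefined (empty window or no positive ",
            "slope) for ", sum(!is.finite(rt)), " node(s)")
  rt
}

#' Action-potential duration at 90% repolarization
#'
#' `APD90` is measured from the upward crossing of `v_gate` (the model's
#' natural activation marker) to the first time after the peak where `v`
#' falls below 10% of its peak value, both crossings located by linear
#' interpolation.
#'
#' @param template an [ap_template()][integrate_ms()].
#' @return APD90 in ms, or `NaN` if `v` never exceeds `v_gate`.
#' @export
compute_apd90 <- function(template) {
  stopifnot(inherits(template, "ap_template"))
  v <- template$v; t <- template$time
  vg <- template$params$v_gate
  up <- which(v[-1] >= vg & v[-length(v)] < vg)
  if (v[1] >= vg) {
    t_act <- t[1]
  } else if (length(up) == 0) {
    return(NaN)
  } else {
    i <- up[1]
    t_act <- t[i] + (vg - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
  }
  ipk <- which.max(v)
  thr <- 0.1 * v[ipk]
  below <- which(v[(ipk + 1):length(v)] < thr)
  if (length(below) == 0) return(NaN)
  j <- ipk + below[1] - 1  # last sample >= thr
  t_rep <- t[j] + (v[j] - thr) / (v[j] - v[j + 1]) * (t[j + 1] - t[j])
  t_rep - t_act
}

#' Endo-epicardial activation delays
#'
#' For each epicardial vertex, the delay `tau(epi) - tau(paired endo)` using
#' the closest-point pairing, with a box-plot summary (median, first and
#' third quartiles by linear interpolation, and extremes).
#'
#' @param mesh a [surface_mesh()].
#' @param pairing result of [pair_endo_epi()].
#' @param tau per-vertex activation times in ms.
#' @return A list with `delays` (per-EPI-vertex, named by vertex index) and
#'   `summary` (`median`, `q1`, `q3`, `min`, `max`).
#' @export
endo_epi_delays <- function(mesh, pairing, tau) {
  if (length(tau) != mesh$n_vertices)
    stop("tau length must match the mesh")
  delays <- tau[pairing$epi] - tau[pairing$endo]
  names(delays) <- pairing$epi
  q <- quantile(delays, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(delays = delays,
       summary = list(median = q[2], q1 = q[1], q3 = q[3],
                      min = min(delays), max = max(delays)))
}

#' Earliest-activation site and localization error
#'
#' `localize_earliest_site` returns the vertex with the earliest activation
#' time over the requested sub-surface (ties to the smallest index);
#' `localization_distance` is the geodesic distance in mm between the true
#' and identified sites.
#'
#' With `exclude_isolated = TRUE`, candidate vertices whose one-ring mean
#' activation time exceeds their own by more than `isolation_threshold` ms
#' are skipped: an automated stand-in for the visual exclusion of isolated,
#' irrelevant early activations.  Off by default.
#'
#' @param mesh a [surface_mesh()].
#' @param tau per-vertex activation times (finite on the restricted set).
#' @param restrict_to `"ALL"`, `"EPI"` or `"ENDO"`.
#' @param exclude_isolated drop isolated early-activation outliers.
#' @param isolation_threshold ms; see above.
#' @return Vertex index (1-based).
#' @export
localize_earliest_site <- function(mesh, tau, restrict_to = "ALL",
                                   exclude_isolated = FALSE,
                                   isolation_threshold = 30) {
  restrict_to <- match.arg(restrict_to, c("ALL", "EPI", "ENDO"))
  idx <- if (restrict_to == "ALL") seq_len(mesh$n_vertices) else
    which(mesh$surface_label == restrict_to)
  if (length(idx) == 0) stop("no vertices with label ", restrict_to)
  if (!exclude_isolated) return(idx[which.min(tau[idx])])
  e <- mesh_edges(mesh)
  ord <- idx[order(tau[idx])]
  for (v in ord) {
    nb <- c(e[e[, 1] == v, 2], e[e[, 2] == v, 1])
    if (length(nb) == 0 ||
        mean(tau[nb]) - tau[v] <= isolation_threshold)
      return(v)
  }
  ord[1]  # everything isolated: fall back to the plain argmin
}

#' @rdname localize_earliest_site
#' @param true_idx,found_idx vertex indices to compare.
#' @param extra_edges optional bridge edges passed to [geodesic_distances()].
#' @export
localization_distance <- function(mesh, true_idx, found_idx,
                                  extra_edges = NULL) {
  geodesic_distances(mesh, true_idx, extra_edges)[found_idx]
}

#' Full evaluation report for a reconstruction
#'
#' Collects every metric used to validate a reconstruction against ground
#' truth: CC/RE of activation and repolarization maps (global and per
#' sub-surface), per-time BSPM CC and RMSE, endo-epicardial delays (when the
#' mesh has an endocardium), and pacing-site localization.
#'
#' @param solution an `inverse_solution` from [solve_inverse()], or a
#'   [parameter_field()].
#' @param truth ground-truth list as produced by [synthesize_recording()]
#'   (fields `tau`, `rt`, `field`).
#' @param mesh,electrodes the geometry.
#' @param target the measured [bspm_recording()].
#' @param pacing_vertex optional true pacing-site vertex index for
#'   localization.
#' @param dt_template template step for re-simulating the fitted recording.
#' @return A list of class `evaluation_report`.
#' @export
evaluate_reconstruction <- function(solution, truth, mesh, electrodes,
                                    target, pacing_vertex = NULL,
                                    dt_template = 0.05) {
  field <- if (inherits(solution, "inverse_solution")) solution$field else
    solution
  labels <- mesh$surface_label
  at <- map_metrics(field$tau, truth$tau, labels)

  # reconstructed phi_e and RTs by the same max-positive-slope rule
  fitted <- simulate_bspm(mesh, electrodes, field, target$times,
                          dt_template)
  S <- outer(-field$tau, target$times, "+")
  bank <- template_bank(field$tau_out, field$tau_close,
                        field_template_duration(field, target$times,
                                                dt_template),
                        dt_template)
  Vm <- field$A * bank_lookup(bank$v, bank$pair_index, S, dt_template)
  hp <- vm_to_extracellular(Vm)
  rt_rec <- suppressWarnings(
    extract_repolarization_times(hp, field$tau, target$times))
  ok <- is.finite(rt_rec) & is.finite(truth$rt)
  rt <- if (sum(ok) >= 3)
    map_metrics(rt_rec[ok], truth$rt[ok], labels[ok]) else
    list(cc = NaN, re = NaN)

  bspm <- bspm_metrics(fitted, target)

  report <- list(cc_at = at$cc, re_at = at$re,
                 cc_at_epi = at$cc_epi, cc_at_endo = at$cc_endo,
                 cc_rt = rt$cc, re_rt = rt$re,
                 cc_rt_epi = rt$cc_epi, cc_rt_endo = rt$cc_endo,
                 cc_bspm_mean = bspm$cc_mean, cc_bspm_sd = bspm$cc_sd,
                 rmse_bspm_mean = bspm$rmse_mean,
                 rmse_bspm_sd = bspm$rmse_sd,
                 cc_bspm = bspm$cc, rmse_bspm = bspm$rmse,
                 rt_reconstructed = rt_rec)
  if (any(labels == "ENDO")) {
    pairing <- pair_endo_epi(mesh)
    report$delays <- endo_epi_delays(mesh, pairing, field$tau)
    report$delays_reference <- endo_epi_delays(mesh, pairing, truth$tau)
  }
  if (!is.null(pacing_vertex)) {
    found <- localize_earliest_site(mesh, field$tau, "ALL")
    report$localization_vertex <- found
    report$localization_mm <-
      localization_distance(mesh, pacing_vertex, found,
                            extra_edges = auto_bridges(mesh))
  }
  structure(report, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report\n")
  cat(sprintf("  AT:   CC = %.3f  RE = %.3f\n", x$cc_at, x$re_at))
  cat(sprintf("  RT:   CC = %.3f  RE = %.3f\n", x$cc_rt, x$re_rt))
  cat(sprintf("  BSPM: CC = %.2f +/- %.2f  RMSE = %.3g +/- %.3g\n",
              x$cc_bspm_mean, x$cc_bspm_sd, x$rmse_bspm_mean, x$rmse_bspm_sd))
  if (!is.null(x$localization_mm))
    cat(sprintf("  pacing-site localization: %.1f mm (vertex %d)\n",
                x$localization_mm, x$localization_vertex))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' `write_report_json` writes the full report; `write_report_csv` writes one
#' flat row of the scalar metrics (for multi-case summary tables).
#'
#' @param report an `evaluation_report`.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_report_csv <- function(report, path) {
  scalars <- report[c("cc_at", "re_at", "cc_at_epi", "cc_at_endo",
                      "cc_rt", "re_rt", "cc_bspm_mean", "cc_bspm_sd",
                      "rmse_bspm_mean", "rmse_bspm_sd")]
  scalars <- scalars[!vapply(scalars, is.null, logical(1))]
  if (!is.null(report$localization_mm))
    scalars$localization_mm <- report$localization_mm
  write.csv(as.data.frame(scalars), path, row.names = FALSE)
  invisible(path)
}
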