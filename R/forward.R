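#' Build the infinite-medium transfer matrix
#'
#' Entry `(j, i)` is `1 / (4 pi ||x_i - y_j||)` (units 1/mm): the kernel of
#' the Laplace solution in an infinite homogeneous medium, linking the
#' extracellular potential at heart vertex `i` to the potential at electrode
#' `j`.
#'
#' @param mesh a [surface_mesh()].
#' @param electrodes an [electrode_set()].
#' @return Numeric matrix `N_T x N_H`.
#' @export
build_transfer <- function(mesh, electrodes) {
  stopifnot(inherits(mesh, "surface_mesh"),
            inherits(electrodes, "electrode_set"))
  y <- electrodes$positions
  x <- mesh$vertices
  d2 <- outer(rowSums(y^2), rowSums(x^2), "+") - 2 * y %*% t(x)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  if (any(d == 0)) {
    bad <- which(d == 0, arr.ind = TRUE)[1, ]
    stop("electrode ", bad[1], " coincides with mesh vertex ", bad[2],
         " (zero distance in transfer kernel)")
  }
  1 / (4 * pi * d)
}

#' Transmembrane voltage to extracellular potentials
#'
#' Spatial-mean referencing: `phi_e(x_i, t) = Vm_bar(t) - Vm(x_i, t)` where
#' `Vm_bar(t)` is the unweighted mean over all vertices of both surfaces.
#' Each time-column of `phi_e` therefore sums to zero.
#'
#' @param Vm numeric matrix `N_H x T_max` of transmembrane voltages.
#' @return A list of class `heart_potential_set` with `phi_e` (`N_H x T_max`)
#'   and `vm_mean` (length `T_max`).
#' @export
vm_to_extracellular <- function(Vm) {
  Vm <- as.matrix(Vm)
  vbar <- colMeans(Vm)
  phi_e <- matrix(vbar, nrow(Vm), ncol(Vm), byrow = TRUE) - Vm
  structure(list(phi_e = phi_e, vm_mean = vbar),
            class = "heart_potential_set")
}

#' Project extracellular potentials to the body surface
#'
#' Matrix product of the transfer kernel with the heart potentials, per time
#' sample.
#'
#' @param hp a `heart_potential_set` from [vm_to_extracellular()].
#' @param transfer transfer matrix from [build_transfer()].
#' @param times time grid in ms (strictly increasing, length = ncol(phi_e)).
#' @return A `bspm_recording`: list with `phi` (`N_T x T_max`) and `times`.
#' @export
extracellular_to_body <- function(hp, transfer, times) {
  stopifnot(inherits(hp, "heart_potential_set"))
  if (ncol(transfer) != nrow(hp$phi_e))
    stop("transfer matrix has ", ncol(transfer),
         " columns but phi_e has ", nrow(hp$phi_e), " vertices")
  bspm_recording(transfer %*% hp$phi_e, times)
}

#' Body-surface potential recording
#'
#' @param phi numeric matrix `N_T x T_max` (electrodes by time samples).
#' @param times strictly increasing time grid in ms, length `T_max` (>= 2).
#' @return An object of class `bspm_recording`.
#' @export
bspm_recording <- function(phi, times) {
  phi <- as.matrix(phi)
  times <- as.numeric(times)
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("'times' must be strictly increasing with at least 2 samples")
  if (ncol(phi) != length(times))
    stop("ncol(phi) must equal length(times)")
  structure(list(phi = phi, times = times), class = "bspm_recording")
}

#' @export
print.bspm_recording <- function(x, ...) {
  cat("bspm_recording:", nrow(x$phi), "electrodes x", ncol(x$phi),
      "samples, t in [", min(x$times), ",", max(x$times), "] ms\n")
  invisible(x)
}

#' Read/write a body-surface recording as CSV
#'
#' First row holds the time grid (ms), each following row one electrode.
#' Values are written at full double precision, so a write-read round trip is
#' exact.
#'
#' @param recording a [bspm_recording()].
#' @param path file path.
#' @export
write_bspm_csv <- function(recording, path) {
  stopifnot(inherits(recording, "bspm_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(v) paste(formatC(v, format = "g", digits = 17),
                           collapse = ",")
  writeLines(fmt(recording$times), con)
  for (j in seq_len(nrow(recording$phi))) writeLines(fmt(recording$phi[j, ]),
                                                     con)
  invisible(path)
}

#' @rdname write_bspm_csv
#' @export
read_bspm_csv <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(strsplit(lines, ","), as.numeric)
  times <- rows[[1]]
  phi <- do.call(rbind, rows[-1])
  bspm_recording(phi, times)
}

## ---------------------------------------------------------------------------
## Template-bank evaluation: one Mitchell-Schaeffer template per unique
## (tau_out, tau_close) pair (rounded to 1e-6 ms), evaluated for all vertices
## and times by vectorized linear interpolation on the shared uniform grid.

template_bank <- function(tau_out, tau_close, duration, dt,
                          params_base = ms_parameters(),
                          with_sens = FALSE, v0 = 0.15, h0 = 1) {
  key <- paste(round(tau_out, 6), round(tau_close, 6))
  uniq <- !duplicated(key)
  bank <- .ms_bank_cpp(tau_out[uniq], tau_close[uniq],
                       params_base$tau_in, params_base$tau_open,
                       params_base$v_gate, v0, h0, duration, dt, with_sens)
  bank$pair_index <- match(key, key[uniq])
  bank$dt <- dt
  bank
}

# Interpolate bank trace matrix M (L x U) at S (N x T) of per-vertex template
# times; pair_index maps vertex -> bank column.
bank_lookup <- function(M, pair_index, S, dt, slope = FALSE) {
  L <- nrow(M)
  s_end <- (L - 1) * dt
  Sc <- pmin(pmax(S, 0), s_end)
  i0 <- pmin(floor(Sc / dt), L - 2)
  col <- matrix(pair_index, nrow(S), ncol(S))
  li0 <- (col - 1) * L + i0 + 1
  if (slope) {
    out <- (M[li0 + 1] - M[li0]) / dt
    out[S < 0 | S > s_end] <- 0
  } else {
    fr <- Sc / dt - i0
    out <- M[li0] * (1 - fr) + M[li0 + 1] * fr
    out[S < 0] <- 0
  }
  dim(out) <- dim(S)
  out
}

# Template duration needed so every (t - tau) query lands on the grid.
field_template_duration <- function(field, times, dt) {
  needed <- max(times) - min(field$tau)
  max(ceiling(max(needed, 10) / dt) * dt, 10 * dt)
}

#' Simulate a body-surface recording from a parameter field
#'
#' Composes the full forward model: per-node action-potential templates for
#' each unique `(tau_out, tau_close)` pair (cached within the call), the
#' shifted/rescaled ansatz `Vm(x_i, t_k) = A v_i(t_k - tau_i)`, spatial-mean
#' referencing, and projection through the transfer matrix.
#'
#' @param mesh a [surface_mesh()].
#' @param electrodes an [electrode_set()].
#' @param field a [parameter_field()] matching the mesh.
#' @param times recording time grid in ms.
#' @param dt_template template integration step in ms.
#' @param params_base fixed model constants ([ms_parameters()]); `tau_out`
#'   and `tau_close` entries are overridden per node by `field`.
#' @param transfer optional precomputed transfer matrix.
#' @return A [bspm_recording()].
#' @export
simulate_bspm <- function(mesh, electrodes, field, times,
                          dt_template = 0.05,
                          params_base = ms_parameters(),
                          transfer = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"),
            inherits(field, "parameter_field"))
  if (length(field$tau) != mesh$n_vertices)
    stop("parameter field has ", length(field$tau),
         " nodes but mesh has ", mesh$n_vertices)
  if (is.null(transfer)) transfer <- build_transfer(mesh, electrodes)
  dur <- field_template_duration(field, times, dt_template)
  bank <- template_bank(field$tau_out, field$tau_close, dur, dt_template,
                        params_base)
  S <- outer(-field$tau, times, "+")
  Vm <- field$A * bank_lookup(bank$v, bank$pair_index, S, dt_template)
  hp <- vm_to_extracellular(Vm)
  extracellular_to_body(hp, transfer, times)
}
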