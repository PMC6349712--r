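#' Distributed parameter field
#'
#' The unknowns of the identification problem: a single global amplitude `A`
#' and three per-vertex fields (`tau_out`, `tau_close`, activation time
#' `tau`), `1 + 3 N_H` values in all.  The packing order into one vector is
#' `c(A, tau_out, tau_close, tau)`.
#'
#' @param A global amplitude (scalar).
#' @param tau_out,tau_close per-vertex repolarization parameters in ms;
#'   scalars are recycled to `n` vertices.
#' @param tau per-vertex activation times in ms.
#' @param n number of vertices (defaults to the longest field given).
#' @return An object of class `parameter_field`.
#' @export
parameter_field <- function(A = 10, tau_out = 6, tau_close = 150, tau = 0,
                            n = NULL) {
  if (is.null(n)) n <- max(length(tau_out), length(tau_close), length(tau))
  f <- structure(list(A = as.numeric(A)[1],
                      tau_out = rep_len(as.numeric(tau_out), n),
                      tau_close = rep_len(as.numeric(tau_close), n),
                      tau = rep_len(as.numeric(tau), n)),
                 class = "parameter_field")
  f
}

#' @export
print.parameter_field <- function(x, ...) {
  cat("parameter_field:", length(x$tau), "nodes, A =", signif(x$A, 4), "\n")
  cat("  tau      [", signif(min(x$tau), 4), ",", signif(max(x$tau), 4),
      "] ms\n")
  cat("  tau_out  [", signif(min(x$tau_out), 4), ",",
      signif(max(x$tau_out), 4), "] ms\n")
  cat("  tau_close[", signif(min(x$tau_close), 4), ",",
      signif(max(x$tau_close), 4), "] ms\n")
  invisible(x)
}

#' Pack / unpack a parameter field to the optimization vector
#'
#' @param field a [parameter_field()].
#' @return `pack_field`: numeric vector `c(A, tau_out, tau_close, tau)` of
#'   length `1 + 3 n`; `unpack_field`: the [parameter_field()].
#' @export
pack_field <- function(field) {
  c(field$A, field$tau_out, field$tau_close, field$tau)
}

#' @rdname pack_field
#' @param p packed numeric vector of length `1 + 3 n`.
#' @param n number of vertices.
#' @export
unpack_field <- function(p, n) {
  if (length(p) != 1 + 3 * n)
    stop("packed vector length ", length(p), " != 1 + 3*", n)
  parameter_field(A = p[1],
                  tau_out = p[1 + seq_len(n)],
                  tau_close = p[1 + n + seq_len(n)],
                  tau = p[1 + 2 * n + seq_len(n)])
}

# lower bounds enforced after every update
.tau_out_min <- 0.5
.tau_close_min <- 10

clip_field_vector <- function(p, n) {
  io <- 1 + seq_len(n)
  ic <- 1 + n + seq_len(n)
  p[io] <- pmax(p[io], .tau_out_min)
  p[ic] <- pmax(p[ic], .tau_close_min)
  p
}

center_columns <- function(M) {
  # subtract per-time (column) electrode mean: reference-electrode freedom
  M - matrix(colMeans(M), nrow(M), ncol(M), byrow = TRUE)
}

## ---------------------------------------------------------------------------
## Objective machinery.  cost/cost_gradient share one evaluation path; the
## gradient is the exact chain rule through the implemented pipeline:
##   J = 1/2 || C_T (T M Vm - phi*) ||_F^2
## with C_T = I - 11'/N_T (electrode centering, idempotent) and
## M = 11'/N_H - I (spatial-mean referencing, symmetric), so
##   dJ/dVm = M (T' R) with R the centered residual,
## then the ansatz partials contract dJ/dVm down to (A, tau_out, tau_close,
## tau) components.

objective_context <- function(mesh, electrodes, target, dt_template,
                              params_base, transfer = NULL) {
  stopifnot(inherits(target, "bspm_recording"))
  if (nrow(target$phi) != electrodes$n_electrodes)
    stop("target recording has ", nrow(target$phi),
         " electrodes but the electrode set has ", electrodes$n_electrodes)
  if (is.null(transfer)) transfer <- build_transfer(mesh, electrodes)
  list(mesh = mesh, electrodes = electrodes, transfer = transfer,
       times = target$times, phis_c = center_columns(target$phi),
       dt = dt_template, params_base = params_base,
       n = mesh$n_vertices)
}

eval_objective <- function(ctx, field, gradient = FALSE) {
  n <- ctx$n
  dur <- field_template_duration(field, ctx$times, ctx$dt)
  bank <- template_bank(field$tau_out, field$tau_close, dur, ctx$dt,
                        ctx$params_base, with_sens = gradient)
  S <- outer(-field$tau, ctx$times, "+")
  Vtr <- bank_lookup(bank$v, bank$pair_index, S, ctx$dt)
  Vm <- field$A * Vtr
  phi_e <- vm_to_extracellular(Vm)$phi_e
  phi <- ctx$transfer %*% phi_e
  R <- center_columns(phi) - ctx$phis_c
  J <- 0.5 * sum(R * R)
  if (!gradient) return(list(J = J))
  G <- crossprod(ctx$transfer, R)                 # T' R, N_H x T
  G_Vm <- matrix(colMeans(G), n, ncol(G), byrow = TRUE) - G  # M G
  g_A <- sum(G_Vm * Vtr)
  sl <- bank_lookup(bank$v, bank$pair_index, S, ctx$dt, slope = TRUE)
  g_tau <- rowSums(G_Vm * (-field$A * sl))
  so <- bank_lookup(bank$s_out, bank$pair_index, S, ctx$dt)
  sc <- bank_lookup(bank$s_close, bank$pair_index, S, ctx$dt)
  g_out <- rowSums(G_Vm * (field$A * so))
  g_close <- rowSums(G_Vm * (field$A * sc))
  list(J = J, grad = c(g_A, g_out, g_close, g_tau))
}

#' Mean-centered least-squares cost
#'
#' \deqn{J = \frac12 \sum_k \sum_j
#'   [(\phi_T(y_j,t_k) - \bar\phi_T(t_k)) -
#'    (\phi^\star(y_j,t_k) - \bar\phi^\star(t_k))]^2}
#' where the bars are per-time means over electrodes: potentials are defined
#' up to a per-time constant and are referenced to their electrode mean
#' (Wilson-central-terminal style).
#'
#' @param field a [parameter_field()].
#' @param target the measured [bspm_recording()]; its time grid is the
#'   optimization grid.
#' @param mesh,electrodes the geometry.
#' @param dt_template template integration step in ms.
#' @param params_base fixed model constants.
#' @param transfer optional precomputed transfer matrix.
#' @return Scalar `J >= 0`.
#' @export
cost <- function(field, target, mesh, electrodes, dt_template = 0.05,
                 params_base = ms_parameters(), transfer = NULL) {
  ctx <- objective_context(mesh, electrodes, target, dt_template,
                           params_base, transfer)
  eval_objective(ctx, field)$J
}

#' Analytic gradient of the cost
#'
#' Exact chain rule through the implemented forward pipeline (electrode
#' centering, transfer matrix, spatial-mean referencing, ansatz partials).
#' Returned in packing order `c(A, tau_out, tau_close, tau)`.
#'
#' @inheritParams cost
#' @return Numeric vector of length `1 + 3 N_H` (attribute `J` holds the
#'   cost at `field`).
#' @export
cost_gradient <- function(field, target, mesh, electrodes,
                          dt_template = 0.05,
                          params_base = ms_parameters(), transfer = NULL) {
  ctx <- objective_context(mesh, electrodes, target, dt_template,
                           params_base, transfer)
  res <- eval_objective(ctx, field, gradient = TRUE)
  structure(res$grad, J = res$J)
}

#' One RMSprop update
#'
#' \deqn{\kappa \leftarrow \gamma\kappa + (1-\gamma)\, \nabla J \odot \nabla J}
#' \deqn{P \leftarrow P - \eta\, \nabla J \oslash (\kappa^{\circ 1/2} + 10^{-7})}
#' (elementwise), followed by clipping `tau_out >= 0.5` ms and
#' `tau_close >= 10` ms.
#'
#' @param state optimizer state: list with packed vector `P`, accumulator
#'   `kappa`, `n` (vertex count), and optionally `gamma` (default 0.9) and
#'   `epsilon` (default 1e-7).
#' @param gradient packed gradient vector.
#' @param eta learning rate.
#' @return The updated state.
#' @export
rmsprop_update <- function(state, gradient, eta) {
  gamma <- state$gamma %||% 0.9
  eps <- state$epsilon %||% 1e-7
  if (length(gradient) != length(state$P))
    stop("gradient length does not match parameter vector")
  kappa <- gamma * state$kappa + (1 - gamma) * gradient * gradient
  P <- state$P - eta * gradient / (sqrt(kappa) + eps)
  state$P <- clip_field_vector(P, state$n)
  state$kappa <- kappa
  state$eta <- eta
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-iteration learning-rate search
#'
#' Evaluates the tentative RMSprop update on a fixed grid of `n_grid`
#' log-spaced learning rates spanning `[1e-5, 1e2]` and returns the one whose
#' resulting cost is smallest (ties to the smaller rate).  The step is taken
#' even if every candidate raises the cost, matching plain RMSprop behavior.
#'
#' @param state optimizer state (see [rmsprop_update()]).
#' @param gradient packed gradient at `state$P`.
#' @param cost_evaluator function taking a packed vector, returning `J`.
#' @param eta_range numeric length-2 range of learning rates.
#' @param n_grid number of grid points (default 15).
#' @return Selected `eta`, with attributes `J` (cost at the chosen update)
#'   and `P` (the chosen updated vector) and `kappa`.
#' @export
select_learning_rate <- function(state, gradient, cost_evaluator,
                                 eta_range = c(1e-5, 1e2), n_grid = 15) {
  gamma <- state$gamma %||% 0.9
  eps <- state$epsilon %||% 1e-7
  kappa <- gamma * state$kappa + (1 - gamma) * gradient * gradient
  step_dir <- gradient / (sqrt(kappa) + eps)
  etas <- 10^seq(log10(eta_range[1]), log10(eta_range[2]),
                 length.out = n_grid)
  Js <- numeric(n_grid)
  Ps <- vector("list", n_grid)
  for (i in seq_len(n_grid)) {
    Ps[[i]] <- clip_field_vector(state$P - etas[i] * step_dir, state$n)
    Js[i] <- cost_evaluator(Ps[[i]])
  }
  best <- which.min(Js)  # first minimum = smallest eta on the ascending grid
  structure(etas[best], J = Js[best], P = Ps[[best]], kappa = kappa)
}

#' Stopping rule for the inverse solver
#'
#' The optimization stops when the relative change in `J` stays below
#' `flat_tolerance` for `flat_window` consecutive iterations, or at
#' `max_iterations`.
#'
#' @param max_iterations maximum outer iterations (>= 1).
#' @param flat_tolerance relative cost-change threshold (> 0).
#' @param flat_window number of consecutive flat iterations required.
#' @export
stopping_rule <- function(max_iterations = 500, flat_tolerance = 1e-6,
                          flat_window = 10) {
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (flat_tolerance <= 0) stop("flat_tolerance must be positive")
  structure(list(max_iterations = max_iterations,
                 flat_tolerance = flat_tolerance,
                 flat_window = flat_window), class = "stopping_rule")
}

#' Solve the parameter-identification problem
#'
#' RMSprop gradient descent on the mean-centered least-squares cost, with an
#' analytic gradient and a per-iteration learning-rate search over
#' `[1e-5, 1e2]`.  Default initialization: `A = 10`, `tau_out = 6` ms,
#' `tau_close = 150` ms at every node, and a spatially constant activation
#' time `tau = tau0`.  With this uniform start the predicted torso potentials
#' are identically zero.
#'
#' @param target measured [bspm_recording()].
#' @param mesh,electrodes the geometry the solution lives on.
#' @param init optional [parameter_field()] initial guess; default as above.
#' @param tau0 initial activation time in ms (default 60).
#' @param stop a [stopping_rule()].
#' @param dt_template template integration step in ms.
#' @param params_base fixed model constants.
#' @param verbose print progress every `verbose` iterations (0 = silent).
#' @return A list of class `inverse_solution`: `field` (recovered
#'   [parameter_field()]) and `diagnostics` (`J_history`, `grad_norm`,
#'   `eta_history`, `iterations`, `elapsed_sec`, `n_cost_evaluations`).
#' @export
solve_inverse <- function(target, mesh, electrodes, init = NULL, tau0 = 60,
                          stop = stopping_rule(), dt_template = 0.05,
                          params_base = ms_parameters(), verbose = 0) {
  ctx <- objective_context(mesh, electrodes, target, dt_template,
                           params_base)
  n <- mesh$n_vertices
  if (is.null(init))
    init <- parameter_field(A = 10, tau_out = 6, tau_close = 150,
                            tau = tau0, n = n)
  n_evals <- 0L
  cost_eval <- function(p) {
    n_evals <<- n_evals + 1L
    eval_objective(ctx, unpack_field(p, n))$J
  }
  state <- list(P = clip_field_vector(pack_field(init), n),
                kappa = numeric(1 + 3 * n), gamma = 0.9, epsilon = 1e-7,
                n = n)
  t0 <- proc.time()[["elapsed"]]
  res0 <- eval_objective(ctx, unpack_field(state$P, n), gradient = TRUE)
  J <- res0$J
  grad <- res0$grad
  J_history <- J
  grad_norm <- sqrt(sum(grad^2))
  eta_history <- numeric(0)
  flat <- 0L
  iter <- 0L
  while (iter < stop$max_iterations) {
    if (!is.finite(J) || !all(is.finite(grad)))
      stop("non-finite cost or gradient at iteration ", iter,
           " (J = ", J, ", |grad| finite: ", all(is.finite(grad)), ")")
    if (J == 0) break  # perfect fit (e.g. uniform init against zero target)
    sel <- select_learning_rate(state, grad, cost_eval)
    state$P <- attr(sel, "P")
    state$kappa <- attr(sel, "kappa")
    J_new <- attr(sel, "J")
    eta_history <- c(eta_history, as.numeric(sel))
    rel <- abs(J - J_new) / max(J, .Machine$double.eps)
    flat <- if (rel < stop$flat_tolerance) flat + 1L else 0L
    J <- J_new
    iter <- iter + 1L
    res <- eval_objective(ctx, unpack_field(state$P, n), gradient = TRUE)
    grad <- res$grad
    J_history <- c(J_history, J)
    grad_norm <- c(grad_norm, sqrt(sum(grad^2)))
    if (verbose > 0 && iter %% verbose == 0)
      message(sprintf("iter %4d  J = %.6g  |grad| = %.3g  eta = %.3g",
                      iter, J, grad_norm[length(grad_norm)],
                      eta_history[length(eta_history)]))
    if (flat >= stop$flat_window) break
  }
  structure(list(
    field = unpack_field(state$P, n),
    diagnostics = list(J_history = J_history, grad_norm = grad_norm,
                       eta_history = eta_history, iterations = iter,
                       elapsed_sec = proc.time()[["elapsed"]] - t0,
                       n_cost_evaluations = n_evals)),
    class = "inverse_solution")
}

#' @export
print.inverse_solution <- function(x, ...) {
  d <- x$diagnostics
  cat("inverse_solution:", d$iterations, "iterations, J",
      signif(d$J_history[1], 4), "->",
      signif(d$J_history[length(d$J_history)], 4),
      sprintf("(%.1f s)\n", d$elapsed_sec))
  invisible(x)
}

#' Write solver diagnostics and recovered fields
#'
#' `write_diagnostics_csv` writes one row per iteration (iteration, J,
#' gradient norm, selected learning rate).  `write_field_csv` writes the
#' recovered per-vertex fields; `write_field_vtk` attaches them as scalar
#' fields to a VTK copy of the mesh.
#'
#' @param solution an `inverse_solution` from [solve_inverse()].
#' @param path output file.
#' @export
write_diagnostics_csv <- function(solution, path) {
  d <- solution$diagnostics
  k <- d$iterations
  write.csv(data.frame(iteration = 0:k,
                       J = d$J_history,
                       grad_norm = d$grad_norm,
                       eta = c(NA, d$eta_history)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diagnostics_csv
#' @param field a [parameter_field()].
#' @export
write_field_csv <- function(field, path) {
  write.csv(data.frame(vertex = seq_along(field$tau),
                       tau_ms = field$tau,
                       tau_out_ms = field$tau_out,
                       tau_close_ms = field$tau_close,
                       A = field$A),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diagnostics_csv
#' @param mesh the [surface_mesh()] the field lives on.
#' @export
write_field_vtk <- function(field, mesh, path) {
  write_mesh(mesh, path,
             point_data = list(tau = field$tau, tau_out = field$tau_out,
                               tau_close = field$tau_close))
  invisible(path)
}
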