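#' Mitchell-Schaeffer model parameters
#'
#' The two-variable ionic model has five parameters.  `tau_in`, `tau_open`
#' and `v_gate` shape the upstroke and excitability threshold and are kept at
#' their standard values; `tau_out` (repolarization speed) and `tau_close`
#' (plateau duration) are the ones identified by the inverse solver.
#'
#' @param tau_in,tau_out,tau_open,tau_close time constants in ms (all > 0).
#' @param v_gate dimensionless threshold in (0, 1).
#' @return A list of class `ms_parameters`.
#' @export
ms_parameters <- function(tau_in = 0.3, tau_out = 6, tau_open = 120,
                          tau_close = 150, v_gate = 0.13) {
  p <- list(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
            tau_close = tau_close, v_gate = v_gate)
  if (any(unlist(p[1:4]) <= 0))
    stop("all Mitchell-Schaeffer time constants must be positive")
  if (v_gate <= 0 || v_gate >= 1)
    stop("v_gate must lie strictly between 0 and 1")
  structure(p, class = "ms_parameters")
}

.template_cache <- new.env(parent = emptyenv())

#' Clear the cached action-potential templates
#' @export
template_cache_clear <- function() {
  rm(list = ls(.template_cache), envir = .template_cache)
  invisible(NULL)
}

#' Integrate the Mitchell-Schaeffer model
#'
#' Fixed-step RK4 solution of
#' \deqn{v' = h v^2 (1 - v)/\tau_{in} - v/\tau_{out}}
#' \deqn{h' = (1 - h)/\tau_{open} \textrm{ if } v < v_{gate}, \quad
#'       h' = -h/\tau_{close} \textrm{ otherwise}}
#' from the excited initial state `(v, h) = (0.15, 1)` (the model's resting
#' state is `(0, 1)`).  With `with_sensitivities = TRUE`, forward sensitivity
#' equations for `dv/dtau_out` and `dv/dtau_close` are co-integrated; the
#' gate regime in the sensitivity system follows the nominal trajectory's
#' indicator and the switch time itself is not differentiated.
#'
#' Results are memoised per parameter set (keyed to 1e-6 ms).
#'
#' @param params an [ms_parameters()] object.
#' @param duration template length in ms (>= one full action potential).
#' @param dt_template integration/storage step in ms; steps above 0.5 ms
#'   under-resolve the upstroke and trigger a warning.
#' @param with_sensitivities logical; also integrate parameter sensitivities.
#' @param v0,h0 initial state; defaults give the action-potential shape.
#' @param cache logical; reuse memoised templates.
#' @return An object of class `ap_template`: uniform `time` grid, traces
#'   `v`, `h`, `dv_dt`, and (if requested) `s_out = dv/dtau_out`,
#'   `s_close = dv/dtau_close`, plus `dt` and the parameters.
#' @examples
#' tpl <- integrate_ms(ms_parameters(), duration = 500)
#' max(tpl$v)
#' @export
integrate_ms <- function(params = ms_parameters(), duration = 500,
                         dt_template = 0.05, with_sensitivities = FALSE,
                         v0 = 0.15, h0 = 1, cache = TRUE) {
  stopifnot(inherits(params, "ms_parameters"))
  if (duration <= 0 || dt_template <= 0)
    stop("'duration' and 'dt_template' must be positive")
  if (dt_template > 0.5)
    warning("dt_template > 0.5 ms under-resolves the upstroke (tau_in = ",
            params$tau_in, " ms)")
  key <- paste(sprintf("%.6f", c(unlist(params), duration, dt_template,
                                 v0, h0)), collapse = "|")
  key <- paste0(key, if (with_sensitivities) "|s" else "")
  if (cache && !is.null(tpl <- .template_cache[[key]])) return(tpl)
  out <- .ms_integrate_cpp(params$tau_in, params$tau_out, params$tau_open,
                           params$tau_close, params$v_gate, v0, h0,
                           duration, dt_template, with_sensitivities)
  tpl <- structure(list(time = out$time, v = out$v, h = out$h,
                        dv_dt = out$dv_dt,
                        s_out = if (with_sensitivities) out$s_out,
                        s_close = if (with_sensitivities) out$s_close,
                        dt = dt_template, params = params),
                   class = "ap_template")
  if (cache) .template_cache[[key]] <- tpl
  tpl
}

#' @export
print.ap_template <- function(x, ...) {
  cat("ap_template:", length(x$time), "samples, dt =", x$dt, "ms, peak v =",
      signif(max(x$v), 4), "\n")
  invisible(x)
}

#' Export a template as a two-column (t, v) CSV
#' @param template an [ap_template()][integrate_ms()].
#' @param path output file.
#' @export
write_template_csv <- function(template, path) {
  write.csv(data.frame(t_ms = template$time, v = template$v), path,
            row.names = FALSE)
  invisible(path)
}

# Linear interpolation of a template trace on its uniform grid.
# s: query times relative to activation (may be < 0 -> 0); returns value and,
# if slope = TRUE, the interpolant's segment slope (0 outside the template).
interp_uniform <- function(trace, dt, s, final_hold = TRUE) {
  L <- length(trace)
  s_end <- (L - 1) * dt
  sc <- pmin(pmax(s, 0), s_end)
  i0 <- pmin(floor(sc / dt), L - 2)
  fr <- sc / dt - i0
  val <- trace[i0 + 1] * (1 - fr) + trace[i0 + 2] * fr
  val[s < 0] <- 0
  val
}

interp_uniform_slope <- function(trace, dt, s) {
  L <- length(trace)
  s_end <- (L - 1) * dt
  sc <- pmin(pmax(s, 0), s_end)
  i0 <- pmin(floor(sc / dt), L - 2)
  sl <- (trace[i0 + 2] - trace[i0 + 1]) / dt
  sl[s < 0 | s > s_end] <- 0
  sl
}

#' Evaluate the action-potential ansatz and its partial derivatives
#'
#' The transmembrane voltage ansatz is `Vm(t) = A * v(t - tau)`, with the
#' template trace `v` linearly interpolated on its grid, defined as 0 before
#' activation (`t < tau`), and held at its final value past the template end.
#' Partial derivatives with respect to the amplitude `A`, the activation time
#' `tau`, and the repolarization parameters `tau_out` / `tau_close` (via the
#' co-integrated sensitivity traces) are returned alongside.
#'
#' `dVm/dtau` uses the interpolant's piecewise-constant segment slope; it is
#' exactly zero strictly before activation (as is the voltage), so the
#' gradient stays consistent with the causal, discretized voltage, and the
#' onset jump (v: 0 -> 0.15 at `t = tau`) itself contributes no derivative.
#'
#' @param template an [ap_template()][integrate_ms()] (with sensitivities if
#'   `dVm_dtau_out` / `dVm_dtau_close` are needed).
#' @param A amplitude factor.
#' @param tau activation time in ms (any real).
#' @param query_times numeric vector of times in ms.
#' @return A list with numeric vectors `vm`, `dVm_dA`, `dVm_dtau`,
#'   `dVm_dtau_out`, `dVm_dtau_close` (the last two `NULL` without
#'   sensitivities).
#' @examples
#' tpl <- integrate_ms()
#' eval_ansatz(tpl, A = 10, tau = 50, query_times = c(0, 50, 100))$vm
#' @export
eval_ansatz <- function(template, A, tau, query_times) {
  stopifnot(inherits(template, "ap_template"))
  s <- query_times - tau
  v <- interp_uniform(template$v, template$dt, s)
  sl <- interp_uniform_slope(template$v, template$dt, s)
  out <- list(vm = A * v,
              dVm_dA = v,
              dVm_dtau = -A * sl,
              dVm_dtau_out = NULL, dVm_dtau_close = NULL)
  if (!is.null(template$s_out)) {
    so <- interp_uniform(template$s_out, template$dt, s)
    sc <- interp_uniform(template$s_close, template$dt, s)
    out$dVm_dtau_out <- A * so
    out$dVm_dtau_close <- A * sc
  }
  out
}
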