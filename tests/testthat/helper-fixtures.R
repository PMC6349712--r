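# Shared fixtures and independent oracles, all built in code.

# regular tetrahedron surface: smallest valid closed mesh
tetra_mesh <- function(labels = NULL) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tr <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  surface_mesh(v, tr, labels)
}

# n x n planar unit grid, triangulated; vertex (i, j) -> index (i-1)*n + j
grid_mesh <- function(n) {
  v <- as.matrix(expand.grid(y = seq_len(n) - 1, x = seq_len(n) - 1))
  v <- cbind(v[, "x"], v[, "y"], 0)
  tr <- NULL
  idx <- function(i, j) (i - 1L) * n + j
  for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
    tr <- rbind(tr,
                c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  surface_mesh(v, tr)
}

# structured apex + rings triangulation of a spherical cap (independent of the
# package's generator); n_vertices = 1 + n_rings * m
ring_cap_mesh <- function(n_rings, m, radius = 30, labels = NULL) {
  theta <- seq_len(n_rings) / n_rings * (pi / 2)
  v <- matrix(c(0, 0, -radius), 1, 3)
  for (r in seq_len(n_rings)) {
    phi <- (seq_len(m) - 1) / m * 2 * pi
    v <- rbind(v, cbind(radius * sin(theta[r]) * cos(phi),
                        radius * sin(theta[r]) * sin(phi),
                        -radius * cos(theta[r])))
  }
  start <- function(r) 1L + (r - 1L) * m + 1L
  tr <- cbind(1L, start(1) + seq_len(m) - 1L,
              start(1) + seq_len(m) %% m)
  for (r in seq_len(n_rings - 1)) {
    lo <- start(r); hi <- start(r + 1)
    for (j in seq_len(m)) {
      j2 <- j %% m + 1L
      tr <- rbind(tr, c(lo + j - 1L, hi + j - 1L, hi + j2 - 1L),
                  c(lo + j - 1L, hi + j2 - 1L, lo + j2 - 1L))
    }
  }
  surface_mesh(v, tr, labels)
}

# attach an arbitrary valid triangulation to a point cloud (connectivity only;
# used where tests care about vertex positions, not surface shape)
cloud_mesh <- function(vertices, labels = NULL) {
  n <- nrow(vertices)
  stopifnot(n >= 3)
  tr <- cbind(seq_len(n - 2), seq_len(n - 2) + 1L, seq_len(n - 2) + 2L)
  surface_mesh(vertices, tr, labels)
}

# independent shortest-path oracle: iterative edge relaxation (Bellman-Ford
# style), no igraph
relaxation_shortest_path <- function(mesh, source) {
  e <- rbind(mesh$triangles[, c(1, 2)], mesh$triangles[, c(2, 3)],
             mesh$triangles[, c(1, 3)])
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  d <- rep(Inf, mesh$n_vertices)
  d[source] <- 0
  for (k in seq_len(mesh$n_vertices)) {
    d_new <- d
    for (r in seq_len(nrow(e))) {
      d_new[e[r, 2]] <- min(d_new[e[r, 2]], d[e[r, 1]] + w[r])
      d_new[e[r, 1]] <- min(d_new[e[r, 1]], d[e[r, 2]] + w[r])
    }
    if (identical(d_new, d)) break
    d <- d_new
  }
  d
}

# brute-force nearest-neighbor scan oracle
brute_force_pairing <- function(mesh) {
  epi <- which(mesh$surface_label == "EPI")
  endo <- which(mesh$surface_label == "ENDO")
  t(vapply(epi, function(i) {
    d <- sqrt(colSums((t(mesh$vertices[endo, , drop = FALSE]) -
                       mesh$vertices[i, ])^2))
    j <- which.min(d)
    c(endo[j], d[j])
  }, numeric(2)))
}

# independent Mitchell-Schaeffer reference: deSolve fixed-step RK4 on a
# plainly written RHS
desolve_ms <- function(params = ms_parameters(), duration = 400, dt = 0.01,
                       v0 = 0.15, h0 = 1) {
  rhs <- function(t, y, p) {
    v <- y[1]; h <- y[2]
    dv <- h * v^2 * (1 - v) / p$tau_in - v / p$tau_out
    dh <- if (v >= p$v_gate) -h / p$tau_close else (1 - h) / p$tau_open
    list(c(dv, dh))
  }
  out <- deSolve::ode(c(v = v0, h = h0), seq(0, duration, by = dt), rhs,
                      params, method = "rk4")
  list(time = out[, 1], v = out[, 2], h = out[, 3])
}

# APD90 computed directly from any (t, v) trace, independent of the package
trace_apd90 <- function(t, v, v_gate = 0.13) {
  up <- which(v[-1] >= v_gate & v[-length(v)] < v_gate)
  t_act <- if (v[1] >= v_gate) t[1] else {
    i <- up[1]
    t[i] + (v_gate - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
  }
  ipk <- which.max(v)
  thr <- 0.1 * v[ipk]
  j <- ipk + which(v[(ipk + 1):length(v)] < thr)[1] - 1
  t_rep <- t[j] + (v[j] - thr) / (v[j] - v[j + 1]) * (t[j + 1] - t[j])
  t_rep - t_act
}

# linear interpolation on a template grid (plain reimplementation)
interp_val <- function(tpl, t) {
  i <- floor(t / tpl$dt)
  fr <- t / tpl$dt - i
  tpl$v[i + 1] * (1 - fr) + tpl$v[i + 2] * fr
}

# small complete synthetic case shared by solver tests
small_case <- function(n_target = 30, n_electrodes = 16, t_end = 99,
                       seed = 42) {
  g <- make_synthetic_geometry(n_target = n_target,
                               n_electrodes = n_electrodes)
  set.seed(seed)
  n <- g$mesh$n_vertices
  truth <- parameter_field(A = 10, tau_out = runif(n, 5, 8),
                           tau_close = runif(n, 120, 180),
                           tau = runif(n, 0, 40), n = n)
  times <- seq(0, t_end, 1)
  list(mesh = g$mesh, electrodes = g$electrodes, truth = truth,
       times = times,
       target = simulate_bspm(g$mesh, g$electrodes, truth, times))
}
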