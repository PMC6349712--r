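test_that("scenario construction validates its inputs", {
  expect_error(scenario(data.frame(vertex = 1, onset = 0)), "seed")
  expect_error(scenario(data.frame(v = 1), seed = 1), "pacing")
  expect_error(scenario(data.frame(vertex = 1, onset = 0),
                        conduction_velocity = 0, seed = 1), "positive")
})

test_that("activation maps follow geodesic front spread", {
  m <- ring_cap_mesh(6, 10)
  # pacing vertex activates at its onset
  tau <- make_activation_map(m, data.frame(vertex = 5, onset = 12), cv = 2)
  expect_equal(tau[5], 12)
  # unit velocity: activation equals geodesic distance
  tau1 <- make_activation_map(m, data.frame(vertex = 1, onset = 0), cv = 1)
  expect_equal(tau1, geodesic_distances(m, 1), tolerance = 1e-9)
  # two sites: elementwise minimum of single-site maps
  tau_a <- make_activation_map(m, data.frame(vertex = 1, onset = 0), cv = 1)
  tau_b <- make_activation_map(m, data.frame(vertex = 40, onset = 5), cv = 1)
  tau_ab <- make_activation_map(m, data.frame(vertex = c(1, 40),
                                              onset = c(0, 5)), cv = 1)
  expect_equal(tau_ab, pmin(tau_a, tau_b), tolerance = 1e-12)
  expect_error(make_activation_map(m, data.frame(vertex = 999, onset = 0),
                                   cv = 1), "out of range")
})

test_that("activation maps satisfy the eikonal bound on every edge", {
  g <- make_synthetic_geometry(semi_axes = c(30, 30, 60),
                               wall_thickness = 8, n_target = 60,
                               n_electrodes = 8)
  m <- g$mesh
  cv <- 0.8
  tau <- make_activation_map(m, data.frame(vertex = 3, onset = 0), cv)
  e <- ecginverse:::mesh_edges(m)
  len <- sqrt(rowSums((m$vertices[e[, 1], ] - m$vertices[e[, 2], ])^2))
  expect_true(all(abs(tau[e[, 1]] - tau[e[, 2]]) <= len / cv + 1e-9))
})

test_that("transmural bridges connect separate shells", {
  g <- make_synthetic_geometry(semi_axes = c(30, 30, 60),
                               wall_thickness = 8, n_target = 60,
                               n_electrodes = 8)
  endo_idx <- which(g$mesh$surface_label == "ENDO")[1]
  # endocardial pacing must reach the epicardium through auto bridges
  tau <- make_activation_map(g$mesh, data.frame(vertex = endo_idx,
                                                onset = 0), cv = 1)
  expect_true(all(is.finite(tau)))
  # with bridging disabled the two shells are mutually unreachable
  expect_error(make_activation_map(g$mesh,
                                   data.frame(vertex = endo_idx, onset = 0),
                                   cv = 1, bridges = "none"), "unreachable")
})

test_that("parameter fields implement gradients, noise and determinism", {
  g <- make_synthetic_geometry(semi_axes = c(30, 30, 60),
                               wall_thickness = 8, n_target = 60,
                               n_electrodes = 8)
  m <- g$mesh
  # degenerate spec: constant fields
  f0 <- make_parameter_fields(m, list(endo_epi_delta_tau_close = 0,
                                      apex_base_delta_tau_close = 0,
                                      noise_sd_tau_close = 0,
                                      noise_sd_tau_out = 0), seed = 2)
  expect_true(all(f0$tau_close == 150))
  expect_true(all(f0$tau_out == 6))
  # endo-epi offset: ENDO mean sits delta below EPI mean (no noise)
  f1 <- make_parameter_fields(m, list(endo_epi_delta_tau_close = -20,
                                      apex_base_delta_tau_close = 0,
                                      noise_sd_tau_close = 0,
                                      noise_sd_tau_out = 0), seed = 2)
  endo <- m$surface_label == "ENDO"
  expect_equal(mean(f1$tau_close[endo]) - mean(f1$tau_close[!endo]), -20,
               tolerance = 1e-12)
  # determinism
  f2 <- make_parameter_fields(m, list(), seed = 7)
  f3 <- make_parameter_fields(m, list(), seed = 7)
  expect_identical(f2, f3)
  # out-of-range values are clipped with a warning
  expect_warning(make_parameter_fields(m, list(tau_close = 295,
                                               apex_base_delta_tau_close = 30),
                                       seed = 1), "clipped")
})

test_that("noiseless synthesis reproduces the forward model bit-for-bit", {
  g <- make_synthetic_geometry(n_target = 30, n_electrodes = 8)
  scn <- scenario(pacing = data.frame(vertex = 2, onset = 0), seed = 3)
  times <- seq(0, 400, 2)
  sim <- synthesize_recording(scn, g$mesh, g$electrodes, times)
  truth <- sim$truth$field
  direct <- simulate_bspm(g$mesh, g$electrodes, truth, times)
  expect_identical(sim$recording$phi, direct$phi)
  # earliest activation at the pacing vertex
  expect_identical(which.min(sim$truth$tau), 2L)
  expect_equal(min(sim$truth$tau), 0)
})

test_that("noise injection hits the requested SNR", {
  g <- make_synthetic_geometry(n_target = 30, n_electrodes = 8)
  scn_clean <- scenario(pacing = data.frame(vertex = 2, onset = 0),
                        seed = 3)
  scn_noisy <- scenario(pacing = data.frame(vertex = 2, onset = 0),
                        noise_snr_db = 20, seed = 3)
  times <- seq(0, 400, 2)
  clean <- synthesize_recording(scn_clean, g$mesh, g$electrodes, times)
  noisy <- synthesize_recording(scn_noisy, g$mesh, g$electrodes, times)
  noise <- noisy$recording$phi - clean$recording$phi
  snr <- 10 * log10(mean(clean$recording$phi^2) / mean(noise^2))
  expect_lt(abs(snr - 20), 0.5)
})

test_that("noise is unbiased around the clean recording", {
  g <- make_synthetic_geometry(n_target = 20, n_electrodes = 6)
  times <- seq(0, 300, 5)
  clean <- suppressWarnings(synthesize_recording(
    scenario(pacing = data.frame(vertex = 2, onset = 0), seed = 1),
    g$mesh, g$electrodes, times))$recording
  n_rep <- 100
  acc <- matrix(0, nrow(clean$phi), ncol(clean$phi))
  sigma2 <- 0
  for (s in seq_len(n_rep)) {
    noisy <- suppressWarnings(synthesize_recording(
      scenario(pacing = data.frame(vertex = 2, onset = 0),
               noise_snr_db = 10, seed = s),
      g$mesh, g$electrodes, times))$recording
    acc <- acc + (noisy$phi - clean$phi)
    sigma2 <- sigma2 + mean((noisy$phi - clean$phi)^2)
  }
  bias <- mean(acc / n_rep)
  se <- sqrt(sigma2 / n_rep) / sqrt(n_rep * length(clean$phi))
  expect_lt(abs(bias), 3 * se)
})

test_that("model-mismatch modes break the inverse crime", {
  g <- make_synthetic_geometry(n_target = 30, n_electrodes = 8)
  times <- seq(0, 400, 2)
  base <- scenario(pacing = data.frame(vertex = 2, onset = 0), seed = 3)
  clean <- synthesize_recording(base, g$mesh, g$electrodes, times)
  pert <- synthesize_recording(
    scenario(pacing = data.frame(vertex = 2, onset = 0),
             mismatch = "perturbed-template", seed = 3),
    g$mesh, g$electrodes, times)
  expect_gt(max(abs(pert$recording$phi - clean$recording$phi)), 0)
  refined <- synthesize_recording(
    scenario(pacing = data.frame(vertex = 2, onset = 0),
             mismatch = "refined-mesh", seed = 3),
    g$mesh, g$electrodes, times)
  # data come from the finer mesh but the truth lives on the coarse one
  expect_identical(length(refined$truth$tau), g$mesh$n_vertices)
  expect_gt(max(abs(refined$recording$phi - clean$recording$phi)), 0)
})

test_that("mesh subdivision quadruples faces and keeps originals first", {
  m <- tetra_mesh(c("EPI", "EPI", "ENDO", "ENDO"))
  s <- ecginverse:::subdivide_mesh(m)
  expect_identical(nrow(s$triangles), 4L * nrow(m$triangles))
  expect_identical(s$vertices[1:4, ], m$vertices)
  expect_identical(s$surface_label[1:4], m$surface_label)
})
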