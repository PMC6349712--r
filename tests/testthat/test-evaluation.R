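test_that("map metrics behave under identity, sign flip and shift", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  m1 <- map_metrics(x, x)
  expect_equal(m1$cc, 1)
  expect_equal(m1$re, 0)
  expect_equal(map_metrics(-x, x)$cc, -1)
  m2 <- map_metrics(x + 5, x)
  expect_equal(m2$cc, 1)
  expect_equal(m2$re, sqrt(sum(rep(5, 8)^2)) / sqrt(sum(x^2)))
  expect_warning(m3 <- map_metrics(rep(1, 5), x[1:5]), "variance")
  expect_true(is.nan(m3$cc))
  expect_error(map_metrics(1:3, 1:4), "differ")
})

test_that("map metrics are scale/shift invariant in CC, scale-free in RE", {
  set.seed(21)
  for (k in 1:5) {
    a <- rnorm(30); b <- rnorm(30)
    cc0 <- map_metrics(a, b)$cc
    expect_equal(map_metrics(2.7 * a + 3, b)$cc, cc0, tolerance = 1e-12)
    expect_equal(map_metrics(a, 0.3 * b - 1)$cc, cc0, tolerance = 1e-12)
    expect_equal(map_metrics(5 * a, 5 * b)$re, map_metrics(a, b)$re,
                 tolerance = 1e-12)
  }
})

test_that("sub-surface CCs restrict by label", {
  set.seed(22)
  lab <- rep(c("EPI", "ENDO"), each = 10)
  a <- rnorm(20); b <- rnorm(20)
  m <- map_metrics(a, b, lab)
  expect_equal(m$cc_epi, cor(a[1:10], b[1:10]))
  expect_equal(m$cc_endo, cor(a[11:20], b[11:20]))
})

test_that("BSPM metrics match hand arithmetic", {
  t2 <- c(0, 1)
  rec <- bspm_recording(rbind(c(1, 2), c(2, 1), c(3, 6)), t2)
  ref <- bspm_recording(rbind(c(1, 1), c(2, 2), c(4, 3)), t2)
  m <- bspm_metrics(rec, ref)
  expect_equal(m$cc[1], cor(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(m$cc[2], cor(c(2, 1, 6), c(1, 2, 3)))
  expect_equal(m$rmse[1], sqrt(mean(c(0, 0, 1))))
  expect_equal(m$rmse[2], sqrt(mean(c(1, 1, 9))))
  # identical: cc 1, rmse 0
  m2 <- bspm_metrics(ref, ref)
  expect_true(all(m2$cc == 1))
  expect_true(all(m2$rmse == 0))
  # scaling the reconstruction leaves cc, sets rmse to the residual rms
  rec2 <- bspm_recording(2 * ref$phi, t2)
  m3 <- bspm_metrics(rec2, ref)
  expect_true(all(m3$cc == 1))
  expect_equal(m3$rmse, sqrt(colMeans(ref$phi^2)))
  expect_error(bspm_metrics(rec, bspm_recording(ref$phi, c(0, 2))), "grid")
})

test_that("repolarization times sit at the steepest upslope", {
  times <- seq(0, 400, 1)
  # build phi_e from a 3-node simulation and compare 1-ms grid against a
  # 10x finer grid oracle
  f <- parameter_field(A = 10, tau_out = c(5, 6, 7),
                       tau_close = c(140, 150, 160), tau = c(0, 30, 60))
  mk_phi_e <- function(tt) {
    Vm <- matrix(0, 3, length(tt))
    for (i in 1:3) {
      tpl <- integrate_ms(ms_parameters(tau_out = f$tau_out[i],
                                        tau_close = f$tau_close[i]),
                          duration = 500)
      Vm[i, ] <- eval_ansatz(tpl, f$A, f$tau[i], tt)$vm
    }
    vm_to_extracellular(Vm)
  }
  rt <- extract_repolarization_times(mk_phi_e(times), f$tau, times)
  fine <- seq(0, 400, 0.1)
  rt_fine <- extract_repolarization_times(mk_phi_e(fine), f$tau, fine)
  expect_true(all(is.finite(rt)))
  # near-flat upslope maxima can move the argmax by a couple of coarse
  # samples; the recovered RT must still be a near-maximum of the fine slope
  expect_lt(max(abs(rt - rt_fine)), 3 + 1e-9)
  # repolarization after activation
  expect_true(all(rt > f$tau + 50))
})

test_that("uniform potentials yield undefined repolarization times", {
  phi_e <- matrix(0, 4, 100)
  expect_warning(rt <- extract_repolarization_times(phi_e, rep(0, 4),
                                                    seq(0, 99, 1)),
                 "undefined")
  expect_true(all(is.nan(rt)))
})

test_that("APD90 matches synthetic pulses and the fine-step reference", {
  # rectangular pulse of width 120 ms
  dt <- 0.05
  t <- seq(0, 400, dt)
  v <- as.numeric(t >= 10 & t <= 130)
  tpl <- structure(list(time = t, v = v, h = rep(1, length(t)),
                        dv_dt = rep(0, length(t)), dt = dt,
                        params = ms_parameters()), class = "ap_template")
  # both interpolated crossings can shift by up to one sample
  expect_lt(abs(compute_apd90(tpl) - 120), 2 * dt + 1e-9)
  # against the independent fine-step reference
  own <- integrate_ms(duration = 500)
  ref <- desolve_ms(duration = 500, dt = 0.01)
  expect_lt(abs(compute_apd90(own) - trace_apd90(ref$time, ref$v)), 0.1)
  # no activation -> NaN
  tpl0 <- structure(list(time = t, v = rep(0.01, length(t)),
                         h = rep(1, length(t)), dv_dt = rep(0, length(t)),
                         dt = dt, params = ms_parameters()),
                    class = "ap_template")
  expect_true(is.nan(compute_apd90(tpl0)))
})

test_that("endo-epi delays and their quartiles are exact order statistics", {
  g <- make_synthetic_geometry(semi_axes = c(30, 30, 60),
                               wall_thickness = 8, n_target = 40,
                               n_electrodes = 8)
  m <- g$mesh
  pairing <- pair_endo_epi(m)
  tau <- rep(0, m$n_vertices)
  d0 <- endo_epi_delays(m, pairing, tau)
  expect_true(all(d0$delays == 0))
  # endo activates 10 ms earlier everywhere
  tau2 <- ifelse(m$surface_label == "ENDO", 0, 10)
  d2 <- endo_epi_delays(m, pairing, tau2)
  expect_true(all(d2$delays == 10))
  # random delays: quartiles against direct computation on the sorted array
  set.seed(31)
  tau3 <- rnorm(m$n_vertices, 50, 15)
  d3 <- endo_epi_delays(m, pairing, tau3)
  expected <- tau3[pairing$epi] - tau3[pairing$endo]
  expect_equal(sort(d3$delays), sort(expected), ignore_attr = TRUE)
  expect_equal(d3$summary$median, median(expected))
  expect_equal(d3$summary$q1,
               quantile(expected, 0.25, type = 7, names = FALSE))
  expect_equal(d3$summary$q3,
               quantile(expected, 0.75, type = 7, names = FALSE))
  expect_equal(d3$summary$min, min(expected))
  expect_equal(d3$summary$max, max(expected))
})

test_that("earliest-site localization is exact and shift-invariant", {
  g <- make_synthetic_geometry(semi_axes = c(30, 30, 60),
                               wall_thickness = 8, n_target = 60,
                               n_electrodes = 8)
  m <- g$mesh
  endo_first <- which(m$surface_label == "ENDO")[1]
  tau <- make_activation_map(m, data.frame(vertex = endo_first, onset = 0),
                             cv = 1)
  expect_identical(localize_earliest_site(m, tau, "ALL"), endo_first)
  expect_identical(localize_earliest_site(m, tau + 37, "ALL"), endo_first)
  # epicardial breakthrough: brute-force scan over EPI labels
  epi <- which(m$surface_label == "EPI")
  expect_identical(localize_earliest_site(m, tau, "EPI"),
                   epi[which.min(tau[epi])])
  # distance of the true site to itself is zero
  expect_equal(localization_distance(m, endo_first, endo_first), 0)
  expect_error(localize_earliest_site(tetra_mesh(), rep(0, 4), "ENDO"),
               "no vertices")
})

test_that("isolated early-activation outliers can be excluded", {
  m <- grid_mesh(5)
  tau <- make_activation_map(m, data.frame(vertex = 13, onset = 0), cv = 1)
  # corrupt a far corner with an isolated spuriously early time
  tau_bad <- tau
  tau_bad[25] <- -50
  expect_identical(localize_earliest_site(m, tau_bad), 25L)
  expect_identical(localize_earliest_site(m, tau_bad,
                                          exclude_isolated = TRUE), 13L)
  # a genuine early region (outlier plus its neighbors) is kept
  tau_bad[c(24, 20)] <- -45
  expect_identical(localize_earliest_site(m, tau_bad,
                                          exclude_isolated = TRUE), 25L)
})

test_that("evaluation reports serialize to JSON and CSV", {
  g <- make_synthetic_geometry(n_target = 30, n_electrodes = 8)
  scn <- scenario(pacing = data.frame(vertex = 2, onset = 0), seed = 3)
  times <- seq(0, 400, 2)
  sim <- synthesize_recording(scn, g$mesh, g$electrodes, times)
  # evaluate the truth against itself: perfect scores
  report <- evaluate_reconstruction(sim$truth$field, sim$truth, g$mesh,
                                    g$electrodes, sim$recording,
                                    pacing_vertex = 2)
  expect_equal(report$cc_at, 1)
  expect_equal(report$re_at, 0)
  expect_equal(report$localization_mm, 0)
  # inverse-crime identity: RTs extracted from the perfect reconstruction
  # match the reference RT map
  expect_equal(report$rt_reconstructed, sim$truth$rt)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".csv")
  write_report_json(report, p1)
  write_report_csv(report, p2)
  j <- jsonlite::read_json(p1)
  expect_equal(j$cc_at, 1)
  expect_equal(read.csv(p2)$cc_at, 1)
  unlink(c(p1, p2))
})
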