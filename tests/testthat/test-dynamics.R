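test_that("integration is deterministic under a fixed seed", {
  sys <- build_loop_system(4, torque_pNnm = 2)
  st <- integrator_settings(dt = 2e-3, n_steps = 5000, report_every = 500,
                            seed = 42)
  t1 <- run_langevin(sys, settings = st)
  t2 <- run_langevin(sys, settings = st)
  expect_identical(t1$series, t2$series)
  expect_identical(t1$system$positions, t2$system$positions)
  t3 <- run_langevin(sys, settings = modifyList(st, list(seed = 43)))
  expect_false(identical(t1$series$Rg, t3$series$Rg))
})

test_that("a harmonic dimer samples the closed-form bond-length variance", {
  pos <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  sys <- fiber_system(pos, box = 20)
  p <- ff_params(eps = 0, k_tor = 0, k_perp = 0)
  tr <- run_langevin(sys, p,
                     integrator_settings(dt = 2e-3, n_steps = 4e5,
                                         report_every = 40, seed = 5))
  blen <- vapply(seq_len(dim(tr$frames)[3]), function(k) {
    f <- frame_beads(tr, k)
    sqrt(sum((f[2, ] - f[1, ])^2))
  }, numeric(1))
  blen <- blen[-(1:100)]
  expect_equal(var(blen), 1 / p$k_bond, tolerance = 0.05)
})

test_that("at zero temperature a relaxed state is stationary", {
  sys <- tiny_chain(12)
  tr <- run_langevin(sys, settings = integrator_settings(
    dt = 1e-3, kT = 0, n_steps = 2000, report_every = 1000, seed = 1))
  expect_equal(tr$system$positions, sys$positions, tolerance = 1e-12)
})

test_that("microcanonical runs conserve energy", {
  set.seed(9)
  sys <- tiny_chain(20, jitter = 0.03)
  n_steps <- 2e4
  tr <- run_langevin(sys, ff_params(), integrator_settings(
    dt = 1e-3, gamma = 0, kT = 1, n_steps = n_steps, report_every = 500,
    seed = 3))
  s <- tr$series
  etot <- s$E_ev + s$E_bond + s$E_bend + s$E_tor + s$E_frame +
    s$E_restraint + s$E_kin
  expect_lt(max(abs(etot - etot[1])), 1e-4 * n_steps)
  expect_lt(max(abs(etot - etot[1])) / etot[1], 0.02)
})

test_that("the integrator aborts on blow-up with a diagnostic", {
  sys <- tiny_chain(8)
  sys$positions[5, ] <- sys$positions[1, ] + c(0.03, 0, 0)  # deep overlap
  expect_error(
    run_langevin(sys, ff_params(),
                 integrator_settings(dt = 0.005, n_steps = 5000, seed = 1)),
    "blow-up")
})

test_that("passive sampling satisfies equipartition of bend and twist energy", {
  # ideal chain (no excluded volume) so the analytic references are exact
  sys <- tiny_chain(30)
  p <- ff_params(eps = 0)
  tr <- run_langevin(sys, p, integrator_settings(
    dt = 2e-3, n_steps = 4e5, report_every = 200, seed = 12),
    store_frames = FALSE)
  s <- tr$series[-(1:300), ]
  njoints <- 28
  nbonds <- 29
  # torsion is harmonic: kT/2 per bond
  expect_equal(mean(s$E_tor) / nbonds, 0.5, tolerance = 0.05)
  # Kratky-Porod joint: <V> = eps_b (1 - <cos theta>), two transverse dof
  vbend_exact <- 5 * (1 - wlc_mean_cos(5))
  expect_equal(mean(s$E_bend) / njoints, vbend_exact, tolerance = 0.05)
})

test_that("Langevin sampling matches direct Boltzmann draws of the ideal chain", {
  n <- 40
  set.seed(31)
  rg2_direct <- mean(replicate(3000, {
    p <- wlc_chain_positions(n)
    mean(rowSums(sweep(p, 2, colMeans(p))^2))
  }))
  # analytic discrete worm-like-chain closed form agrees with the draws
  expect_equal(rg2_direct, wlc_rg2_analytic(n, 5), tolerance = 0.03)
  # Langevin run with frame terms decoupled (they are documented to add
  # effective stiffness): compare fast-mixing internal distances tightly and
  # the slow-mixing radius of gyration loosely (its autocorrelation time at
  # this length is ~2e5 steps, so desk runs carry ~10% standard error)
  set.seed(32)
  sys <- build_linear_system(n * 0.4, torque_pNnm = 0,
                             terminal_borders = FALSE, init = "wlc")
  p <- ff_params(eps = 0, k_tor = 0, k_perp = 0)
  tr <- run_langevin(sys, p, integrator_settings(
    dt = 2e-3, n_steps = 1.6e6, report_every = 800, seed = 13))
  fr <- supercoilr:::.bead_frames(tr)[-(1:500)]
  for (m in c(3, 6, 12))
    expect_equal(frames_msd(fr, m), wlc_msd_analytic(m, 5), tolerance = 0.03,
                 label = sprintf("internal distance over %d bonds", m))
  rg2_lang <- mean(tr$series$Rg[-(1:500)]^2)
  expect_equal(rg2_lang, wlc_rg2_analytic(n, 5), tolerance = 0.3)
})

test_that("excluded-volume chain matches an independent pivot Monte Carlo", {
  n <- 30
  m_sep <- 10
  set.seed(17)
  msd_mc <- pivot_mc_msd(n, m_sep, n_moves = 30000)
  set.seed(18)
  sys <- build_linear_system(n * 0.4, torque_pNnm = 0,
                             terminal_borders = FALSE, init = "wlc")
  tr <- run_langevin(sys, ff_params(k_tor = 0, k_perp = 0), integrator_settings(
    dt = 2e-3, n_steps = 1e6, report_every = 500, seed = 19))
  fr <- supercoilr:::.bead_frames(tr)[-(1:400)]
  expect_equal(frames_msd(fr, m_sep), mean(msd_mc), tolerance = 0.04)
})

test_that("autocorrelation time behaves on reference series", {
  set.seed(4)
  # white noise: ~1 sampling interval
  expect_equal(autocorrelation_time(rnorm(20000)), 1, tolerance = 0.15)
  # AR(1), coefficient 0.9: closed form (1 + a) / (1 - a) = 19
  x <- as.numeric(arima.sim(list(ar = 0.9), 30000))
  expect_equal(autocorrelation_time(x), 19, tolerance = 0.15)
  expect_error(autocorrelation_time(rep(2, 100)), "constant")
  expect_error(autocorrelation_time(rnorm(10)), "short")
})

test_that("replicas are independent, reproducible and thermalization-aware", {
  sys <- build_loop_system(4, torque_pNnm = 0)
  st <- integrator_settings(dt = 2e-3, n_steps = 3e4, report_every = 100,
                            seed = 7, n_replicas = 3, therm_steps = 6000,
                            max_steps = 6e4)
  trs <- run_scenario_replicas(sys, settings = st)
  expect_length(trs, 3)
  seeds <- vapply(trs, function(t) t$seed, numeric(1))
  expect_equal(length(unique(seeds)), 3)
  # pairwise Rg correlation ~ 0 between replicas
  rg <- sapply(trs, function(t) t$series$Rg)
  cc <- cor(rg)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.35)
  # determinism of the whole replica schedule
  trs2 <- run_scenario_replicas(sys, settings = st)
  expect_identical(trs[[2]]$series, trs2[[2]]$series)
  # zero production steps: thermalized state only
  st0 <- modifyList(st, list(n_steps = 0L, n_replicas = 1L))
  class(st0) <- "integrator_settings"
  tr0 <- run_scenario_replicas(sys, settings = st0)
  expect_equal(nrow(tr0[[1]]$series), 1)
})
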