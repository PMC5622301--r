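test_that("pair and bonded potentials match direct formula evaluation", {
  # cut-and-shifted repulsive LJ: zero at and beyond the cutoff
  expect_equal(excluded_volume_energy(1.0), 0)
  expect_equal(excluded_volume_energy(2.0), 0)
  expect_equal(excluded_volume_energy(0.9, eps = 1),
               4 * ((1 / 0.9)^12 - (1 / 0.9)^6), tolerance = 1e-12)
  # continuity at a non-trivial cutoff
  rc <- 2^(1 / 6)
  expect_equal(excluded_volume_energy(rc - 1e-9, r_cut = rc), 0,
               tolerance = 1e-6)
  expect_error(excluded_volume_energy(0), "singularity")
  # Kratky-Porod bending
  expect_equal(bending_energy(0), 0)
  expect_equal(bending_energy(pi / 2, eps_bend = 5), 5)
  th <- seq(0, pi, length.out = 20)
  expect_true(all(diff(bending_energy(th)) > 0))  # monotone on [0, pi]
  # harmonic wrapped torsion
  expect_equal(torsion_energy(0, k = 4), 0)
  expect_equal(torsion_energy(pi, k = 4), 2 * pi^2, tolerance = 1e-12)
  expect_equal(torsion_energy(0.3 + 2 * pi, k = 4), torsion_energy(0.3, k = 4),
               tolerance = 1e-12)  # periodic
  expect_equal(torsion_energy(1, k = 0), 0)  # swivel
})

test_that("zone pairs use the softened excluded-volume prefactor", {
  p <- ff_params()
  # hairpin: non-adjacent contacts (2,5) and (1,6) at distance 0.8 sigma
  pos <- cbind(c(0, 1, 2, 2, 1, 0), c(0, 0, 0, 0.8, 0.8, 0.8), 0)
  base <- fiber_system(pos, box = 50)
  zoned <- fiber_system(pos, passage_zones = data.frame(start = 4, end = 6),
                        box = 50)
  e1 <- compute_forces(base, p)$energy[["excluded_volume"]]
  e2 <- compute_forces(zoned, p)$energy[["excluded_volume"]]
  expect_equal(e1, 2 * excluded_volume_energy(0.8), tolerance = 1e-9)
  expect_equal(e2 / e1, p$zone_eps / p$eps, tolerance = 1e-9)
  # default zone prefactor: ~2 eps0 barrier for a segment 0.5 sigma from two
  # zone beads
  expect_equal(2 * excluded_volume_energy(0.5, eps = p$zone_eps), 2,
               tolerance = 1e-9)
})

test_that("forces are exact negative gradients (central differences)", {
  set.seed(42)
  p <- ff_params()
  # messy small system: zones, swivels, bends, torsional strain (motors off
  # for the conservative check; the motor drive is tested separately)
  sys <- build_linear_system(c(2, 2), torque_pNnm = 0, zone_beads = 3)
  sys$positions <- sys$positions + matrix(rnorm(3 * sys$n_beads, 0, 0.05),
                                          ncol = 3)
  sys$side_sites <- sys$side_sites + matrix(rnorm(3 * sys$n_beads, 0, 0.03),
                                            ncol = 3)
  check_fd <- function(sys, p, k_checks = 10) {
    fr <- compute_forces(sys, p)
    pos <- supercoilr:::.stack_positions(sys)
    h <- 1e-6
    for (i in sample(nrow(pos), k_checks)) for (q in 1:3) {
      m1 <- pos; m1[i, q] <- m1[i, q] + h
      m2 <- pos; m2[i, q] <- m2[i, q] - h
      e1 <- compute_forces(supercoilr:::.unstack_positions(sys, m1),
                           p)$energy[["total"]]
      e2 <- compute_forces(supercoilr:::.unstack_positions(sys, m2),
                           p)$energy[["total"]]
      fd <- -(e1 - e2) / (2 * h)
      expect_equal(fr$forces[i, q], fd, tolerance = 1e-5)
    }
    fr
  }
  fr <- check_fd(sys, p)
  # Newton's third law: all internal -> total force zero
  expect_lt(max(abs(colSums(fr$forces))), 1e-9)
  # with rings and anchors
  set.seed(7)
  sysc <- build_cohesin_system(18, spacing_kb = 4)
  sysc$positions <- sysc$positions + matrix(rnorm(3 * 18, 0, 0.05), ncol = 3)
  frc <- check_fd(sysc, p)
  expect_lt(max(abs(colSums(frc$forces))), 1e-9)
})

test_that("motor drive applies a pure torque about the local tangent", {
  sys <- tiny_chain(10)
  sys$motors <- data.frame(bond = 5, direction = 1, torque_pNnm = 2)
  fr <- compute_forces(sys)
  fm <- fr$motor_forces
  # force couple: zero net force
  expect_lt(max(abs(colSums(fm))), 1e-12)
  # torque about the chain axis (x) on each motor bead's frame = g/2
  g <- motor_generalized_force(1, 2)
  for (b in c(5, 6)) {
    u <- sys$side_sites[b, ] - sys$positions[b, ]
    trq <- c(u[2] * fm[10 + b, 3] - u[3] * fm[10 + b, 2],
             u[3] * fm[10 + b, 1] - u[1] * fm[10 + b, 3],
             u[1] * fm[10 + b, 2] - u[2] * fm[10 + b, 1])
    expect_equal(trq[1], g / 2, tolerance = 1e-9)
    expect_lt(abs(trq[2]) + abs(trq[3]), 1e-9)
  }
  # torque 0 reduces to the passive fibre
  sys0 <- sys
  sys0$motors$torque_pNnm <- 0
  expect_lt(max(abs(compute_forces(sys0)$motor_forces)), 1e-12)
})

test_that("straight relaxed chain has vanishing forces and energies", {
  sys <- tiny_chain(15)
  fr <- compute_forces(sys)
  expect_lt(max(abs(fr$forces)), 1e-9)
  expect_lt(fr$energy[["total"]], 1e-12)
  bad <- sys
  bad$positions[2, 1] <- NaN
  expect_error(compute_forces(bad), "finite")
})
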