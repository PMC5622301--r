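test_that("writhe obeys exact geometric identities", {
  # planar closed curve: writhe 0
  th <- 2 * pi * (0:39) / 40
  circle <- cbind(cos(th) * 6, sin(th) * 6, 0)
  expect_lt(abs(writhe(circle, closed = TRUE)), 1e-10)
  # chirality antisymmetry: mirror image negates writhe exactly
  set.seed(3)
  curve <- wlc_chain_positions(60)
  mir <- curve
  mir[, 3] <- -mir[, 3]
  wr <- writhe(curve)
  expect_equal(writhe(mir), -wr, tolerance = 1e-12)
  expect_gt(abs(wr), 1e-4)  # non-degenerate case
  # coincident consecutive beads rejected
  bad <- curve
  bad[5, ] <- bad[4, ]
  expect_error(writhe(bad), "coincident")
})

test_that("pairwise solid-angle writhe matches fine double quadrature", {
  # (2,5) torus-knot-like closed curve
  tt <- 2 * pi * (0:79) / 80
  knot <- cbind((3 + cos(5 * tt)) * cos(2 * tt),
                (3 + cos(5 * tt)) * sin(2 * tt), sin(5 * tt))
  expect_equal(writhe(knot, closed = TRUE), quad_writhe(knot, sub = 48),
               tolerance = 1e-3)
  # open random coil
  set.seed(11)
  coil <- wlc_chain_positions(40)
  expect_equal(writhe(coil), quad_writhe(coil, closed = FALSE, sub = 48),
               tolerance = 1e-3)
})

test_that("twist reproduces constructed frame rotations", {
  # parallel-transported (flat) ladder: zero twist
  n <- 30
  pos <- cbind(1:n, 0, 0) * 1.0
  sites <- pos + matrix(rep(c(0, 0, 0.5), each = n), n, 3)
  expect_lt(abs(twist(pos, sites)), 1e-12)
  # uniform rotation by 2*pi/(n-1) per bond on a straight chain: 1 turn
  alpha <- 2 * pi * (0:(n - 1)) / (n - 1)
  sites2 <- pos + 0.5 * cbind(0, sin(alpha), cos(alpha))
  expect_equal(twist(pos, sites2), -1, tolerance = 1e-12)
  # random frames: total equals the independent per-bond geometric oracle
  set.seed(5)
  posr <- wlc_chain_positions(25)
  ur <- matrix(rnorm(75), 25, 3)
  tv <- rbind(posr[2, ] - posr[1, ],
              posr[3:25, ] - posr[1:23, ],
              posr[25, ] - posr[24, ])
  ur <- ur - tv * rowSums(ur * tv) / rowSums(tv^2)
  ur <- 0.5 * ur / sqrt(rowSums(ur^2))
  sitesr <- posr + ur
  phi <- twist(posr, sitesr, per_bond = TRUE)
  oracle <- vapply(1:24, function(b) {
    e <- posr[b + 1, ] - posr[b, ]; e <- e / sqrt(sum(e^2))
    a <- ur[b, ] - sum(ur[b, ] * e) * e
    c <- ur[b + 1, ] - sum(ur[b + 1, ] * e) * e
    cr <- c(a[2] * c[3] - a[3] * c[2], a[3] * c[1] - a[1] * c[3],
            a[1] * c[2] - a[2] * c[1])
    atan2(sum(cr * e), sum(a * c))
  }, numeric(1))
  expect_equal(phi, oracle, tolerance = 1e-10)
})

test_that("Lk = Tw + Wr holds and is conserved without passages", {
  rb <- twisted_ribbon(80, -4)
  sys <- fiber_system(rb$positions, rb$sites, closed = TRUE, box = 60)
  expect_equal(twist(sys), -4, tolerance = 1e-9)
  expect_lt(abs(writhe(sys)), 1e-9)
  expect_equal(linking_number(sys), -4, tolerance = 1e-9)
  # evolve and check the identity at every frame
  tr <- run_langevin(sys, ff_params(),
                     integrator_settings(dt = 2e-3, n_steps = 4e4,
                                         report_every = 2000, seed = 7),
                     store_frames = FALSE)
  lk <- tr$series$Tw + tr$series$Wr
  expect_lt(max(abs(lk + 4)), 1e-2)
  # relaxed closed ribbon with no imposed twist stays at Lk = 0
  rb0 <- twisted_ribbon(60, 0)
  sys0 <- fiber_system(rb0$positions, rb0$sites, closed = TRUE, box = 50)
  expect_lt(abs(linking_number(sys0)), 1e-10)
  # Lk undefined for open chains or through swivels
  expect_error(linking_number(tiny_chain(10)), "open")
  sysw <- fiber_system(rb$positions, rb$sites, closed = TRUE, box = 60,
                       swivel_bonds = 3)
  expect_error(linking_number(sysw), "swivel")
})

test_that("writhe of well-separated domains is nearly additive", {
  # two like-handed helical domains with substantial writhe, far apart:
  # the domain-domain Gauss cross terms must be below 5% of the domain sum
  helix <- function(x0) {
    t <- seq(0, 5 * 2 * pi, length.out = 61)[-61]
    cbind(x0 + t * 0.35 / (2 * pi) * 2, 1.5 * cos(t), 1.5 * sin(t))
  }
  a <- helix(0)
  b <- helix(82)
  joined <- rbind(a, b)  # domains 1..60 and 61..120 of one (gappy) polyline
  wr_a <- writhe(joined, range = c(1, 60))
  wr_b <- writhe(joined, range = c(61, 120))
  expect_gt(abs(wr_a), 1)                  # strongly writhed domains
  expect_equal(wr_a, writhe(a), tolerance = 1e-12)  # restriction consistency
  # independent midpoint-quadrature cross sum over A x B segment pairs
  cross <- 0
  ta <- diff(a); tb <- diff(b)
  ma <- (a[-1, ] + a[-nrow(a), ]) / 2
  mb <- (b[-1, ] + b[-nrow(b), ]) / 2
  for (i in seq_len(nrow(ma))) {
    r <- sweep(-mb, 2, -ma[i, ])           # r_a - r_b
    cx <- cbind(ta[i, 2] * tb[, 3] - ta[i, 3] * tb[, 2],
                ta[i, 3] * tb[, 1] - ta[i, 1] * tb[, 3],
                ta[i, 1] * tb[, 2] - ta[i, 2] * tb[, 1])
    cross <- cross + sum(rowSums(cx * r) / rowSums(r^2)^1.5)
  }
  cross <- 2 * cross / (4 * pi)
  expect_lt(abs(cross), 0.05 * abs(wr_a + wr_b))
})

test_that("persistence length recovers the Kratky-Porod relation", {
  # direct Boltzmann draws (ideal chain) are an equilibrated ensemble
  lp_from_draws <- function(eps_bend, n = 120, reps = 400) {
    frames <- replicate(reps, wlc_chain_positions(n, eps_bend),
                        simplify = FALSE)
    persistence_length(frames, discard = 0)
  }
  set.seed(21)
  # eps_bend = 10: ideal discrete Lp = -b/log(coth(10) - 1/10) ~ 94.9 nm
  expect_equal(lp_from_draws(10), -10 / log(wlc_mean_cos(10)), tolerance = 0.05)
  # freely jointed limit: Lp collapses toward the bond scale
  expect_lt(lp_from_draws(0.3, n = 60), 12)
})

test_that("passage events are detected and the constructed jump is two turns", {
  expect_equal(nrow(detect_passage_events(rep(1.3, 50))), 0)
  wr <- c(rep(-3, 25), rep(-5, 25))
  ev <- detect_passage_events(wr, domain = 2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$dWr, -2.0)
  expect_equal(ev$domain, 2)
  expect_equal(ev$step, 25)
  # constructed intersegmental passage with twist held fixed: |dWr| = 2
  pw <- passage_writhe_change()
  expect_equal(abs(pw$delta), 2, tolerance = 0.1)
  # chirality: passing back reverses the sign
  expect_equal(sign(pw$wr_before), -sign(pw$wr_after))
})
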