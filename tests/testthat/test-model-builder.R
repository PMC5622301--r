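test_that("loop system carries two convergent motors flanking one swivel", {
  sys <- build_loop_system(50, torque_pNnm = 2)
  expect_true(sys$closed)
  expect_equal(sys$n_beads, 129)   # 125-bead domain + 2 x 2 motor beads
  expect_equal(nrow(sys$motors), 2)
  expect_equal(sort(sys$motors$direction), c(-1, 1))
  expect_equal(length(sys$swivel_bonds), 1)
  expect_equal(nrow(sys$passage_zones), 0)
  expect_equal(nrow(sys$bonds), sys$n_beads)  # cycle
  # nearly perfect circular start: writhe and twist zero
  expect_lt(abs(writhe(sys)), 1e-10)
  expect_lt(abs(twist(sys)), 1e-10)
  expect_true(validate_system(sys, strict_frame = TRUE))
  # torque-0 loop is valid and passive
  sys0 <- build_loop_system(50, torque_pNnm = 0)
  expect_equal(unique(sys0$motors$torque_pNnm), 0)
  # minimal 4 kb domain still hosts 2 motors + 1 swivel
  tiny <- build_loop_system(4)
  expect_equal(nrow(tiny$motors), 2)
  expect_equal(length(tiny$swivel_bonds), 1)
  expect_true(validate_system(tiny, strict_frame = TRUE))
  expect_error(build_loop_system(0.8), "too small")
})

test_that("linear system layout arithmetic matches hand-computed indices", {
  sys <- build_linear_system(c(40, 60), torque_pNnm = 2)
  # terminal border: 10-bead zone + swivel + 2-bead motor -> domain 1 at 13
  expect_equal(sys$domains$start[1], 13)
  expect_equal(sys$domains$end[1], 13 + 100 - 1)
  # internal border: motor(2) + zone(10) + motor(2) = 14 beads
  expect_equal(sys$domains$start[2], 112 + 14 + 1)
  expect_equal(sys$domains$end[2], 126 + 150)
  expect_equal(sys$n_beads, 2 * 12 + 100 + 150 + 14)
  expect_equal(nrow(sys$motors), 4)       # 2 internal + 2 terminal
  expect_equal(length(sys$swivel_bonds), 4)
  expect_equal(nrow(sys$passage_zones), 3)
  expect_true(validate_system(sys, strict_frame = TRUE))
  # swivels sit ahead of their motors, flanking each zone
  z <- sys$passage_zones
  expect_true(all((z$start - 1) %in% sys$swivel_bonds |
                    (z$end) %in% sys$swivel_bonds))
})

test_that("border element counts scale linearly with domain number", {
  for (k in c(1, 3, 6)) {
    sys <- build_linear_system(rep(50, k))
    expect_equal(nrow(sys$motors), 2 * k)
    expect_equal(nrow(sys$passage_zones), k + 1)
    expect_equal(length(sys$swivel_bonds), 2 * k)
    expect_equal(nrow(sys$domains), k)
  }
  one <- build_linear_system(50)  # single bordered domain
  expect_equal(nrow(one$domains), 1)
})

test_that("worm-like-chain initial configurations have correct local statistics", {
  set.seed(8)
  sys <- build_linear_system(c(40, 40), init = "wlc")
  expect_true(validate_system(sys, strict_frame = TRUE))
  cth <- replicate(200, {
    p <- wlc_chain_positions(100)
    t <- diff(p); t <- t / sqrt(rowSums(t^2))
    mean(rowSums(t[-1, ] * t[-nrow(t), ]))
  })
  expect_equal(mean(cth), wlc_mean_cos(5), tolerance = 0.01)
})

test_that("cohesin systems thread rigid rings at the requested spacing", {
  sys <- build_cohesin_system(1250, spacing_kb = 50)
  expect_equal(length(sys$rings), 10)
  expect_equal(nrow(sys$motors), 0)
  expect_equal(length(sys$swivel_bonds), 0)
  expect_equal(nrow(sys$passage_zones), 0)
  anchors <- attr(sys, "anchors")
  expect_equal(length(anchors), 10)
  expect_true(all(abs(diff(anchors) - 125) <= 1))
  expect_true(validate_system(sys))
  # spacing beyond chain length: one central ring
  one <- build_cohesin_system(100, spacing_kb = 200)
  expect_equal(length(one$rings), 1)
  # ring geometry: 16 x 10 nm beads -> centre-line diameter 160/pi
  g <- cohesin_ring_geometry()
  expect_equal(g$diameter_nm, 160 / pi, tolerance = 1e-12)
  expect_equal(g$diameter_nm, 50.93, tolerance = 0.001)
  r <- sys$rings[[1]]
  d <- sqrt(rowSums((r$positions - matrix(colMeans(r$positions), 16, 3,
                                          byrow = TRUE))^2))
  expect_equal(2 * mean(d) * 10, 160 / pi, tolerance = 1e-8)  # nm
})

test_that("validator rejects inconsistent annotations", {
  pos <- cbind(1:30 - 15.5, 0, 0) * 1.0
  # overlapping zones
  expect_error(
    fiber_system(pos, passage_zones = data.frame(start = c(2, 8),
                                                 end = c(10, 12)), box = 40),
    "overlap")
  # motor on a swivel bond is contradictory
  expect_error(
    fiber_system(pos, motors = data.frame(bond = 5, direction = 1,
                                          torque_pNnm = 2),
                 swivel_bonds = 5, box = 40),
    "overlap")
  # motor beads inside a zone
  expect_error(
    fiber_system(pos, motors = data.frame(bond = 5, direction = 1,
                                          torque_pNnm = 2),
                 passage_zones = data.frame(start = 4, end = 9), box = 40),
    "overlap")
})

test_that("BED-like layouts are converted at 400 bp per bead", {
  f <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t0\t20000\tdomain\t.",
    "chr1\t20000\t20800\tmotor+\t2",
    "chr1\t21200\t25200\tzone\t.",
    "chr1\t25200\t26000\tmotor-\t1.5"), f)
  sys <- read_layout_bed(f)
  expect_equal(sys$n_beads, 65)
  expect_equal(sys$domains$start, 1)
  expect_equal(sys$domains$end, 50)
  expect_equal(sys$motors$bond, c(51, 64))
  expect_equal(sys$motors$torque_pNnm, c(2, 1.5))
  expect_equal(sys$passage_zones$start, 54)
  expect_equal(sys$passage_zones$end, 63)
  unlink(f)
})
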