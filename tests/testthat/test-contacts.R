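make_frames <- function(k, n = 60, seed = 2) {
  set.seed(seed)
  replicate(k, wlc_chain_positions(n), simplify = FALSE)
}

test_that("contact maps are symmetric, additive and match a brute-force check", {
  fr <- make_frames(3)
  cm <- contact_map(fr, cutoff = 1.5)
  M <- cm$counts
  expect_identical(M, t(M))
  expect_true(all(M >= 0))
  # diagonal counts frames and is maximal per row
  expect_true(all(diag(M) == 3))
  expect_true(all(M <= 3))
  # additivity: same frames twice -> exactly doubled counts
  cm2 <- contact_map(c(fr, fr), cutoff = 1.5)
  expect_identical(cm2$counts, 2L * M)
  # brute force O(n^2) oracle per frame
  brute <- matrix(0L, 60, 60)
  for (f in fr) {
    d <- as.matrix(dist(f))
    hit <- (d <= 1.5) & (abs(outer(1:60, 1:60, "-")) > 1)
    brute <- brute + (hit * 1L)
  }
  diag(brute) <- 3L
  dimnames(brute) <- NULL
  expect_identical(M, brute)
  # straight line: near-diagonal band only
  line <- cbind(1:40, 0, 0) * 1.0
  cml <- contact_map(list(line), cutoff = 1.5, exclude_adjacent = FALSE)
  far <- abs(outer(1:40, 1:40, "-")) > 1
  expect_true(all(cml$counts[far] == 0))
  expect_error(contact_map(fr, cutoff = -1), "cutoff")
})

test_that("binning block-averages tiles and conserves the map mean", {
  fr <- make_frames(2, n = 50)
  cm <- contact_map(fr)
  expect_identical(bin_map(cm, 1)$counts, cm$counts)
  # constant matrix stays constant
  cmc <- cm
  cmc$counts <- matrix(7, 50, 50)
  b <- bin_map(cmc, 25)
  expect_equal(b$counts, matrix(7, 2, 2))
  # 50x50 checkerboard, bin 25 -> 2x2 of tile means
  chk <- cm
  chk$counts <- outer(1:50, 1:50, function(i, j) (i + j) %% 2)
  bc <- bin_map(chk, 25)
  tiles <- sapply(list(1:25, 26:50), function(jj)
    sapply(list(1:25, 26:50), function(ii) mean(chk$counts[ii, jj])))
  expect_equal(bc$counts, tiles)
  # exact mean conservation for divisible n
  b2 <- bin_map(cm, 10)
  expect_equal(mean(b2$counts), mean(cm$counts), tolerance = 1e-12)
  expect_equal(b2$bp_per_bin, 4000)
})

test_that("domain scores separate block structure from uniform maps", {
  doms <- data.frame(start = c(1, 31), end = c(30, 60))
  blocky <- matrix(1, 60, 60)
  blocky[1:30, 1:30] <- 8
  blocky[31:60, 31:60] <- 8
  cmb <- structure(list(counts = blocky, n_frames = 1, cutoff = 1.5,
                        bin_beads = 1L, bp_per_bin = 400L),
                   class = "contact_matrix")
  sb <- domain_contact_scores(cmb, doms)
  expect_true(all(sb$ratio > 5))
  cmu <- cmb
  cmu$counts <- matrix(3, 60, 60)
  su <- domain_contact_scores(cmu, doms)
  expect_equal(su$ratio, c(1, 1), tolerance = 1e-9)
})

test_that("insulation boundaries land on constructed block borders", {
  n <- 60
  blocky <- matrix(0.2, n, n)
  for (a in list(1:20, 21:40, 41:60)) blocky[a, a] <- 5
  cm <- structure(list(counts = blocky, n_frames = 1, cutoff = 1.5,
                       bin_beads = 1L, bp_per_bin = 400L),
                  class = "contact_matrix")
  bc <- boundary_coincidence(cm, convergence = c(20, 40), window = 5)
  expect_equal(sort(bc$boundaries), c(20, 40))
  expect_equal(bc$distance_bins, c(0.5, 0.5), tolerance = 1e-9)
  # uniform map: no boundaries
  cmu <- cm
  cmu$counts <- matrix(1, n, n)
  expect_equal(length(boundary_coincidence(cmu, window = 5)$boundaries), 0)
  # borders displaced by 2 bins from the annotated convergence points
  blocky2 <- matrix(0.2, n, n)
  for (a in list(1:22, 23:42, 43:60)) blocky2[a, a] <- 5
  cm2 <- structure(list(counts = blocky2, n_frames = 1, cutoff = 1.5,
                        bin_beads = 1L, bp_per_bin = 400L),
                   class = "contact_matrix")
  bc2 <- boundary_coincidence(cm2, convergence = c(20, 40), window = 5)
  expect_equal(median(bc2$distance_bins), 2, tolerance = 0.51)
})

test_that("ring anchors show contact depletion scores", {
  n <- 80
  M <- matrix(5, n, n)
  cm <- structure(list(counts = M, n_frames = 1, cutoff = 1.5,
                       bin_beads = 1L, bp_per_bin = 400L),
                  class = "contact_matrix")
  d0 <- depletion_lines(cm, anchors = c(25, 55))
  expect_equal(d0$score, c(1, 1), tolerance = 1e-9)
  # zeroed band at an anchor -> score ~ 0 there
  M2 <- M
  M2[24:26, ] <- 0
  M2[, 24:26] <- 0
  cm2 <- cm
  cm2$counts <- M2
  d2 <- depletion_lines(cm2, anchors = c(25, 55))
  expect_lt(d2$score[1], 0.05)
  expect_gt(d2$score[2], 0.8)
})

test_that("contact matrices round-trip through dense text and triplets", {
  fr <- make_frames(2, n = 30)
  cm <- contact_map(fr)
  f <- tempfile()
  write_contact_matrix(cm, f)
  cm2 <- read_contact_matrix(f)
  expect_equal(cm2$counts, cm$counts)
  expect_equal(cm2$cutoff, cm$cutoff)
  expect_equal(cm2$n_frames, cm$n_frames)
  ft <- tempfile()
  write_contact_triplets(cm, ft)
  tr <- read.table(ft, header = TRUE)
  expect_true(all(tr$count > 0))
  M <- matrix(0L, 30, 30)
  M[cbind(tr$bin1, tr$bin2)] <- tr$count
  M[cbind(tr$bin2, tr$bin1)] <- tr$count
  expect_identical(M, cm$counts)
  unlink(c(f, ft))
})
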