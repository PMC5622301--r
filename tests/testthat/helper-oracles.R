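# Independent oracles used across the suite: quadrature writhe, constructed
# twisted ribbons, discrete worm-like-chain closed forms and a pivot-move
# Metropolis sampler.

# Gauss double integral over a polygonal curve by midpoint quadrature on
# subdivided segments (independent of the pairwise solid-angle kernel).
quad_writhe <- function(pos, closed = TRUE, sub = 48) {
  n <- nrow(pos)
  segs <- if (closed) cbind(1:n, c(2:n, 1)) else cbind(1:(n - 1), 2:n)
  pts <- list(); tans <- list()
  for (k in seq_len(nrow(segs))) {
    a <- pos[segs[k, 1], ]; b <- pos[segs[k, 2], ]
    f <- (seq_len(sub) - 0.5) / sub
    pts[[k]] <- outer(1 - f, a) + outer(f, b)
    tans[[k]] <- matrix((b - a) / sub, sub, 3, byrow = TRUE)
  }
  tot <- 0
  for (k1 in seq_len(nrow(segs) - 1)) for (k2 in (k1 + 1):nrow(segs)) {
    P1 <- pts[[k1]]; T1 <- tans[[k1]]; P2 <- pts[[k2]]; T2 <- tans[[k2]]
    for (a in seq_len(sub)) {
      r <- sweep(-P2, 2, -P1[a, ])          # r1 - r2 for all quadrature points
      cx <- cbind(T1[a, 2] * T2[, 3] - T1[a, 3] * T2[, 2],
                  T1[a, 3] * T2[, 1] - T1[a, 1] * T2[, 3],
                  T1[a, 1] * T2[, 2] - T1[a, 2] * T2[, 1])
      tot <- tot + sum(rowSums(cx * r) / rowSums(r^2)^1.5)
    }
  }
  2 * tot / (4 * pi)
}

# closed circular ribbon with an imposed integer linking number: side sites
# rotated progressively about the local tangent
twisted_ribbon <- function(n, lk) {
  r <- n / (2 * pi)
  th <- 2 * pi * (0:(n - 1)) / n
  pos <- cbind(r * cos(th), r * sin(th), 0)
  alpha <- -2 * pi * lk * (0:(n - 1)) / n  # rad->z rotation is about -tangent
  sites <- matrix(0, n, 3)
  for (i in 1:n) {
    rad <- c(cos(th[i]), sin(th[i]), 0)
    sites[i, ] <- pos[i, ] + 0.5 * (cos(alpha[i]) * rad +
                                      sin(alpha[i]) * c(0, 0, 1))
  }
  list(positions = pos, sites = sites)
}

# exact <cos theta> of one joint under exp(eps_b cos theta): Langevin function
wlc_mean_cos <- function(eps_bend) 1 / tanh(eps_bend) - 1 / eps_bend

# exact mean-squared internal distance over m bonds of the ideal discrete
# worm-like chain (bond length b)
wlc_msd_analytic <- function(m, eps_bend, b = 1) {
  c <- wlc_mean_cos(eps_bend)
  b^2 * (m * (1 + c) / (1 - c) - 2 * c * (1 - c^m) / (1 - c)^2)
}

# exact <Rg^2> of the ideal discrete worm-like chain
wlc_rg2_analytic <- function(n, eps_bend, b = 1) {
  m <- 1:(n - 1)
  sum((n - m) * wlc_msd_analytic(m, eps_bend, b)) / n^2
}

# mean-squared distance between beads m apart, averaged over frames
frames_msd <- function(frames, m) {
  mean(vapply(frames, function(f) {
    n <- nrow(f)
    mean(rowSums((f[(1 + m):n, , drop = FALSE] -
                    f[1:(n - m), , drop = FALSE])^2))
  }, numeric(1)))
}

# pivot-move Metropolis sampler for an open chain with Kratky-Porod bending
# and the package's excluded-volume potential (no frames); returns samples of
# the squared distance over `m_sep` bonds (averaged along the chain)
pivot_mc_msd <- function(n, m_sep, n_moves = 20000, eps_bend = 5, eps = 1,
                         r_cut = 1, sample_every = 20) {
  pos <- cbind(seq_len(n) - (n + 1) / 2, 0, 0) * 1.0
  ev_energy <- function(p) {
    d <- as.matrix(dist(p))
    d <- d[upper.tri(d)]
    sep <- abs(outer(seq_len(n), seq_len(n), "-"))[upper.tri(diag(n))]
    d <- d[sep > 1]
    sum(excluded_volume_energy(d[d < r_cut], eps = eps, r_cut = r_cut))
  }
  bend_energy_tot <- function(p) {
    t <- diff(p)
    cth <- rowSums(t[-1, , drop = FALSE] * t[-nrow(t), , drop = FALSE]) /
      (sqrt(rowSums(t[-1, , drop = FALSE]^2)) *
         sqrt(rowSums(t[-nrow(t), , drop = FALSE]^2)))
    sum(eps_bend * (1 - cth))
  }
  rot_mat <- function() {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, -pi, pi)
    c <- cos(ang); s <- sin(ang); K <- matrix(c(0, ax[3], -ax[2],
      -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    diag(3) * c + s * K + (1 - c) * outer(ax, ax)
  }
  e_cur <- ev_energy(pos) + bend_energy_tot(pos)
  rg2 <- numeric(0)
  for (m in seq_len(n_moves)) {
    piv <- sample(2:(n - 1), 1)
    cand <- pos
    tail <- (piv + 1):n
    cand[tail, ] <- sweep(sweep(cand[tail, , drop = FALSE], 2, cand[piv, ]) %*%
                            rot_mat(), 2, cand[piv, ], "+")
    e_new <- ev_energy(cand) + bend_energy_tot(cand)
    if (is.finite(e_new) && runif(1) < exp(e_cur - e_new)) {
      pos <- cand; e_cur <- e_new
    }
    if (m %% sample_every == 0 && m > n_moves / 5) {
      rg2 <- c(rg2, mean(rowSums((pos[(1 + m_sep):n, , drop = FALSE] -
                                    pos[1:(n - m_sep), , drop = FALSE])^2)))
    }
  }
  rg2
}

# small helper: relaxed open test chain with frames
tiny_chain <- function(n = 12, jitter = 0, seed = 1) {
  set.seed(seed)
  pos <- cbind(seq_len(n) - (n + 1) / 2, 0, 0) * 1.0
  if (jitter > 0) pos <- pos + matrix(rnorm(3 * n, 0, jitter), n, 3)
  fiber_system(pos, box = 10 * n)
}
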