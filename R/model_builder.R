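# Construction of fibre systems: geometry, topology and annotations for the
# loop, linear multi-domain and cohesin-barrier scenarios, plus arbitrary
# layouts read from a BED-like file.

#' Create a fibre system
#'
#' Low-level constructor; most users should call [build_loop_system()],
#' [build_linear_system()] or [build_cohesin_system()]. Positions are in
#' sigma (1 sigma = 10 nm = 400 bp); side sites define the material frame and
#' sit 0.5 sigma from their parent bead, perpendicular to the local tangent.
#'
#' @param positions n x 3 matrix of bead coordinates (sigma).
#' @param side_sites n x 3 matrix of side-site coordinates; if `NULL`, sites
#'   are generated perpendicular to the local chord.
#' @param closed logical; `TRUE` for a loop (n bonds), `FALSE` for a linear
#'   chain (n - 1 bonds).
#' @param motors data frame with columns `bond`, `direction` (+1/-1, sense of
#'   transcription along increasing bead index) and `torque_pNnm`.
#' @param swivel_bonds integer bond indices with zero torsional stiffness.
#' @param passage_zones data frame with columns `start`, `end` (bead ranges
#'   with softened excluded volume).
#' @param rings list of cohesin rings as returned by `make_ring()` internals;
#'   each has `positions`, `anchor`, `rest`.
#' @param domains data frame with columns `start`, `end`: bead ranges of the
#'   divergent-transcription domains (used for per-domain writhe and contact
#'   scores).
#' @param box periodic box edge in sigma (minimum-image convention); `<= 0`
#'   disables periodicity.
#' @param phi0 optional per-bond rest dihedral (radians), e.g. to impose a
#'   linking-number deficit on a closed fibre.
#' @return an object of class `fiber_system`.
#' @export
fiber_system <- function(positions, side_sites = NULL, closed = FALSE,
                         motors = NULL, swivel_bonds = integer(0),
                         passage_zones = NULL, rings = list(),
                         domains = NULL, box = -1, phi0 = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2 || ncol(positions) != 3) stop("positions must be an n x 3 matrix, n >= 2")
  if (is.null(side_sites)) side_sites <- .default_side_sites(positions, closed)
  side_sites <- as.matrix(side_sites)
  if (!all(dim(side_sites) == dim(positions)))
    stop("side_sites must match positions")
  if (is.null(motors))
    motors <- data.frame(bond = integer(0), direction = integer(0),
                         torque_pNnm = numeric(0))
  if (is.null(passage_zones))
    passage_zones <- data.frame(start = integer(0), end = integer(0))
  if (is.null(domains))
    domains <- data.frame(start = integer(0), end = integer(0))
  nb <- if (closed) n else n - 1
  bonds <- cbind(seq_len(nb), c(seq_len(nb - 1) + 1, if (closed) 1L else nb + 1L))
  sys <- structure(
    list(n_beads = n, positions = positions, side_sites = side_sites,
         bonds = bonds, closed = closed, motors = motors,
         swivel_bonds = as.integer(swivel_bonds),
         passage_zones = passage_zones, rings = rings, domains = domains,
         box = box, phi0 = phi0),
    class = "fiber_system")
  validate_system(sys)
  sys
}

#' @export
print.fiber_system <- function(x, ...) {
  cat(sprintf(
    "fiber_system: %d beads (%s kb), %s, %d motor(s), %d swivel(s), %d zone(s), %d ring(s)\n",
    x$n_beads, format(beads_to_bp(x$n_beads) / 1000),
    if (x$closed) "closed" else "linear", nrow(x$motors),
    length(x$swivel_bonds), nrow(x$passage_zones), length(x$rings)))
  if (nrow(x$domains) > 0)
    cat(sprintf("  domains: %d (beads %s)\n", nrow(x$domains),
                paste(x$domains$start, x$domains$end, sep = "-", collapse = ", ")))
  cat(sprintf("  box edge: %g sigma\n", x$box))
  invisible(x)
}

# side sites perpendicular to the local chord, offset 0.5 sigma
.default_side_sites <- function(pos, closed) {
  n <- nrow(pos)
  u <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    im <- if (closed) ((i - 2) %% n) + 1 else max(i - 1, 1)
    ip <- if (closed) (i %% n) + 1 else min(i + 1, n)
    tv <- pos[ip, ] - pos[im, ]
    tv <- tv / sqrt(sum(tv^2))
    # any unit vector perpendicular to tv, continuous along the chain:
    ref <- if (abs(tv[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    v <- ref - sum(ref * tv) * tv
    u[i, ] <- v / sqrt(sum(v^2))
  }
  pos + 0.5 * u
}

#' Validate a fibre system
#'
#' Checks connectivity, side-site geometry (offset 0.5 sigma, perpendicular
#' to the local tangent at construction), disjointness of motor bonds, swivel
#' bonds and passage zones, finite coordinates, and that every cohesin ring
#' is threaded by the chain (the chain crosses the ring disc exactly once).
#'
#' @param sys a `fiber_system`.
#' @param tol_offset tolerance on the side-site offset.
#' @param tol_perp tolerance on |cos| between side-site vector and tangent
#'   (checked only when `strict_frame = TRUE`; after dynamics the frame
#'   fluctuates thermally).
#' @param strict_frame check frame orthogonality (construction-time check).
#' @return `TRUE` invisibly; errors describe the first violated invariant.
#' @export
validate_system <- function(sys, tol_offset = 1e-6, tol_perp = 1e-6,
                            strict_frame = FALSE) {
  n <- sys$n_beads
  if (any(!is.finite(sys$positions)) || any(!is.finite(sys$side_sites)))
    stop("non-finite coordinates")
  nb <- if (sys$closed) n else n - 1
  if (nrow(sys$bonds) != nb) stop("bond list does not form a single path")
  # bead/bond index ranges
  if (nrow(sys$motors) > 0) {
    if (any(sys$motors$bond < 1 | sys$motors$bond > nb))
      stop("motor bond index out of range")
    if (any(abs(sys$motors$direction) != 1)) stop("motor direction must be +1/-1")
    if (any(sys$motors$torque_pNnm < 0)) stop("motor torque must be >= 0")
  }
  if (length(sys$swivel_bonds) > 0 &&
      any(sys$swivel_bonds < 1 | sys$swivel_bonds > nb))
    stop("swivel bond index out of range")
  if (any(sys$motors$bond %in% sys$swivel_bonds))
    stop("motor and swivel annotations overlap")
  zb <- integer(0)
  if (nrow(sys$passage_zones) > 0) {
    for (i in seq_len(nrow(sys$passage_zones)))
      zb <- c(zb, sys$passage_zones$start[i]:sys$passage_zones$end[i])
    if (anyDuplicated(zb)) stop("passage zones overlap")
    if (any(zb < 1 | zb > n)) stop("passage zone out of range")
  }
  motor_beads <- unique(c(sys$motors$bond, sys$motors$bond + 1))
  if (sys$closed && length(motor_beads) > 0)
    motor_beads <- ((motor_beads - 1) %% n) + 1
  if (length(intersect(motor_beads, zb)) > 0)
    stop("motor beads and passage zones overlap")
  # side-site geometry at construction
  off <- sqrt(rowSums((sys$side_sites - sys$positions)^2))
  if (any(abs(off - 0.5) > max(tol_offset, 0.2)))
    stop("side-site offset far from 0.5 sigma")
  if (strict_frame) {
    if (any(abs(off - 0.5) > tol_offset))
      stop("side-site offset != 0.5 sigma at construction")
    for (i in seq_len(n)) {
      im <- if (sys$closed) ((i - 2) %% n) + 1 else max(i - 1, 1)
      ip <- if (sys$closed) (i %% n) + 1 else min(i + 1, n)
      tv <- sys$positions[ip, ] - sys$positions[im, ]
      tv <- tv / sqrt(sum(tv^2))
      u <- (sys$side_sites[i, ] - sys$positions[i, ]) / off[i]
      if (abs(sum(u * tv)) > tol_perp)
        stop("side site not perpendicular to local tangent at construction")
    }
  }
  for (r in sys$rings) {
    if (r$anchor < 1 || r$anchor > n) stop("ring anchor out of range")
    if (.ring_crossings(sys$positions, r) != 1)
      stop("ring is not threaded by the chain (disc crossings != 1)")
  }
  invisible(TRUE)
}

# count chain-segment crossings through the disc spanned by a ring
.ring_crossings <- function(pos, ring) {
  ctr <- colMeans(ring$positions)
  # normal from first two ring beads
  a <- ring$positions[1, ] - ctr
  b <- ring$positions[2, ] - ctr
  nv <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  nv <- nv / sqrt(sum(nv^2))
  rho <- mean(sqrt(rowSums(sweep(ring$positions, 2, ctr)^2)))
  s <- as.numeric((pos - matrix(ctr, nrow(pos), 3, byrow = TRUE)) %*% nv)
  s[s == 0] <- 1e-12  # anchor bead sits on the ring plane
  cross <- 0L
  for (i in seq_len(nrow(pos) - 1)) {
    if (s[i] * s[i + 1] < 0) {
      f <- s[i] / (s[i] - s[i + 1])
      pt <- pos[i, ] + f * (pos[i + 1, ] - pos[i, ])
      if (sum((pt - ctr)^2) < rho^2) cross <- cross + 1L
    }
  }
  cross
}

#' Cohesin ring geometry
#'
#' Ring of `n_ring_beads` beads of diameter `bead_diameter_nm` evenly spaced
#' on a circle whose circumference equals the summed bead diameters (adjacent
#' beads tangent along the arc). For 16 beads of 10 nm this gives a
#' centre-line diameter of 160/pi ~ 50.9 nm.
#'
#' @param n_ring_beads beads per ring.
#' @param bead_diameter_nm bead diameter in nm.
#' @return list with `diameter_nm` (centre-line), `radius_sigma`, and the
#'   bead angles.
#' @export
cohesin_ring_geometry <- function(n_ring_beads = 16, bead_diameter_nm = 10) {
  circ_nm <- n_ring_beads * bead_diameter_nm
  diameter_nm <- circ_nm / pi
  list(diameter_nm = diameter_nm,
       radius_sigma = diameter_nm / 2 / .SIGMA_NM,
       angles = 2 * pi * (seq_len(n_ring_beads) - 1) / n_ring_beads)
}

# build one ring threaded on the chain at `anchor`, in the plane
# perpendicular to the local chain direction
.make_ring <- function(pos, anchor, n_ring_beads = 16) {
  g <- cohesin_ring_geometry(n_ring_beads)
  n <- nrow(pos)
  ip <- min(anchor + 1, n); im <- max(anchor - 1, 1)
  tv <- pos[ip, ] - pos[im, ]
  tv <- tv / sqrt(sum(tv^2))
  ref <- if (abs(tv[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * tv) * tv
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(tv[2] * e1[3] - tv[3] * e1[2], tv[3] * e1[1] - tv[1] * e1[3],
          tv[1] * e1[2] - tv[2] * e1[1])
  ctr <- pos[anchor, ]
  rp <- t(vapply(g$angles, function(a)
    ctr + g$radius_sigma * (cos(a) * e1 + sin(a) * e2), numeric(3)))
  # rest distances of the rigid elastic network (all pairs, packed a < b)
  rest <- numeric(0)
  for (a in seq_len(n_ring_beads - 1))
    for (b in (a + 1):n_ring_beads)
      rest <- c(rest, sqrt(sum((rp[b, ] - rp[a, ])^2)))
  list(positions = rp, anchor = as.integer(anchor), rest = rest)
}

#' Closed-loop divergent-transcription system
#'
#' One divergently transcribed region of `domain_kb` closed into a loop. The
#' closure point is flanked by two convergent torsional motors (two beads
#' each) and the bond between them -- the closure bond -- is a swivel, so
#' positive torsional stress generated ahead of the motors dissipates freely
#' while negative supercoiling accumulates in the domain. The starting
#' configuration is a flat circle (writhe and twist zero).
#'
#' @param domain_kb domain size in kb (> 1).
#' @param torque_pNnm motor torque (default 2 pN nm).
#' @param box periodic box edge in sigma; default sized to the dilute regime.
#' @return a `fiber_system` with one domain record.
#' @examples
#' sys <- build_loop_system(50, torque_pNnm = 2)
#' sys$n_beads  # ~129
#' @export
build_loop_system <- function(domain_kb, torque_pNnm = 2, box = NULL) {
  if (domain_kb <= 1) stop("domain too small to host motors and swivel")
  nd <- bp_to_beads(domain_kb * 1000)
  if (nd < 6) stop("domain too small to host motors and swivel")
  n <- nd + 4L  # 2 motor beads on each side of the swivel
  # layout: beads 1,2 = motor (dir -1), 3..n-2 = domain, n-1,n = motor (dir +1)
  # swivel = closure bond n (bead n -> bead 1)
  r <- n / (2 * pi)
  th <- 2 * pi * (seq_len(n) - 1) / n
  pos <- cbind(r * cos(th), r * sin(th), 0)
  # side sites radially outward: perpendicular to tangent, flat ladder
  sites <- cbind((r + 0.5) * cos(th), (r + 0.5) * sin(th), 0)
  if (is.null(box)) box <- max(4 * sqrt(2 * 5 * n / 6), 2.5 * r + 4)
  motors <- data.frame(bond = c(1L, n - 1L), direction = c(-1L, 1L),
                       torque_pNnm = torque_pNnm)
  fiber_system(pos, sites, closed = TRUE, motors = motors,
               swivel_bonds = n, domains = data.frame(start = 3L, end = n - 2L),
               box = box)
}

#' Sample domain sizes
#'
#' Default stand-in for the experimental distribution of fission-yeast
#' self-interacting domain sizes: uniform on 40-100 kb (the experimental
#' distribution is not tabulated; 50-100 kb is the reported range).
#'
#' @param n number of domains.
#' @param min_kb,max_kb range in kb.
#' @return numeric vector of sizes in kb.
#' @export
sample_domain_sizes <- function(n, min_kb = 40, max_kb = 100) {
  runif(n, min_kb, max_kb)
}

#' Worm-like-chain starting configuration
#'
#' Draws successive bond directions from the Kratky-Porod Boltzmann weight
#' `exp(eps_bend cos theta)` (azimuth uniform), so the returned conformation
#' is an equilibrated ideal discrete worm-like chain; residual excluded-volume
#' overlaps relax within a short Langevin run. Uses R's RNG (set the seed for
#' reproducibility).
#'
#' @param n beads.
#' @param eps_bend bending stiffness in eps0.
#' @return n x 3 matrix of bead positions (bond length 1 sigma), centred.
#' @export
wlc_chain_positions <- function(n, eps_bend = 5) {
  tv <- matrix(0, n - 1, 3)
  tv[1, ] <- c(1, 0, 0)
  if (n > 2) for (i in 2:(n - 1)) {
    # inverse-CDF sample of cos(theta) under exp(eps_b cos)
    u <- runif(1)
    cth <- 1 + log(u + (1 - u) * exp(-2 * eps_bend)) / eps_bend
    sth <- sqrt(max(0, 1 - cth^2))
    psi <- runif(1, 0, 2 * pi)
    tp <- tv[i - 1, ]
    ref <- if (abs(tp[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * tp) * tp
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(tp[2] * e1[3] - tp[3] * e1[2], tp[3] * e1[1] - tp[1] * e1[3],
            tp[1] * e1[2] - tp[2] * e1[1])
    tv[i, ] <- cth * tp + sth * (cos(psi) * e1 + sin(psi) * e2)
  }
  pos <- rbind(c(0, 0, 0), apply(tv, 2, cumsum))
  sweep(pos, 2, colMeans(pos))
}

# rejection-sample worm-like-chain draws until free of steric clashes
# (a clash would put the integrator on the singular core of the potential)
.wlc_self_avoiding <- function(n, min_dist = 0.85, tries = 200) {
  for (t in seq_len(tries)) {
    pos <- wlc_chain_positions(n)
    d <- as.matrix(dist(pos))
    sep <- abs(outer(seq_len(n), seq_len(n), "-"))
    if (min(d[sep > 1]) >= min_dist) return(pos)
  }
  stop("could not draw a clash-free worm-like chain; use init = 'straight'")
}

#' Linear multi-domain system
#'
#' A linear chromosome fragment of divergent-transcription domains. Each
#' internal border carries, in order along the chain: a motor (2 beads)
#' transcribing toward the border, a swivel bond ahead of it, a passage zone
#' (`zone_beads` beads of weak excluded volume), a second swivel, and the
#' next domain's motor transcribing back toward the border (convergent
#' orientation). With `terminal_borders = TRUE` both chain ends also get a
#' motor + swivel + zone, so every domain is flanked by convergent motors.
#'
#' @param domain_sizes_kb numeric vector of domain sizes in kb (>= 1 domain).
#' @param torque_pNnm motor torque (default 2 pN nm).
#' @param zone_beads passage-zone length in beads (default 10).
#' @param terminal_borders place border elements at the chain ends too.
#' @param box periodic box edge in sigma (default: dilute, fits the chain).
#' @param init `"straight"` (default) or `"wlc"` (equilibrated worm-like-chain
#'   draw via [wlc_chain_positions()]; uses R's RNG).
#' @return a `fiber_system` with one domain record per size and the
#'   motor-convergence bead positions in `attr(, "convergence")`.
#' @examples
#' sys <- build_linear_system(c(40, 60), torque_pNnm = 2)
#' sys$domains
#' @export
build_linear_system <- function(domain_sizes_kb, torque_pNnm = 2,
                                zone_beads = 10, terminal_borders = TRUE,
                                box = NULL, init = c("straight", "wlc")) {
  init <- match.arg(init)
  if (length(domain_sizes_kb) < 1) stop("need at least one domain")
  nd <- bp_to_beads(domain_sizes_kb * 1000)
  if (any(nd < 3)) stop("domain too small")
  K <- length(nd)

  # assemble the track bead by bead
  motors <- data.frame(bond = integer(0), direction = integer(0),
                       torque_pNnm = numeric(0))
  swivels <- integer(0)
  zones <- data.frame(start = integer(0), end = integer(0))
  domains <- data.frame(start = integer(0), end = integer(0))
  convergence <- integer(0)
  cur <- 0L  # beads placed so far

  add_zone <- function(cur) {
    zones[nrow(zones) + 1, ] <<- c(cur + 1L, cur + zone_beads)
    convergence <<- c(convergence, cur + as.integer(ceiling(zone_beads / 2)))
    cur + zone_beads
  }
  add_motor <- function(cur, dir) {
    # two beads; motor bond joins them; swivel ahead (dir>0: after, dir<0: before)
    b <- cur + 1L  # bond index between beads cur+1 and cur+2
    motors[nrow(motors) + 1, ] <<- c(b, dir, torque_pNnm)
    if (dir > 0) swivels <<- c(swivels, b + 1L) else swivels <<- c(swivels, b - 1L)
    cur + 2L
  }

  if (terminal_borders) {
    cur <- add_zone(cur)
    cur <- add_motor(cur, -1L)  # transcribes toward the chain start
  }
  for (k in seq_len(K)) {
    domains[k, ] <- c(cur + 1L, cur + nd[k])
    cur <- cur + nd[k]
    last <- k == K
    if (!last || terminal_borders) cur <- add_motor(cur, +1L)
    if (!last) {
      cur <- add_zone(cur)
      cur <- add_motor(cur, -1L)
    } else if (terminal_borders) {
      cur <- add_zone(cur)
    }
  }
  n <- cur
  pos <- if (init == "wlc") .wlc_self_avoiding(n) else
    cbind(seq_len(n) - (n + 1) / 2, 0, 0)
  sites <- if (init == "wlc") NULL else
    pos + matrix(rep(c(0, 0, 0.5), each = n), n, 3)
  if (is.null(box)) box <- max(4 * sqrt(2 * 5 * n / 6), 1.25 * n)
  sys <- fiber_system(pos, sites, closed = FALSE, motors = motors,
                      swivel_bonds = swivels, passage_zones = zones,
                      domains = domains, box = box)
  attr(sys, "convergence") <- convergence
  sys
}

#' Cohesin-barrier system
#'
#' A passive linear fibre (no motors, swivels or passage zones) threaded
#' through rigid 16-bead cohesin rings tethered at regular genomic spacing.
#' Each ring is held at its anchor bead by a harmonic restraint between the
#' ring centre and the anchor (constant `k_anchor` in [ff_params()]).
#'
#' @param n_beads chain length in beads.
#' @param spacing_kb genomic spacing between rings (default ~50 kb).
#' @param n_ring_beads beads per ring (default 16).
#' @param box periodic box edge in sigma.
#' @return a `fiber_system` with rings; anchors in `attr(, "anchors")`.
#' @examples
#' sys <- build_cohesin_system(250, spacing_kb = 50)
#' length(sys$rings)  # 2
#' @export
build_cohesin_system <- function(n_beads, spacing_kb = 50, n_ring_beads = 16,
                                 box = NULL) {
  n <- as.integer(n_beads)
  sp <- bp_to_beads(spacing_kb * 1000)
  if (sp < 4) stop("ring spacing below the ring footprint")
  anchors <- if (sp >= n) as.integer(round(n / 2)) else
    as.integer(round(seq(sp / 2, n, by = sp)))
  anchors <- anchors[anchors >= 2 & anchors <= n - 1]
  pos <- cbind(seq_len(n) - (n + 1) / 2, 0, 0)
  sites <- pos + matrix(rep(c(0, 0, 0.5), each = n), n, 3)
  rings <- lapply(anchors, function(a) .make_ring(pos, a, n_ring_beads))
  if (is.null(box)) box <- max(4 * sqrt(2 * 5 * n / 6), 1.25 * n)
  sys <- fiber_system(pos, sites, closed = FALSE, rings = rings, box = box)
  attr(sys, "anchors") <- anchors
  sys
}

#' Read a BED-like layout file
#'
#' Columns: chrom, start, end (0-based half-open, bp), element_type in
#' `domain`, `motor+`, `motor-`, `swivel`, `zone`, `ring`, and torque (pN nm,
#' used for motors). Coordinates are converted at 400 bp/bead and the
#' elements are applied to a straight linear fibre spanning the layout.
#'
#' @param path file path.
#' @param torque_default torque for motor rows with missing torque.
#' @return a `fiber_system`.
#' @export
read_layout_bed <- function(path, torque_default = 2) {
  df <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("layout needs >= 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "type")
  df$torque <- if (ncol(df) >= 5) as.numeric(df[[5]]) else NA_real_
  if (any(df$start < 0 | df$end <= df$start)) stop("invalid intervals")
  n <- bp_to_beads(max(df$end))
  b0 <- function(bp) pmax(bp_to_beads(bp) + 1L, 1L)     # first bead of interval
  b1 <- function(bp) pmin(bp_to_beads(bp), n)           # last bead (half-open end)
  motors <- data.frame(bond = integer(0), direction = integer(0),
                       torque_pNnm = numeric(0))
  swivels <- integer(0)
  zones <- data.frame(start = integer(0), end = integer(0))
  domains <- data.frame(start = integer(0), end = integer(0))
  ring_anchors <- integer(0)
  for (i in seq_len(nrow(df))) {
    s <- b0(df$start[i]); e <- b1(df$end[i])
    tq <- if (is.na(df$torque[i])) torque_default else df$torque[i]
    switch(df$type[i],
      "domain" = { domains[nrow(domains) + 1, ] <- c(s, e) },
      "motor+" = { motors[nrow(motors) + 1, ] <- c(s, 1L, tq) },
      "motor-" = { motors[nrow(motors) + 1, ] <- c(s, -1L, tq) },
      "swivel" = { swivels <- c(swivels, s) },
      "zone" = { zones[nrow(zones) + 1, ] <- c(s, e) },
      "ring" = { ring_anchors <- c(ring_anchors, s) },
      stop("unknown element_type: ", df$type[i]))
  }
  pos <- cbind(seq_len(n) - (n + 1) / 2, 0, 0)
  sites <- pos + matrix(rep(c(0, 0, 0.5), each = n), n, 3)
  rings <- lapply(ring_anchors, function(a) .make_ring(pos, a))
  fiber_system(pos, sites, closed = FALSE, motors = motors,
               swivel_bonds = swivels, passage_zones = zones,
               domains = domains, rings = rings,
               box = max(4 * sqrt(2 * 5 * n / 6), 1.25 * n))
}
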