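#' Force-field parameters
#'
#' All constants are in reduced units: lengths in sigma (10 nm), energies in
#' eps0 = kBT. Defaults follow the chromatin fibre model: purely repulsive
#' cut-and-shifted Lennard-Jones excluded volume with `r_cut = 1` sigma,
#' harmonic bonds, Kratky-Porod bending with `eps_bend = 5` (persistence
#' length ~50 nm), and a harmonic ladder dihedral with `k_tor = 4`.
#'
#' @param eps excluded-volume prefactor (eps0).
#' @param r_cut excluded-volume cutoff in sigma; must be <= 2^(1/6).
#' @param k_bond backbone bond spring constant (eps0/sigma^2). The bond
#'   stiffness is not dictated by the fibre physics; the default keeps
#'   bond-length fluctuations below ~4% at kT = 1.
#' @param r0_bond bond rest length (sigma).
#' @param eps_bend bending stiffness of `eps_bend * (1 - cos theta)` (eps0).
#' @param k_tor torsional stiffness of the ladder dihedral,
#'   `0.5 * k_tor * phi^2` (eps0/rad^2); swivel bonds override this with 0.
#' @param k_side side-site tether stiffness (eps0/sigma^2); stiff so the
#'   material frame follows its bead rigidly.
#' @param r0_side side-site offset from the parent bead (sigma).
#' @param k_perp stiffness keeping side sites perpendicular to the local
#'   chord (eps0), applied to the squared cosine. Stiff enough that a side
#'   site cannot thermally cross the chain axis, which would let the material
#'   frame slip a full turn and leak linking number; the frame constraint
#'   adds a small effective bending stiffness (fitted persistence length
#'   ~55 nm at eps_bend = 5).
#' @param zone_eps excluded-volume prefactor for pairs involving a
#'   passage-zone bead. The default puts the barrier felt by a segment
#'   mid-plane between two zone beads at ~2 eps0, making thermal
#'   intersegmental passages possible. This is the main free parameter
#'   controlling the passage rate.
#' @param k_ring stiffness of the elastic network keeping cohesin rings rigid
#'   (eps0/sigma^2).
#' @param k_anchor restraint between a ring's centre and its anchor bead
#'   (eps0/sigma^2).
#' @param kT_pNnm thermal torque conversion, pN nm per eps0.
#' @return an object of class `ff_params` (named list).
#' @examples
#' p <- ff_params()
#' p$eps_bend
#' @export
ff_params <- function(eps = 1, r_cut = 1, k_bond = 800, r0_bond = 1,
                      eps_bend = 5, k_tor = 4, k_side = 8000, r0_side = 0.5,
                      k_perp = 100, zone_eps = NULL, k_ring = 1000,
                      k_anchor = 10, kT_pNnm = .KT_PNNM) {
  if (r_cut > 2^(1 / 6) + 1e-12) stop("r_cut must be <= 2^(1/6)")
  if (is.null(zone_eps)) {
    # full-overlap barrier ~ 2 eps0 for a segment sitting 0.5 sigma from two
    # zone beads: 2 * V_wca(0.5; eps = 1) * zone_eps = 2
    zone_eps <- 1 / excluded_volume_energy(0.5, eps = 1, r_cut = r_cut)
  }
  p <- list(eps = eps, r_cut = r_cut, k_bond = k_bond, r0_bond = r0_bond,
            eps_bend = eps_bend, k_tor = k_tor, k_side = k_side,
            r0_side = r0_side, k_perp = k_perp, zone_eps = zone_eps,
            k_ring = k_ring, k_anchor = k_anchor, kT_pNnm = kT_pNnm)
  bad <- vapply(p, function(v) !is.finite(v) || v < 0, logical(1))
  if (any(bad)) stop("force-field constants must be finite and >= 0")
  class(p) <- "ff_params"
  p
}

#' @export
print.ff_params <- function(x, ...) {
  cat("Force-field parameters (reduced units, eps0 = kBT, sigma = 10 nm):\n")
  for (nm in names(x)) cat(sprintf("  %-9s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Repulsive excluded-volume pair energy
#'
#' Cut-and-shifted repulsive Lennard-Jones:
#' `V(r) = 4 eps ((1/r)^12 - (1/r)^6) - V(r_cut)` below the cutoff, else 0.
#' With `r_cut = 1` the shift term is exactly zero.
#'
#' @param r centre-centre distance in sigma (> 0).
#' @param eps prefactor in eps0.
#' @param r_cut cutoff in sigma.
#' @return energy in eps0.
#' @export
excluded_volume_energy <- function(r, eps = 1, r_cut = 1) {
  if (any(r <= 0)) stop("overlap singularity: r must be > 0")
  sh <- 4 * (r_cut^-12 - r_cut^-6)
  ifelse(r < r_cut, 4 * eps * (r^-12 - r^-6) - eps * sh, 0)
}

#' Bending energy of a joint
#'
#' Kratky-Porod form `eps_bend * (1 - cos theta)`; `theta` is the angle
#' between consecutive bond vectors (0 on a straight chain).
#'
#' @param theta bending angle in radians, in `[0, pi]`.
#' @param eps_bend stiffness in eps0.
#' @return energy in eps0.
#' @export
bending_energy <- function(theta, eps_bend = 5) {
  if (any(theta < -1e-12 | theta > pi + 1e-12)) stop("theta must be in [0, pi]")
  eps_bend * (1 - cos(theta))
}

#' Torsional energy of a bond dihedral
#'
#' Harmonic dihedral `0.5 k (phi - phi0)^2` with the angle wrapped to
#' `(-pi, pi]`. Swivel bonds have `k = 0`, hence zero energy at any angle.
#'
#' @param phi dihedral angle in radians.
#' @param k torsional stiffness in eps0/rad^2.
#' @param phi0 rest dihedral (radians), used to impose a linking-number
#'   deficit on closed fibres.
#' @return energy in eps0.
#' @export
torsion_energy <- function(phi, k = 4, phi0 = 0) {
  d <- wrap_angle(phi - phi0)
  0.5 * k * d^2
}

# wrap angles to (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Generalized motor torque on the fibre twist coordinate
#'
#' A torsional motor rotates the fibre axially at its location: an external
#' torque of magnitude `tau` (in eps0/rad after conversion from pN nm) acts
#' on the material frame of the motor beads about the local tangent, with
#' the reaction absorbed by the implicit medium, as for a polymerase
#' anchored by viscous drag. The motor stalls when the accumulated elastic
#' torsional stress opposing it reaches `tau`. The sign follows the
#' handedness of transcription: a motor transcribing toward increasing bead
#' index drives the twist behind it (lower indices) negative, so the applied
#' lab-frame torque is `-direction * tau`.
#'
#' @param direction +1 or -1, sense of transcription along increasing bead
#'   index.
#' @param torque_pNnm motor torque in pN nm.
#' @return signed generalized torque in eps0/rad.
#' @export
motor_generalized_force <- function(direction, torque_pNnm) {
  if (any(abs(direction) != 1)) stop("direction must be +1 or -1")
  .MOTOR_SIGN * direction * motor_torque_reduced(torque_pNnm)
}

# lab-frame torque sign per unit transcription direction: negative twist
# accumulates behind each motor (Fig-1 orientation gives negative writhe)
.MOTOR_SIGN <- -1

#' Forces and energy breakdown of a system
#'
#' Evaluates the full force field (excluded volume with minimum-image
#' convention, bonds, bending, torsion, motors, side-site frame terms, ring
#' network and anchors). Forces are exact negative gradients of the total
#' energy.
#'
#' @param system a `fiber_system`.
#' @param params `ff_params`.
#' @return list with `forces` (one row per particle: beads, then side sites,
#'   then ring beads) and `energy` (named per-term totals in eps0; `total` is
#'   their sum).
#' @export
compute_forces <- function(system, params = ff_params()) {
  stopifnot(inherits(system, "fiber_system"))
  pos <- .stack_positions(system)
  if (any(!is.finite(pos))) stop("non-finite coordinates")
  cpp_compute_forces(pos, .sys_to_cpp(system, params), .par_to_cpp(params))
}

# ---- internal marshalling -------------------------------------------------

.stack_positions <- function(sys) {
  m <- rbind(sys$positions, sys$side_sites)
  for (r in sys$rings) m <- rbind(m, r$positions)
  m
}

.unstack_positions <- function(sys, pos) {
  n <- sys$n_beads
  sys$positions <- pos[seq_len(n), , drop = FALSE]
  sys$side_sites <- pos[n + seq_len(n), , drop = FALSE]
  off <- 2 * n
  for (k in seq_along(sys$rings)) {
    m <- nrow(sys$rings[[k]]$positions)
    sys$rings[[k]]$positions <- pos[off + seq_len(m), , drop = FALSE]
    off <- off + m
  }
  sys
}

.sys_to_cpp <- function(sys, params) {
  n <- sys$n_beads
  nb <- if (sys$closed) n else n - 1
  ktor <- rep(params$k_tor, nb)
  ktor[sys$swivel_bonds] <- 0
  phi0 <- sys$phi0
  if (is.null(phi0)) phi0 <- rep(0, nb)
  mott <- rep(0, n)
  if (nrow(sys$motors) > 0) {
    for (i in seq_len(nrow(sys$motors))) {
      b <- sys$motors$bond[i]
      if (b %in% sys$swivel_bonds)
        stop("motor on a swivel bond: contradictory annotation")
      g <- motor_generalized_force(sys$motors$direction[i],
                                   sys$motors$torque_pNnm[i])
      # the motor spans two beads; the torque is split between their frames
      beads <- c(b, if (sys$closed && b == n) 1L else b + 1L)
      mott[beads] <- mott[beads] + g / 2
    }
  }
  zone <- integer(n)
  if (nrow(sys$passage_zones) > 0) {
    for (i in seq_len(nrow(sys$passage_zones)))
      zone[sys$passage_zones$start[i]:sys$passage_zones$end[i]] <- 1L
  }
  rings <- list()
  anchors <- integer(0)
  ring_rest <- list()
  off <- 2 * n
  for (r in sys$rings) {
    m <- nrow(r$positions)
    rings[[length(rings) + 1]] <- as.integer(off + seq_len(m) - 1)
    anchors <- c(anchors, as.integer(r$anchor - 1))
    ring_rest[[length(ring_rest) + 1]] <- r$rest
    off <- off + m
  }
  list(n = as.integer(n), closed = sys$closed, zone = as.integer(zone),
       ktor = ktor, phi0 = phi0, mott = mott, rings = rings,
       anchors = anchors, ring_rest = ring_rest, box = sys$box)
}

.par_to_cpp <- function(p) {
  list(eps = p$eps, r_cut = p$r_cut, k_bond = p$k_bond, r0_bond = p$r0_bond,
       eps_bend = p$eps_bend, k_side = p$k_side, r0_side = p$r0_side,
       k_perp = p$k_perp, zone_eps = p$zone_eps, k_ring = p$k_ring,
       k_anchor = p$k_anchor)
}
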