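# Unit system: length in sigma (1 sigma = 10 nm of 10 nm fibre = 400 bp),
# energy in eps0 = kBT, torque in eps0/rad; kBT = 4.1 pN nm at ~298 K.

.BP_PER_BEAD <- 400
.SIGMA_NM <- 10
.KT_PNNM <- 4.1
.ETA_WATER <- 8.9e-4    # Pa s
.BEAD_RADIUS_M <- 5e-9  # Stokes radius of a 10 nm bead
.SIGMA_M <- 1e-8
.KT_J <- 4.11e-21
# steps worth of Brownian time per reported step at the reference dt;
# fixed so that one step in water corresponds to ~5 microseconds.
.STEP_CAL <- 2.45
.DT_REF <- 1e-3

#' Convert genomic length to bead count
#'
#' One bead of the 10 nm fibre model covers 400 bp.
#'
#' @param bp genomic length in base pairs (non-negative).
#' @return integer bead count, `round(bp / 400)`.
#' @examples
#' bp_to_beads(50000)  # 125
#' @export
bp_to_beads <- function(bp) {
  if (any(!is.finite(bp)) || any(bp < 0)) stop("genomic length must be >= 0")
  as.integer(round(bp / .BP_PER_BEAD))
}

#' Convert bead count to genomic length
#'
#' @param beads bead count.
#' @return genomic length in bp (exact multiplication by 400).
#' @export
beads_to_bp <- function(beads) {
  if (any(beads < 0)) stop("bead count must be >= 0")
  beads * .BP_PER_BEAD
}

#' Motor torque in reduced units
#'
#' Converts a torque in pN nm to the reduced generalized force on a dihedral
#' coordinate, eps0 per radian, using kBT = 4.1 pN nm.
#'
#' @param torque_pNnm torque in pN nm (>= 0).
#' @return torque in eps0/rad.
#' @examples
#' motor_torque_reduced(2)  # ~0.488
#' @export
motor_torque_reduced <- function(torque_pNnm) {
  if (any(torque_pNnm < 0)) stop("torque must be >= 0")
  torque_pNnm / .KT_PNNM
}

#' Physical time represented by one integration step
#'
#' Uses Stokes' drag for a 5 nm-radius bead, `gamma_phys = 6 pi eta r`, to map
#' reduced time to seconds. The Brownian time of one bead,
#' `tau_B = gamma_phys sigma^2 / kBT`, is ~2.04 us in water; a documented
#' calibration constant (2.45 tau_B per reference step) anchors the mapping so
#' that one step at the reference dt corresponds to ~5 us in water and ~75 ms
#' at 15000x the viscosity of water. The result is linear in both viscosity
#' and `dt`.
#'
#' @param viscosity solvent viscosity as a multiple of water (> 0).
#' @param dt integration step in reduced time units (default reference 1e-3).
#' @return seconds of physical time per integration step.
#' @examples
#' physical_time_per_step(1)      # ~5e-6 s
#' physical_time_per_step(15000)  # ~0.075 s
#' @export
physical_time_per_step <- function(viscosity = 1, dt = .DT_REF) {
  if (any(viscosity <= 0)) stop("viscosity must be > 0")
  gamma_phys <- 6 * pi * .ETA_WATER * viscosity * .BEAD_RADIUS_M
  tau_b <- gamma_phys * .SIGMA_M^2 / .KT_J
  .STEP_CAL * tau_b * (dt / .DT_REF)
}
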