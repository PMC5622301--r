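# Langevin dynamics driver: settings, single runs, replica management and
# autocorrelation-based thermalization control.

#' Integrator settings
#'
#' BAOAB Langevin integrator settings in reduced units (unit bead mass,
#' kT = 1 eps0). The stability of the stiffest mode (side-site tethers,
#' omega = sqrt(k_side)) is checked at run start.
#'
#' @param dt time step in reduced time units.
#' @param gamma friction per bead (reduced); `0` gives microcanonical
#'   velocity-Verlet (used for energy-conservation checks).
#' @param kT thermostat temperature in eps0.
#' @param n_steps production steps.
#' @param report_every steps between recorded frames/series rows.
#' @param seed integer seed (each replica r uses `seed + 1009 * (r - 1)`).
#' @param n_replicas independent copies (default 5).
#' @param therm_steps pre-thermalization steps (default `n_steps %/% 4`).
#' @param tau_multiplier production length required, in units of the measured
#'   Rg autocorrelation time (default 8).
#' @param max_steps cap on automatically extended production length.
#' @param abort_dr abort threshold: one-step displacement in sigma.
#' @return object of class `integrator_settings`.
#' @export
integrator_settings <- function(dt = 1e-3, gamma = 1, kT = 1, n_steps = 1e5,
                                report_every = 1000, seed = 1, n_replicas = 5,
                                therm_steps = NULL, tau_multiplier = 8,
                                max_steps = NULL, abort_dr = 0.5) {
  if (dt <= 0 || gamma < 0 || kT < 0) stop("invalid integrator settings")
  if (is.null(therm_steps)) therm_steps <- max(as.integer(n_steps) %/% 4L, 1000L)
  if (is.null(max_steps)) max_steps <- 4 * n_steps
  s <- list(dt = dt, gamma = gamma, kT = kT, n_steps = as.integer(n_steps),
            report_every = as.integer(report_every), seed = as.integer(seed),
            n_replicas = as.integer(n_replicas),
            therm_steps = as.integer(therm_steps),
            tau_multiplier = tau_multiplier,
            max_steps = as.integer(max_steps), abort_dr = abort_dr)
  class(s) <- "integrator_settings"
  s
}

#' Run Langevin dynamics on a fibre system
#'
#' Evolves the system with the BAOAB splitting at temperature `kT` under the
#' minimum-image convention. Coordinates are integrated unwrapped (topology
#' measures need unwrapped copies); periodicity enters through the non-bonded
#' interactions. Without motors, long runs sample the Boltzmann distribution
#' of the force field.
#'
#' @param system a `fiber_system`.
#' @param params `ff_params`.
#' @param settings `integrator_settings`.
#' @param writhe_domains optional data frame (`start`, `end`) of bead ranges
#'   whose writhe is recorded each report; defaults to the system's domains,
#'   extended by the flanking motor beads (`include_motor_beads`).
#' @param include_motor_beads extend per-domain writhe ranges over the
#'   flanking motor beads (they are part of the transcribed fibre).
#' @param store_frames keep coordinates of every reported frame.
#' @return a `fiber_trajectory`: list with `series` (data frame: step, Rg in
#'   sigma, twist and writhe in turns, per-term energies, kinetic energy, one
#'   `Wr_dom*` column per domain), `frames` (np x 3 x n_frames array or
#'   NULL), `system` (final state), `settings`, `seed`.
#' @export
run_langevin <- function(system, params = ff_params(),
                         settings = integrator_settings(),
                         writhe_domains = NULL, include_motor_beads = TRUE,
                         store_frames = TRUE) {
  stopifnot(inherits(system, "fiber_system"))
  stiff <- max(params$k_bond, params$k_side, params$k_ring)
  if (settings$dt * sqrt(2 * stiff) > 1.8)
    stop("dt unstable for the stiffest bonded mode; reduce dt")
  if (is.null(writhe_domains)) {
    writhe_domains <- system$domains
    if (include_motor_beads && nrow(writhe_domains) > 0) {
      writhe_domains$start <- pmax(writhe_domains$start - 2L, 1L)
      writhe_domains$end <- pmin(writhe_domains$end + 2L, system$n_beads)
    }
  }
  dom <- if (nrow(writhe_domains) > 0)
    cbind(as.integer(writhe_domains$start) - 1L,
          as.integer(writhe_domains$end) - 1L)
  else matrix(integer(0), 0, 2)
  pos <- .stack_positions(system)
  cs <- list(dt = settings$dt, gamma = settings$gamma, kT = settings$kT,
             n_steps = settings$n_steps, report_every = settings$report_every,
             seed = as.double(settings$seed), abort_dr = settings$abort_dr)
  out <- cpp_run_langevin(pos, .sys_to_cpp(system, params),
                          .par_to_cpp(params), cs, dom, store_frames)
  if (out$status != 0)
    stop(sprintf(
      "integrator blow-up at step %d (one-step displacement > %g sigma); reduce dt",
      out$steps_done, settings$abort_dr))
  rows <- out$rows
  ser <- out$series[seq_len(rows), , drop = FALSE]
  cn <- c("step", "Rg", "Tw", "Wr", "E_ev", "E_bond", "E_bend", "E_tor",
          "E_motor", "E_frame", "E_restraint", "E_kin")
  if (nrow(dom) > 0) cn <- c(cn, paste0("Wr_dom", seq_len(nrow(dom))))
  ser <- as.data.frame(ser)
  names(ser) <- cn
  frames <- NULL
  if (store_frames) {
    frames <- out$frames
    if (rows < dim(frames)[3]) frames <- frames[, , seq_len(rows), drop = FALSE]
  }
  traj <- structure(
    list(series = ser, frames = frames,
         system = .unstack_positions(system, out$final),
         settings = settings, seed = settings$seed,
         writhe_domains = writhe_domains, tau_ac = NA_real_,
         tau_converged = NA),
    class = "fiber_trajectory")
  traj
}

#' @export
print.fiber_trajectory <- function(x, ...) {
  cat(sprintf("fiber_trajectory: %d frames, %d beads, seed %d\n",
              nrow(x$series), x$system$n_beads, x$seed))
  cat(sprintf("  final Rg %.2f sigma, Tw %.3f, Wr %.3f turns\n",
              tail(x$series$Rg, 1), tail(x$series$Tw, 1),
              tail(x$series$Wr, 1)))
  if (!is.na(x$tau_ac))
    cat(sprintf("  Rg autocorrelation time: %.1f report intervals (converged: %s)\n",
                x$tau_ac, x$tau_converged))
  invisible(x)
}

#' Extract stored frame coordinates
#'
#' @param traj a `fiber_trajectory` with stored frames.
#' @param k frame index (1-based).
#' @return n x 3 matrix of bead (`frame_beads`) or side-site (`frame_sites`)
#'   coordinates.
#' @export
frame_beads <- function(traj, k) {
  n <- traj$system$n_beads
  traj$frames[seq_len(n), , k]
}

#' @rdname frame_beads
#' @export
frame_sites <- function(traj, k) {
  n <- traj$system$n_beads
  traj$frames[n + seq_len(n), , k]
}

#' Integrated autocorrelation time
#'
#' Sum of the normalized autocorrelation function up to its first zero
#' crossing: `tau = 1 + 2 sum_k rho(k)`, in units of the sampling interval.
#' White noise gives ~1; an AR(1) series with coefficient a gives
#' ~(1 + a)/(1 - a).
#'
#' @param x numeric series (e.g. Rg values at the reporting interval).
#' @param interval sampling interval represented by one element of `x`.
#' @return autocorrelation time in the units of `interval`.
#' @export
autocorrelation_time <- function(x, interval = 1) {
  if (length(x) < 50) stop("series too short for autocorrelation estimate")
  if (sd(x) == 0) stop("constant series: autocorrelation time undefined")
  r <- as.numeric(acf(x, lag.max = min(length(x) %/% 2, 5000),
                      plot = FALSE)$acf)[-1]
  k0 <- which(r <= 0)[1]
  if (is.na(k0)) k0 <- length(r) + 1L
  tau <- 1 + 2 * sum(r[seq_len(k0 - 1L)])
  max(tau, 1) * interval
}

#' Run independent replicas with thermalization control
#'
#' Each replica (distinct seed) is pre-thermalized, its Rg autocorrelation
#' time is estimated, and production is extended if shorter than
#' `tau_multiplier` autocorrelation times (up to `max_steps`). If the
#' autocorrelation time cannot be estimated, the trajectory is flagged and a
#' warning raised.
#'
#' @param system a `fiber_system` (or a factory function returning one, so
#'   replicas can differ in construction randomness).
#' @param params `ff_params`.
#' @param settings `integrator_settings`; `n_replicas`, `therm_steps`,
#'   `tau_multiplier` and `max_steps` control the schedule.
#' @param ... passed to [run_langevin()].
#' @return list of `fiber_trajectory`, one per replica, each carrying its
#'   seed and `tau_ac`.
#' @export
run_scenario_replicas <- function(system, params = ff_params(),
                                  settings = integrator_settings(), ...) {
  stopifnot(settings$n_replicas >= 1)
  out <- vector("list", settings$n_replicas)
  for (r in seq_len(settings$n_replicas)) {
    seed_r <- settings$seed + 1009L * (r - 1L)
    sys_r <- if (is.function(system)) system(r) else system
    th_set <- modifyList(settings,
                         list(n_steps = settings$therm_steps, seed = seed_r))
    class(th_set) <- "integrator_settings"
    th <- run_langevin(sys_r, params, th_set, store_frames = FALSE, ...)
    tau <- tryCatch(autocorrelation_time(th$series$Rg),
                    error = function(e) NA_real_)
    n_prod <- settings$n_steps
    converged <- TRUE
    if (is.na(tau)) {
      converged <- FALSE
      warning(sprintf("replica %d: Rg autocorrelation time not estimable", r))
    } else if (settings$n_steps > 0) {
      need <- ceiling(settings$tau_multiplier * tau) * settings$report_every
      if (need > n_prod) n_prod <- min(need, settings$max_steps)
      if (need > settings$max_steps) {
        converged <- FALSE
        warning(sprintf(
          "replica %d: %d steps needed for %g autocorrelation times, capped at %d",
          r, need, settings$tau_multiplier, settings$max_steps))
      }
    }
    pr_set <- modifyList(settings,
                         list(n_steps = as.integer(n_prod), seed = seed_r + 1L))
    class(pr_set) <- "integrator_settings"
    tr <- run_langevin(th$system, params, pr_set, ...)
    tr$tau_ac <- tau
    tr$tau_converged <- converged
    tr$seed <- seed_r
    out[[r]] <- tr
  }
  out
}
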