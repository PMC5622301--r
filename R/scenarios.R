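# Declarative scenario runner: the four study designs (loop with divergent
# transcription, linear multi-domain fragment, supercoiling homeostasis,
# cohesin barrier) plus the motor torque sweep.

.SCENARIOS <- c("loop_divergent", "linear_domains", "homeostasis",
                "cohesin_barrier", "torque_sweep")

.scenario_defaults <- function(scenario) {
  common <- list(
    scenario = scenario,
    replicas = 5L, seed = 1L,
    dt = 1e-3, gamma = 1, kT = 1,
    n_steps = 2e5, therm_steps = 5e4, report_every = 500L,
    tau_multiplier = 8, max_steps = 8e5,
    torque_pNnm = 2,
    contact_cutoff = 1.5, bin_beads = 25L,
    forcefield = list())
  extra <- switch(scenario,
    loop_divergent = list(domain_kb = 50),
    linear_domains = list(n_domains = 10L, domain_min_kb = 40,
                          domain_max_kb = 100, domain_sizes_kb = NULL,
                          zone_beads = 10L, terminal_borders = TRUE),
    homeostasis = list(n_domains = 10L, domain_min_kb = 40,
                       domain_max_kb = 100, domain_sizes_kb = NULL,
                       zone_beads = 10L, terminal_borders = TRUE,
                       passage_threshold = 1.5),
    cohesin_barrier = list(n_beads = 1250L, spacing_kb = 50),
    torque_sweep = list(torques = c(0, 1, 2, 4), n_domains = 10L,
                        domain_min_kb = 40, domain_max_kb = 100,
                        domain_sizes_kb = NULL, zone_beads = 10L,
                        terminal_borders = TRUE))
  c(common, extra)
}

#' Scenario configuration
#'
#' Builds a fully resolved configuration for one of the study scenarios:
#' `loop_divergent` (one ~50 kb divergently transcribed region closed into a
#' loop), `linear_domains` (a linear fragment of divergent-transcription
#' domains with border motors, swivels and passage zones), `homeostasis`
#' (the same system with per-domain writhe tracing and passage-event
#' detection), `cohesin_barrier` (a passive fibre threaded through rigid
#' rings) and `torque_sweep` (linear system at motor torques 0/1/2/4 pN nm).
#' Unknown keys are rejected. Defaults follow the study conditions: torque 2
#' pN nm, 5 replicas, 10 domains of 40-100 kb, 10-bead zones, 25-bead
#' (10 kb) binning.
#'
#' @param scenario one of the names above.
#' @param ... overrides of the scenario's default keys.
#' @return object of class `scenario_config` (named list).
#' @export
scenario_config <- function(scenario = .SCENARIOS, ...) {
  scenario <- match.arg(scenario)
  defaults <- .scenario_defaults(scenario)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, over)
  cfg$scenario <- scenario
  class(cfg) <- "scenario_config"
  cfg
}

#' Read a scenario configuration from a YAML file
#'
#' The file must contain a `scenario` key; all other keys override that
#' scenario's defaults (unknown keys are rejected).
#'
#' @param path YAML file.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$scenario)) stop("config must name a scenario")
  sc <- y$scenario
  y$scenario <- NULL
  do.call(scenario_config, c(list(scenario = sc), y))
}

.cfg_params <- function(cfg) do.call(ff_params, cfg$forcefield)

.cfg_settings <- function(cfg) {
  integrator_settings(dt = cfg$dt, gamma = cfg$gamma, kT = cfg$kT,
                      n_steps = cfg$n_steps, report_every = cfg$report_every,
                      seed = cfg$seed, n_replicas = cfg$replicas,
                      therm_steps = cfg$therm_steps,
                      tau_multiplier = cfg$tau_multiplier,
                      max_steps = cfg$max_steps)
}

.cfg_build <- function(cfg) {
  switch(cfg$scenario,
    loop_divergent = build_loop_system(cfg$domain_kb, cfg$torque_pNnm),
    cohesin_barrier = build_cohesin_system(cfg$n_beads, cfg$spacing_kb),
    {
      sizes <- cfg$domain_sizes_kb
      if (is.null(sizes)) {
        set.seed(cfg$seed)
        sizes <- sample_domain_sizes(cfg$n_domains, cfg$domain_min_kb,
                                     cfg$domain_max_kb)
      }
      build_linear_system(sizes, cfg$torque_pNnm, cfg$zone_beads,
                          cfg$terminal_borders)
    })
}

#' Run a scenario end to end
#'
#' Builds the system, runs the replicas, and writes to `out_dir`: the
#' resolved config (`config.yaml`), a run manifest (`manifest.json`: seed,
#' package version, stage status), per-replica topology series
#' (`series_r*.tsv`), event logs (`events_r*.tsv`), XYZ trajectories
#' (optional), pooled contact maps at bead and binned resolution
#' (`contacts_bead.txt`, `contacts_binned.txt`), domain scores
#' (`domain_scores.tsv`), depletion scores for ring scenarios
#' (`depletion.tsv`), and a per-replica summary (`summary.tsv`). A stage
#' failure keeps earlier outputs and marks the manifest.
#'
#' @param config a `scenario_config`.
#' @param out_dir output directory (created).
#' @param write_xyz_frames also write XYZ trajectories (large).
#' @return the output bundle: list with `config`, `system`, `trajectories`,
#'   `contacts`, `contacts_binned`, `scores`, `summary`, `events`, `dir`.
#' @export
run_scenario <- function(config, out_dir = tempfile("scenario_"),
                         write_xyz_frames = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$scenario == "torque_sweep") return(.run_torque_sweep(config, out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(scenario = config$scenario, seed = config$seed,
                   version = as.character(packageVersion("supercoilr")),
                   status = "running", failed_stage = NULL)
  cfg_plain <- unclass(config)
  yaml::write_yaml(cfg_plain, file.path(out_dir, "config.yaml"))
  .write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null")
  }
  .write_manifest()
  bundle <- list(config = config, dir = out_dir)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$status <<- "failed"
      manifest$failed_stage <<- paste0(name, ": ", conditionMessage(e))
      .write_manifest()
      stop(e)
    })
  }

  params <- .cfg_params(config)
  settings <- .cfg_settings(config)
  bundle$system <- stage("build", .cfg_build(config))
  bundle$trajectories <- stage("dynamics",
    run_scenario_replicas(bundle$system, params, settings))

  stage("outputs", {
    for (r in seq_along(bundle$trajectories)) {
      tr <- bundle$trajectories[[r]]
      write_topology_series(tr, file.path(out_dir, sprintf("series_r%d.tsv", r)))
      if (write_xyz_frames)
        write_xyz(tr, file.path(out_dir, sprintf("traj_r%d.xyz", r)))
    }
  })

  stage("analysis", {
    bundle$contacts <- contact_map(bundle$trajectories,
                                   cutoff = config$contact_cutoff)
    bundle$contacts_binned <- bin_map(bundle$contacts, config$bin_beads)
    write_contact_matrix(bundle$contacts, file.path(out_dir, "contacts_bead.txt"))
    write_contact_matrix(bundle$contacts_binned,
                         file.path(out_dir, "contacts_binned.txt"))
    if (nrow(bundle$system$domains) > 0) {
      bundle$scores <- domain_contact_scores(bundle$contacts,
                                             bundle$system$domains)
      write.table(bundle$scores, file.path(out_dir, "domain_scores.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (length(bundle$system$rings) > 0) {
      bundle$depletion <- depletion_lines(bundle$contacts,
                                          attr(bundle$system, "anchors"))
      write.table(bundle$depletion, file.path(out_dir, "depletion.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    thr <- if (!is.null(config$passage_threshold)) config$passage_threshold else 1.5
    ev_all <- list()
    for (r in seq_along(bundle$trajectories)) {
      tr <- bundle$trajectories[[r]]
      wr_cols <- grep("^Wr_dom", names(tr$series), value = TRUE)
      evs <- lapply(seq_along(wr_cols), function(d)
        detect_passage_events(tr$series[[wr_cols[d]]], threshold = thr,
                              steps = tr$series$step, domain = d))
      ev <- do.call(rbind, evs)
      if (!is.null(ev) && nrow(ev) > 0) {
        ev$replica <- r
        ev_all[[length(ev_all) + 1]] <- ev
      }
      write_events(if (is.null(ev)) detect_passage_events(numeric(0)) else ev,
                   file.path(out_dir, sprintf("events_r%d.tsv", r)))
    }
    bundle$events <- if (length(ev_all) > 0) do.call(rbind, ev_all) else
      data.frame(step = numeric(0), domain = integer(0), dWr = numeric(0),
                 replica = integer(0))
  })

  bundle$summary <- stage("summary", summarize_run(bundle))
  write.table(bundle$summary, file.path(out_dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$status <- "ok"
  .write_manifest()
  invisible(bundle)
}

.run_torque_sweep <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # shared domain sizes across torques: matched systems
  sizes <- config$domain_sizes_kb
  if (is.null(sizes)) {
    set.seed(config$seed)
    sizes <- sample_domain_sizes(config$n_domains, config$domain_min_kb,
                                 config$domain_max_kb)
  }
  bundles <- list()
  for (tq in config$torques) {
    sub <- scenario_config("linear_domains",
      replicas = config$replicas, seed = config$seed, dt = config$dt,
      gamma = config$gamma, kT = config$kT, n_steps = config$n_steps,
      therm_steps = config$therm_steps, report_every = config$report_every,
      tau_multiplier = config$tau_multiplier, max_steps = config$max_steps,
      torque_pNnm = tq, contact_cutoff = config$contact_cutoff,
      bin_beads = config$bin_beads, forcefield = config$forcefield,
      domain_sizes_kb = sizes, zone_beads = config$zone_beads,
      terminal_borders = config$terminal_borders)
    bundles[[sprintf("torque_%g", tq)]] <-
      run_scenario(sub, file.path(out_dir, sprintf("torque_%g", tq)))
  }
  # per-domain writhe table across torques
  tab <- do.call(rbind, lapply(names(bundles), function(nm) {
    s <- bundles[[nm]]$summary
    s$torque_pNnm <- bundles[[nm]]$config$torque_pNnm
    s
  }))
  write.table(tab, file.path(out_dir, "torque_sweep_writhe.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(config = config, bundles = bundles, writhe_table = tab,
                 dir = out_dir))
}

#' Summarize a scenario run
#'
#' One row per replica x domain: steady-state mean writhe with standard
#' error (steady window = last half of production), passage-event count and
#' (when domains exist) the pooled intra/inter contact ratio.
#'
#' @param bundle output of [run_scenario()], or a list of trajectories.
#' @return data frame with `replica`, `domain`, `Wr_mean`, `Wr_se`,
#'   `n_events`, `ratio`.
#' @export
summarize_run <- function(bundle) {
  trajs <- if (inherits(bundle, "fiber_trajectory")) list(bundle)
  else if (!is.null(bundle$trajectories)) bundle$trajectories
  else bundle
  scores <- if (!is.null(bundle$scores)) bundle$scores else NULL
  rows <- list()
  for (r in seq_along(trajs)) {
    tr <- trajs[[r]]
    wr_cols <- grep("^Wr_dom", names(tr$series), value = TRUE)
    if (length(wr_cols) == 0) wr_cols <- "Wr"
    for (d in seq_along(wr_cols)) {
      wr <- tr$series[[wr_cols[d]]]
      half <- wr[seq.int(floor(length(wr) / 2) + 1, length(wr))]
      # batch-means standard error (5 batches) to respect autocorrelation
      nb <- 5
      bm <- tapply(half, cut(seq_along(half), nb, labels = FALSE), mean)
      se <- sd(bm) / sqrt(nb)
      ev <- detect_passage_events(wr, steps = tr$series$step, domain = d)
      rows[[length(rows) + 1]] <- data.frame(
        replica = r, domain = d, Wr_mean = mean(half), Wr_se = se,
        n_events = nrow(ev),
        ratio = if (!is.null(scores) && d <= nrow(scores))
          scores$ratio[d] else NA_real_)
    }
  }
  do.call(rbind, rows)
}
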