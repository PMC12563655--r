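#' Plan a field/species sweep
#'
#' A sweep runs the simulate -> classify -> kinetics/transitions/transport/
#' density pipeline over a panel of species and field magnitudes, with
#' several independent seeds per condition.
#'
#' @param species Character vector of species names.
#' @param fields Field magnitudes in V/nm (default 0, 0.1, 0.2, 0.3, 0.4).
#' @param seeds Integer seeds per condition (default 3).
#' @param ... Further arguments passed to \code{\link{build_config}} for
#'   every run (e.g. \code{n_steps}, \code{lattice}).
#' @return Object of class \code{sweep_plan}.
#' @export
sweep_plan <- function(species, fields = c(0, 0.1, 0.2, 0.3, 0.4),
                       seeds = 1:3, ...) {
  stopifnot(length(species) >= 1, length(fields) >= 1, length(seeds) >= 1)
  for (s in species) build_species(s)  # fail fast on unknown species
  stopifnot(all(fields >= 0))
  structure(list(species = species, fields = fields,
                 seeds = as.integer(seeds), config_args = list(...)),
            class = "sweep_plan")
}

#' Run a sweep and aggregate its reports
#'
#' Executes every (species, field, seed) condition: Brownian-dynamics run,
#' compartment classification, residence-time fits, lag-1 transition matrix
#' and transport summary; density maps are normalized as one set per
#' species across its fields. A failed condition is recorded and the sweep
#' continues. Rerunning an identical plan reproduces the summaries exactly.
#'
#' @param plan A \code{sweep_plan}.
#' @param out_dir Optional output directory; per-run subdirectories
#'   \code{<species>_E<field>_s<seed>} receive the trajectory
#'   (extended-XYZ), labels CSV and JSON reports, and aggregate CSV tables
#'   are written at the top level.
#' @param lag Transition-matrix lag in saved frames.
#' @param min_events Minimum events per survival fit.
#' @param verbose Print progress.
#' @return Object of class \code{sweep_result}: list with data.frames
#'   \code{tau} (residence times per compartment/condition),
#'   \code{transport} (velocity, current, resistivity per condition),
#'   \code{transitions} (list of transition matrices keyed by run id),
#'   \code{density} (list of normalized map sets per species),
#'   \code{failures} (character vector of failed run ids).
#' @export
run_sweep <- function(plan, out_dir = NULL, lag = 1L, min_events = 20,
                      verbose = FALSE) {
  stopifnot(inherits(plan, "sweep_plan"))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tau_rows <- list(); tr_rows <- list()
  trans <- list(); dens <- list(); failures <- character()
  trajs_by_species <- list()

  for (sp in plan$species) {
    for (E in plan$fields) {
      for (sd in plan$seeds) {
        run_id <- sprintf("%s_E%g_s%d", sp, E, sd)
        res <- tryCatch({
          cfg <- do.call(build_config,
                         c(list(species = sp, field = E, seed = sd),
                           plan$config_args))
          traj <- run_bd(cfg, save_beads = FALSE)
          labels <- classify_trajectory(
            traj, compartment_spec(cfg$lattice))
          dt <- attr(labels, "dt")
          tau <- tryCatch(
            residence_times(labels, dt = dt, min_events = min_events),
            error = function(e) NULL)
          tm <- transition_matrix(labels, lag = lag)
          vbar <- axial_velocities(unwrap(traj))
          ts <- ionic_current(vbar, cfg$species, cfg$lattice$box, field = E)
          list(cfg = cfg, traj = traj, labels = labels, tau = tau,
               tm = tm, ts = ts)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures <- c(failures, run_id)
          warning(sprintf("run %s failed: %s", run_id, conditionMessage(res)),
                  call. = FALSE)
          next
        }
        if (verbose) message("done: ", run_id)
        hash <- res$traj$metadata$config_hash
        if (!is.null(res$tau))
          tau_rows[[run_id]] <- cbind(
            data.frame(species = sp, field = E, seed = sd,
                       config_hash = hash), res$tau)
        tr_rows[[run_id]] <- data.frame(
          species = sp, field = E, seed = sd, config_hash = hash,
          v_mean = res$ts$v_mean, v_se = res$ts$v_se,
          current = res$ts$current, conductivity = res$ts$conductivity,
          resistivity = res$ts$resistivity)
        trans[[run_id]] <- res$tm
        trajs_by_species[[sp]] <- c(trajs_by_species[[sp]],
                                    stats::setNames(list(res$traj), run_id))
        if (!is.null(out_dir)) {
          rd <- file.path(out_dir, run_id)
          dir.create(rd, showWarnings = FALSE)
          write_extxyz(res$traj, file.path(rd, "traj.extxyz"))
          utils::write.csv(res$labels, file.path(rd, "labels.csv"),
                           row.names = FALSE)
          jsonlite::write_json(
            list(lag = res$tm$lag, order = c("O", "I", "T"),
                 counts = res$tm$counts, P = res$tm$P),
            file.path(rd, "transitions.json"), auto_unbox = TRUE, digits = NA,
            na = "null")
        }
      }
    }
  }
  for (sp in names(trajs_by_species))
    dens[[sp]] <- density_maps(trajs_by_species[[sp]])

  tau_tab <- if (length(tau_rows)) do.call(rbind, tau_rows) else NULL
  tr_tab <- if (length(tr_rows)) do.call(rbind, tr_rows) else NULL
  if (!is.null(out_dir)) {
    if (!is.null(tau_tab))
      utils::write.csv(tau_tab, file.path(out_dir, "tau_vs_field.csv"),
                       row.names = FALSE)
    if (!is.null(tr_tab))
      utils::write.csv(tr_tab, file.path(out_dir, "transport_vs_field.csv"),
                       row.names = FALSE)
  }
  out <- structure(list(tau = tau_tab, transport = tr_tab,
                        transitions = trans, density = dens,
                        failures = failures, plan = plan),
                   class = "sweep_result")
  if (length(failures))
    attr(out, "exit_status") <- 1L
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  n_runs <- length(x$transitions)
  cat(sprintf("Sweep: %d completed runs, %d failures\n", n_runs,
              length(x$failures)))
  if (!is.null(x$transport)) {
    cat("Transport summary (mean over seeds):\n")
    agg <- stats::aggregate(cbind(v_mean, current) ~ species + field,
                            data = x$transport, FUN = mean)
    print(agg, row.names = FALSE)
  }
  invisible(x)
}
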