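#' Initialize anions on a collision-free grid in the void space
#'
#' Candidate positions are a regular grid over the box; points closer to any
#' NP (minimum image) than the NP radius plus one anion extent are discarded,
#' and \code{n_anions} of the survivors are chosen at random with random
#' orientations.
#'
#' @param config A \code{sim_config}.
#' @return A \code{sim_state}: list with \code{centers} (n x 3, wrapped),
#'   \code{quats} (n x 4 unit quaternions), \code{wrap_counts} (n x 3
#'   integers), \code{time}.
#' @keywords internal
init_state <- function(config) {
  n <- config$n_anions
  box <- config$lattice$box
  sp <- config$species
  extent <- max(sqrt(rowSums(sp$body^2))) + sp$bead_diameter / 2
  clearance <- config$lattice$np_radius + extent + 0.05
  np <- config$lattice$np_positions

  for (ngrid in c(max(4L, ceiling(n^(1 / 3)) + 2L), 8L, 12L, 16L)) {
    gx <- (seq_len(ngrid) - 0.5) / ngrid
    pts <- as.matrix(expand.grid(gx * box[1], gx * box[2], gx * box[3]))
    if (nrow(np) > 0) {
      keep <- rep(TRUE, nrow(pts))
      for (k in seq_len(nrow(np))) {
        d <- sweep(pts, 2, np[k, ], "-")
        d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
        keep <- keep & sqrt(rowSums(d^2)) > clearance
      }
      pts <- pts[keep, , drop = FALSE]
    }
    if (nrow(pts) >= n) {
      centers <- pts[sample.int(nrow(pts), n), , drop = FALSE]
      quats <- random_quaternions(n)
      return(structure(list(centers = unname(centers), quats = quats,
                            wrap_counts = matrix(0L, n, 3), time = 0),
                       class = "sim_state"))
    }
  }
  stop(sprintf("packing error: could not place %d anions in the void space", n))
}

random_quaternions <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

force_pars <- function(config) {
  site_factor <- ifelse(config$lattice$site_type == "corner",
                        config$corner_ads_factor, config$face_ads_factor)
  list(kBT = config$temperature_energy,
       gamma_bead = config$friction,
       sigma = config$species$bead_diameter,
       wca_epsilon = config$wca_epsilon,
       bjerrum = config$bjerrum_scale,
       debye = config$debye_length,
       ads_depth = as.numeric(config$adsorption_depth * site_factor),
       ads_range = config$adsorption_range,
       np_radius = config$lattice$np_radius,
       efield = config$field_energy_scale * config$field$magnitude *
         config$field$axis)
}

#' Forces, torques and potential energy of a configuration
#'
#' Per-anion center forces and torques from the field term (q_b E per bead),
#' screened-Coulomb (Yukawa) interactions with every NP and with beads of
#' other anions, WCA repulsion, and the interfacial adsorption well. Pair
#' distances use the minimum-image convention; cutoffs are 4 Debye lengths
#' (Yukawa) and 2^(1/6) sigma (WCA).
#'
#' @param state A \code{sim_state} (or list with \code{centers}, \code{quats}).
#' @param config A \code{sim_config}.
#' @return List with \code{force} (n x 3), \code{torque} (n x 3),
#'   \code{energy} (total potential, kBT), \code{bead_positions}.
#' @export
compute_forces <- function(state, config) {
  bd_forces_cpp(state$centers, state$quats, config$species$body,
                config$species$bead_charges,
                config$lattice$np_positions,
                config$lattice$np_charge_per_site,
                config$lattice$box, force_pars(config))
}

#' Advance the Brownian dynamics by a number of steps
#'
#' Euler-Maruyama update of anion centers and orientations: the center moves
#' by mobility x force x dt plus Gaussian noise of variance 2 D_t dt per
#' axis; the orientation rotates by torque/drag x dt plus rotational noise.
#' Positions are rewrapped into the box with periodic image counts updated.
#' Deterministic given the R RNG state.
#'
#' @param state A \code{sim_state}.
#' @param config A \code{sim_config}.
#' @param n_steps Number of steps to take (default 1).
#' @return The advanced \code{sim_state}.
#' @export
step_bd <- function(state, config, n_steps = 1L) {
  out <- bd_run_cpp(state$centers, state$quats, config$species$body,
                    config$species$bead_charges,
                    config$lattice$np_positions,
                    config$lattice$np_charge_per_site,
                    config$lattice$box, force_pars(config),
                    config$timestep, as.integer(n_steps),
                    as.integer(n_steps), FALSE)
  nf <- length(out$times)
  n <- nrow(state$centers)
  structure(list(
    centers = matrix(out$centers[, , nf], n, 3),
    quats = out$quats,
    wrap_counts = state$wrap_counts + matrix(out$wrap_counts[, , nf], n, 3),
    time = state$time + out$times[nf]
  ), class = "sim_state")
}

#' Run a Brownian-dynamics trajectory
#'
#' Initializes anions in the void space (unless \code{state} is supplied),
#' integrates \code{n_steps} steps and saves a frame every \code{save_every}
#' steps (plus the initial frame). The run is reproducible: the seed in the
#' configuration fully determines the trajectory.
#'
#' @param config A \code{sim_config} from \code{\link{build_config}} or
#'   \code{\link{read_config}}.
#' @param state Optional initial \code{sim_state}.
#' @param save_beads Keep per-frame bead positions in the trajectory
#'   (memory permitting); anion centers are always kept.
#' @return A \code{trajectory} object (see \code{\link{trajectory}}).
#' @examples
#' \donttest{
#' cfg <- build_config("P3", field = 0.2, n_steps = 2000, seed = 1)
#' traj <- run_bd(cfg)
#' traj
#' }
#' @export
run_bd <- function(config, state = NULL, save_beads = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(state)) state <- init_state(config)
  out <- bd_run_cpp(state$centers, state$quats, config$species$body,
                    config$species$bead_charges,
                    config$lattice$np_positions,
                    config$lattice$np_charge_per_site,
                    config$lattice$box, force_pars(config),
                    config$timestep, config$n_steps, config$save_every,
                    save_beads)
  if (any(!is.finite(out$centers)))
    stop("non-finite coordinates in saved frames")
  trajectory(
    centers = out$centers,
    wrap_counts = out$wrap_counts,
    frame_times = out$times,
    box = config$lattice$box,
    species_name = config$species$name,
    beads = out$beads,
    metadata = list(seed = config$seed,
                    field = config$field$magnitude,
                    field_axis = config$field$axis,
                    species = config$species$name,
                    n_anions = config$n_anions,
                    config_hash = config_hash(config))
  )
}
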