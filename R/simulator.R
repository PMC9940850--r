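## Desk-scale Langevin dynamics in a cubic periodic box.  Not a production
## MD engine: a minimal, reproducible integrator used to generate small
## condensation/dissolution trajectories that exercise the analysis stack
## end to end.

#' Integrator settings for the toy Langevin simulator
#'
#' The default time step (0.01 ps) is set by stability of the stiffest term,
#' the harmonic bond: omega = sqrt(k/m) with k = 1e3 kJ mol^-1 nm^-2 and a
#' ~110 Da bead gives a ~2 ps period, so 10 fs resolves it comfortably.
#'
#' @param n_steps Number of integration steps.
#' @param dt Time step, ps.
#' @param friction Langevin friction, 1/ps.
#' @param temperature Temperature, K.
#' @param seed Integer seed; a fixed seed gives a bitwise-reproducible
#'   trajectory.
#' @param save_every Save a frame every this many steps.
#' @param mass Uniform bead mass, Da; defaults to the mean residue mass of
#'   the simulated topologies (dynamics need not be chemically faithful at
#'   this scale).
#' @return List of class `integrator_config`.
#' @export
integrator_config <- function(n_steps, dt = 0.01, friction = 1.0,
                              temperature = 300, seed = 1, save_every = 100,
                              mass = NULL) {
  stopifnot(dt > 0, temperature > 0, friction > 0, n_steps >= 0,
            save_every >= 1)
  structure(list(n_steps = as.integer(n_steps), dt = dt, friction = friction,
                 temperature = temperature, seed = as.integer(seed),
                 save_every = as.integer(save_every), mass = mass),
            class = "integrator_config")
}

#' Initial bead configuration for a simulation
#'
#' `homogeneous` mode places random-walk coils (bond length `bond_r0`)
#' with starting points uniform in the box — a supersaturated homogeneous
#' dilute phase. `droplet` mode places the first `n_droplet` chain centers
#' of mass uniformly inside a central sphere whose volume gives the target
#' chain number density, and the remaining chains uniformly in the box
#' outside that sphere.
#'
#' @param n_chains Number of chains.
#' @param chain_length Beads per chain.
#' @param box_length Cubic box edge, nm.
#' @param mode `"homogeneous"` or `"droplet"`.
#' @param seed Integer seed (fixed seed, identical coordinates).
#' @param n_droplet Number of chains planted in the droplet (droplet mode;
#'   default all).
#' @param rho_droplet_nm3 Chain number density of the planted droplet,
#'   chains/nm^3 (droplet mode).
#' @param vapor_buffer Exclusion zone around the droplet sphere in which no
#'   vapor chain center is placed, nm (droplet mode); guarantees the
#'   planted droplet/vapor separation exceeds typical contact cutoffs.
#' @param bond_r0 Bond length of the random-walk coils, nm.
#' @return List of class `simulation_state`: `coords` (n_beads x 3, nm),
#'   `box_length`, `chain_id`, `time` (ps). In droplet mode the planted
#'   member chains are recorded in attribute `droplet_chains`.
#' @export
init_configuration <- function(n_chains, chain_length, box_length,
                               mode = c("homogeneous", "droplet"), seed = 1,
                               n_droplet = n_chains, rho_droplet_nm3 = 0.02,
                               vapor_buffer = 2.5, bond_r0 = 0.38) {
  mode <- match.arg(mode)
  stopifnot(n_chains >= 1, chain_length >= 1, box_length > 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  walk <- function() {
    ## random-walk coil with fixed bond length, centered on its COM
    if (chain_length == 1) return(matrix(0, 1, 3))
    u <- matrix(rnorm(3 * (chain_length - 1)), ncol = 3)
    u <- u / sqrt(rowSums(u^2)) * bond_r0
    xyz <- rbind(0, apply(u, 2, cumsum))
    sweep(xyz, 2, colMeans(xyz))
  }
  centers <- matrix(NA_real_, n_chains, 3)
  droplet_chains <- integer(0)
  if (mode == "homogeneous") {
    centers[] <- runif(3 * n_chains, 0, box_length)
  } else {
    stopifnot(n_droplet >= 1, n_droplet <= n_chains, rho_droplet_nm3 > 0)
    R <- (3 * n_droplet / (4 * pi * rho_droplet_nm3))^(1 / 3)
    if (2 * R >= box_length)
      stop("planted droplet does not fit in the box; lower n_droplet or raise density")
    mid <- box_length / 2
    for (i in seq_len(n_droplet)) {
      repeat {  # uniform in sphere by rejection
        p <- runif(3, -R, R)
        if (sum(p^2) <= R^2) break
      }
      centers[i, ] <- mid + p
    }
    if (n_droplet < n_chains) {
      if (2 * (R + vapor_buffer) >= box_length * sqrt(3))
        stop("no room for vapor chains outside the droplet buffer")
      for (i in (n_droplet + 1):n_chains) {
        repeat {
          p <- runif(3, 0, box_length)
          if (sum((p - mid)^2) > (R + vapor_buffer)^2) break
        }
        centers[i, ] <- p
      }
    }
    droplet_chains <- seq_len(n_droplet)
  }
  coords <- do.call(rbind, lapply(seq_len(n_chains), function(i)
    sweep(walk(), 2, centers[i, ], `+`)))
  structure(list(coords = coords, box_length = box_length,
                 chain_id = rep(seq_len(n_chains), each = chain_length),
                 chain_length = chain_length, time = 0),
            class = "simulation_state", droplet_chains = droplet_chains)
}

#' Run BAOAB Langevin dynamics
#'
#' Propagates the coarse-grained system with the BAOAB splitting at the
#' configured temperature. Coordinates are stored unwrapped (periodicity is
#' applied through the minimum-image convention in the force evaluation and
#' in the analysis code), which keeps diffusion observables trivial to
#' compute. Non-finite forces (bead overlap) abort with the offending step
#' index.
#'
#' @param state A [init_configuration()] state.
#' @param topologies List of [chain_topology()], one per chain.
#' @param config An [ff_config()].
#' @param integrator An [integrator_config()].
#' @return List of class `cg_trajectory`: `frames` (list of coordinate
#'   matrices, first frame = initial state), `times` (ps), `box_length`,
#'   `chain_id`, `e_pot` (kJ/mol per frame).
#' @export
run_langevin <- function(state, topologies, config, integrator) {
  stopifnot(inherits(state, "simulation_state"),
            inherits(integrator, "integrator_config"))
  .check_box(state$box_length, config)
  ft <- .flatten_topologies(topologies)
  stopifnot(nrow(state$coords) == length(ft$sigma))
  mass <- if (is.null(integrator$mass)) mean(ft$mass) else integrator$mass
  kT <- kT_kJmol(integrator$temperature)
  if (integrator$n_steps == 0) {
    return(structure(list(frames = list(state$coords), times = state$time,
                          box_length = state$box_length,
                          chain_id = ft$chain_id,
                          e_pot = as.numeric(total_energy(
                            state$coords, state$box_length, topologies, config))),
                     class = "cg_trajectory"))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(integrator$seed)
  r <- cpp_langevin(state$coords, state$box_length, ft$sigma, ft$sticker,
                    ft$charge, ft$bonds, config$bond_r0, config$bond_k,
                    config$eps_stst, config$debye_length,
                    config$dielectric_prefactor, config$lj_cutoff,
                    config$coulomb_cutoff, mass, integrator$dt,
                    integrator$friction, kT, integrator$n_steps,
                    integrator$save_every)
  if (r$bad_step >= 0)
    stop(sprintf("non-finite force at step %d (frame %d): bead overlap?",
                 r$bad_step, r$n_saved))
  frames <- r$frames[seq_len(r$n_saved)]
  times <- state$time +
    integrator$dt * integrator$save_every * (seq_len(r$n_saved) - 1)
  structure(list(frames = frames, times = times,
                 box_length = state$box_length, chain_id = ft$chain_id,
                 e_pot = r$e_pot[seq_len(r$n_saved)]),
            class = "cg_trajectory")
}

#' Relax steric overlaps by capped steepest descent
#'
#' Moves beads along the analytic forces with a per-step displacement cap
#' until the largest force component falls below `f_tol` or `max_steps` is
#' reached. Intended to remove accidental overlaps in randomly placed
#' initial configurations before Langevin dynamics; not a production
#' minimizer.
#'
#' @param state A [init_configuration()] state.
#' @param topologies List of [chain_topology()], one per chain.
#' @param config An [ff_config()].
#' @param max_steps Maximum descent steps (default 500).
#' @param max_disp Per-step displacement cap, nm (default 0.02).
#' @param f_tol Convergence threshold on the max force component,
#'   kJ mol^-1 nm^-1 (default 1e3).
#' @return The state with relaxed coordinates.
#' @export
minimize_energy <- function(state, topologies, config, max_steps = 500,
                            max_disp = 0.02, f_tol = 1e3) {
  x <- state$coords
  for (s in seq_len(max_steps)) {
    f <- cg_forces(x, state$box_length, topologies, config)
    f[is.nan(f)] <- 0
    f[is.infinite(f)] <- sign(f[is.infinite(f)]) * 1e10
    fmax <- max(abs(f))
    if (fmax < f_tol) break
    step <- f / fmax * max_disp
    x <- x + step
  }
  state$coords <- x
  state
}
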