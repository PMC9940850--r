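## Planted-ground-truth synthetic fixtures.  Every fixture carries its
## generating truth as attributes so downstream recovery tests can consume
## only the data and compare against the carried truth.  Identical
## arguments and seed give bit-identical fixtures.

#' Droplet-plus-vapor bead configuration with planted membership
#'
#' Places `n_in` random-walk chains with centers of mass uniformly inside a
#' central sphere sized so that the sphere's chain number density matches
#' the target condensed-phase mass density, and `n_out` chains in the
#' remaining volume. The planted split is returned as ground truth.
#'
#' @param n_in Chains planted in the droplet.
#' @param n_out Chains planted in the vapor.
#' @param rho_c_target_mgml Target droplet mass density, mg/mL.
#' @param box_length Cubic box edge, nm.
#' @param chain_length Beads per chain.
#' @param chain_mass Chain molar mass, Da (default 110 Da per bead).
#' @param seed Integer seed.
#' @param vapor_buffer Exclusion zone around the sphere for vapor chain
#'   centers, nm (see [init_configuration()]).
#' @param ensure_contact_cutoff When set (nm), the droplet is redrawn (with
#'   deterministically incremented sub-seeds) until its chains form a
#'   single contact-connected component at this cutoff — membership ground
#'   truth is only well defined for an internally connected droplet.
#' @param bond_r0 Coil bond length, nm.
#' @return A `simulation_state` whose attribute `truth` holds
#'   `droplet_chains`, `vapor_chains` and `rho_c_target_mgml`.
#' @export
make_droplet_configuration <- function(n_in, n_out, rho_c_target_mgml,
                                       box_length, chain_length,
                                       chain_mass = 110 * chain_length,
                                       seed = 1, vapor_buffer = 2.5,
                                       ensure_contact_cutoff = NULL,
                                       bond_r0 = 0.38) {
  rho_nm3 <- mgml_to_nm3(rho_c_target_mgml, chain_mass)
  draw <- function(s)
    init_configuration(n_in + n_out, chain_length, box_length,
                       mode = "droplet", seed = s, n_droplet = n_in,
                       rho_droplet_nm3 = rho_nm3,
                       vapor_buffer = vapor_buffer, bond_r0 = bond_r0)
  st <- draw(seed)
  if (!is.null(ensure_contact_cutoff)) {
    connected <- function(st) {
      beads <- st$chain_id <= n_in
      cc <- cpp_contact_counts(st$coords[beads, , drop = FALSE],
                               st$box_length,
                               as.integer(st$chain_id[beads]),
                               ensure_contact_cutoff)
      if (nrow(cc) == 0) return(n_in == 1)
      g <- igraph::graph_from_edgelist(cc[, 1:2, drop = FALSE],
                                       directed = FALSE)
      g <- igraph::add_vertices(g, max(0, n_in - igraph::vcount(g)))
      igraph::components(g)$no == 1
    }
    tries <- 0
    while (!connected(st)) {
      tries <- tries + 1
      if (tries > 100)
        stop("could not draw an internally connected droplet; raise the ",
             "target density or the connectivity cutoff")
      st <- draw(seed + 100003L * tries)
    }
  }
  attr(st, "truth") <- list(droplet_chains = seq_len(n_in),
                            vapor_chains = seq_len(n_out) + n_in,
                            rho_c_target_mgml = rho_c_target_mgml,
                            chain_mass = chain_mass)
  st
}

#' Synthetic steady-state observation table from known parameters
#'
#' The inverse of the global Kelvin fit: for each (L, N) condition the
#' steady-state droplet size is computed from the known thermodynamic
#' parameters via [predict_nss()], then perturbed by multiplicative
#' Gaussian noise truncated at 3 standard deviations (matching the small
#' relative block errors of steady-state size measurements). Conditions
#' without a stable root are flagged `none`. The default design mirrors a
#' nucleation study grid: box edges 40-70 nm crossed with total densities
#' 0.00039, 0.00055 and 0.00078 chains/nm^3.
#'
#' @param sigma0 True surface tension, mN/m.
#' @param rho_d_star0 True dilute-phase equilibrium density, mg/mL.
#' @param rho_c_mgml Condensed-phase density, mg/mL.
#' @param chain_mass Chain molar mass, Da.
#' @param design Data frame with columns `L_nm` and `N`; default grid as
#'   described.
#' @param noise_frac Relative noise on n_ss (default 0).
#' @param seed Integer seed.
#' @param temperature Temperature, K.
#' @return An observation table (see [read_observation_table()]) with the
#'   generating parameters in attribute `truth`.
#' @export
make_observation_table <- function(sigma0, rho_d_star0, rho_c_mgml,
                                   chain_mass, design = NULL,
                                   noise_frac = 0, seed = 1,
                                   temperature = 300) {
  params <- thermo_params(sigma0, rho_d_star0, rho_c_mgml, chain_mass,
                          temperature)
  if (is.null(design)) {
    ## the nucleation-study grid: box edges 40-70 nm at three target
    ## densities (approximately 0.00039, 0.00055, 0.00078 chains/nm^3)
    design <- data.frame(
      L_nm = rep(c(40, 50, 60, 70), each = 3),
      N = c(25, 35, 50, 49, 69, 98, 84, 118, 169, 133, 187, 268))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    L <- design$L_nm[i]; N <- design$N[i]
    nss <- predict_nss(params, canonical_system(N = N, L = L))
    ## conditions without a stable root show no phase separation
    flag <- if (attr(nss, "status") == "stable") "stable" else "none"
    nss <- as.numeric(nss)
    err <- NA_real_
    if (flag == "stable" && noise_frac > 0) {
      z <- rnorm(1)
      while (abs(z) > 3) z <- rnorm(1)  # truncate at 3 sd
      nss <- nss * (1 + noise_frac * z)
      err <- noise_frac * nss
    } else if (flag == "stable") err <- 0
    data.frame(system = sprintf("synthetic-%02d", i), L_nm = L, N = N,
               rho0_nm3 = N / L^3,
               rho0_mgml = nm3_to_mgml(N / L^3, chain_mass),
               nss = if (flag == "stable") nss else NA_real_,
               nss_err = err, flag = flag)
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(sigma0 = sigma0, rho_d_star0 = rho_d_star0,
                             rho_c_mgml = rho_c_mgml,
                             chain_mass = chain_mass, seed = seed,
                             noise_frac = noise_frac)
  out
}

#' Telegraph-process state trajectories with known exchange rates
#'
#' Independent two-state Markov chains switching condensed -> dilute with
#' per-frame probability 1 - exp(-k_cd dt) and back with
#' 1 - exp(-k_dc dt); initial states are drawn from the stationary
#' occupancy k_dc/(k_cd + k_dc).
#'
#' @param n_chains Number of independent chains.
#' @param n_frames Number of frames.
#' @param k_cd Condensed-to-dilute rate, 1/us.
#' @param k_dc Dilute-to-condensed rate, 1/us.
#' @param frame_interval_ns Frame spacing, ns.
#' @param seed Integer seed.
#' @return A [state_trajectory()] carrying the true rates in attribute
#'   `truth`.
#' @export
make_telegraph_states <- function(n_chains, n_frames, k_cd, k_dc,
                                  frame_interval_ns, seed = 1) {
  dt_us <- frame_interval_ns / 1000
  stopifnot(k_cd >= 0, k_dc >= 0, k_cd * dt_us < 1, k_dc * dt_us < 1)
  p_cd <- 1 - exp(-k_cd * dt_us)
  p_dc <- 1 - exp(-k_dc * dt_us)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  S <- matrix(0L, n_frames, n_chains)
  pi_c <- if (k_cd + k_dc > 0) k_dc / (k_cd + k_dc) else 1
  S[1, ] <- as.integer(runif(n_chains) < pi_c)
  for (t in 2:n_frames) {
    u <- runif(n_chains)
    prev <- S[t - 1, ]
    S[t, ] <- ifelse(prev == 1L, as.integer(u >= p_cd), as.integer(u < p_dc))
  }
  out <- state_trajectory(S, frame_interval_ns)
  attr(out, "truth") <- list(k_cd = k_cd, k_dc = k_dc, seed = seed)
  out
}
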