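# Shared fixtures: the two study proteins' parameter sets (central values
# from the packaged observation tables) and small utilities.

nddx4_params <- function() {
  thermo_params(sigma_mN_m = 0.101, rho_d_star_mgml = 4.87,
                rho_c_mgml = 359, chain_mass = 25427)
}

fuslc_params <- function() {
  thermo_params(sigma_mN_m = 0.37, rho_d_star_mgml = 1.03,
                rho_c_mgml = 527, chain_mass = 17182)
}

# wrap a single configuration (or list of them) as a trajectory object
as_traj <- function(frames, box_length, chain_id) {
  if (!is.list(frames)) frames <- list(frames)
  structure(list(frames = frames, times = seq_along(frames) - 1,
                 box_length = box_length, chain_id = chain_id,
                 e_pot = rep(NA_real_, length(frames))),
            class = "cg_trajectory")
}

# random small multi-chain configuration for force checks: random-walk
# coils clustered well inside the cutoffs (all interaction terms active),
# then briefly relaxed so no pair sits deep in the r^-12 core — finite
# differences lose precision when energies are astronomically large
random_ff_config <- function(seed, n_chains = 3, chain_length = 5,
                             box = 8) {
  set.seed(seed)
  seqs <- replicate(n_chains, paste(sample(c("G", "S", "R", "Q", "E", "K"),
                                           chain_length, replace = TRUE),
                                    collapse = ""))
  tops <- lapply(seqs, chain_topology)
  coords <- do.call(rbind, lapply(seq_len(n_chains), function(i) {
    origin <- runif(3, 3.2, 4.8)
    steps <- matrix(rnorm(chain_length * 3), ncol = 3)
    steps <- steps / sqrt(rowSums(steps^2)) * 0.38
    sweep(apply(steps, 2, cumsum), 2, origin, `+`)
  }))
  st <- structure(list(coords = coords, box_length = box,
                       chain_id = rep(seq_len(n_chains),
                                      each = chain_length)),
                  class = "simulation_state")
  st <- minimize_energy(st, tops, ff_config(eps_stst = 2.1),
                        max_steps = 300, f_tol = 200)
  list(coords = st$coords, box = box, tops = tops, chain_id = st$chain_id)
}
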