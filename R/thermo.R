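## Canonical (NVT) droplet thermodynamics: the finite-size nucleation free
## energy with reservoir depletion, its macroscopic CNT limit, stationary
## points, barriers, crossovers and the confinement stability diagram.

#' Macroscopic thermodynamic parameters of a condensing protein
#'
#' Bundles the planar surface tension, the equilibrium dilute-phase density,
#' the condensed-phase density, the temperature and the chain molar mass.
#' Densities are given in mg/mL and converted internally to chains/nm^3
#' through the chain mass; the surface tension is converted to kT/nm^2.
#'
#' @param sigma_mN_m Planar surface tension of the condensed phase, mN/m.
#' @param rho_d_star_mgml Equilibrium dilute-phase density, mg/mL.
#' @param rho_c_mgml Condensed-phase density, mg/mL.
#' @param chain_mass Chain molar mass, Da.
#' @param temperature Temperature, K.
#' @return An object of class `thermo_params`.
#' @examples
#' nd <- thermo_params(0.101, 4.87, 359, chain_mass = 25427)
#' nd$rho_c_nm3
#' @export
thermo_params <- function(sigma_mN_m, rho_d_star_mgml, rho_c_mgml,
                          chain_mass, temperature = 300) {
  stopifnot(rho_d_star_mgml > 0, rho_c_mgml > 0, chain_mass > 0,
            temperature > 0)
  if (rho_d_star_mgml >= rho_c_mgml)
    stop("dilute-phase equilibrium density must be below the condensed-phase density")
  p <- list(
    sigma_mN_m = sigma_mN_m,
    rho_d_star_mgml = rho_d_star_mgml,
    rho_c_mgml = rho_c_mgml,
    chain_mass = chain_mass,
    temperature = temperature,
    beta_sigma = sigma_to_kT_nm2(sigma_mN_m, temperature),
    rho_d_star_nm3 = mgml_to_nm3(rho_d_star_mgml, chain_mass),
    rho_c_nm3 = mgml_to_nm3(rho_c_mgml, chain_mass)
  )
  structure(p, class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("Condensation thermodynamic parameters\n")
  cat(sprintf("  surface tension : %.4g mN/m (%.4g kT/nm^2)\n",
              x$sigma_mN_m, x$beta_sigma))
  cat(sprintf("  rho_d* (dilute) : %.4g mg/mL (%.4g nm^-3)\n",
              x$rho_d_star_mgml, x$rho_d_star_nm3))
  cat(sprintf("  rho_c (dense)   : %.4g mg/mL (%.4g nm^-3)\n",
              x$rho_c_mgml, x$rho_c_nm3))
  cat(sprintf("  chain mass      : %.5g Da;  T = %g K\n",
              x$chain_mass, x$temperature))
  invisible(x)
}

#' A finite canonical simulation condition
#'
#' @param N Total number of chains in the box.
#' @param L Cubic box edge, nm (give either `L` or `V`).
#' @param V Box volume, nm^3.
#' @return An object of class `canonical_system` with fields `N`, `V`, `L`.
#' @export
canonical_system <- function(N, L = NULL, V = NULL) {
  if (is.null(V)) {
    stopifnot(!is.null(L), L > 0)
    V <- L^3
  } else if (is.null(L)) {
    L <- V^(1 / 3)
  }
  stopifnot(N >= 1, V > 0)
  structure(list(N = N, V = V, L = L), class = "canonical_system")
}

#' Surface area and radius of a spherical droplet of n chains
#'
#' A droplet of `n` chains at condensed-phase number density `rho_c_nm3`
#' occupies volume n/rho_c; assuming sphericity,
#' A(n) = (36 pi)^(1/3) (n/rho_c)^(2/3) and r(n) = (3n/(4 pi rho_c))^(1/3).
#'
#' @param n Number of chains in the droplet (real-valued allowed).
#' @param rho_c_nm3 Condensed-phase number density, chains/nm^3.
#' @return Area in nm^2 (`droplet_area`) or radius in nm (`droplet_radius`).
#' @export
droplet_area <- function(n, rho_c_nm3) {
  stopifnot(all(n >= 0), rho_c_nm3 > 0)
  (36 * pi)^(1 / 3) * (n / rho_c_nm3)^(2 / 3)
}

#' @rdname droplet_area
#' @export
droplet_radius <- function(n, rho_c_nm3) {
  (3 * n / (4 * pi * rho_c_nm3))^(1 / 3)
}

## dA/dn, nm^2 per chain
.droplet_area_deriv <- function(n, rho_c_nm3) {
  (2 / 3) * (36 * pi)^(1 / 3) * rho_c_nm3^(-2 / 3) * n^(-1 / 3)
}

#' Dilute-phase density depleted by a droplet of n chains
#'
#' In a closed box the chains condensed into the droplet are removed from the
#' surrounding dilute phase, which also loses the volume the droplet
#' occupies: rho_d^n = (N - n) / (V - n/rho_c).
#'
#' @param n Droplet size in chains.
#' @param system A [canonical_system()].
#' @param rho_c_nm3 Condensed-phase number density, chains/nm^3.
#' @return Dilute-phase number density, chains/nm^3.
#' @export
depleted_density <- function(n, system, rho_c_nm3) {
  stopifnot(inherits(system, "canonical_system"))
  if (any(n < 0) || any(n > system$N))
    stop("droplet size must satisfy 0 <= n <= N")
  vol_left <- system$V - n / rho_c_nm3
  if (any(vol_left <= 0))
    stop("droplet of this size does not fit in the box (V - n/rho_c <= 0)")
  (system$N - n) / vol_left
}

## beta*F(n) for the canonical finite-size droplet.  This is the unique
## profile with F(0) = 0 whose stationary points satisfy the
## Gibbs-Thomson/Kelvin relation exactly:
##   d(betaF)/dn = beta*sigma*A'(n) - ln(rho_d^n / rho_d*),
## integrated in closed form (log1p keeps N = 1e6+ numerically exact):
##   betaF(n) = bs*A(n) - n ln(rho0/rho*)
##              + (N - n) log1p(-n/N) + (n - V*rho_c) log1p(-n/(V*rho_c))
.beta_F_finite <- function(n, params, system) {
  N <- system$N; V <- system$V
  rc <- params$rho_c_nm3
  rho0 <- N / V
  bs <- params$beta_sigma
  Vrc <- V * rc
  bs * droplet_area(n, rc) - n * log(rho0 / params$rho_d_star_nm3) +
    (N - n) * log1p(-n / N) + (n - Vrc) * log1p(-n / Vrc)
}

.beta_F_macro <- function(n, params, rho0_nm3) {
  S <- rho0_nm3 / params$rho_d_star_nm3
  -n * log(S) + params$beta_sigma * droplet_area(n, params$rho_c_nm3)
}

## analytic d(betaF)/dn for either kind
.dbeta_F <- function(n, params, system = NULL, rho0_nm3 = NULL) {
  bs <- params$beta_sigma; rc <- params$rho_c_nm3
  surf <- bs * .droplet_area_deriv(n, rc)
  if (!is.null(system)) {
    surf - log(depleted_density(n, system, rc) / params$rho_d_star_nm3)
  } else {
    surf - log(rho0_nm3 / params$rho_d_star_nm3)
  }
}

## default profile grid: linear up to n = 1, log-spaced above
.profile_grid <- function(n_max, n_points = 400) {
  n_lin <- max(10, round(n_points * 0.05))
  c(seq(0, 1, length.out = n_lin + 1),
    exp(seq(log(1), log(n_max), length.out = n_points - n_lin))[-1])
}

#' Finite-size (canonical) nucleation free energy profile
#'
#' Evaluates the modified-liquid-droplet free energy beta*F(n) of forming an
#' n-chain condensed droplet in a closed box of N chains and volume V. The
#' reference state (n = 0) is the homogeneous dilute solution, so
#' beta*F(0) = 0. The profile accounts for depletion of the dilute phase as
#' the droplet grows; its local maximum is the critical nucleus and its
#' local minimum the self-limiting steady-state droplet.
#'
#' @param params A [thermo_params()].
#' @param system A [canonical_system()].
#' @param n_max Largest droplet size on the grid; defaults to just below the
#'   smaller of N and the depletion singularity V*rho_c.
#' @param n_points Number of grid points (default 400).
#' @return A data frame of class `free_energy_profile` with columns `n` and
#'   `beta_F`, carrying `kind`, `params` and `system` as attributes.
#' @export
finite_size_profile <- function(params, system, n_max = NULL, n_points = 400) {
  stopifnot(inherits(params, "thermo_params"),
            inherits(system, "canonical_system"))
  hard_max <- min(system$N, system$V * params$rho_c_nm3) * 0.9999
  if (is.null(n_max)) {
    n_max <- hard_max
  } else if (n_max > hard_max) {
    warning("n_max extends past the depletion singularity; truncating grid")
    n_max <- hard_max
  }
  n <- .profile_grid(n_max, n_points)
  out <- data.frame(n = n, beta_F = .beta_F_finite(n, params, system))
  structure(out, class = c("free_energy_profile", "data.frame"),
            kind = "finite_size", params = params, system = system)
}

#' Macroscopic (CNT) nucleation free energy profile
#'
#' The N >> n, V -> infinity limit of the finite-size profile at fixed total
#' density rho_d0: beta*F(n) = -n ln(S) + beta*sigma*A(n) with
#' supersaturation S = rho_d0 / rho_d*. For S <= 1 the profile increases
#' monotonically (no barrier); this is reported, not an error.
#'
#' @param params A [thermo_params()].
#' @param rho0_mgml Bulk (total) protein density, mg/mL.
#' @param n_max Largest droplet size on the grid. By default the grid covers
#'   ten times the CNT critical size (when S > 1), auto-extending (up to
#'   n = 1e6) until the maximum is bracketed.
#' @inheritParams finite_size_profile
#' @return A `free_energy_profile` with attribute `kind = "macroscopic"`.
#' @export
macroscopic_profile <- function(params, rho0_mgml, n_max = NULL,
                                n_points = 400) {
  stopifnot(inherits(params, "thermo_params"), rho0_mgml > 0)
  rho0 <- mgml_to_nm3(rho0_mgml, params$chain_mass)
  S <- rho0 / params$rho_d_star_nm3
  if (is.null(n_max)) {
    if (S > 1) {
      nc <- cnt_critical_size(params, rho0_mgml)
      n_max <- min(max(10 * nc, 100), 1e6)
    } else {
      n_max <- 1000
    }
  }
  n <- .profile_grid(n_max, n_points)
  out <- data.frame(n = n, beta_F = .beta_F_macro(n, params, rho0))
  structure(out, class = c("free_energy_profile", "data.frame"),
            kind = "macroscopic", params = params, rho0_nm3 = rho0,
            rho0_mgml = rho0_mgml, supersaturation = S)
}

#' Stationary points of a nucleation free energy profile
#'
#' Brackets sign changes of the derivative of beta*F(n) and refines them by
#' root finding (the analytic derivative of the profile's own parameters is
#' used, so the result does not depend on grid resolution). Profiles are
#' classified as `monotonic` (no stationary point), `flex` (a single
#' degenerate stationary point, the stability-diagram boundary case) or
#' `two_stationary` (critical nucleus plus steady-state droplet).
#'
#' @param profile A `free_energy_profile`.
#' @param flex_tol Tolerance on the derivative minimum used to declare a
#'   flex (default 1e-8).
#' @return A list of class `stationary_points` with `n_crit`, `n_ss`,
#'   `barrier` (beta*F at the critical size) and `profile_class`.
#' @export
stationary_points <- function(profile, flex_tol = 1e-8) {
  stopifnot(inherits(profile, "free_energy_profile"))
  params <- attr(profile, "params")
  kind <- attr(profile, "kind")
  n_lo <- 1e-8
  if (kind == "finite_size") {
    system <- attr(profile, "system")
    n_hi <- min(system$N, system$V * params$rho_c_nm3) * (1 - 1e-9)
    g <- function(n) .dbeta_F(n, params, system = system)
    bF <- function(n) .beta_F_finite(n, params, system)
  } else {
    system <- NULL
    n_hi <- max(profile$n)
    rho0 <- attr(profile, "rho0_nm3")
    g <- function(n) .dbeta_F(n, params, rho0_nm3 = rho0)
    bF <- function(n) .beta_F_macro(n, params, rho0)
  }
  res <- list(n_crit = NA_real_, n_ss = NA_real_, barrier = NA_real_,
              profile_class = "monotonic")
  if (kind == "macroscopic") {
    ## g is monotone decreasing: at most one root (the critical nucleus)
    if (g(n_hi) < 0) {
      r <- uniroot(g, c(n_lo, n_hi), tol = 1e-12)
      res$n_crit <- r$root
      res$barrier <- bF(r$root)
      res$profile_class <- "single_maximum"  # growth past n* is unbounded
    }
  } else {
    opt <- optimize(g, c(n_lo, n_hi), tol = 1e-10)
    gmin <- opt$objective
    if (gmin > flex_tol) {
      res$profile_class <- "monotonic"
    } else if (abs(gmin) <= flex_tol) {
      res$profile_class <- "flex"
      res$n_crit <- opt$minimum
      res$barrier <- bF(opt$minimum)
    } else {
      r1 <- uniroot(g, c(n_lo, opt$minimum), tol = 1e-12)
      r2 <- uniroot(g, c(opt$minimum, n_hi), tol = 1e-12)
      res$n_crit <- r1$root
      res$n_ss <- r2$root
      res$barrier <- bF(r1$root)
      res$profile_class <- "two_stationary"
    }
  }
  structure(res, class = "stationary_points")
}

#' @export
print.stationary_points <- function(x, ...) {
  cat(sprintf("Profile class: %s\n", x$profile_class))
  if (!is.na(x$n_crit))
    cat(sprintf("  critical nucleus n* = %.4g, barrier = %.4g kT\n",
                x$n_crit, x$barrier))
  if (!is.na(x$n_ss))
    cat(sprintf("  steady-state droplet n_ss = %.4g\n", x$n_ss))
  invisible(x)
}

#' Closed-form CNT barrier and critical nucleus size
#'
#' For the macroscopic profile beta*F(n) = -n ln S + beta*sigma*A(n), the
#' maximum is at n* = 32 pi (beta sigma)^3 / (3 rho_c^2 ln^3 S) and the
#' barrier is beta*dF* = 16 pi (beta sigma)^3 / (3 rho_c^2 ln^2 S).
#' Both diverge as the bulk density approaches rho_d* from above; densities
#' at or below rho_d* are reported as an infinite barrier.
#'
#' @inheritParams macroscopic_profile
#' @return Barrier in kT (`cnt_barrier`) or size in chains
#'   (`cnt_critical_size`); `Inf` when rho0 <= rho_d*.
#' @export
cnt_barrier <- function(params, rho0_mgml) {
  S <- rho0_mgml / params$rho_d_star_mgml
  out <- rep(Inf, length(S))
  ok <- S > 1
  out[ok] <- 16 * pi * params$beta_sigma^3 /
    (3 * params$rho_c_nm3^2 * log(S[ok])^2)
  out
}

#' @rdname cnt_barrier
#' @export
cnt_critical_size <- function(params, rho0_mgml) {
  S <- rho0_mgml / params$rho_d_star_mgml
  out <- rep(Inf, length(S))
  ok <- S > 1
  out[ok] <- 32 * pi * params$beta_sigma^3 /
    (3 * params$rho_c_nm3^2 * log(S[ok])^3)
  out
}

#' Nucleation barrier and critical size across bulk densities
#'
#' @inheritParams macroscopic_profile
#' @param rho0_grid_mgml Bulk densities, mg/mL.
#' @return Data frame with `rho0_mgml`, `supersaturation`, `barrier_kT`,
#'   `n_crit`.
#' @export
barrier_curve <- function(params, rho0_grid_mgml) {
  data.frame(
    rho0_mgml = rho0_grid_mgml,
    supersaturation = rho0_grid_mgml / params$rho_d_star_mgml,
    barrier_kT = cnt_barrier(params, rho0_grid_mgml),
    n_crit = cnt_critical_size(params, rho0_grid_mgml)
  )
}

#' Density at which two proteins' nucleation barriers (or critical sizes) cross
#'
#' Finds the bulk density where the CNT barrier (or critical nucleus size)
#' computed from parameter set A equals that of parameter set B, by
#' bracketing root finding on ln(rho). A protein with higher surface tension
#' but lower solubility can nucleate more easily than a low-tension,
#' high-solubility one at low enough density; the crossover marks where the
#' ordering flips.
#'
#' @param params_A,params_B [thermo_params()] for the two proteins.
#' @param quantity `"barrier"` or `"n_crit"`.
#' @param interval_mgml Search interval in mg/mL; defaults to from just
#'   above the larger rho_d* to 50x the larger rho_d*.
#' @return Crossover density in mg/mL, or `NA` (with a message) if the two
#'   curves do not cross in the interval.
#' @export
crossover_density <- function(params_A, params_B,
                              quantity = c("barrier", "n_crit"),
                              interval_mgml = NULL) {
  quantity <- match.arg(quantity)
  fn <- if (quantity == "barrier") cnt_barrier else cnt_critical_size
  rs_max <- max(params_A$rho_d_star_mgml, params_B$rho_d_star_mgml)
  if (is.null(interval_mgml))
    interval_mgml <- c(rs_max * 1.001, rs_max * 50)
  diff_fn <- function(lrho) {
    r <- exp(lrho)
    fn(params_A, r) - fn(params_B, r)
  }
  lint <- log(interval_mgml)
  f_lo <- diff_fn(lint[1]); f_hi <- diff_fn(lint[2])
  if (is.finite(f_lo) && is.finite(f_hi) &&
      abs(f_lo) < 1e-12 && abs(f_hi) < 1e-12) {
    message("degenerate: identical ", quantity,
            " curves; crossover everywhere")
    return(NA_real_)
  }
  if (!is.finite(f_lo)) {
    ## just above the binodal of one protein the other's barrier is finite:
    ## step in until both are finite
    for (frac in seq(0.01, 0.5, by = 0.01)) {
      lint[1] <- log(interval_mgml[1]) + frac * (lint[2] - log(interval_mgml[1]))
      f_lo <- diff_fn(lint[1])
      if (is.finite(f_lo)) break
    }
  }
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo * f_hi > 0) {
    message("no crossover of ", quantity, " in the scanned interval")
    return(NA_real_)
  }
  exp(uniroot(diff_fn, lint, tol = 1e-12)$root)
}

#' Finite-size stability diagram of droplet formation
#'
#' Classifies each (bulk density, box size) condition: `unstable` when the
#' total density is below the dilute-phase equilibrium density (phase
#' separation thermodynamically impossible), `inhibited` when the density is
#' nominally supersaturated but confinement makes the finite-size free
#' energy monotonically increasing (no droplet can be sustained), and
#' `stable` when the profile has a minimum at finite droplet size. The
#' boundary between `inhibited` and `stable` — where the profile has a
#' single degenerate stationary point (a flex) — is located by bisection on
#' the box size at each density.
#'
#' @inheritParams macroscopic_profile
#' @param rho0_grid_mgml Bulk densities, mg/mL.
#' @param L_grid_nm Box edges, nm.
#' @return List with `grid` (data frame `rho0_mgml`, `L_nm`, `region`) and
#'   `boundary` (data frame `rho0_mgml`, `boundary_L_nm`, `NA` where no
#'   boundary exists in the scanned L range).
#' @export
stability_diagram <- function(params, rho0_grid_mgml, L_grid_nm) {
  stopifnot(inherits(params, "thermo_params"))
  min_g <- function(rho0_nm3, L) {
    V <- L^3
    N <- rho0_nm3 * V
    sys <- canonical_system(N = N, V = V)
    n_hi <- min(N, V * params$rho_c_nm3) * (1 - 1e-9)
    optimize(function(n) .dbeta_F(n, params, system = sys),
             c(1e-8, n_hi), tol = 1e-10)$objective
  }
  grid <- expand.grid(rho0_mgml = rho0_grid_mgml, L_nm = L_grid_nm,
                      KEEP.OUT.ATTRS = FALSE)
  grid$region <- vapply(seq_len(nrow(grid)), function(i) {
    rho0 <- grid$rho0_mgml[i]
    if (rho0 <= params$rho_d_star_mgml) return("unstable")
    r3 <- mgml_to_nm3(rho0, params$chain_mass)
    if (min_g(r3, grid$L_nm[i]) > 0) "inhibited" else "stable"
  }, character(1))
  L_lo <- min(L_grid_nm); L_hi <- max(L_grid_nm)
  boundary <- vapply(rho0_grid_mgml, function(rho0) {
    if (rho0 <= params$rho_d_star_mgml) return(NA_real_)
    r3 <- mgml_to_nm3(rho0, params$chain_mass)
    f <- function(L) min_g(r3, L)
    if (f(L_lo) < 0 || f(L_hi) > 0) return(NA_real_)  # boundary outside range
    uniroot(f, c(L_lo, L_hi), tol = 1e-6)$root
  }, numeric(1))
  list(grid = grid,
       boundary = data.frame(rho0_mgml = rho0_grid_mgml,
                             boundary_L_nm = boundary))
}
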