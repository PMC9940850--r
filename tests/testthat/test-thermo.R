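test_that("droplet area follows the spherical scaling law", {
  rc <- 0.008512
  expect_equal(droplet_area(0, rc), 0)
  n <- c(1, 10, 117)
  expect_equal(droplet_area(8 * n, rc), 4 * droplet_area(n, rc))
  # two-route cross-check: A(n) equals 4 pi r(n)^2
  expect_equal(droplet_area(100, rc), 4 * pi * droplet_radius(100, rc)^2)
  expect_equal(droplet_area(100, rc), 2.50e3, tolerance = 0.002)
  expect_equal(droplet_radius(100, rc), 14.1, tolerance = 0.005)
})

test_that("depleted dilute-phase density accounts for chains and volume removed", {
  sys <- canonical_system(N = 187, V = 343000)
  rc <- 0.008512
  expect_equal(depleted_density(0, sys, rc), 187 / 343000)
  expect_equal(depleted_density(187, sys, rc), 0)
  expect_equal(depleted_density(130, sys, rc),
               (187 - 130) / (343000 - 130 / 0.008512))
  expect_equal(depleted_density(130, sys, rc), 1.74e-4, tolerance = 0.005)
  expect_error(depleted_density(200, sys, rc), "0 <= n <= N")
})

test_that("finite-size profile is anchored at zero and matches its analytic derivative", {
  params <- nddx4_params()
  sys <- canonical_system(N = 187, L = 70)
  prof <- finite_size_profile(params, sys)
  expect_equal(prof$beta_F[prof$n == 0], 0)
  # the closed-form profile must integrate the Kelvin-consistent derivative:
  # compare centered finite differences with bs*A'(n) - ln(rho_d^n/rho_d*)
  bF <- function(n) mldroplet:::.beta_F_finite(n, params, sys)
  for (n in c(2, 17, 60, 130)) {
    h <- 1e-4
    fd <- (bF(n + h) - bF(n - h)) / (2 * h)
    an <- mldroplet:::.dbeta_F(n, params, system = sys)
    expect_equal(fd, an, tolerance = 1e-6)
  }
})

test_that("confinement reshapes the profile as the box grows at fixed chain count", {
  # small box: both critical nucleus and steady-state droplet; large box:
  # the minimum disappears or becomes much shallower
  params <- thermo_params(0.182, 1.0, 359, chain_mass = 25427)
  sp68 <- stationary_points(finite_size_profile(params,
                                                canonical_system(187, L = 68)))
  expect_equal(sp68$profile_class, "two_stationary")
  expect_lt(sp68$n_crit, sp68$n_ss)
  expect_gt(sp68$barrier, mldroplet:::.beta_F_finite(sp68$n_ss, params,
                                                     canonical_system(187, L = 68)))
  sp105 <- stationary_points(finite_size_profile(params,
                                                 canonical_system(187, L = 105)))
  if (sp105$profile_class == "two_stationary") {
    # minimum must be shallower (less negative depth) than at L = 68
    d68 <- mldroplet:::.beta_F_finite(sp68$n_ss, params,
                                      canonical_system(187, L = 68))
    d105 <- mldroplet:::.beta_F_finite(sp105$n_ss, params,
                                       canonical_system(187, L = 105))
    expect_gt(d105, d68)
  } else {
    expect_equal(sp105$profile_class, "monotonic")
  }
})

test_that("Kelvin stationarity: the profile minimum obeys the Gibbs-Thomson relation", {
  # the central internal-consistency oracle, over random valid systems
  set.seed(4001)
  n_checked <- 0
  draws <- 0
  while (n_checked < 120 && (draws <- draws + 1) < 3000) {
    params <- thermo_params(runif(1, 0.05, 0.5), runif(1, 0.5, 8),
                            runif(1, 300, 600), runif(1, 1.5e4, 3e4))
    L <- runif(1, 40, 90)
    rho0 <- runif(1, 2, 8) * params$rho_d_star_nm3
    N <- round(rho0 * L^3)
    if (N < 10) next
    sys <- canonical_system(N = N, L = L)
    sp <- stationary_points(finite_size_profile(params, sys))
    if (sp$profile_class != "two_stationary") next
    lhs <- depleted_density(sp$n_ss, sys, params$rho_c_nm3)
    rhs <- kelvin_density(sp$n_ss, params)
    expect_equal(lhs / rhs, 1, tolerance = 1e-4)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 100)
})

test_that("the canonical profile converges to the CNT limit as 1/N", {
  params <- nddx4_params()
  rho0_nm3 <- 0.00055
  rho0_mgml <- nm3_to_mgml(rho0_nm3, params$chain_mass)
  n <- 1:50
  dev <- vapply(c(1e6, 1e7), function(N) {
    sys <- canonical_system(N = N, V = N / rho0_nm3)
    max(abs(mldroplet:::.beta_F_finite(n, params, sys) -
              mldroplet:::.beta_F_macro(n, params, rho0_nm3)))
  }, 0)
  # the exact leading deviation is (1 - rho0/rho_c) n^2 / (2N)
  bound <- (1 - rho0_nm3 / params$rho_c_nm3) * max(n)^2 / 2
  expect_lt(dev[1], 1.05 * bound / 1e6)
  expect_gt(dev[1], 0.5 * bound / 1e6)
  expect_lt(dev[2], 1.05 * bound / 1e7)
  # and the ratio confirms first-order 1/N convergence
  expect_equal(dev[1] / dev[2], 10, tolerance = 0.05)
})

test_that("numeric CNT barrier and critical size match the closed forms", {
  for (seed in 1:5) {
    set.seed(seed)
    params <- thermo_params(runif(1, 0.05, 0.5), runif(1, 0.5, 8),
                            runif(1, 300, 600), runif(1, 1.5e4, 3e4))
    rho0 <- params$rho_d_star_mgml * runif(1, 1.5, 10)
    sp <- stationary_points(macroscopic_profile(params, rho0))
    expect_equal(sp$n_crit, cnt_critical_size(params, rho0),
                 tolerance = 1e-6)
    expect_equal(sp$barrier, cnt_barrier(params, rho0), tolerance = 1e-6)
  }
  # NDDX4-like barrier at 10 mg/mL: 16 pi (bs)^3/(3 rc^2 ln^2 S) ~ 6.5 kT
  expect_equal(cnt_barrier(nddx4_params(), 10), 6.5, tolerance = 0.01)
})

test_that("macroscopic profiles behave across supersaturation regimes", {
  params <- nddx4_params()
  # at the binodal the profile is the pure surface term
  prof <- macroscopic_profile(params, params$rho_d_star_mgml, n_max = 100)
  expect_equal(prof$beta_F,
               params$beta_sigma * droplet_area(prof$n, params$rho_c_nm3))
  # below the binodal: monotonic, no barrier, reported not an error
  sp <- stationary_points(macroscopic_profile(params, 2, n_max = 100))
  expect_equal(sp$profile_class, "monotonic")
  expect_true(is.na(sp$n_crit))
  # zero surface tension and S > 1: strictly decreasing
  p0 <- thermo_params(1e-12, 4.87, 359, chain_mass = 25427)
  pr0 <- macroscopic_profile(p0, 10, n_max = 100)
  expect_true(all(diff(pr0$beta_F) < 0))
})

test_that("barrier curves decrease with density and diverge at the binodal", {
  params <- fuslc_params()
  grid <- seq(2, 20, by = 1)
  bc <- barrier_curve(params, grid)
  expect_true(all(diff(bc$barrier_kT) < 0))
  # divergence approaching rho_d* from above
  expect_gt(cnt_barrier(params, params$rho_d_star_mgml * 1.001), 1e5)
  expect_true(is.infinite(cnt_barrier(params, params$rho_d_star_mgml)))
  # closed-form invariant: n*^3 ln^3 S is constant along the curve
  inv <- bc$n_crit * log(bc$supersaturation)^3
  expect_equal(max(inv) / min(inv), 1, tolerance = 1e-9)
})

test_that("barrier and critical-size crossovers between the two proteins", {
  nd <- nddx4_params(); fu <- fuslc_params()
  rb <- crossover_density(nd, fu, "barrier")
  rn <- crossover_density(nd, fu, "n_crit")
  expect_equal(rb, 10, tolerance = 0.15)
  expect_equal(rn, 16, tolerance = 0.25)
  # the ordering flips across the barrier crossover
  expect_gt(cnt_barrier(fu, rb * 1.5), cnt_barrier(nd, rb * 1.5))
  expect_lt(cnt_barrier(fu, rb * 0.9), cnt_barrier(nd, rb * 0.9))
  # degenerate case: identical parameter sets never cross
  expect_message(res <- crossover_density(nd, nd, "barrier"),
                 "degenerate")
  expect_true(is.na(res))
})

test_that("stability diagram partitions density/size space with a flex boundary", {
  params <- nddx4_params()
  d <- stability_diagram(params, rho0_grid_mgml = c(2, 16.5, 23.2),
                        L_grid_nm = c(30, 40, 60, 90))
  g <- d$grid
  # below rho_d*: unstable everywhere
  expect_true(all(g$region[g$rho0_mgml == 2] == "unstable"))
  # the smallest simulated condition at 16.5 mg/mL is confinement-inhibited
  expect_equal(g$region[g$rho0_mgml == 16.5 & g$L_nm == 40], "inhibited")
  # at fixed supersaturated density, growing the box flips inhibited ->
  # stable exactly once (monotone finite-size effect)
  for (rho in c(16.5, 23.2)) {
    regs <- g$region[g$rho0_mgml == rho][order(c(30, 40, 60, 90))]
    expect_true(all(diff(regs == "stable") >= 0))
  }
  # boundary: at the flex box size the derivative minimum is ~zero, and the
  # flanks classify as expected
  bL <- d$boundary$boundary_L_nm[d$boundary$rho0_mgml == 16.5]
  expect_true(is.finite(bL))
  r3 <- mgml_to_nm3(16.5, params$chain_mass)
  cls <- function(L) {
    sys <- canonical_system(N = r3 * L^3, V = L^3)
    stationary_points(finite_size_profile(params, sys))$profile_class
  }
  expect_equal(cls(bL * 0.97), "monotonic")
  expect_equal(cls(bL * 1.03), "two_stationary")
})
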