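test_that("dispersed chains yield no clusters; planted droplets are recovered exactly", {
  # all chains mutually farther than the contact cutoff
  coords <- as.matrix(expand.grid(x = c(5, 15, 25), y = c(5, 15, 25), z = 5))
  a <- detect_clusters(coords, 30, seq_len(nrow(coords)))
  expect_equal(a$largest_size, 0L)
  expect_true(all(a$labels == 0))
  # planted droplet fixtures: membership recovered exactly across seeds
  for (seed in c(1, 2, 3)) {
    st <- make_droplet_configuration(n_in = 60, n_out = 10,
                                     rho_c_target_mgml = 700,
                                     box_length = 30, chain_length = 10,
                                     seed = seed,
                                     ensure_contact_cutoff = 1.0)
    truth <- attr(st, "truth")
    a <- detect_clusters(st$coords, st$box_length, st$chain_id)
    expect_equal(a$largest_size, 60L)
    expect_setequal(which(a$labels == 1), truth$droplet_chains)
  }
})

test_that("single linkage merges droplets closer than the contact cutoff", {
  # two dense bead blobs with nearest beads inside the cutoff: one cluster
  blob <- function(center, chain0) {
    g <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2)) * 0.5
    list(coords = sweep(g, 2, center, `+`),
         chain = rep(chain0 + 0:8, each = 3))
  }
  b1 <- blob(c(10, 10, 10), 1)
  b2 <- blob(c(11.8, 10, 10), 10)   # 0.8 nm gap between nearest beads
  coords <- rbind(b1$coords, b2$coords)
  chain <- c(b1$chain, b2$chain)
  a <- detect_clusters(coords, 30, chain,
                       cluster_criteria(com_cutoff = 100))
  expect_equal(a$largest_size, 18L)
  # same blobs far apart: two separate clusters of 9
  b3 <- blob(c(20, 20, 20), 10)
  a2 <- detect_clusters(rbind(b1$coords, b3$coords), 30,
                        c(b1$chain, b3$chain),
                        cluster_criteria(com_cutoff = 100))
  expect_equal(a2$largest_size, 9L)
  expect_equal(sort(unique(a2$labels)), c(1L, 2L))
})

test_that("cluster labels are invariant under chain relabeling and rigid translation", {
  st <- make_droplet_configuration(40, 15, 700, 30, 10, seed = 8,
                                   ensure_contact_cutoff = 1.0)
  a0 <- detect_clusters(st$coords, st$box_length, st$chain_id)
  # rigid translation across the periodic boundary
  a1 <- detect_clusters(st$coords + 13.7, st$box_length, st$chain_id)
  expect_equal(a1$labels, a0$labels)
  expect_equal(a1$largest_size, a0$largest_size)
  # reverse the chain numbering
  n_chains <- max(st$chain_id)
  perm <- rev(seq_len(n_chains))
  a2 <- detect_clusters(st$coords, st$box_length, perm[st$chain_id])
  expect_equal(a2$labels[perm], a0$labels)
})

test_that("periodic-aware COM handles boundary-straddling clusters", {
  set.seed(77)
  pts <- matrix(rnorm(300, sd = 0.8), ncol = 3) %% 30  # blob at the origin corner
  com <- periodic_com(pts, 30)
  d <- com - 30 * round(com / 30)
  expect_lt(sqrt(sum(d^2)), 0.3)  # near the corner, not at the box center
})

test_that("steady-state size averages, blocks and flags behave as specified", {
  # constant series
  o <- steady_state_size(rep(42, 100))
  expect_equal(o$n_ss, 42); expect_equal(o$n_err, 0)
  expect_equal(o$outcome_flag, "stable")
  # alternating sizes average to the midpoint
  expect_equal(steady_state_size(rep(c(40, 44), 50))$n_ss, 42)
  # telegraph series with known mean: recovered within 2 block errors
  set.seed(31)
  s <- 40 + 10 * (runif(4000) < 0.3)  # mean 43
  for (i in 2:4000) if (runif(1) > 0.2) s[i] <- s[i - 1]  # correlate
  o2 <- steady_state_size(s, equilibration_fraction = 0)
  expect_lt(abs(o2$n_ss - 43), 2 * max(o2$n_err, 0.2))
  # stationary series: estimate independent of block count within error
  o5 <- steady_state_size(s, equilibration_fraction = 0, n_blocks = 5)
  o10 <- steady_state_size(s, equilibration_fraction = 0, n_blocks = 10)
  expect_lt(abs(o5$n_ss - o10$n_ss), 1e-9)  # mean unaffected by blocking
  expect_lt(abs(o5$n_err / o10$n_err - 1), 1.5)
  # no droplet: sizes below the threshold nearly always
  expect_equal(steady_state_size(c(rep(2, 95), rep(6, 5)))$outcome_flag,
               "none")
  # wildly fluctuating series
  set.seed(32)
  expect_equal(steady_state_size(c(rep(80, 30), rep(5, 40), rep(80, 30)),
                                 equilibration_fraction = 0)$outcome_flag,
               "fluctuating")
  expect_error(steady_state_size(rep(10, 6), equilibration_fraction = 0.5),
               "too few")
})

test_that("radial profiles are flat in a planted core, empty outside, bin-width stable", {
  frames <- lapply(1:20, function(s)
    make_droplet_configuration(200, 0, 359, 40, 10, seed = 900 + s)$coords)
  traj <- as_traj(frames, 40, rep(1:200, each = 10))
  prof <- radial_density_profile(traj, bead_mass = 110, bin_width = 1)
  R <- (3 * 200 / (4 * pi * mgml_to_nm3(359, 1100)))^(1 / 3)
  core <- prof$r_nm <= 0.6 * R
  expect_equal(mean(prof$rho_mgml[core]), 359, tolerance = 0.08)
  expect_true(all(prof$rho_mgml[prof$r_nm > R + 2] < 10))
  # doubling the bin width preserves the core plateau mean
  prof2 <- radial_density_profile(traj, bead_mass = 110, bin_width = 2)
  expect_equal(mean(prof2$rho_mgml[prof2$r_nm <= 0.6 * R]),
               mean(prof$rho_mgml[core]), tolerance = 0.10)
})

test_that("condensed-phase density estimates hit the planted values", {
  for (rho in c(359, 527)) {
    frames <- lapply(1:60, function(s)
      make_droplet_configuration(400, 20, rho, 40, 5,
                                 seed = 7 * rho + s)$coords)
    traj <- as_traj(frames, 40, rep(1:420, each = 5))
    prof <- radial_density_profile(traj, bead_mass = 110, bin_width = 1)
    est <- estimate_rho_c(prof)
    expect_equal(as.numeric(est), rho, tolerance = 0.07)
    expect_equal(attr(est, "flag"), "ok")
  }
  # zero-density fixture
  zero <- structure(data.frame(r_nm = 1:10, rho_mgml = 0, rho_nm3 = 0),
                    class = c("radial_profile", "data.frame"))
  expect_equal(as.numeric(estimate_rho_c(zero)), 0)
})

test_that("asphericity separates spheres, rods and prolate ellipsoids", {
  all_one <- function(n) structure(list(labels = rep(1L, n),
                                        largest_size = n),
                                   class = "cluster_assignment")
  set.seed(12)
  # spherical shell: near zero
  u <- matrix(rnorm(15000), ncol = 3)
  shell <- 15 + 3 * u / sqrt(rowSums(u^2))
  expect_lt(asphericity(shell, 40, seq_len(nrow(shell)),
                        all_one(nrow(shell))), 0.02)
  # collinear beads: maximal (1)
  line <- cbind(seq(10, 20, length.out = 50), 15, 15)
  expect_equal(asphericity(line, 40, seq_len(50), all_one(50)), 1)
  # uniform prolate ellipsoid 2:1:1: gyration eigenvalues (4,1,1)a^2/5
  # so normalized asphericity = (4 - 1)/6 = 0.5
  pts <- matrix(runif(60000, -1, 1), ncol = 3)
  pts <- pts[rowSums(pts^2) <= 1, ]
  ell <- sweep(pts, 2, c(4, 2, 2), `*`) / 2 + 15  # semi-axes (2,1,1)
  expect_equal(asphericity(ell, 40, seq_len(nrow(ell)),
                           all_one(nrow(ell))), 0.5, tolerance = 0.05)
  expect_error(asphericity(matrix(c(1, 1, 1), 1), 40, 1, all_one(1)),
               "fewer than 2")
})
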