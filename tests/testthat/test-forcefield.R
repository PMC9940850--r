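test_that("sticker classification matches the aromatic/planar residue set", {
  expect_true(all(classify_stickers("RFYWQ") == "sticker"))
  expect_true(all(classify_stickers("GSGS") == "spacer"))
  expect_equal(classify_stickers("RGQA"),
               c("sticker", "spacer", "sticker", "spacer"))
  expect_error(classify_stickers("RGXA"), "position 3")
})

test_that("harmonic bond energy is half k dr^2 about 0.38 nm", {
  expect_equal(bond_energy(0.38), 0)
  expect_equal(bond_energy(0.48), 5.0)   # 0.5 * 1000 * 0.1^2
  expect_equal(bond_energy(0.28), bond_energy(0.48))  # symmetric
})

test_that("Debye-Hueckel term has the right screening, signs and domain", {
  cfg <- ff_config()
  expect_equal(debye_huckel_energy(1.3, 0, 1, cfg), 0)
  # closed-form ratio: U(2 lambda)/U(lambda) = (1/2) exp(-1)
  r1 <- cfg$debye_length; r2 <- 2 * cfg$debye_length
  expect_equal(debye_huckel_energy(r2, 1, 1, cfg) /
                 debye_huckel_energy(r1, 1, 1, cfg), 0.5 * exp(-1))
  expect_lt(debye_huckel_energy(0.8, 1, -1, cfg), 0)
  expect_equal(debye_huckel_energy(5, 1, 1, cfg), 0)  # beyond cutoff
  expect_error(debye_huckel_energy(0, 1, 1, cfg), "r <= 0")
})

test_that("Lennard-Jones term has textbook zero crossing, minimum and class mixing", {
  pars <- read_residue_params()
  cfg <- ff_config(eps_stst = 1.7)
  pR <- c(as.list(pars["R", ]), epsilon_class = "sticker")
  pG <- c(as.list(pars["G", ]), epsilon_class = "spacer")
  sij <- (pR$sigma_nm + pG$sigma_nm) / 2
  expect_equal(lj_energy(sij, pR, pG, cfg), 0)
  rmin <- 2^(1 / 6) * sij
  expect_equal(lj_energy(rmin, pR, pG, cfg), -cfg$eps_stsp)
  # numeric minimum coincides with 2^(1/6) sigma
  opt <- optimize(function(r) lj_energy(r, pR, pG, cfg), c(0.5, 1.5),
                  tol = 1e-10)
  expect_equal(opt$minimum, rmin, tolerance = 1e-6)
  # class mixing ratios hold exactly for arbitrary eps_stst
  for (eps in c(0.3, 1, 4.7)) {
    cfg2 <- ff_config(eps_stst = eps)
    e_stst <- -lj_energy(2^(1/6) * pR$sigma_nm, pR, pR, cfg2)
    e_spsp <- -lj_energy(2^(1/6) * pG$sigma_nm, pG, pG, cfg2)
    e_stsp <- -lj_energy(2^(1/6) * sij, pR, pG, cfg2)
    expect_equal(e_stst / e_spsp, 3)
    expect_equal(e_stst / e_stsp, 1.5)
  }
})

test_that("total energy assembles bonded and nonbonded terms with 1-2 exclusion", {
  cfg <- ff_config(eps_stst = 1.0)
  # single isolated bead
  expect_equal(as.numeric(total_energy(matrix(c(4, 4, 4), 1), 8,
                                       list(chain_topology("G")), cfg)), 0)
  # a bonded spacer dimer at r0: bond term is zero and the 1-2 pair is
  # excluded from the nonbonded sums, so the total vanishes
  coords <- rbind(c(4, 4, 4), c(4.38, 4, 4))
  e <- total_energy(coords, 8, list(chain_topology("GG")), cfg)
  expect_equal(as.numeric(e), 0)
  # two NON-bonded spacers at the same distance feel LJ (+ DH if charged):
  # hand evaluation of the pair terms at 0.38 nm
  tops2 <- list(chain_topology("G"), chain_topology("G"))
  e2 <- total_energy(coords, 8, tops2, cfg)
  sij <- 0.450; sr6 <- (sij / 0.38)^6
  expect_equal(as.numeric(e2), 4 * (1.0 / 3) * (sr6^2 - sr6),
               tolerance = 1e-10)
  # charged pair picks up the screened Coulomb term too
  topsRK <- list(chain_topology("R"), chain_topology("E"))
  e3 <- total_energy(coords, 8, topsRK, cfg)
  expect_lt(attr(e3, "components")["dh"], 0)
  expect_equal(unname(attr(e3, "components")["dh"]),
               (138.935458 / 80) * (1) * (-1) * exp(-0.38) / 0.38,
               tolerance = 1e-10)
})

test_that("energy is invariant under lattice translation and chain permutation", {
  rc <- random_ff_config(101)
  cfg <- ff_config(eps_stst = 1.3)
  e0 <- as.numeric(total_energy(rc$coords, rc$box, rc$tops, cfg))
  # translation by an arbitrary vector plus a full lattice vector
  shift <- matrix(rep(c(1.1, -0.7, rc$box + 0.3), each = nrow(rc$coords)), ncol = 3)
  e1 <- as.numeric(total_energy(rc$coords + shift, rc$box, rc$tops, cfg))
  expect_equal(e1, e0, tolerance = 1e-10)
  # permuting two identical chains leaves the energy unchanged
  rc2 <- random_ff_config(102, n_chains = 3)
  rc2$tops[[2]] <- rc2$tops[[1]]  # make chains 1 and 2 identical
  ids <- rc2$chain_id
  coords_sw <- rc2$coords
  coords_sw[ids == 1, ] <- rc2$coords[ids == 2, ]
  coords_sw[ids == 2, ] <- rc2$coords[ids == 1, ]
  ea <- as.numeric(total_energy(rc2$coords, rc2$box, rc2$tops, cfg))
  eb <- as.numeric(total_energy(coords_sw, rc2$box, rc2$tops, cfg))
  expect_equal(eb, ea, tolerance = 1e-10)
})

test_that("analytic forces match centered finite differences", {
  cfg <- ff_config(eps_stst = 2.1)
  h <- 1e-5
  for (seed in 1:4) {
    rc <- random_ff_config(seed)
    f <- cg_forces(rc$coords, rc$box, rc$tops, cfg)
    for (k in sample(nrow(rc$coords), 4)) for (d in 1:3) {
      cp <- rc$coords; cp[k, d] <- cp[k, d] + h
      cm <- rc$coords; cm[k, d] <- cm[k, d] - h
      fd <- -(as.numeric(total_energy(cp, rc$box, rc$tops, cfg)) -
                as.numeric(total_energy(cm, rc$box, rc$tops, cfg))) / (2 * h)
      expect_equal(f[k, d], fd, tolerance = 1e-5)
    }
  }
})

test_that("box smaller than twice the largest cutoff is rejected", {
  expect_error(total_energy(matrix(c(1, 1, 1), 1), 5,
                            list(chain_topology("G")), ff_config()),
               "twice the largest cutoff")
})

test_that("configuration files and residue tables read back what was written", {
  cfg <- read_ff_config(system.file("extdata", "ff_default.toml",
                                    package = "mldroplet"))
  expect_s3_class(cfg, "ff_config")
  expect_equal(cfg$debye_length, 1.0)
  expect_equal(cfg$eps_stsp * 1.5, cfg$eps_stst)
  tmp <- withr::local_tempfile(fileext = ".toml")
  writeLines(c("eps_stst = 2.5  # stronger stickers", "debye_length = 0.8"),
             tmp)
  cfg2 <- read_ff_config(tmp)
  expect_equal(cfg2$eps_stst, 2.5)
  expect_equal(cfg2$eps_spsp, 2.5 / 3)
  bad <- withr::local_tempfile(fileext = ".toml")
  writeLines("not_a_key = 3", bad)
  expect_error(read_ff_config(bad), "unknown force-field keys")
  # overriding the residue table from file
  tab <- read_residue_params()
  tab$sigma_nm[tab$code1 == "G"] <- 0.5
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, tmp2, row.names = FALSE)
  topo <- chain_topology("G", residue_params = read_residue_params(tmp2))
  expect_equal(topo$sigma_nm, 0.5)
})

test_that("FASTA sequences build topologies with consistent masses and bonds", {
  seqs <- read_fasta_sequences(system.file("extdata",
                                           "example_sequences.fasta",
                                           package = "mldroplet"))
  expect_length(seqs, 2)
  topo <- chain_topology(seqs[[1]])
  expect_equal(nrow(topo$bond_list), nchar(seqs[[1]]) - 1)
  pars <- read_residue_params()
  expect_equal(topo$chain_mass,
               sum(pars[strsplit(seqs[[1]], "")[[1]], "mass_Da"]))
})
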