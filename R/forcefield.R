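## One-bead-per-residue coarse-grained force field in the
## stickers-and-spacers spirit: harmonic bonds between consecutive residues,
## Debye-Hueckel screened electrostatics between charged beads, and a 12-6
## Lennard-Jones contact potential whose pair well depth is set by sticker
## class (St-St : St-Sp : Sp-Sp = 1 : 1/1.5 : 1/3).

.STICKER_SET <- c("R", "F", "Y", "W", "Q")

.residue_env <- new.env(parent = emptyenv())

#' Per-residue bead parameters
#'
#' Reads the residue parameter table (one-letter code, three-letter code,
#' bead Lennard-Jones sigma in nm, net charge in elementary units, residue
#' mass in Da). The packaged defaults use bead sizes from a standard
#' one-bead-per-residue convention (amino-acid van der Waals diameters) and
#' are a documented stand-in: any table with the same columns can be
#' supplied to override them. Charge convention: Asp/Glu -1, Lys/Arg +1,
#' His 0.
#'
#' @param path Optional path to a delimited text table with columns
#'   `code1`, `code3`, `sigma_nm`, `charge`, `mass_Da`. Defaults to the
#'   packaged table.
#' @return Data frame of residue parameters keyed by one-letter code.
#' @export
read_residue_params <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.residue_env$default)) return(.residue_env$default)
    path <- system.file("extdata", "residue_params.csv", package = "mldroplet",
                        mustWork = TRUE)
  }
  tab <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("code1", "code3", "sigma_nm", "charge", "mass_Da")
  if (!all(need %in% names(tab)))
    stop("residue table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$sigma_nm <= 0)) stop("residue sigma must be positive")
  rownames(tab) <- tab$code1
  if (is.null(.residue_env$default) &&
      grepl("mldroplet", path, fixed = TRUE)) .residue_env$default <- tab
  tab
}

#' Classify residues as stickers or spacers
#'
#' Arg, Phe, Tyr, Trp and Gln — residues with large aromatic or planar side
#' chains implicated in driving phase separation — are stickers; all other
#' residues are spacers.
#'
#' @param sequence Amino-acid sequence: a single string or a character
#'   vector of one-letter codes.
#' @param sticker_set One-letter codes treated as stickers.
#' @return Character vector, one of `"sticker"`/`"spacer"` per residue.
#' @examples
#' classify_stickers("RGQA")
#' @export
classify_stickers <- function(sequence, sticker_set = .STICKER_SET) {
  aa <- .as_residue_vector(sequence)
  valid <- read_residue_params()$code1
  bad <- which(!(aa %in% valid))
  if (length(bad))
    stop(sprintf("unknown residue code '%s' at position %d",
                 aa[bad[1]], bad[1]))
  ifelse(aa %in% sticker_set, "sticker", "spacer")
}

.as_residue_vector <- function(sequence) {
  if (length(sequence) == 1 && nchar(sequence) > 1)
    sequence <- strsplit(sequence, "")[[1]]
  toupper(sequence)
}

#' Force-field configuration
#'
#' The absolute sticker-sticker well depth `eps_stst` is the model's single
#' free energy-scale parameter; the mixed and spacer-spacer depths are
#' derived exactly as `eps_stst/1.5` and `eps_stst/3`. The Debye screening
#' length defaults to 1 nm (about 100 mM ionic strength); the electrostatic
#' prefactor defaults to Coulomb's constant over a relative permittivity of
#' 80 (138.935/80 kJ mol^-1 nm e^-2). Cutoffs default to 2.0 nm (LJ) and
#' 3.5 nm (Debye-Hueckel).
#'
#' @param eps_stst Sticker-sticker LJ well depth, kJ/mol.
#' @param debye_length Electrostatic screening length, nm.
#' @param lj_cutoff,coulomb_cutoff Interaction cutoffs, nm.
#' @param dielectric_prefactor Energy*length per squared elementary charge,
#'   kJ mol^-1 nm.
#' @param bond_r0 Equilibrium bond length, nm (0.38 between consecutive
#'   residues).
#' @param bond_k Bond spring constant, kJ mol^-1 nm^-2 (1e3).
#' @return An object of class `ff_config`.
#' @export
ff_config <- function(eps_stst = 1.0, debye_length = 1.0, lj_cutoff = 2.0,
                      coulomb_cutoff = 3.5,
                      dielectric_prefactor = 138.935458 / 80,
                      bond_r0 = 0.38, bond_k = 1000) {
  stopifnot(eps_stst > 0, debye_length > 0, lj_cutoff > 0,
            coulomb_cutoff > 0, bond_r0 > 0, bond_k > 0)
  structure(list(eps_stst = eps_stst,
                 eps_stsp = eps_stst / 1.5,
                 eps_spsp = eps_stst / 3,
                 debye_length = debye_length,
                 lj_cutoff = lj_cutoff,
                 coulomb_cutoff = coulomb_cutoff,
                 dielectric_prefactor = dielectric_prefactor,
                 bond_r0 = bond_r0, bond_k = bond_k),
            class = "ff_config")
}

#' Read a force-field configuration from a flat TOML file
#'
#' Accepts a minimal flat `key = value` TOML subset (comments with `#`,
#' no tables); unknown keys are rejected.
#'
#' @param path Path to the config file.
#' @return An [ff_config()].
#' @export
read_ff_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", lines))
  if (any(lengths(kv) != 3))
    stop("malformed config line: ", lines[which(lengths(kv) != 3)[1]])
  keys <- vapply(kv, `[`, "", 2)
  vals <- as.numeric(vapply(kv, `[`, "", 3))
  allowed <- names(formals(ff_config))
  bad <- setdiff(keys, allowed)
  if (length(bad)) stop("unknown force-field keys: ", paste(bad, collapse = ", "))
  do.call(ff_config, as.list(setNames(vals, keys)))
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case one-letter sequences.
#' @export
read_fasta_sequences <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  toupper(unlist(seqs))
}

#' Build the bead topology of one chain
#'
#' @param sequence Amino-acid sequence (string or one-letter vector).
#' @param residue_params Residue parameter table
#'   (default [read_residue_params()]).
#' @param sticker_set One-letter codes treated as stickers.
#' @return List of class `chain_topology`: `sequence`, per-bead `sigma_nm`,
#'   `charge`, `mass_Da`, `epsilon_class`, consecutive `bond_list`
#'   (1-based index pairs) and total `chain_mass` in Da.
#' @export
chain_topology <- function(sequence, residue_params = read_residue_params(),
                           sticker_set = .STICKER_SET) {
  aa <- .as_residue_vector(sequence)
  cls <- classify_stickers(aa, sticker_set)
  pars <- residue_params[aa, , drop = FALSE]
  nb <- length(aa)
  bonds <- if (nb > 1) cbind(seq_len(nb - 1), 2:nb) else
    matrix(integer(0), 0, 2)
  structure(list(sequence = aa,
                 sigma_nm = pars$sigma_nm,
                 charge = pars$charge,
                 mass_Da = pars$mass_Da,
                 epsilon_class = cls,
                 bond_list = bonds,
                 chain_mass = sum(pars$mass_Da)),
            class = "chain_topology")
}

## flatten a list of chain topologies into per-bead arrays and a global
## 0-based bond matrix, as the compiled kernels expect
.flatten_topologies <- function(topologies) {
  sigma <- unlist(lapply(topologies, `[[`, "sigma_nm"))
  charge <- unlist(lapply(topologies, `[[`, "charge"))
  sticker <- unlist(lapply(topologies, function(t)
    as.integer(t$epsilon_class == "sticker")))
  mass <- unlist(lapply(topologies, `[[`, "mass_Da"))
  chain_id <- rep(seq_along(topologies),
                  vapply(topologies, function(t) length(t$sequence), 1L))
  offs <- cumsum(c(0, head(vapply(topologies, function(t)
    length(t$sequence), 1L), -1)))
  bonds <- do.call(rbind, lapply(seq_along(topologies), function(i) {
    b <- topologies[[i]]$bond_list
    if (nrow(b) == 0) return(matrix(integer(0), 0, 2))
    b + offs[i] - 1L  # 0-based
  }))
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  list(sigma = sigma, charge = charge, sticker = sticker, mass = mass,
       chain_id = as.integer(chain_id), bonds = bonds)
}

#' Pairwise potential terms
#'
#' `bond_energy` is the harmonic bond 0.5*k*(r - r0)^2;
#' `debye_huckel_energy` is the screened Coulomb interaction
#' pref*qi*qj*exp(-r/lambda)/r, zero beyond the Coulomb cutoff;
#' `lj_energy` is the 12-6 Lennard-Jones term with pair sigma from the
#' arithmetic (Lorentz) mean and pair epsilon from the sticker-class mixing
#' rule, truncated at the LJ cutoff.
#'
#' @param r Interbead distance, nm.
#' @param config An [ff_config()].
#' @return Energy in kJ/mol.
#' @export
bond_energy <- function(r, config = ff_config()) {
  stopifnot(all(r >= 0))
  0.5 * config$bond_k * (r - config$bond_r0)^2
}

#' @rdname bond_energy
#' @param qi,qj Bead charges in elementary units.
#' @export
debye_huckel_energy <- function(r, qi, qj, config = ff_config()) {
  if (any(r <= 0)) stop("Debye-Hueckel energy undefined at r <= 0")
  e <- config$dielectric_prefactor * qi * qj *
    exp(-r / config$debye_length) / r
  e[r > config$coulomb_cutoff] <- 0
  e
}

#' @rdname bond_energy
#' @param params_i,params_j Per-bead parameters: lists (or one-row data
#'   frames) with `sigma_nm` (or `sigma_lj`) and `epsilon_class`.
#' @export
lj_energy <- function(r, params_i, params_j, config = ff_config()) {
  if (any(r <= 0)) stop("Lennard-Jones energy undefined at r <= 0")
  get_sigma <- function(p) if (!is.null(p$sigma_nm)) p$sigma_nm else p$sigma_lj
  sij <- (get_sigma(params_i) + get_sigma(params_j)) / 2
  ns <- (params_i$epsilon_class == "sticker") +
    (params_j$epsilon_class == "sticker")
  eij <- c(config$eps_spsp, config$eps_stsp, config$eps_stst)[ns + 1]
  sr6 <- (sij / r)^6
  e <- 4 * eij * (sr6^2 - sr6)
  e[r > config$lj_cutoff] <- 0
  e
}

.check_box <- function(box_length, config) {
  if (box_length < 2 * max(config$lj_cutoff, config$coulomb_cutoff))
    stop("box smaller than twice the largest cutoff")
}

#' Total potential energy and forces of a configuration
#'
#' Sums bonded, Debye-Hueckel and Lennard-Jones terms over all bead pairs
#' with the minimum-image convention in a cubic periodic box. Directly
#' bonded (1-2) pairs are excluded from the nonbonded sums.
#'
#' @param coords Numeric matrix (n_beads x 3) of positions, nm.
#' @param box_length Cubic box edge, nm; must be at least twice the largest
#'   cutoff.
#' @param topologies List of [chain_topology()] objects, one per chain, in
#'   bead order.
#' @param config An [ff_config()].
#' @return `total_energy`: energy in kJ/mol with attribute `components`
#'   (bond, lj, dh). `cg_forces`: an (n_beads x 3) matrix of analytic
#'   forces in kJ mol^-1 nm^-1.
#' @export
total_energy <- function(coords, box_length, topologies, config = ff_config()) {
  .check_box(box_length, config)
  ft <- .flatten_topologies(topologies)
  stopifnot(nrow(coords) == length(ft$sigma))
  r <- cpp_energy_forces(coords, box_length, ft$sigma, ft$sticker, ft$charge,
                         ft$bonds, config$bond_r0, config$bond_k,
                         config$eps_stst, config$debye_length,
                         config$dielectric_prefactor, config$lj_cutoff,
                         config$coulomb_cutoff, FALSE)
  structure(r$energy,
            components = c(bond = r$e_bond, lj = r$e_lj, dh = r$e_dh))
}

#' @rdname total_energy
#' @export
cg_forces <- function(coords, box_length, topologies, config = ff_config()) {
  .check_box(box_length, config)
  ft <- .flatten_topologies(topologies)
  stopifnot(nrow(coords) == length(ft$sigma))
  r <- cpp_energy_forces(coords, box_length, ft$sigma, ft$sticker, ft$charge,
                         ft$bonds, config$bond_r0, config$bond_k,
                         config$eps_stst, config$debye_length,
                         config$dielectric_prefactor, config$lj_cutoff,
                         config$coulomb_cutoff, TRUE)
  r$forces
}
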