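## Readers and writers for the package's plain-text formats: observation
## tables and radial profiles as CSV (units in the column names), fit
## reports as JSON, configurations as GRO, and a dependency-free
## whitespace trajectory format.

.OBS_COLS <- c("system", "L_nm", "N", "rho0_nm3", "rho0_mgml", "nss",
               "nss_err", "flag")

#' Read / write steady-state observation tables
#'
#' Observation tables have one row per finite-size simulation condition:
#' `system` (label), `L_nm` (box edge), `N` (chains), the paired total
#' densities `rho0_nm3` and `rho0_mgml`, the steady-state droplet size
#' `nss` with block-average error `nss_err` (empty for non-stable rows),
#' and `flag` (`stable`, `fluctuating` — an unstable or multiple droplet —
#' or `none` — no phase separation).
#'
#' @param path CSV file path.
#' @return Data frame with the columns above.
#' @export
read_observation_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.OBS_COLS, names(tab))
  if (length(miss))
    stop("observation table ", path, " lacks columns: ",
         paste(miss, collapse = ", "))
  bad <- which(!(tab$flag %in% c("stable", "fluctuating", "none")))
  if (length(bad))
    stop(sprintf("line %d: unknown flag '%s'", bad[1] + 1, tab$flag[bad[1]]))
  tab
}

#' @rdname read_observation_table
#' @param table Observation table to write.
#' @export
write_observation_table <- function(table, path) {
  write.csv(table[, .OBS_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged nucleation-study observation tables
#'
#' Steady-state droplet observations for the NDDX4 and FUS-LC nucleation
#' simulation sets (cubic boxes of 40-70 nm, three total densities each),
#' shipped with the package as CSV.
#'
#' @param protein `"NDDX4"` or `"FUS-LC"`.
#' @return Observation table (see [read_observation_table()]).
#' @examples
#' head(nucleation_observations("NDDX4"))
#' @export
nucleation_observations <- function(protein = c("NDDX4", "FUS-LC")) {
  protein <- match.arg(protein)
  fname <- if (protein == "NDDX4") "observations_nddx4.csv" else "observations_fuslc.csv"
  read_observation_table(system.file("extdata", fname, package = "mldroplet",
                                     mustWork = TRUE))
}

#' Write a free-energy or radial profile as CSV
#'
#' @param profile A `free_energy_profile` (columns `n`, `beta_F`) or
#'   `radial_profile` (columns `r_nm`, `rho_mgml`, `rho_nm3`).
#' @param path Output CSV path.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a Kelvin fit report as JSON
#'
#' Serializes estimates, confidence intervals, residuals and all settings
#' (including seeds) so a fit is reproducible from its report.
#'
#' @param fit A `kelvin_fit`.
#' @param path Output JSON path.
#' @export
write_fit_json <- function(fit, path) {
  keep <- c("sigma_mN_m", "rho_d_star_mgml", "rho_c_mgml", "chain_mass",
            "temperature", "method", "weighted", "n_rows", "rows",
            "observed_nss", "predicted_nss", "residuals", "negative_sigma",
            "ci95_sigma", "ci95_rho", "n_boot", "seed")
  obj <- fit[intersect(keep, names(fit))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write / read a single-frame GRO configuration
#'
#' Minimal GROMACS GRO support: one bead per residue, fixed-width columns,
#' cubic box on the last line. Positions in nm.
#'
#' @param coords Bead coordinate matrix (n x 3), nm.
#' @param box_length Cubic box edge, nm.
#' @param chain_id Integer chain index per bead (stored as residue number).
#' @param path Output path.
#' @param names Per-bead residue names (default `"BEA"`).
#' @export
write_gro <- function(coords, box_length, chain_id, path, names = "BEA") {
  n <- nrow(coords)
  if (length(names) == 1) names <- rep(names, n)
  lines <- c("coarse-grained configuration", sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     chain_id %% 100000, substr(names, 1, 5), "CA",
                     seq_len(n) %% 100000,
                     coords[, 1], coords[, 2], coords[, 3]),
             sprintf("%10.5f%10.5f%10.5f", box_length, box_length,
                     box_length))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gro
#' @return `read_gro` returns a list with `coords`, `box_length`,
#'   `chain_id`.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  at <- lines[3:(2 + n)]
  coords <- cbind(as.numeric(substr(at, 21, 28)),
                  as.numeric(substr(at, 29, 36)),
                  as.numeric(substr(at, 37, 44)))
  chain_id <- as.integer(substr(at, 1, 5))
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1]
  list(coords = coords, box_length = box, chain_id = chain_id)
}

#' Write / read the plain whitespace trajectory format
#'
#' A dependency-free text format: comment headers carrying the box edge and
#' frame times, then one row per bead and frame with columns
#' `frame chain bead x y z` (frame and indices 1-based, coordinates nm).
#'
#' @param traj A `cg_trajectory`.
#' @param path Output path.
#' @export
write_plain_trajectory <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# box_length_nm %.8g", traj$box_length), con)
  writeLines(paste("# times_ps", paste(format(traj$times, digits = 10),
                                       collapse = " ")), con)
  bead_in_chain <- stats::ave(traj$chain_id, traj$chain_id, FUN = seq_along)
  for (f in seq_along(traj$frames)) {
    m <- traj$frames[[f]]
    writeLines(sprintf("%d %d %d %.6f %.6f %.6f", f, traj$chain_id,
                       bead_in_chain, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_plain_trajectory
#' @return `read_plain_trajectory` returns a `cg_trajectory`.
#' @export
read_plain_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  box <- as.numeric(sub("^# box_length_nm\\s+", "",
                        lines[grepl("^# box_length_nm", lines)][1]))
  tline <- lines[grepl("^# times_ps", lines)]
  times <- if (length(tline))
    as.numeric(strsplit(sub("^# times_ps\\s+", "", tline[1]), "\\s+")[[1]])
  else NULL
  dat <- read.table(text = lines[!hdr],
                    col.names = c("frame", "chain", "bead", "x", "y", "z"))
  frames <- lapply(split(dat, factor(dat$frame, levels = sort(unique(dat$frame)))),
                   function(d)
    unname(as.matrix(d[order(d$chain, d$bead), c("x", "y", "z"),
                       drop = FALSE])))
  names(frames) <- NULL
  chain_id <- dat$chain[dat$frame == dat$frame[1]]
  if (is.null(times)) times <- seq_along(frames) - 1
  structure(list(frames = frames, times = times, box_length = box,
                 chain_id = as.integer(sort(chain_id)),
                 e_pot = rep(NA_real_, length(frames))),
            class = "cg_trajectory")
}

#' Write / read a state trajectory as CSV
#'
#' Long-format serialization of per-chain condensed/dilute labels: columns
#' `frame`, `chain`, `state` (`condensed`/`dilute`) and `droplet_size`
#' (largest-cluster size at that frame). The frame interval is carried in
#' a `# frame_interval_ns` header line above the CSV header.
#'
#' @param states A [state_trajectory()].
#' @param path Output CSV path.
#' @export
write_state_trajectory <- function(states, path) {
  n_frames <- nrow(states$states); n_chains <- ncol(states$states)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# frame_interval_ns %.8g", states$frame_interval_ns),
             con)
  df <- data.frame(
    frame = rep(seq_len(n_frames), n_chains),
    chain = rep(seq_len(n_chains), each = n_frames),
    state = ifelse(as.vector(states$states) == 1, "condensed", "dilute"),
    droplet_size = rep(states$droplet_size_series, n_chains))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_state_trajectory
#' @return `read_state_trajectory` returns a [state_trajectory()].
#' @export
read_state_trajectory <- function(path) {
  lines <- readLines(path)
  dt <- as.numeric(sub("^# frame_interval_ns\\s+", "",
                       lines[grepl("^# frame_interval_ns", lines)][1]))
  if (!is.finite(dt)) dt <- 1
  df <- read.csv(text = lines[!grepl("^#", lines)], stringsAsFactors = FALSE)
  n_frames <- max(df$frame); n_chains <- max(df$chain)
  S <- matrix(0L, n_frames, n_chains)
  S[cbind(df$frame, df$chain)] <- as.integer(df$state == "condensed")
  sz <- numeric(n_frames)
  sz[df$frame] <- df$droplet_size
  state_trajectory(S, dt, droplet_size_series = sz)
}
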