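## Droplet identification and characterization: two-stage geometric cluster
## criterion (interchain contacts, then chain-COM distance from the droplet
## COM), block-averaged steady-state sizes, radial density profiles,
## condensed-phase density estimation and shape metrics.

#' Geometric droplet criteria
#'
#' Two chains are linked when at least `min_contacts` bead pairs lie within
#' `contact_cutoff` (minimum image); single-linkage components of that
#' contact graph are candidate droplets. A refinement stage then demotes
#' chains whose center of mass lies farther than `com_cutoff` from their
#' cluster's center of mass. With `com_cutoff = NULL` (default) the cutoff
#' adapts to twice the cluster's radius of gyration.
#'
#' @param contact_cutoff Bead-bead contact distance, nm.
#' @param min_contacts Bead-pair contacts required to link two chains.
#' @param com_cutoff Chain-COM to droplet-COM cutoff, nm, or `NULL` for the
#'   adaptive 2 x Rg default.
#' @return List of class `cluster_criteria`.
#' @export
cluster_criteria <- function(contact_cutoff = 1.0, min_contacts = 1,
                             com_cutoff = NULL) {
  stopifnot(contact_cutoff > 0, min_contacts >= 1,
            is.null(com_cutoff) || com_cutoff > 0)
  structure(list(contact_cutoff = contact_cutoff,
                 min_contacts = as.integer(min_contacts),
                 com_cutoff = com_cutoff),
            class = "cluster_criteria")
}

#' Periodic-aware center of mass
#'
#' Center of mass of points in a cubic periodic box via the circular mean
#' on each axis, robust to clusters crossing the boundary.
#'
#' @param coords Matrix (n x 3) of positions, nm.
#' @param box_length Box edge, nm.
#' @param weights Optional per-point masses.
#' @return Length-3 position inside `[0, box_length)`.
#' @export
periodic_com <- function(coords, box_length, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(coords))
  w <- weights / sum(weights)
  theta <- 2 * pi * (coords %% box_length) / box_length
  s <- colSums(w * sin(theta)); c_ <- colSums(w * cos(theta))
  (atan2(-s, -c_) + pi) * box_length / (2 * pi)
}

## minimum-image displacement vectors from a reference point
.min_image_disp <- function(coords, ref, box_length) {
  d <- sweep(coords, 2, ref)
  d - box_length * round(d / box_length)
}

#' Detect condensed-phase droplets in a configuration
#'
#' Stage 1 builds the interchain contact graph (at least `min_contacts`
#' bead pairs within `contact_cutoff`, minimum image) and takes its
#' single-linkage components; components of one chain are dilute. Stage 2
#' computes each cluster's periodic-aware center of mass and demotes member
#' chains whose own COM is farther than the COM cutoff. Cluster ids are
#' relabelled in order of decreasing size; label 0 means dilute.
#'
#' @param coords Bead coordinate matrix (n x 3), nm.
#' @param box_length Cubic box edge, nm.
#' @param chain_id Integer chain index per bead.
#' @param criteria A [cluster_criteria()].
#' @return List of class `cluster_assignment`: `labels` (per chain, 0 =
#'   dilute), `largest_size` (chains in the most populous cluster, 0 if
#'   none).
#' @export
detect_clusters <- function(coords, box_length, chain_id,
                            criteria = cluster_criteria()) {
  n_chains <- if (length(chain_id)) max(chain_id) else 0L
  if (n_chains == 0)
    return(structure(list(labels = integer(0), largest_size = 0L),
                     class = "cluster_assignment"))
  cc <- cpp_contact_counts(coords, box_length, as.integer(chain_id),
                           criteria$contact_cutoff)
  edges <- cc[cc[, 3] >= criteria$min_contacts, 1:2, drop = FALSE]
  labels <- integer(n_chains)
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n_chains - igraph::vcount(g)))
    comp <- igraph::components(g)
    labels <- comp$membership[seq_len(n_chains)]
    labels[tabulate(labels)[labels] < 2] <- 0L
    ## stage 2: COM-distance refinement
    for (cl in setdiff(unique(labels), 0L)) {
      members <- which(labels == cl)
      beads <- chain_id %in% members
      com <- periodic_com(coords[beads, , drop = FALSE], box_length)
      disp <- .min_image_disp(coords[beads, , drop = FALSE], com, box_length)
      cutoff <- criteria$com_cutoff
      if (is.null(cutoff)) cutoff <- 2 * sqrt(mean(rowSums(disp^2)))  # 2 Rg
      for (ch in members) {
        ch_com <- periodic_com(coords[chain_id == ch, , drop = FALSE],
                               box_length)
        d <- sqrt(sum(.min_image_disp(matrix(ch_com, 1), com, box_length)^2))
        if (d > cutoff) labels[ch] <- 0L
      }
    }
    labels[labels != 0 & tabulate(labels)[pmax(labels, 1)] < 2] <- 0L
  }
  ## relabel by decreasing size
  if (any(labels != 0)) {
    sizes <- table(labels[labels != 0])
    ord <- names(sort(sizes, decreasing = TRUE))
    labels <- match(as.character(labels), ord, nomatch = 0L)
    largest <- as.integer(max(sizes))
  } else largest <- 0L
  structure(list(labels = as.integer(labels), largest_size = largest),
            class = "cluster_assignment")
}

## per-frame largest-cluster size and count of clusters above a size
## threshold, for a trajectory
.traj_cluster_stats <- function(traj, criteria, min_cluster = 5) {
  stats <- lapply(traj$frames, function(fr) {
    a <- detect_clusters(fr, traj$box_length, traj$chain_id, criteria)
    sizes <- if (any(a$labels != 0)) tabulate(a$labels) else integer(0)
    list(largest = a$largest_size, n_big = sum(sizes >= min_cluster),
         labels = a$labels)
  })
  list(largest = vapply(stats, `[[`, 0L, "largest"),
       n_big = vapply(stats, `[[`, 0L, "n_big"),
       labels = lapply(stats, `[[`, "labels"))
}

#' Block-average standard error of a correlated series
#'
#' @param x Numeric series.
#' @param n_blocks Number of contiguous blocks (at least 5 recommended).
#' @return Standard error of the mean from the block means.
#' @export
block_average_error <- function(x, n_blocks = 5) {
  if (length(x) < n_blocks) stop("too few points for ", n_blocks, " blocks")
  idx <- cut(seq_along(x), n_blocks, labels = FALSE)
  bm <- tapply(x, idx, mean)
  sd(bm) / sqrt(n_blocks)
}

#' Steady-state droplet size of a trajectory
#'
#' Discards the equilibration window, averages the largest detected cluster
#' over the remaining frames, and attaches the block-average standard
#' error. The outcome flag mirrors the usual bookkeeping of finite-size
#' nucleation runs: `none` when no sizeable cluster forms in nearly all
#' frames, `fluctuating` when the relative block error is large or several
#' sizeable clusters coexist in a substantial fraction of frames, `stable`
#' otherwise.
#'
#' @param traj A `cg_trajectory`, or a numeric per-frame size series (for
#'   pre-computed label data).
#' @param criteria A [cluster_criteria()] (ignored for a numeric series).
#' @param equilibration_fraction Fraction of frames discarded (default 0.5).
#' @param n_blocks Blocks for the error estimate (default 5).
#' @param min_cluster Cluster size that counts as a droplet (default 5).
#' @param none_frac Flag `none` if largest < `min_cluster` in at least this
#'   fraction of frames (default 0.9).
#' @param fluct_err Flag `fluctuating` above this relative block error
#'   (default 0.25).
#' @param fluct_frac Flag `fluctuating` if several droplet-sized clusters
#'   coexist in at least this fraction of frames (default 0.25).
#' @param N,V Chain count and box volume recorded in the observation
#'   (taken from the trajectory when available).
#' @return List of class `droplet_observation`: `N`, `V`, `n_ss`, `n_err`,
#'   `outcome_flag`.
#' @export
steady_state_size <- function(traj, criteria = cluster_criteria(),
                              equilibration_fraction = 0.5, n_blocks = 5,
                              min_cluster = 5, none_frac = 0.9,
                              fluct_err = 0.25, fluct_frac = 0.25,
                              N = NA, V = NA) {
  if (is.numeric(traj)) {
    largest <- traj
    n_big <- as.integer(largest >= min_cluster)
  } else {
    st <- .traj_cluster_stats(traj, criteria, min_cluster)
    largest <- st$largest
    n_big <- st$n_big
    N <- max(traj$chain_id); V <- traj$box_length^3
  }
  n_frames <- length(largest)
  keep <- largest[seq.int(floor(equilibration_fraction * n_frames) + 1,
                          n_frames)]
  nb <- n_big[seq.int(floor(equilibration_fraction * n_frames) + 1, n_frames)]
  if (length(keep) < n_blocks)
    stop("too few post-equilibration frames for block averaging")
  n_ss <- mean(keep)
  n_err <- block_average_error(keep, n_blocks)
  flag <- if (mean(keep < min_cluster) >= none_frac) {
    "none"
  } else if ((n_err / n_ss) > fluct_err || mean(nb >= 2) >= fluct_frac) {
    "fluctuating"
  } else "stable"
  structure(list(N = N, V = V, n_ss = n_ss, n_err = n_err,
                 outcome_flag = flag),
            class = "droplet_observation")
}

#' Radial mass-density profile about the droplet center
#'
#' Histograms bead mass in spherical shells about the periodic-aware COM of
#' the largest detected cluster, averaged over frames, and converts to
#' mg/mL. Frames without a detectable droplet are skipped; if they exceed
#' half the trajectory the profile is rejected.
#'
#' @param traj A `cg_trajectory`.
#' @param criteria A [cluster_criteria()].
#' @param bin_width Shell width, nm.
#' @param bead_mass Bead mass in Da: a scalar or per-bead vector.
#' @param r_max Outer radius, nm (default half the box edge).
#' @param min_cluster Smallest cluster accepted as a droplet.
#' @return Data frame of class `radial_profile`: `r_nm` (bin centers),
#'   `rho_mgml`, `rho_nm3` (bead number density).
#' @export
radial_density_profile <- function(traj, criteria = cluster_criteria(),
                                   bin_width = 0.5, bead_mass = 110,
                                   r_max = NULL, min_cluster = 5) {
  if (is.null(r_max)) r_max <- traj$box_length / 2
  if (length(bead_mass) == 1)
    bead_mass <- rep(bead_mass, nrow(traj$frames[[1]]))
  edges <- seq(0, r_max, by = bin_width)
  if (max(edges) < r_max) edges <- c(edges, max(edges) + bin_width)
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  acc_mass <- numeric(length(mids)); acc_count <- numeric(length(mids))
  used <- 0
  for (fr in traj$frames) {
    a <- detect_clusters(fr, traj$box_length, traj$chain_id, criteria)
    if (a$largest_size < min_cluster) next
    members <- which(a$labels == 1)
    beads <- traj$chain_id %in% members
    com <- periodic_com(fr[beads, , drop = FALSE], traj$box_length)
    d <- sqrt(rowSums(.min_image_disp(fr, com, traj$box_length)^2))
    bin <- findInterval(d, edges, rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= length(mids)
    acc_mass <- acc_mass + vapply(seq_along(mids), function(b)
      sum(bead_mass[ok & bin == b]), 0)
    acc_count <- acc_count + tabulate(bin[ok], nbins = length(mids))
    used <- used + 1
  }
  if (used < length(traj$frames) / 2)
    stop("no droplet detected in more than half of the frames")
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  rho_da_nm3 <- acc_mass / used / shell_vol
  structure(data.frame(r_nm = mids,
                       rho_mgml = rho_da_nm3 * .DA_NM3_TO_MGML,
                       rho_nm3 = acc_count / used / shell_vol),
            class = c("radial_profile", "data.frame"), n_frames_used = used)
}

#' Condensed-phase density from a radial profile's core plateau
#'
#' Locates the half-density radius (where the profile first falls below
#' half its plateau maximum) and averages the density over the inner core,
#' shells within `core_radius_fraction` of that radius — a region whose
#' mean density is a robust estimate of the equilibrium dense-phase
#' density.
#'
#' @param profile A [radial_density_profile()] result.
#' @param core_radius_fraction Fraction of the half-density radius included
#'   in the core average (default 0.5).
#' @return Density in mg/mL; attribute `flag` is `"ok"` or `"no_plateau"`
#'   (with a warning) when the profile has no resolvable core.
#' @export
estimate_rho_c <- function(profile, core_radius_fraction = 0.5) {
  rho <- profile$rho_mgml
  if (all(rho == 0)) return(structure(0, flag = "ok"))
  ## smooth over 3 bins to locate the half-density radius robustly (inner
  ## shells are small-volume and noisy), then volume-weight the core mean
  sm <- stats::filter(rho, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- rho[is.na(sm)]
  rho_max <- max(sm)
  below <- which(sm < rho_max / 2)
  r_half <- if (length(below)) profile$r_nm[min(below)] else max(profile$r_nm)
  core <- profile$r_nm <= core_radius_fraction * r_half
  vol_w <- profile$r_nm^2  # shell volume ~ r^2 at fixed bin width
  if (sum(core) < 1) {
    warning("profile has no clear core plateau; estimate flagged")
    core <- seq_along(rho) <= 2
    return(structure(mean(rho[core]), flag = "no_plateau"))
  }
  est <- sum(rho[core] * vol_w[core]) / sum(vol_w[core])
  flag <- if (min(which(sm >= rho_max / 2)) > 1 ||
              max(sm[core]) < rho_max / 2) "no_plateau" else "ok"
  if (flag == "no_plateau")
    warning("profile core is not a monotone plateau; estimate flagged")
  structure(est, flag = flag)
}

#' Asphericity of a detected droplet
#'
#' Gyration-tensor shape anisotropy of the largest cluster's beads:
#' b = lambda1 - (lambda2 + lambda3)/2, normalized by the trace. Zero for a
#' spherically symmetric mass distribution, 1 for a line.
#'
#' @inheritParams detect_clusters
#' @param assignment A [detect_clusters()] result for this configuration
#'   (recomputed when `NULL`).
#' @return Normalized asphericity in `[0, 1]`.
#' @export
asphericity <- function(coords, box_length, chain_id, assignment = NULL,
                        criteria = cluster_criteria()) {
  if (is.null(assignment))
    assignment <- detect_clusters(coords, box_length, chain_id, criteria)
  members <- which(assignment$labels == 1)
  beads <- chain_id %in% members
  if (sum(beads) < 2) stop("asphericity undefined for fewer than 2 beads")
  com <- periodic_com(coords[beads, , drop = FALSE], box_length)
  d <- .min_image_disp(coords[beads, , drop = FALSE], com, box_length)
  S <- crossprod(d) / nrow(d)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  (ev[1] - (ev[2] + ev[3]) / 2) / sum(ev)
}
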