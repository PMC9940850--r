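## Two-state Markov-state model of single-chain exchange between the
## condensed droplet and the dilute phase: per-droplet-size escape rates
## (rate = 1 / mean first passage time), their size dependence, and the
## balance between the forward and backward rates.

#' Per-chain condensed/dilute state trajectory
#'
#' @param states Integer or logical matrix (frames x chains); 1/TRUE =
#'   condensed, 0/FALSE = dilute.
#' @param frame_interval_ns Time between frames, ns.
#' @param droplet_size_series Per-frame droplet size (chains); defaults to
#'   the per-frame count of condensed chains.
#' @return List of class `state_trajectory`.
#' @export
state_trajectory <- function(states, frame_interval_ns,
                             droplet_size_series = NULL) {
  states <- matrix(as.integer(states), nrow = nrow(states))
  stopifnot(all(states %in% c(0L, 1L)), frame_interval_ns > 0)
  if (is.null(droplet_size_series)) droplet_size_series <- rowSums(states)
  stopifnot(length(droplet_size_series) == nrow(states))
  structure(list(states = states, frame_interval_ns = frame_interval_ns,
                 droplet_size_series = droplet_size_series),
            class = "state_trajectory")
}

#' Assign per-chain condensed/dilute states along a trajectory
#'
#' A chain is condensed in a frame iff it belongs to the largest detected
#' cluster (same geometric criteria as droplet detection); frames without
#' any cluster leave all chains dilute.
#'
#' @param traj A `cg_trajectory`.
#' @param criteria A [cluster_criteria()].
#' @return A [state_trajectory()] whose `droplet_size_series` records the
#'   largest-cluster size per frame.
#' @export
assign_states <- function(traj, criteria = cluster_criteria()) {
  st <- .traj_cluster_stats(traj, criteria)
  n_chains <- max(traj$chain_id)
  states <- t(vapply(st$labels, function(lab) as.integer(lab == 1),
                     integer(n_chains)))
  dt_ns <- if (length(traj$times) > 1) diff(traj$times)[1] / 1000 else 1
  state_trajectory(states, dt_ns, droplet_size_series = st$largest)
}

## 2x2 sliding-window transition counts at a lag, restricted to start
## frames in `use`
.count_transitions <- function(states, lag, use) {
  from <- states[use, , drop = FALSE]
  to <- states[use + lag, , drop = FALSE]
  c(cc = sum(from == 1 & to == 1), cd = sum(from == 1 & to == 0),
    dc = sum(from == 0 & to == 1), dd = sum(from == 0 & to == 0))
}

## rate and Jeffreys 95% interval from exit counts; rate = p_exit/(lag*dt)
## because the MFPT of leaving a 2-state chain is 1/p_exit lags
.rate_ci <- function(n_exit, n_stay, lag_time_us) {
  tot <- n_exit + n_stay
  if (tot == 0) return(c(NA, NA, NA, bound = 1))
  p <- n_exit / tot
  ci <- stats::qbeta(c(0.025, 0.975), n_exit + 0.5, n_stay + 0.5)
  if (n_exit == 0)  # absorbing in the data: report an upper bound
    return(c(NA, 0, ci[2] / lag_time_us, bound = 1))
  c(p / lag_time_us, ci[1] / lag_time_us, ci[2] / lag_time_us, bound = 0)
}

#' Exchange rates from a two-state Markov model
#'
#' Builds 2x2 transition-count matrices at the chosen lag (sliding window,
#' pooled over chains), optionally stratified by droplet-size bin of the
#' start frame, and converts exit probabilities to rates as the reciprocal
#' mean first passage time of the two-state chain: k = p_exit/(lag * dt).
#' 95% credible intervals are Jeffreys-prior beta intervals on the exit
#' probability. Bins where no exit was observed report only an upper bound
#' (`bound = 1`).
#'
#' @param states A [state_trajectory()].
#' @param lag Lag in frames (default 1).
#' @param size_bins Number of droplet-size quantile bins (default 5,
#'   quintiles; degenerate size series collapse to a single bin), or a
#'   numeric vector of explicit bin edges.
#' @return Data frame of class `rate_estimates` with one row per bin:
#'   droplet-size bin bounds and midpoint, transition counts, `k_cd`,
#'   `k_dc` (1/us) with 95% intervals, and the lag.
#' @export
estimate_rates <- function(states, lag = 1, size_bins = 5) {
  stopifnot(inherits(states, "state_trajectory"), lag >= 1)
  S <- states$states
  n_frames <- nrow(S)
  if (n_frames <= lag) stop("trajectory shorter than the lag")
  starts <- seq_len(n_frames - lag)
  size_at <- states$droplet_size_series[starts]
  lag_time_us <- lag * states$frame_interval_ns / 1000
  if (length(size_bins) == 1) {
    nb <- size_bins
    edges <- if (nb == 1) c(-Inf, Inf) else
      unique(quantile(size_at, probs = seq(0, 1, length.out = nb + 1)))
    if (length(edges) < 2) edges <- c(-Inf, Inf)
  } else edges <- size_bins
  bin <- cut(size_at, edges, include.lowest = TRUE, labels = FALSE)
  rows <- lapply(sort(unique(bin[!is.na(bin)])), function(b) {
    use <- starts[!is.na(bin) & bin == b]
    ct <- .count_transitions(S, lag, use)
    rc <- .rate_ci(ct["cd"], ct["cc"], lag_time_us)
    rd <- .rate_ci(ct["dc"], ct["dd"], lag_time_us)
    data.frame(bin = b, size_lo = min(size_at[bin == b], na.rm = TRUE),
               size_hi = max(size_at[bin == b], na.rm = TRUE),
               size_mid = mean(size_at[bin == b], na.rm = TRUE),
               n_cc = ct["cc"], n_cd = ct["cd"], n_dc = ct["dc"],
               n_dd = ct["dd"],
               k_cd = rc[1], k_cd_lo = rc[2], k_cd_hi = rc[3],
               k_cd_bound = rc[4],
               k_dc = rd[1], k_dc_lo = rd[2], k_dc_hi = rd[3],
               k_dc_bound = rd[4], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("rate_estimates", "data.frame"), lag = lag,
            frame_interval_ns = states$frame_interval_ns)
}

#' Exponential fit of escape rate versus droplet size
#'
#' Least squares of ln(k_cd) against droplet size: k(n) = k0 exp(-a n).
#' Larger droplets hold their chains longer, so the decay constant `a` is
#' positive for condensates with a meaningful surface barrier; steeper
#' decay means stronger size dependence of the escape kinetics.
#'
#' @param rates A [estimate_rates()] result with at least 3 bins carrying
#'   finite `k_cd`.
#' @return List of class `exp_fit`: `prefactor` (1/us), `decay_constant`
#'   (per chain), per-bin `residuals` (log space).
#' @export
fit_exponential_decay <- function(rates) {
  ok <- is.finite(rates$k_cd) & rates$k_cd > 0
  if (any(!ok)) warning(sum(!ok), " bins with non-positive rates excluded")
  if (sum(ok) < 3) stop("need at least 3 size bins with finite escape rates")
  fit <- lm(log(k_cd) ~ size_mid, data = rates[ok, ])
  structure(list(prefactor = exp(unname(coef(fit)[1])),
                 decay_constant = -unname(coef(fit)[2]),
                 residuals = unname(fit$residuals),
                 sizes = rates$size_mid[ok]),
            class = "exp_fit")
}

#' Rate-ratio versus population-ratio balance
#'
#' For exchange consistent with detailed balance the ratio of the
#' condensed-to-dilute and dilute-to-condensed rates equals the ratio of
#' dilute to condensed populations. Splits the trajectory into contiguous
#' blocks, computes both ratios per block, and regresses one on the other;
#' a slope near 1 and intercept near 0 indicate equilibrium-consistent
#' exchange.
#'
#' @param states A [state_trajectory()].
#' @param n_blocks Contiguous blocks (default 10).
#' @param lag Lag in frames for the rate estimates.
#' @return List of class `rate_balance`: per-block data frame `ratios`
#'   (`rate_ratio` = k_cd/k_dc, `pop_ratio` = N_dilute/N_condensed),
#'   regression `slope` and `intercept`.
#' @export
rate_ratio_balance <- function(states, n_blocks = 10, lag = 1) {
  stopifnot(inherits(states, "state_trajectory"))
  S <- states$states
  n_frames <- nrow(S)
  frac_cond <- rowMeans(S)
  if (mean(frac_cond == 0) > 0.5 || mean(frac_cond == 1) > 0.5)
    stop("one phase is empty in more than half of the frames")
  idx <- cut(seq_len(n_frames), n_blocks, labels = FALSE)
  rows <- lapply(seq_len(n_blocks), function(b) {
    sub <- S[idx == b, , drop = FALSE]
    if (nrow(sub) <= lag) return(NULL)
    ct <- .count_transitions(sub, lag, seq_len(nrow(sub) - lag))
    p_cd <- ct["cd"] / (ct["cc"] + ct["cd"])
    p_dc <- ct["dc"] / (ct["dc"] + ct["dd"])
    nc <- sum(sub == 1); nd <- sum(sub == 0)
    if (!is.finite(p_cd) || !is.finite(p_dc) || p_dc == 0 || nc == 0)
      return(NULL)
    data.frame(block = b, rate_ratio = unname(p_cd / p_dc),
               pop_ratio = nd / nc)
  })
  ratios <- do.call(rbind, rows)
  if (is.null(ratios) || nrow(ratios) < 2)
    stop("too few usable blocks for the balance regression")
  fit <- lm(rate_ratio ~ pop_ratio, data = ratios)
  structure(list(ratios = ratios, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1])),
            class = "rate_balance")
}
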