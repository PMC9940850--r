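## Gibbs-Thomson/Kelvin analysis: predicting steady-state droplet sizes and
## globally fitting surface tension and dilute-phase equilibrium density
## from tables of finite-size steady-state observations.

#' Kelvin (Gibbs-Thomson) dilute-phase density over a curved droplet
#'
#' The dilute phase coexisting with a spherical droplet of radius r_ss is
#' elevated above the flat-interface equilibrium density:
#' rho_d = rho_d* exp( 2 beta sigma / (rho_c r_ss) ), with
#' r_ss = (3 n_ss / (4 pi rho_c))^(1/3).
#'
#' @param n_ss Steady-state droplet size, chains.
#' @param params A [thermo_params()].
#' @return Dilute-phase number density, chains/nm^3.
#' @export
kelvin_density <- function(n_ss, params) {
  stopifnot(inherits(params, "thermo_params"), all(n_ss > 0))
  rc <- params$rho_c_nm3
  r <- droplet_radius(n_ss, rc)
  params$rho_d_star_nm3 * exp(2 * params$beta_sigma / (rc * r))
}

#' Predict the steady-state droplet size in a finite box
#'
#' Solves the stationarity condition of the canonical free energy — the
#' depleted dilute-phase density equals the Kelvin density —
#' (N - n)/(V - n/rho_c) = rho_d* exp(2 beta sigma/(rho_c r(n)))
#' by bracketed root finding, selecting the larger root (the free-energy
#' minimum, i.e. the stable self-limiting droplet). When no root exists the
#' condition is inhibited by finite-size effects and `NA` is returned with
#' attribute `status = "inhibited"`.
#'
#' @param params A [thermo_params()].
#' @param system A [canonical_system()].
#' @return Steady-state size in chains (real-valued), or `NA` if inhibited;
#'   the return carries a `status` attribute (`"stable"` or `"inhibited"`).
#' @examples
#' nd <- thermo_params(0.101, 4.87, 359, chain_mass = 25427)
#' predict_nss(nd, canonical_system(N = 187, L = 70))  # about 130 chains
#' @export
predict_nss <- function(params, system) {
  stopifnot(inherits(params, "thermo_params"),
            inherits(system, "canonical_system"))
  g <- function(n) .dbeta_F(n, params, system = system)
  n_hi <- min(system$N, system$V * params$rho_c_nm3) * (1 - 1e-9)
  opt <- optimize(g, c(1e-8, n_hi), tol = 1e-10)
  if (opt$objective >= 0)
    return(structure(NA_real_, status = "inhibited"))
  root <- uniroot(g, c(opt$minimum, n_hi), tol = 1e-12)$root
  structure(root, status = "stable")
}

#' Chain molar mass implied by paired density columns
#'
#' Observation tables report the total density both as chains/nm^3 and as
#' mg/mL; their ratio fixes the chain molar mass. Returns the mean over
#' rows and warns when the per-row spread exceeds 1% (inconsistent table).
#'
#' @param table An observation table (see [read_observation_table()]).
#' @return Chain mass in Da, with per-row values as attribute `per_row`.
#' @export
chain_mass_from_table <- function(table) {
  ok <- is.finite(table$rho0_nm3) & is.finite(table$rho0_mgml)
  if (!any(ok)) stop("no rows with both density representations")
  m <- table$rho0_mgml[ok] / (table$rho0_nm3[ok] * .DA_NM3_TO_MGML)
  spread <- (max(m) - min(m)) / mean(m)
  if (spread > 0.01)
    warning(sprintf("chain masses implied by rows spread by %.1f%%: %s",
                    100 * spread, paste(round(m), collapse = ", ")))
  structure(mean(m), per_row = m)
}

## rows usable for fitting, plus the x/y coordinates of the linearized
## Kelvin relation:  ln rho_d^(n_ss) = ln rho_d* + beta*sigma * 2/(rho_c r_ss)
.kelvin_design <- function(table, rho_c_nm3) {
  use <- table$flag == "stable" & is.finite(table$nss)
  tab <- table[use, , drop = FALSE]
  if (nrow(tab) < 3) stop("need at least 3 stable rows spanning (N, V)")
  V <- tab$L_nm^3
  rho_n <- (tab$N - tab$nss) / (V - tab$nss / rho_c_nm3)
  r_ss <- droplet_radius(tab$nss, rho_c_nm3)
  list(tab = tab, x = 2 / (rho_c_nm3 * r_ss), y = log(rho_n))
}

#' Global Kelvin fit of surface tension and dilute-phase density
#'
#' Fits the Gibbs-Thomson/Kelvin relation to a table of steady-state droplet
#' observations collected at several (N, V). Writing the depleted dilute
#' density of each row as y = ln rho_d^(n_ss) and x = 2/(rho_c kT r_ss), the
#' relation is linear: y = ln rho_d* + sigma x, so ordinary least squares
#' yields the surface tension (slope) and the equilibrium dilute-phase
#' density (exponential of the intercept). A nonlinear least-squares
#' alternative in density space is available via `method = "nonlinear"`
#' (Levenberg-Marquardt, started from the linear solution); optional
#' weights 1/n_err^2 via `weight_by_error`.
#'
#' Only rows flagged `stable` enter the fit; fluctuating and
#' non-phase-separated conditions are excluded.
#'
#' @param table Observation table with columns `L_nm`, `N`, `nss`,
#'   `nss_err`, `flag` and the paired density columns `rho0_nm3`,
#'   `rho0_mgml` (see [read_observation_table()]).
#' @param rho_c_mgml Condensed-phase density held fixed during the fit,
#'   mg/mL (from droplet density profiles).
#' @param chain_mass Chain molar mass in Da; derived from the table's paired
#'   density columns when `NULL`.
#' @param temperature Temperature, K.
#' @param method `"linear"` (default, least squares in log density) or
#'   `"nonlinear"` (least squares in density).
#' @param weight_by_error Weight rows by 1/n_err^2 (default `FALSE`, equal
#'   weights).
#' @return A list of class `kelvin_fit` with `sigma_mN_m`,
#'   `rho_d_star_mgml`, the implied [thermo_params()], per-row residuals
#'   (observed minus refitted n_ss) and fit metadata.
#' @examples
#' tab <- nucleation_observations("NDDX4")
#' fit_parameters(tab, rho_c_mgml = 359)
#' @export
fit_parameters <- function(table, rho_c_mgml, chain_mass = NULL,
                           temperature = 300,
                           method = c("linear", "nonlinear"),
                           weight_by_error = FALSE) {
  method <- match.arg(method)
  if (is.null(chain_mass)) chain_mass <- as.numeric(chain_mass_from_table(table))
  rho_c_nm3 <- mgml_to_nm3(rho_c_mgml, chain_mass)
  d <- .kelvin_design(table, rho_c_nm3)
  w <- if (weight_by_error) {
    if (any(!is.finite(d$tab$nss_err) | d$tab$nss_err <= 0))
      stop("weight_by_error requires positive nss_err on all stable rows")
    1 / d$tab$nss_err^2
  } else rep(1, nrow(d$tab))
  fit <- lm(y ~ x, data = data.frame(x = d$x, y = d$y), weights = w)
  beta_sigma <- unname(coef(fit)[2])
  log_rho_star <- unname(coef(fit)[1])
  if (method == "nonlinear") {
    rho_n <- exp(d$y)
    nl <- minpack.lm::nlsLM(
      rho_n ~ exp(lr) * exp(bs * x),
      data = data.frame(x = d$x, rho_n = rho_n),
      start = list(lr = log_rho_star, bs = beta_sigma),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    cf <- coef(nl)
    log_rho_star <- unname(cf["lr"])
    beta_sigma <- unname(cf["bs"])
  }
  sigma_mN_m <- sigma_from_kT_nm2(beta_sigma, temperature)
  rho_d_star_mgml <- nm3_to_mgml(exp(log_rho_star), chain_mass)
  params <- thermo_params(sigma_mN_m, rho_d_star_mgml, rho_c_mgml,
                          chain_mass, temperature)
  pred <- vapply(seq_len(nrow(d$tab)), function(i) {
    as.numeric(predict_nss(params,
                           canonical_system(N = d$tab$N[i], L = d$tab$L_nm[i])))
  }, numeric(1))
  res <- structure(list(
    sigma_mN_m = sigma_mN_m,
    rho_d_star_mgml = rho_d_star_mgml,
    rho_c_mgml = rho_c_mgml,
    chain_mass = chain_mass,
    temperature = temperature,
    params = params,
    method = method,
    weighted = weight_by_error,
    n_rows = nrow(d$tab),
    rows = d$tab$system,
    observed_nss = d$tab$nss,
    predicted_nss = pred,
    residuals = d$tab$nss - pred,
    negative_sigma = beta_sigma < 0
  ), class = "kelvin_fit")
  if (res$negative_sigma)
    warning("fitted surface tension is negative; result flagged")
  res
}

#' @export
print.kelvin_fit <- function(x, ...) {
  cat("Global Gibbs-Thomson/Kelvin fit (", x$method, ", ",
      x$n_rows, " stable rows)\n", sep = "")
  cat(sprintf("  sigma   = %.4g mN/m\n", x$sigma_mN_m))
  cat(sprintf("  rho_d*  = %.4g mg/mL\n", x$rho_d_star_mgml))
  if (!is.null(x$ci95_sigma))
    cat(sprintf("  95%% CI sigma  : [%.4g, %.4g] mN/m (%d bootstrap replicates)\n",
                x$ci95_sigma[1], x$ci95_sigma[2], x$n_boot))
  if (!is.null(x$ci95_rho))
    cat(sprintf("  95%% CI rho_d* : [%.4g, %.4g] mg/mL\n",
                x$ci95_rho[1], x$ci95_rho[2]))
  cat(sprintf("  rho_c fixed at %.4g mg/mL, chain mass %.5g Da\n",
              x$rho_c_mgml, x$chain_mass))
  cat(sprintf("  parity RMS (obs vs refit n_ss): %.3g chains\n",
              sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Bootstrap confidence intervals for the Kelvin fit
#'
#' Case-resampling bootstrap over table rows (with replacement): each
#' replicate refits the linearized Kelvin relation and the 2.5/97.5
#' percentiles of the replicate estimates give 95% intervals. Replicates
#' with fewer than 3 distinct rows are redrawn (a degenerate design cannot
#' identify slope and intercept). Fully seeded and reproducible.
#'
#' @inheritParams fit_parameters
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Integer RNG seed.
#' @return The `kelvin_fit` with elements `ci95_sigma` (mN/m), `ci95_rho`
#'   (mg/mL), `n_boot`, `seed` and the replicate draws in `boot_sigma`,
#'   `boot_rho`.
#' @export
bootstrap_ci <- function(table, rho_c_mgml, chain_mass = NULL,
                         temperature = 300, n_boot = 10000, seed = 1,
                         weight_by_error = FALSE) {
  fit <- fit_parameters(table, rho_c_mgml, chain_mass, temperature,
                        method = "linear", weight_by_error = weight_by_error)
  rho_c_nm3 <- mgml_to_nm3(rho_c_mgml, fit$chain_mass)
  d <- .kelvin_design(table, rho_c_nm3)
  m <- length(d$x)
  bs <- numeric(n_boot); lr <- numeric(n_boot)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(m, m, replace = TRUE)
      if (length(unique(idx)) >= 3) break
    }
    X <- cbind(1, d$x[idx])
    cf <- lm.fit(X, d$y[idx])$coefficients
    lr[b] <- cf[1]; bs[b] <- cf[2]
  }
  sig <- sigma_from_kT_nm2(bs, temperature)
  rho <- nm3_to_mgml(exp(lr), fit$chain_mass)
  fit$ci95_sigma <- unname(quantile(sig, c(0.025, 0.975)))
  fit$ci95_rho <- unname(quantile(rho, c(0.025, 0.975)))
  fit$boot_sigma <- sig
  fit$boot_rho <- rho
  fit$n_boot <- n_boot
  fit$seed <- seed
  fit
}

## save/restore global RNG state so seeded helpers do not perturb the
## caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
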