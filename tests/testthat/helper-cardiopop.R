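# shared fixtures, all generated in code

# concentration-response data from a known population Hill truth
make_hill_data <- function(n_donors = 16, ec50 = 10, emax = 0.5, hill_n = 1,
                           sigma_ec50 = 0.3, sigma_emax = 0, noise = 0.05,
                           concs = c(0.1, 1, 10, 100), reps = 1,
                           direction = "decrease", seed = 1) {
  set.seed(seed)
  donors <- sprintf("d%02d", seq_len(n_donors))
  z1 <- rnorm(n_donors)
  z2 <- rnorm(n_donors)
  dat <- tidyr::expand_grid(donor_id = donors, conc_uM = concs,
                            rep = seq_len(reps))
  di <- match(dat$donor_id, donors)
  ec_i <- ec50 * exp(sigma_ec50 * z1[di])
  em_i <- emax * exp(sigma_emax * z2[di])
  sgn <- if (direction == "increase") 1 else -1
  frac <- dat$conc_uM^hill_n / (ec_i^hill_n + dat$conc_uM^hill_n)
  dat$response_ratio <- 1 + sgn * em_i * frac + rnorm(nrow(dat), 0, noise)
  attr(dat, "z_ec50") <- z1
  dat
}

# population_posterior built directly from stated parameter distributions,
# for deterministic tests of the POD / TDVF / MOE arithmetic
fake_posterior <- function(n_draws = 1000, mu_log_ec50 = log(10),
                           mu_log_emax = log(0.5), log_hill_n = 0,
                           sigma_log_ec50 = 0, sigma_log_emax = 0,
                           sigma_resid = 0.05, n_donors = 4,
                           z = NULL, rhat_max = 1.0, converged = TRUE,
                           jitter = 0, seed = 1, direction = "decrease") {
  set.seed(seed)
  donors <- sprintf("d%02d", seq_len(n_donors))
  draws <- tibble::tibble(
    mu_log_ec50 = mu_log_ec50 + rnorm(n_draws, 0, jitter),
    mu_log_emax = pmin(mu_log_emax + rnorm(n_draws, 0, jitter), 0),
    log_hill_n = log_hill_n + rnorm(n_draws, 0, jitter),
    sigma_log_ec50 = rep(sigma_log_ec50, n_draws),
    sigma_log_emax = rep(sigma_log_emax, n_draws),
    sigma_resid = rep(sigma_resid, n_draws))
  zmat <- if (is.null(z)) matrix(0, n_draws, n_donors) else
    matrix(rep(z, each = n_draws), n_draws)
  colnames(zmat) <- donors
  rhat <- setNames(rep(1, 6), names(draws))
  structure(list(
    draws = draws, z_ec50 = zmat, z_emax = zmat * 0, donors = donors,
    direction = direction, rhat = rhat, rhat_max = rhat_max,
    converged = converged, n_chains = 4, n_iter = 2000,
    n_obs = 64, priors = hill_priors(), seed = seed
  ), class = "population_posterior")
}

# control-well data with planted donor / plate / residual variance components
sim_controls <- function(seed, sd_donor = 2, sd_resid = 1, sd_plate = 0,
                         n_donors = 16, n_wells = 20, media_shift = 0) {
  set.seed(seed)
  donors <- sprintf("d%02d", seq_len(n_donors))
  d_eff <- rnorm(n_donors, 0, sd_donor)
  out <- tidyr::expand_grid(donor_id = donors, well = seq_len(n_wells))
  di <- match(out$donor_id, donors)
  out$plate_id <- paste0(out$donor_id, "_p", 1 + (out$well %% 2))
  p_eff <- setNames(rnorm(length(unique(out$plate_id)), 0, sd_plate),
                    unique(out$plate_id))
  out$treatment_type <- ifelse(out$well <= 15, "vehicle", "media")
  out$value <- 25 + d_eff[di] + p_eff[out$plate_id] +
    ifelse(out$treatment_type == "media", media_shift, 0) +
    rnorm(nrow(out), 0, sd_resid)
  out
}

# small but complete study configuration for pipeline-level tests
small_config <- function(n_chem = 4, n_donors = 4, seed = 1, traces = FALSE,
                         ...) {
  chems <- pfas_registry()[seq_len(n_chem), ]
  study_config(n_donors = n_donors, chemicals = chems,
               intra_plate_replicates = chems$chemical_id[1:2],
               traces = traces, seed = seed, ...)
}

# brute-force references for the multiple-testing procedures
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}

holm_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# bisection root-finder oracle for the POD: invert hill_response numerically
pod_bisect <- function(ec50, emax, hill_n, b, direction = "decrease",
                       tol = 1e-12) {
  if (emax <= b) return(Inf)
  target <- if (direction == "decrease") 1 - b else 1 + b
  f <- function(c) hill_response(c, ec50, emax, hill_n, direction) - target
  lo <- ec50 * 1e-9; hi <- ec50 * 1e9
  if (sign(f(lo)) == sign(f(hi))) return(Inf)
  uniroot(f, c(lo, hi), tol = tol * ec50)$root
}
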