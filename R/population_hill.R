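#' Default weakly-informative priors for the population Hill model
#'
#' All parameters are fitted on the natural-log scale so they stay strictly
#' positive. The log-EC50 population median is centered mid-range of the
#' tested concentrations with SD 2; log-Emax is centered at log(0.2) with
#' SD 1 and upper-truncated at 0 (population-median Emax <= 1); the log Hill
#' coefficient is centered at 0 with SD 0.5; population SDs get half-normal(0,
#' 1) and the residual SD half-normal(0, 0.2) priors.
#'
#' @param concentrations_uM Tested concentrations, used to center the EC50
#'   prior.
#' @return Named list of prior hyperparameters.
#' @export
hill_priors <- function(concentrations_uM = c(0.1, 1, 10, 100)) {
  list(mu_log_ec50_mean = mean(log(range(concentrations_uM))),
       mu_log_ec50_sd = 2,
       mu_log_emax_mean = log(0.2), mu_log_emax_sd = 1,
       log_hill_n_mean = 0, log_hill_n_sd = 0.5,
       sigma_sd = 1, sigma_resid_sd = 0.2)
}

# draw overdispersed chain initial values from the priors
init_from_priors <- function(pr, n_donors) {
  mu2 <- -abs(rnorm(1, 0, pr$mu_log_emax_sd)) + min(pr$mu_log_emax_mean, 0)
  c(rnorm(1, pr$mu_log_ec50_mean, pr$mu_log_ec50_sd),
    min(mu2, -0.01),
    rnorm(1, pr$log_hill_n_mean, pr$log_hill_n_sd),
    log(abs(rnorm(1, 0, pr$sigma_sd)) + 0.05),
    log(abs(rnorm(1, 0, pr$sigma_sd)) + 0.05),
    log(abs(rnorm(1, 0, pr$sigma_resid_sd)) + 0.02),
    rnorm(2 * n_donors, 0, 0.5))
}

#' Rank-normalized split R-hat
#'
#' Potential scale reduction factor computed on rank-normalized draws after
#' splitting each chain in half, taking the larger of the bulk statistic and
#' the folded statistic (absolute deviations from the median, sensitive to
#' scale mismatch). Values near 1 indicate convergence; fits are accepted at
#' R-hat <= 1.2.
#'
#' @param draws Matrix of posterior draws, iterations x chains, for one
#'   parameter.
#' @return Scalar R-hat (1 when the draws are constant).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sp <- cbind(draws[seq_len(half), , drop = FALSE],
              draws[(n - half + 1):n, , drop = FALSE])
  base_rhat <- function(m) {
    if (all(m == m[1])) return(1)
    nn <- nrow(m)
    r <- matrix(rank(m, ties.method = "average"), nn)
    z <- qnorm((r - 3 / 8) / (length(m) + 1 / 4))
    w <- mean(apply(z, 2, var))
    b <- nn * var(colMeans(z))
    if (w == 0) return(1)
    sqrt(((nn - 1) / nn * w + b / nn) / w)
  }
  max(base_rhat(sp), base_rhat(abs(sp - median(sp))))
}

#' Fit the hierarchical Bayesian random-effects Hill model
#'
#' Fits vehicle-normalized concentration-response data for one chemical and
#' phenotype across donors. Donor random effects are lognormal on EC50 and
#' Emax (non-centered Z-scores); the Hill coefficient is shared across
#' donors; residual error is normal on the response-ratio scale. Sampling
#' uses four independent chains of an adaptive Metropolis-within-Gibbs
#' sampler; the first half of each chain is discarded, convergence is
#' diagnosed with rank-normalized split R-hat <= `rhat_threshold`, and the
#' iteration count is doubled (up to `max_iter`) until convergence. A
#' converged fit is subsampled to `n_subsample` retained draws
#' (`n_subsample / chains` per chain).
#'
#' @param data Tibble with columns `donor_id`, `conc_uM`, `response_ratio`.
#' @param direction `"increase"` or `"decrease"`: the direction of the
#'   phenotype change being modeled.
#' @param priors Prior list from [hill_priors()]; defaults to priors centered
#'   on the tested concentration range.
#' @param chains Number of chains (4).
#' @param iter Initial iterations per chain (8,000 in full mode; use 2,000
#'   for desk-scale work).
#' @param max_iter Iteration ceiling for the doubling schedule (32,000).
#' @param rhat_threshold Convergence threshold (1.2).
#' @param n_subsample Retained posterior draws after subsampling (1,000).
#' @param seed Integer seed controlling initialization, sampling and
#'   subsampling.
#' @return A `population_posterior` object: subsampled draws of the
#'   population-median log-parameters, population SDs, donor Z-scores and
#'   residual SD, with convergence metadata.
#' @export
fit_population <- function(data, direction,
                           priors = NULL,
                           chains = 4, iter = 8000, max_iter = 32000,
                           rhat_threshold = 1.2, n_subsample = 1000,
                           seed = 1L) {
  check_columns(data, c("donor_id", "conc_uM", "response_ratio"), "data")
  data <- dplyr::filter(data, is.finite(.data$response_ratio),
                        !is.na(.data$conc_uM))
  donors <- sort(unique(data$donor_id))
  if (length(donors) < 2) stop("need >= 2 donors to fit the population model")
  direction <- match.arg(direction, c("increase", "decrease"))
  pr <- priors %||% hill_priors(sort(unique(data$conc_uM[data$conc_uM > 0])))
  y <- data$response_ratio
  logc <- ifelse(data$conc_uM > 0, log(data$conc_uM), -Inf)
  donor_idx <- match(data$donor_id, donors) - 1L
  k <- length(donors)
  p_vec <- c(pr$mu_log_ec50_mean, pr$mu_log_ec50_sd,
             pr$mu_log_emax_mean, pr$mu_log_emax_sd,
             pr$log_hill_n_mean, pr$log_hill_n_sd,
             pr$sigma_sd, pr$sigma_resid_sd)
  sgn <- if (direction == "increase") 1 else -1
  set.seed(seed)

  it <- iter
  repeat {
    chain_draws <- lapply(seq_len(chains), function(ch) {
      hill_mcmc_chain(y, logc, donor_idx, k, sgn, it, p_vec,
                      init_from_priors(pr, k))$draws
    })
    n_par <- ncol(chain_draws[[1]])
    rhat <- vapply(seq_len(n_par), function(j) {
      split_rhat(vapply(chain_draws, function(m) m[, j],
                        numeric(nrow(chain_draws[[1]]))))
    }, numeric(1))
    rhat_max <- max(rhat, na.rm = TRUE)
    if (rhat_max <= rhat_threshold || it >= max_iter) break
    it <- min(it * 2, max_iter)
  }
  converged <- rhat_max <= rhat_threshold

  per_chain <- max(1, floor(n_subsample / chains))
  sub <- do.call(rbind, lapply(chain_draws, function(m) {
    m[sample.int(nrow(m), min(per_chain, nrow(m))), , drop = FALSE]
  }))
  param_names <- c("mu_log_ec50", "mu_log_emax", "log_hill_n",
                   "log_sigma_ec50", "log_sigma_emax", "log_sigma_resid",
                   paste0("z_ec50.", donors), paste0("z_emax.", donors))
  colnames(sub) <- param_names
  names(rhat) <- param_names
  draws <- tibble::tibble(
    mu_log_ec50 = sub[, "mu_log_ec50"],
    mu_log_emax = sub[, "mu_log_emax"],
    log_hill_n = sub[, "log_hill_n"],
    sigma_log_ec50 = exp(sub[, "log_sigma_ec50"]),
    sigma_log_emax = exp(sub[, "log_sigma_emax"]),
    sigma_resid = exp(sub[, "log_sigma_resid"]))
  structure(list(
    draws = draws,
    z_ec50 = sub[, paste0("z_ec50.", donors), drop = FALSE],
    z_emax = sub[, paste0("z_emax.", donors), drop = FALSE],
    donors = donors, direction = direction,
    rhat = rhat, rhat_max = rhat_max, converged = converged,
    n_chains = chains, n_iter = it, n_obs = length(y),
    priors = pr, seed = seed
  ), class = "population_posterior")
}

#' @export
print.population_posterior <- function(x, ...) {
  cat(sprintf(
    "<population_posterior> %d draws, %d donors, direction %s\n  chains %d x %d iter, max R-hat %.3f (%s)\n",
    nrow(x$draws), length(x$donors), x$direction, x$n_chains, x$n_iter,
    x$rhat_max, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
tidy.population_posterior <- function(x, ...) {
  core <- x$draws
  tibble::tibble(
    term = names(core),
    estimate = vapply(core, median, numeric(1)),
    conf.low = vapply(core, quantile, numeric(1), probs = 0.05),
    conf.high = vapply(core, quantile, numeric(1), probs = 0.95),
    rhat = unname(x$rhat[c("mu_log_ec50", "mu_log_emax", "log_hill_n",
                           "log_sigma_ec50", "log_sigma_emax",
                           "log_sigma_resid")]))
}

#' @export
glance.population_posterior <- function(x, ...) {
  tibble::tibble(n_draws = nrow(x$draws), n_donors = length(x$donors),
                 n_obs = x$n_obs, n_chains = x$n_chains, n_iter = x$n_iter,
                 rhat_max = x$rhat_max, converged = x$converged)
}

# empirical (type-1) quantile: robust to censored (+Inf) values because no
# interpolation with Inf ever occurs
quantile_type1 <- function(v, p) {
  v <- sort(v)  # drops NA, keeps Inf at the top
  v[pmax(1L, ceiling(p * length(v)))]
}

#' Points of departure from a fitted population posterior
#'
#' For every posterior draw, derives (i) the median individual's POD from the
#' population-median parameters, (ii) each donor's POD from the donor-level
#' parameters, and (iii) the sensitive-individual POD as the empirical 5th
#' percentile of POD over `n_virtual` simulated individuals drawn from the
#' random-effect distribution. PODs unreachable within the fitted Emax are
#' censored at `Inf`; a summary is flagged censored when more than half of
#' its draws are censored. Summaries are posterior medians with 90% credible
#' intervals (5th-95th percentile of draws).
#'
#' @param posterior A `population_posterior` from [fit_population()].
#' @param benchmark_change Benchmark fractional change in (0,1) (0.05 for
#'   chronotropes and the QT proxy, 0.95 for asystole, 0.10 for
#'   cytotoxicity).
#' @param benchmark Label for the benchmark (e.g. `"EC05"`).
#' @param n_virtual Virtual individuals per draw for the population 5th
#'   percentile (1,000).
#' @param seed Seed for the virtual-individual draws.
#' @return A `pod_set` object with elements `summary` (one row), `donor_pods`
#'   and draw-level vectors for downstream analyses.
#' @export
pods_from_posterior <- function(posterior, benchmark_change,
                                benchmark = NULL, n_virtual = 1000,
                                seed = 1L) {
  stopifnot(inherits(posterior, "population_posterior"))
  b <- benchmark_change
  stopifnot(b > 0, b < 1)
  d <- posterior$draws
  nd <- nrow(d)
  hill_n <- exp(d$log_hill_n)
  pod_median_draws <- pod_from_hill(exp(d$mu_log_ec50), exp(d$mu_log_emax),
                                    hill_n, b)
  donors <- posterior$donors
  ec50_don <- exp(d$mu_log_ec50 + d$sigma_log_ec50 * posterior$z_ec50)
  emax_don <- exp(d$mu_log_emax + d$sigma_log_emax * posterior$z_emax)
  donor_pod_draws <- matrix(
    pod_from_hill(as.numeric(ec50_don), as.numeric(emax_don),
                  rep(hill_n, length(donors)), b),
    nrow = nd, dimnames = list(NULL, donors))

  set.seed(seed)
  z1 <- matrix(rnorm(nd * n_virtual), nd)
  z2 <- matrix(rnorm(nd * n_virtual), nd)
  ec50_v <- exp(d$mu_log_ec50 + d$sigma_log_ec50 * z1)
  emax_v <- exp(d$mu_log_emax + d$sigma_log_emax * z2)
  pod_v <- ec50_v * (b / (emax_v - b))^(1 / hill_n)
  pod_v[emax_v <= b] <- Inf
  pod_p05_draws <- vapply(seq_len(nd), function(i) {
    quantile_type1(pod_v[i, ], 0.05)
  }, numeric(1))

  summ <- tibble::tibble(
    benchmark = benchmark %||% sprintf("EC%02d", round(100 * b)),
    benchmark_change = b,
    pod_median = quantile_type1(pod_median_draws, 0.5),
    pod_median_ci90_lo = quantile_type1(pod_median_draws, 0.05),
    pod_median_ci90_hi = quantile_type1(pod_median_draws, 0.95),
    pod_p05 = quantile_type1(pod_p05_draws, 0.5),
    pod_p05_ci90_lo = quantile_type1(pod_p05_draws, 0.05),
    pod_p05_ci90_hi = quantile_type1(pod_p05_draws, 0.95),
    censored_fraction_median = mean(!is.finite(pod_median_draws)),
    censored_fraction_p05 = mean(!is.finite(pod_p05_draws)),
    censored = mean(!is.finite(pod_median_draws)) > 0.5,
    rhat_max = posterior$rhat_max,
    converged = posterior$converged)
  donor_tbl <- tibble::tibble(
    donor_id = donors,
    pod = apply(donor_pod_draws, 2, quantile_type1, p = 0.5),
    pod_ci90_lo = apply(donor_pod_draws, 2, quantile_type1, p = 0.05),
    pod_ci90_hi = apply(donor_pod_draws, 2, quantile_type1, p = 0.95),
    censored_fraction = colMeans(!is.finite(donor_pod_draws)))
  structure(list(
    summary = summ, donor_pods = donor_tbl,
    draws = list(pod_median = pod_median_draws, pod_p05 = pod_p05_draws,
                 donor = donor_pod_draws),
    benchmark_change = b, direction = posterior$direction,
    n_virtual = n_virtual
  ), class = "pod_set")
}

#' @export
print.pod_set <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<pod_set> %s: median-individual POD %.3g uM [%.3g, %.3g], sensitive (5th %%ile) %.3g uM%s\n",
    s$benchmark, s$pod_median, s$pod_median_ci90_lo, s$pod_median_ci90_hi,
    s$pod_p05, if (s$censored) " (censored)" else ""))
  invisible(x)
}

#' @export
tidy.pod_set <- function(x, ...) x$donor_pods

#' @export
glance.pod_set <- function(x, ...) x$summary
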