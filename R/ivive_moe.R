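#' Fit a lognormal exposure distribution from median and upper 95th bound
#'
#' Exposure estimates arrive as the median and 95th-percentile confidence
#' bound of predicted population-median oral exposure (mg/kg BW/day) and are
#' fit to the lognormal matching both quantiles exactly:
#' `mu = ln(median)`, `sigma = (ln(upper95) - ln(median)) / 1.6449`.
#'
#' @param median_exposure,upper95 Positive scalars (or vectors), with
#'   `upper95 >= median_exposure`; equality gives a point mass.
#' @return Tibble with columns `mu`, `sigma` of the log-exposure.
#' @export
fit_exposure_lognormal <- function(median_exposure, upper95) {
  stopifnot(all(median_exposure > 0), all(upper95 >= median_exposure))
  tibble::tibble(mu = log(median_exposure),
                 sigma = (log(upper95) - log(median_exposure)) / qnorm(0.95))
}

#' Default physiological constants for the steady-state model
#'
#' Glomerular filtration rate 1.53 mL/min/kg (0.0918 L/h/kg) and liver blood
#' flow 1.24 L/h/kg, per-kilogram-of-body-weight basis.
#'
#' @return Named list `gfr_perkg`, `q_liver_perkg` (L/h/kg).
#' @export
tk_physiology <- function() {
  list(gfr_perkg = 1.53 * 60 / 1000, q_liver_perkg = 1.24)
}

#' Steady-state plasma concentration per unit oral dose
#'
#' Well-stirred three-compartment steady-state model under chronic daily oral
#' dosing of 1 mg/kg BW/day: the molar dose rate `D = 1000 / mw` µmol/kg/day
#' is divided by total clearance
#' `CL = fup * GFR * 24 + 24 * (Q_liver * fup * Clint) / (Q_liver + fup * Clint)`
#' in L/day/kg. Method `"no_hepatic_clearance"` forces `Clint = 0`, leaving
#' renal filtration of the unbound fraction only.
#'
#' @param tk Tibble/list with `mw` (g/mol), `fup` (fraction unbound, in
#'   (0, 1]), `clint` (intrinsic hepatic clearance, L/h/kg), and optionally
#'   `gfr_perkg`, `q_liver_perkg` (L/h/kg; defaults from [tk_physiology()]).
#' @param method `"steady_state_3c"` or `"no_hepatic_clearance"`.
#' @return Numeric vector: Css in µM per 1 mg/kg BW/day. `fup = 0` gives
#'   `Inf` (flagged downstream; the chemical is excluded from MOE).
#' @export
css_per_unit_dose <- function(tk, method = c("steady_state_3c",
                                             "no_hepatic_clearance")) {
  method <- match.arg(method)
  phys <- tk_physiology()
  mw <- tk$mw
  fup <- tk$fup
  clint <- if (method == "no_hepatic_clearance") 0 else tk$clint
  gfr <- tk$gfr_perkg %||% phys$gfr_perkg
  q <- tk$q_liver_perkg %||% phys$q_liver_perkg
  stopifnot(all(mw > 0), all(fup >= 0), all(fup <= 1))
  d_umol <- 1000 / mw
  cl_renal <- fup * gfr * 24
  cl_hep <- 24 * (q * fup * clint) / (q + fup * clint)
  cl_hep[fup * clint == 0] <- 0
  cl <- cl_renal + cl_hep
  out <- d_umol / cl
  out[cl == 0] <- Inf
  out
}

moe_band <- function(moe) {
  dplyr::case_when(is.na(moe) ~ NA_character_,
                   moe < 1 ~ "<1",
                   moe < 100 ~ "1-100",
                   TRUE ~ ">=100")
}

# random-individual POD draws: one virtual individual's Z per posterior draw
random_individual_pods <- function(posterior, benchmark_change) {
  d <- posterior$draws
  nd <- nrow(d)
  z1 <- rnorm(nd); z2 <- rnorm(nd)
  ec50 <- exp(d$mu_log_ec50 + d$sigma_log_ec50 * z1)
  emax <- exp(d$mu_log_emax + d$sigma_log_emax * z2)
  pod_from_hill(ec50, emax, exp(d$log_hill_n), benchmark_change)
}

#' Probabilistic margins of exposure for one chemical
#'
#' Monte-Carlo in vitro-to-in vivo extrapolation. For each active phenotype
#' and each internal-concentration method, the margin of exposure is the 5th
#' percentile of the POD distribution divided by the 95th percentile of the
#' internal concentration distribution: `moe_population_median` uses the
#' posterior distribution of the median individual's POD,
#' `moe_random_individual` uses per-draw virtual individuals sampled from the
#' population medians, variances and Z-scores. Internal concentrations come
#' from lognormal Monte-Carlo oral-exposure samples multiplied by the Css per
#' unit dose under (i) the well-stirred three-compartment steady state and
#' (ii) the no-hepatic-clearance assumption; a biomonitoring range, when
#' present, is used directly as the internal concentration (its upper bound
#' is the 95th percentile). `min_moe` is the minimum over active phenotypes
#' and methods, banded at the conventional thresholds (< 1 of concern, 1-100
#' of potential concern, >= 100 protective).
#'
#' @param pod_sets Named list of `pod_set` objects for the chemical's active
#'   phenotypes.
#' @param posteriors Named list of the matching `population_posterior`
#'   objects (same names).
#' @param exposure One-row tibble: `oral_median`, `oral_upper95`, optionally
#'   `biomonitoring_lo`, `biomonitoring_hi` (µM).
#' @param tk One-row tibble of toxicokinetic parameters (see
#'   [css_per_unit_dose()]).
#' @param n_mc Monte-Carlo sample size for the exposure distribution
#'   (10,000).
#' @param seed Seed for all Monte-Carlo draws.
#' @param popvar Named logical (same names as `pod_sets`): did the phenotype
#'   qualify for population-variability analysis? The random-individual MOE
#'   is only derived where `TRUE` (`NA` otherwise).
#' @return Tibble with one row per phenotype x method; `min_moe` and `band`
#'   columns are identical across rows.
#' @export
compute_moe <- function(pod_sets, posteriors, exposure, tk,
                        n_mc = 10000, seed = 1L,
                        popvar = setNames(rep(TRUE, length(pod_sets)),
                                          names(pod_sets))) {
  stopifnot(length(pod_sets) >= 1, !is.null(names(pod_sets)),
            all(names(pod_sets) %in% names(posteriors)))
  if (!is.finite(exposure$oral_median) || exposure$oral_median <= 0) {
    stop("no usable oral exposure estimate")
  }
  if (!is.finite(tk$fup) || tk$fup <= 0) {
    stop("fraction unbound is zero: Css infinite, chemical excluded")
  }
  set.seed(seed)
  ln <- fit_exposure_lognormal(exposure$oral_median, exposure$oral_upper95)
  dose <- if (ln$sigma > 0) rlnorm(n_mc, ln$mu, ln$sigma)
          else rep(exposure$oral_median, n_mc)
  methods <- c(steady_state_3c = css_per_unit_dose(tk, "steady_state_3c"),
               no_hepatic_clearance = css_per_unit_dose(tk,
                                                        "no_hepatic_clearance"))
  conc_q95 <- vapply(methods, function(f) quantile_type1(dose * f, 0.95),
                     numeric(1))
  has_biomon <- !is.null(exposure$biomonitoring_hi) &&
    is.finite(exposure$biomonitoring_hi)
  if (has_biomon) {
    conc_q95 <- c(conc_q95, biomonitoring = exposure$biomonitoring_hi)
  }
  rows <- purrr::map_dfr(names(pod_sets), function(ph) {
    ps <- pod_sets[[ph]]
    med_draws <- ps$draws$pod_median
    if (all(!is.finite(med_draws))) return(NULL)
    pod_q05_med <- quantile_type1(med_draws, 0.05)
    pod_q05_rnd <- if (isTRUE(popvar[[ph]])) {
      rnd_draws <- random_individual_pods(posteriors[[ph]],
                                          ps$benchmark_change)
      quantile_type1(rnd_draws, 0.05)
    } else NA_real_
    purrr::map_dfr(names(conc_q95), function(m) {
      tibble::tibble(
        phenotype = ph, method = m,
        internal_conc_q95 = unname(conc_q95[m]),
        moe_population_median = pod_q05_med / conc_q95[[m]],
        moe_random_individual = pod_q05_rnd / conc_q95[[m]])
    })
  })
  if (nrow(rows) == 0) stop("all PODs censored: MOE undefined")
  min_moe <- min(c(rows$moe_population_median, rows$moe_random_individual),
                 na.rm = TRUE)
  rows$min_moe <- min_moe
  rows$band <- moe_band(min_moe)
  rows
}
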