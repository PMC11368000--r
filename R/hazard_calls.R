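#' Activity and population-variability criteria for one chemical-phenotype fit
#'
#' Applies the four activity criteria and the three additional
#' population-variability criteria:
#' (i) adequate convergence, R-hat <= 1.2; (ii) model-fit coefficient of
#' variability < 20%; (iii) median-individual POD below 3x the maximum tested
#' concentration (300 µM at the 100 µM default); (iv) posterior 5th
#' percentile of Emax above a 10% change. A combination passing all four is
#' `active`. Additionally: (5) the 90% CI of the population-median POD spans
#' < 100-fold; (6) the 90% CI of the sensitive (5th percentile) POD spans
#' < 100-fold; (7) at least half of the donors have non-zero data at three or
#' more concentrations. Passing all seven gives `active_popvar`, the
#' precondition for deriving a toxicodynamic variability factor.
#'
#' @param pod_set A [pods_from_posterior()] result.
#' @param posterior The matching `population_posterior`.
#' @param data_coverage Fraction of donors with non-zero (usable) data at >=
#'   3 concentrations.
#' @param max_conc_uM Maximum tested concentration (100).
#' @param thresholds Named list overriding the defaults
#'   (`rhat = 1.2, fit_cv = 20, pod_factor = 3, emax_p05 = 0.10,
#'   ci_span = 100, coverage = 0.5`).
#' @param fit_cv_method `"residual"` (posterior median residual SD as % of
#'   the control-normalized response; default) or `"pod"` (posterior CV of
#'   the median-individual POD) — the paper's criterion (ii) is ambiguous
#'   between the two.
#' @return One-row tibble with the seven criterion flags, the quantities they
#'   test, and `status` in `inactive` / `active` / `active_popvar`.
#' @export
call_activity <- function(pod_set, posterior, data_coverage,
                          max_conc_uM = 100,
                          thresholds = list(),
                          fit_cv_method = c("residual", "pod")) {
  fit_cv_method <- match.arg(fit_cv_method)
  th <- modifyList(list(rhat = 1.2, fit_cv = 20, pod_factor = 3,
                        emax_p05 = 0.10, ci_span = 100, coverage = 0.5),
                   thresholds)
  if (is.null(posterior)) {
    return(tibble::tibble(
      c1_convergence = FALSE, c2_cv_fit = FALSE, c3_pod_range = FALSE,
      c4_emax = FALSE, v5_median_ci_span = FALSE, v6_sensitive_ci_span = FALSE,
      v7_data_coverage = FALSE, fit_cv = NA_real_, emax_p05 = NA_real_,
      median_ci_span = NA_real_, sensitive_ci_span = NA_real_,
      data_coverage = NA_real_, status = "inactive",
      reason = "no posterior available"))
  }
  s <- pod_set$summary
  fit_cv <- if (fit_cv_method == "residual") {
    100 * median(posterior$draws$sigma_resid)
  } else {
    pd <- pod_set$draws$pod_median
    pd <- pd[is.finite(pd)]
    if (length(pd) < 2) Inf else 100 * sd(pd) / mean(pd)
  }
  emax_p05 <- quantile_type1(exp(posterior$draws$mu_log_emax), 0.05)
  span_med <- s$pod_median_ci90_hi / s$pod_median_ci90_lo
  span_p05 <- s$pod_p05_ci90_hi / s$pod_p05_ci90_lo
  c1 <- is.finite(s$rhat_max) && s$rhat_max <= th$rhat
  c2 <- is.finite(fit_cv) && fit_cv < th$fit_cv
  c3 <- is.finite(s$pod_median) && s$pod_median < th$pod_factor * max_conc_uM
  c4 <- emax_p05 > th$emax_p05
  v5 <- is.finite(span_med) && span_med < th$ci_span
  v6 <- is.finite(span_p05) && span_p05 < th$ci_span
  v7 <- is.finite(data_coverage) && data_coverage >= th$coverage
  active <- c1 && c2 && c3 && c4
  status <- if (!active) "inactive" else if (v5 && v6 && v7) "active_popvar"
            else "active"
  tibble::tibble(
    c1_convergence = c1, c2_cv_fit = c2, c3_pod_range = c3, c4_emax = c4,
    v5_median_ci_span = v5, v6_sensitive_ci_span = v6, v7_data_coverage = v7,
    fit_cv = fit_cv, emax_p05 = unname(emax_p05),
    median_ci_span = span_med, sensitive_ci_span = span_p05,
    data_coverage = data_coverage, status = status, reason = NA_character_)
}

#' Toxicodynamic variability factor (TDVF05)
#'
#' The TDVF05 is the ratio of the median individual's POD to the sensitive
#' (population 5th percentile) individual's POD, computed draw-wise (the
#' posterior ratio, not the ratio of posterior summaries, preserving the
#' draw-wise ordering POD_p05 <= POD_median). Draws with a censored sensitive
#' POD are excluded and their fraction recorded. The summary is the posterior
#' median with a 90% CI, plus membership in the bands below / within / above
#' the default toxicodynamic uncertainty factor range `10^(1/2)` to 10.
#'
#' @param pod_set A [pods_from_posterior()] result (for an `active_popvar`
#'   combination).
#' @return One-row tibble: `tdvf05`, `tdvf05_ci90_lo`, `tdvf05_ci90_hi`,
#'   `excluded_fraction`, `band`.
#' @export
tdvf05 <- function(pod_set) {
  stopifnot(inherits(pod_set, "pod_set"))
  num <- pod_set$draws$pod_median
  den <- pod_set$draws$pod_p05
  ok <- is.finite(den) & is.finite(num)
  excluded <- mean(!ok)
  if (!any(ok)) {
    return(tibble::tibble(tdvf05 = NA_real_, tdvf05_ci90_lo = NA_real_,
                          tdvf05_ci90_hi = NA_real_,
                          excluded_fraction = excluded, band = NA_character_))
  }
  r <- num[ok] / den[ok]
  est <- quantile_type1(r, 0.5)
  tibble::tibble(
    tdvf05 = est,
    tdvf05_ci90_lo = quantile_type1(r, 0.05),
    tdvf05_ci90_hi = quantile_type1(r, 0.95),
    excluded_fraction = excluded,
    band = tdvf_band(est))
}

#' Classify a TDVF value against the default uncertainty-factor bands
#'
#' Bands: below `10^(1/2)` (= 3.16, the default toxicodynamic half-log
#' factor), between `10^(1/2)` and 10, and above 10.
#'
#' @param tdvf Numeric vector of TDVF values.
#' @return Character vector in `c("<10^(1/2)", "10^(1/2)-10", ">10")`.
#' @export
tdvf_band <- function(tdvf) {
  dplyr::case_when(
    is.na(tdvf) ~ NA_character_,
    tdvf < 10^0.5 ~ "<10^(1/2)",
    tdvf <= 10 ~ "10^(1/2)-10",
    TRUE ~ ">10")
}
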