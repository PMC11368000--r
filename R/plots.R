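#' Plot donor-specific PODs from a fitted pod_set
#'
#' Forest-style plot of the posterior median POD per donor with 90% credible
#' intervals, plus the population-median and sensitive-individual PODs as
#' reference lines.
#'
#' @param object A `pod_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pod_set <- function(object, ...) {
  dp <- object$donor_pods
  dp <- dp[is.finite(dp$pod), ]
  s <- object$summary
  ggplot2::ggplot(dp, ggplot2::aes(x = .data$pod, y = .data$donor_id)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$pod_ci90_lo,
                                          xmax = .data$pod_ci90_hi),
                             linewidth = 0.3, size = 0.3) +
    ggplot2::geom_vline(xintercept = s$pod_median, linetype = 2,
                        color = "steelblue") +
    ggplot2::geom_vline(xintercept = s$pod_p05, linetype = 3,
                        color = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = sprintf("POD (%s), µM", s$benchmark),
                  y = NULL,
                  title = "Donor-specific points of departure",
                  subtitle = "dashed: population median; dotted: sensitive 5th %ile") +
    ggplot2::theme_minimal()
}

#' Concentration-response plot of a population Hill fit
#'
#' Normalized responses per donor with the posterior-median population curve
#' and a draw ribbon.
#'
#' @param posterior A `population_posterior`.
#' @param data The fitted tibble (`donor_id`, `conc_uM`, `response_ratio`).
#' @param n_curve Number of concentrations for the curve grid.
#' @return A ggplot object.
#' @export
plot_concentration_response <- function(posterior, data, n_curve = 60) {
  d <- posterior$draws
  concs <- data$conc_uM[data$conc_uM > 0]
  grid <- 10^seq(log10(min(concs)) - 0.5, log10(max(concs)) + 0.5,
                 length.out = n_curve)
  med <- apply(vapply(seq_len(nrow(d)), function(i) {
    hill_response(grid, exp(d$mu_log_ec50[i]), exp(d$mu_log_emax[i]),
                  exp(d$log_hill_n[i]), posterior$direction)
  }, numeric(n_curve)), 1, quantile, probs = c(0.05, 0.5, 0.95))
  curve <- tibble::tibble(conc_uM = grid, lo = med[1, ], mid = med[2, ],
                          hi = med[3, ])
  ggplot2::ggplot(data, ggplot2::aes(x = .data$conc_uM,
                                     y = .data$response_ratio)) +
    ggplot2::geom_ribbon(data = curve,
                         ggplot2::aes(x = .data$conc_uM, ymin = .data$lo,
                                      ymax = .data$hi),
                         inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$conc_uM, y = .data$mid),
                       inherit.aes = FALSE, color = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(color = .data$donor_id), alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::guides(color = "none") +
    ggplot2::labs(x = "Concentration, µM",
                  y = "Response ratio (vehicle = 1)") +
    ggplot2::theme_minimal()
}

#' Bar chart of ToxPi scores
#'
#' @param toxpi Output of [toxpi_scores()].
#' @param top_n Show the top-ranked chemicals only.
#' @return A ggplot object.
#' @export
plot_toxpi <- function(toxpi, top_n = 20) {
  slices <- grep("^score_", names(toxpi), value = TRUE)
  df <- toxpi |>
    dplyr::slice_min(.data$rank, n = top_n) |>
    tidyr::pivot_longer(dplyr::all_of(slices), names_to = "slice",
                        values_to = "score") |>
    dplyr::mutate(slice = sub("^score_", "", .data$slice))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$score / length(slices),
    y = stats::reorder(.data$chemical_id, -.data$rank),
    fill = .data$slice)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "ToxPi score (weighted slice contributions)", y = NULL,
                  fill = "Phenotype") +
    ggplot2::theme_minimal()
}

#' Stacked variance-component fractions per phenotype
#'
#' @param vd Output of the variance-decomposition QC stage (one row per
#'   phenotype).
#' @return A ggplot object.
#' @export
plot_variance_decomposition <- function(vd) {
  df <- vd |>
    tidyr::pivot_longer(dplyr::starts_with("frac_"), names_to = "component",
                        values_to = "fraction") |>
    dplyr::mutate(component = sub("^frac_", "", .data$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phenotype, y = .data$fraction,
                                   fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Fraction of total variance",
                  fill = "Component") +
    ggplot2::theme_minimal()
}

#' Margins of exposure by chemical with risk bands
#'
#' @param moe Output of the MOE stage (`chemical_id`, `method`,
#'   `moe_population_median`, `moe_random_individual`).
#' @return A ggplot object.
#' @export
plot_moe <- function(moe) {
  df <- moe |>
    tidyr::pivot_longer(c("moe_population_median", "moe_random_individual"),
                        names_to = "type", values_to = "moe") |>
    dplyr::filter(is.finite(.data$moe)) |>
    dplyr::mutate(type = sub("^moe_", "", .data$type))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$moe,
    y = stats::reorder(.data$chemical_id, .data$moe, FUN = min),
    color = .data$type, shape = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 1, color = "firebrick", linetype = 2) +
    ggplot2::geom_vline(xintercept = 100, color = "steelblue", linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Margin of exposure", y = NULL, color = "POD type",
                  shape = "Internal concentration") +
    ggplot2::theme_minimal()
}
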