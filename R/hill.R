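#' Expected response ratio under the normalized Hill model
#'
#' Concentration-response curves are modeled on the vehicle-normalized ratio
#' scale, anchored at 1.0 for untreated wells. The maximal fractional change
#' `emax` is approached as concentration grows, with half of it reached at
#' `ec50_uM`:
#' \deqn{r(c) = 1 \pm \frac{E_{max} \, c^{n}}{EC_{50}^{n} + c^{n}}}
#' The sign is `+` for phenotypes that increase with dose (e.g. positive
#' chronotropy) and `-` for decreasing phenotypes (e.g. cytotoxicity).
#'
#' @param conc_uM Numeric vector of concentrations (µM), `>= 0`.
#' @param ec50_uM Half-maximal concentration (µM), `> 0`.
#' @param emax Maximal fractional change from control, `> 0` (and `<= 1` for
#'   decreasing phenotypes so the ratio stays non-negative).
#' @param hill_n Hill coefficient, `> 0`.
#' @param direction `"increase"` or `"decrease"`.
#' @return Numeric vector of expected response ratios (1 = control level).
#' @examples
#' hill_response(10, ec50_uM = 10, emax = 0.5, hill_n = 1,
#'               direction = "decrease")  # 0.75
#' @export
hill_response <- function(conc_uM, ec50_uM, emax, hill_n,
                          direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  stopifnot(all(conc_uM >= 0), ec50_uM > 0, emax > 0, hill_n > 0)
  sgn <- if (direction == "increase") 1 else -1
  frac <- conc_uM^hill_n / (ec50_uM^hill_n + conc_uM^hill_n)
  frac[conc_uM == 0] <- 0  # guard 0^n / (e^n + 0^n) when n is tiny
  1 + sgn * emax * frac
}

#' Point of departure from Hill parameters
#'
#' The POD is the concentration producing a stated benchmark fractional change
#' from control (EC05 for chronotropy and QT-proxy phenotypes, EC95 for
#' asystole, EC10 for cytotoxicity). Inverting the Hill curve gives the closed
#' form
#' \deqn{POD = EC_{50} \left(\frac{b}{E_{max} - b}\right)^{1/n}}
#' where `b` is the benchmark change. When `emax <= b` the benchmark is never
#' reached and the POD is censored at `Inf`.
#'
#' @inheritParams hill_response
#' @param benchmark_change Benchmark fractional change in (0, 1), e.g. 0.05.
#' @return Numeric vector of PODs in µM; `Inf` where censored. Vectorized over
#'   the parameter arguments.
#' @examples
#' pod_from_hill(10, 0.5, 1, 0.05)   # 10 * (0.05/0.45) = 1.111...
#' pod_from_hill(50, 1.0, 2, 0.95)   # 50 * sqrt(19)
#' pod_from_hill(10, 0.04, 1, 0.05)  # Inf (benchmark unreachable)
#' @export
pod_from_hill <- function(ec50_uM, emax, hill_n, benchmark_change) {
  stopifnot(benchmark_change > 0, benchmark_change < 1)
  n <- max(length(ec50_uM), length(emax), length(hill_n))
  ec50_uM <- rep_len(ec50_uM, n)
  emax <- rep_len(emax, n)
  hill_n <- rep_len(hill_n, n)
  out <- rep_len(Inf, n)
  ok <- emax > benchmark_change
  out[ok] <- ec50_uM[ok] *
    (benchmark_change / (emax[ok] - benchmark_change))^(1 / hill_n[ok])
  out
}

#' Phenotype channels scored by the assay
#'
#' Five phenotypes are modeled per chemical: positive and negative chronotropy
#' (EC05 on the beat-rate ratio, increasing resp. decreasing), QT-prolongation
#' proxy (EC05 on the decay-to-rise ratio, increasing), asystole (EC95 on the
#' beat-rate ratio, decreasing) and cytotoxicity (EC10 on the nuclei-count
#' ratio, decreasing).
#'
#' @return Tibble with columns `phenotype`, `measure`, `direction`,
#'   `benchmark`, `benchmark_change`.
#' @export
phenotype_channels <- function() {
  tibble::tribble(
    ~phenotype,        ~measure,        ~direction,  ~benchmark, ~benchmark_change,
    "chronotrope_pos", "beat_rate",     "increase",  "EC05",     0.05,
    "chronotrope_neg", "beat_rate",     "decrease",  "EC05",     0.05,
    "qt_prolongation", "decay_to_rise", "increase",  "EC05",     0.05,
    "asystole",        "beat_rate",     "decrease",  "EC95",     0.95,
    "cytotoxicity",    "nuclei",        "decrease",  "EC10",     0.10
  )
}
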