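#' Detect calcium-transient peaks in a fluorescence trace
#'
#' Peaks are local maxima whose topographic prominence is at least
#' `min_prominence_frac` of the trace range, thinned so that retained peaks
#' are separated by at least `min_period_s` (taller peaks win). The default
#' separation of 0.25 s corresponds to a 240 bpm ceiling. Detection is fully
#' deterministic; a constant trace yields no peaks.
#'
#' @param x Numeric vector of fluorescence samples.
#' @param rate_hz Sampling rate (frames per second).
#' @param min_prominence_frac Minimum prominence as a fraction of the trace
#'   range (max - min).
#' @param min_period_s Minimum separation between retained peaks in seconds.
#' @param smooth_window Moving-average window (frames, odd) applied before
#'   candidate detection to suppress single-frame noise spikes; the trace
#'   itself is never modified. 1 disables smoothing.
#' @return Integer vector of peak indices (1-based), sorted increasing.
#' @export
detect_peaks <- function(x, rate_hz = 8, min_prominence_frac = 0.2,
                         min_period_s = 0.25, smooth_window = 3) {
  stopifnot(is.numeric(x), all(is.finite(x)), rate_hz > 0,
            smooth_window >= 1, smooth_window %% 2 == 1)
  n <- length(x)
  if (n < 3) return(integer(0))
  x_raw <- x
  half <- (smooth_window - 1L) %/% 2L
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    xs <- as.numeric(stats::filter(x, k, sides = 2))
    xs[seq_len(half)] <- x[seq_len(half)]
    xs[(n - half + 1L):n] <- x[(n - half + 1L):n]
    x <- xs
  }
  rng <- max(x) - min(x)
  if (rng == 0) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    lmin <- h; j <- i - 1L
    while (j >= 1L && x[j] <= h) { if (x[j] < lmin) lmin <- x[j]; j <- j - 1L }
    rmin <- h; j <- i + 1L
    while (j <= n && x[j] <= h) { if (x[j] < rmin) rmin <- x[j]; j <- j + 1L }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence_frac * rng]
  # snap each detected peak to the raw local maximum within the smoothing
  # window so kinetics measured on the raw trace see the true peak frame
  if (half > 0L && length(keep)) {
    keep <- vapply(keep, function(i) {
      win <- max(1L, i - half):min(n, i + half)
      win[which.max(x_raw[win])]
    }, integer(1))
    keep <- unique(keep)
  }
  if (length(keep) <= 1) return(keep)
  # enforce refractory period, keeping the taller of any close pair
  min_gap <- min_period_s * rate_hz
  ord <- keep[order(-x_raw[keep], keep)]
  sel <- integer(0)
  for (i in ord) {
    if (!length(sel) || all(abs(sel - i) >= min_gap)) sel <- c(sel, i)
  }
  sort(sel)
}

# per-beat rise/decay times at the 10%-of-prominence baseline crossing;
# beats whose crossings fall outside the recording window are excluded
beat_kinetics <- function(x, peaks, rate_hz) {
  if (length(peaks) == 0) return(tibble::tibble(rise_s = numeric(),
                                                decay_s = numeric()))
  n <- length(x)
  bounds_l <- c(1L, peaks[-length(peaks)])
  bounds_r <- c(peaks[-1], n)
  out <- lapply(seq_along(peaks), function(j) {
    p <- peaks[j]
    seg_l <- bounds_l[j]:p
    seg_r <- p:bounds_r[j]
    left_min <- min(x[seg_l]); right_min <- min(x[seg_r])
    thr_l <- left_min + 0.1 * (x[p] - left_min)
    thr_r <- right_min + 0.1 * (x[p] - right_min)
    below_l <- seg_l[x[seg_l] <= thr_l & seg_l < p]
    below_r <- seg_r[x[seg_r] <= thr_r & seg_r > p]
    if (!length(below_l) || !length(below_r)) return(NULL)
    i <- max(below_l)  # last sample at/below threshold before the peak
    t_up <- if (x[i + 1L] > x[i]) {
      (i - 1 + (thr_l - x[i]) / (x[i + 1L] - x[i])) / rate_hz
    } else (i - 1) / rate_hz
    k <- min(below_r)  # first sample at/below threshold after the peak
    t_dn <- if (x[k - 1L] > x[k]) {
      (k - 2 + (x[k - 1L] - thr_r) / (x[k - 1L] - x[k])) / rate_hz
    } else (k - 1) / rate_hz
    t_pk <- (p - 1) / rate_hz
    tibble::tibble(rise_s = t_pk - t_up, decay_s = t_dn - t_pk)
  })
  dplyr::bind_rows(out)
}

#' Summary features of one calcium trace
#'
#' @inheritParams detect_peaks
#' @param duration_s Recording duration; defaults to `length(x) / rate_hz`.
#' @return One-row tibble: `peak_count`, `beat_rate_bpm`
#'   (`60 * peak_count / duration_s`) and `decay_to_rise` (mean over complete
#'   beats of decay time / rise time; `NA` when no complete beat).
#' @export
trace_features <- function(x, rate_hz = 8, min_prominence_frac = 0.2,
                           min_period_s = 0.25,
                           duration_s = length(x) / rate_hz) {
  peaks <- detect_peaks(x, rate_hz, min_prominence_frac, min_period_s)
  kin <- beat_kinetics(x, peaks, rate_hz)
  ok <- kin$rise_s > 0 & kin$decay_s > 0
  tibble::tibble(
    peak_count = length(peaks),
    beat_rate_bpm = 60 * length(peaks) / duration_s,
    decay_to_rise = if (any(ok)) mean(kin$decay_s[ok] / kin$rise_s[ok])
                    else NA_real_)
}

#' Phenotypes from one well's paired baseline/treated traces
#'
#' Converts the two recordings of a well into the scored phenotypes: beat
#' rate (bpm) per phase, decay-to-rise ratio per phase, chronotropy delta
#' (treated / baseline beat rate), and the asystole flag (zero treated peaks
#' with no concurrent cytotoxicity). Wells whose baseline shows no beats are
#' flagged unusable (quality failure) and get an undefined chronotropy delta.
#'
#' @param baseline,treated Numeric trace vectors for the two phases.
#' @param nuclei Nuclei count for the well (passed through).
#' @param cytotox_flag Was the well cytotoxic (normalized nuclei below the
#'   benchmark)? Needed to separate asystole from cell death.
#' @inheritParams detect_peaks
#' @return One-row tibble of phenotype values plus `usable`.
#' @export
phenotypes_from_traces <- function(baseline, treated, nuclei = NA_real_,
                                   cytotox_flag = FALSE, rate_hz = 8,
                                   min_prominence_frac = 0.2,
                                   min_period_s = 0.25) {
  fb <- trace_features(baseline, rate_hz, min_prominence_frac, min_period_s)
  ft <- trace_features(treated, rate_hz, min_prominence_frac, min_period_s)
  usable <- fb$peak_count > 0
  tibble::tibble(
    beat_rate_bpm_baseline = fb$beat_rate_bpm,
    beat_rate_bpm_treated = ft$beat_rate_bpm,
    decay_to_rise_baseline = fb$decay_to_rise,
    decay_to_rise_treated = ft$decay_to_rise,
    peak_count_treated = ft$peak_count,
    chronotropy_delta = if (usable) ft$beat_rate_bpm / fb$beat_rate_bpm
                        else NA_real_,
    asystole = ft$peak_count == 0 && !isTRUE(cytotox_flag),
    nuclei_count = nuclei,
    usable = usable)
}

#' Compute per-well phenotypes for a whole study
#'
#' Runs the feature extraction over a long trace table, joins nuclei counts,
#' and derives the cytotoxicity flag (normalized nuclei count below 0.9 of
#' the plate vehicle mean, mirroring the EC10 benchmark direction) used to
#' distinguish asystole from cell death.
#'
#' @param traces Long tibble: `plate_id`, `well`, `phase`
#'   (`baseline`/`treated`), `frame`, `value`.
#' @param nuclei Tibble: `plate_id`, `well`, `nuclei_count`.
#' @param wells Well table (for vehicle identification): `plate_id`, `well`,
#'   `treatment_type`.
#' @inheritParams detect_peaks
#' @return Tibble with one row per well: identities, phase-wise beat rates
#'   and decay-to-rise ratios, `peak_count_treated`, `chronotropy_delta`,
#'   `asystole`, `nuclei_count`, `usable`.
#' @export
compute_phenotypes <- function(traces, nuclei, wells, rate_hz = 8,
                               min_prominence_frac = 0.2,
                               min_period_s = 0.25) {
  check_columns(traces, c("plate_id", "well", "phase", "frame", "value"),
                "traces")
  check_columns(nuclei, c("plate_id", "well", "nuclei_count"), "nuclei")
  check_columns(wells, c("plate_id", "well", "treatment_type"), "wells")
  veh_mean <- nuclei |>
    dplyr::inner_join(wells, by = c("plate_id", "well")) |>
    dplyr::filter(.data$treatment_type == "vehicle") |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(vehicle_nuclei = mean(.data$nuclei_count), .groups = "drop")
  cyto <- nuclei |>
    dplyr::left_join(veh_mean, by = "plate_id") |>
    dplyr::mutate(cytotox_flag = .data$nuclei_count <
                    0.9 * .data$vehicle_nuclei)
  traces <- dplyr::arrange(traces, .data$plate_id, .data$well, .data$phase,
                           .data$frame)
  split_key <- paste(traces$plate_id, traces$well, traces$phase, sep = "\r")
  groups <- split(traces$value, factor(split_key, levels = unique(split_key)))
  meta <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  feat <- dplyr::bind_rows(lapply(groups, function(v) {
    trace_features(v, rate_hz, min_prominence_frac, min_period_s)
  }))
  feat$plate_id <- meta[, 1]; feat$well <- meta[, 2]; feat$phase <- meta[, 3]
  wide <- tidyr::pivot_wider(
    feat, names_from = "phase",
    values_from = c("peak_count", "beat_rate_bpm", "decay_to_rise"))
  out <- wide |>
    dplyr::left_join(cyto[c("plate_id", "well", "nuclei_count",
                            "cytotox_flag")],
                     by = c("plate_id", "well")) |>
    dplyr::mutate(
      usable = .data$peak_count_baseline > 0,
      chronotropy_delta = ifelse(.data$usable,
                                 .data$beat_rate_bpm_treated /
                                   .data$beat_rate_bpm_baseline, NA_real_),
      asystole = .data$peak_count_treated == 0 &
        !dplyr::coalesce(.data$cytotox_flag, FALSE))
  out[c("plate_id", "well", "beat_rate_bpm_baseline", "beat_rate_bpm_treated",
        "decay_to_rise_baseline", "decay_to_rise_treated",
        "peak_count_treated", "chronotropy_delta", "asystole",
        "nuclei_count", "usable")]
}
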