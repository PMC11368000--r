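#' Normalize phenotype values to plate vehicle controls
#'
#' Every experimental well is divided by its own plate's mean over vehicle
#' (0.5% DMSO) wells, measure by measure, so 1.0 is the control level.
#' Vehicle wells themselves are normalized too and average to 1.0 per plate
#' and measure by construction; applying the normalization twice is a no-op.
#'
#' @param phenotypes Per-well phenotype table (`plate_id`, `well`, plus the
#'   measure columns).
#' @param wells Well table with `plate_id`, `well`, `donor_id`,
#'   `treatment_type`, `chemical_id`, `conc_uM`.
#' @param measures Named character vector mapping measure name to phenotype
#'   column, default the three modeled raw measures.
#' @return Long tibble: `plate_id`, `well`, `donor_id`, `treatment_type`,
#'   `chemical_id`, `conc_uM`, `measure`, `value`, `response_ratio`.
#' @export
normalize_to_vehicle <- function(phenotypes, wells,
                                 measures = c(
                                   beat_rate = "beat_rate_bpm_treated",
                                   decay_to_rise = "decay_to_rise_treated",
                                   nuclei = "nuclei_count")) {
  check_columns(phenotypes, c("plate_id", "well", unname(measures)),
                "phenotypes")
  check_columns(wells, c("plate_id", "well", "donor_id", "treatment_type",
                         "chemical_id", "conc_uM"), "wells")
  long <- phenotypes |>
    dplyr::select(dplyr::all_of(c("plate_id", "well", unname(measures)))) |>
    tidyr::pivot_longer(-c("plate_id", "well"), names_to = "column",
                        values_to = "value") |>
    dplyr::mutate(measure = names(measures)[match(.data$column,
                                                  unname(measures))]) |>
    dplyr::select(-"column") |>
    dplyr::inner_join(
      wells[c("plate_id", "well", "donor_id", "treatment_type", "chemical_id",
              "conc_uM")],
      by = c("plate_id", "well"))
  veh <- long |>
    dplyr::filter(.data$treatment_type == "vehicle") |>
    dplyr::group_by(.data$plate_id, .data$measure) |>
    dplyr::summarise(vehicle_mean = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  missing_plates <- setdiff(unique(long$plate_id), unique(veh$plate_id))
  if (length(missing_plates) > 0) {
    stop(sprintf("no vehicle wells on plate(s): %s",
                 paste(missing_plates, collapse = ", ")), call. = FALSE)
  }
  long |>
    dplyr::left_join(veh, by = c("plate_id", "measure")) |>
    dplyr::mutate(response_ratio = .data$value / .data$vehicle_mean) |>
    dplyr::select("plate_id", "well", "donor_id", "treatment_type",
                  "chemical_id", "conc_uM", "measure", "value",
                  "response_ratio")
}

#' Pearson correlation between paired replicate measurements
#'
#' @param a,b Paired numeric vectors of raw phenotype values (n >= 3).
#' @return One-row tibble: `pearson_r`, `p_value`, `n`, `defined` (`FALSE`
#'   with `NA` correlation when either vector has zero variance).
#' @export
replicate_correlation <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) stop("need at least 3 complete pairs")
  if (sd(a) == 0 || sd(b) == 0) {
    return(tibble::tibble(pearson_r = NA_real_, p_value = NA_real_,
                          n = length(a), defined = FALSE))
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  tibble::tibble(pearson_r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(a), defined = TRUE)
}

#' Decompose control-well variability into technical and biological parts
#'
#' Fits a nested random-effects model by REML (donor and plate-within-donor
#' random; vehicle-vs-media as a fixed contrast whose contribution is
#' measured as explained variance) and reports each component as a fraction
#' of total variance, plus coefficients of variability
#' (`sqrt(component) / grand mean * 100`).
#'
#' @param data Control-well tibble with columns `donor_id`, `plate_id`,
#'   `treatment_type` (`vehicle` / `media`) and `value` (raw units).
#' @return One-row tibble: variance fractions `frac_donor`, `frac_plate`,
#'   `frac_vehicle_vs_media`, `frac_residual` (summing to 1), `cv_total`,
#'   `cv_donor` (percent).
#' @export
decompose_variance <- function(data) {
  check_columns(data, c("donor_id", "plate_id", "treatment_type", "value"),
                "data")
  data <- dplyr::filter(data, is.finite(.data$value))
  if (dplyr::n_distinct(data$donor_id) < 2) {
    stop("need >= 2 donors to decompose variance")
  }
  grand <- mean(data$value)
  if (var(data$value) == 0) {
    return(tibble::tibble(frac_donor = 0, frac_plate = 0,
                          frac_vehicle_vs_media = 0, frac_residual = 0,
                          cv_total = 0, cv_donor = 0, zero_variance = TRUE))
  }
  has_media <- dplyr::n_distinct(data$treatment_type) > 1
  plates_per_donor <- data |>
    dplyr::distinct(.data$donor_id, .data$plate_id) |>
    dplyr::count(.data$donor_id)
  multi_plate <- any(plates_per_donor$n > 1)
  if (!multi_plate) {
    warning("single plate per donor: plate component set to 0")
  }
  form <- stats::as.formula(paste(
    "value ~", if (has_media) "treatment_type" else "1",
    "+ (1 | donor_id)", if (multi_plate) "+ (1 | donor_id:plate_id)" else ""))
  fit <- lme4::lmer(form, data = data, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  lme4::.makeCC("ignore", tol = 1e-4)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v[1] else 0
  }
  v_donor <- getv("donor_id")
  v_plate <- getv("donor_id:plate_id")
  v_resid <- getv("Residual")
  # fixed vehicle-vs-media contribution as variance explained by its fitted
  # contrast across observations
  v_vm <- if (has_media) {
    fe <- stats::model.matrix(fit) %*% lme4::fixef(fit)
    stats::var(as.numeric(fe))
  } else 0
  total <- v_donor + v_plate + v_resid + v_vm
  tibble::tibble(
    frac_donor = v_donor / total,
    frac_plate = v_plate / total,
    frac_vehicle_vs_media = v_vm / total,
    frac_residual = v_resid / total,
    cv_total = sqrt(total) / grand * 100,
    cv_donor = sqrt(v_donor) / grand * 100,
    zero_variance = FALSE)
}

#' Directional quality gate on positive and negative controls
#'
#' A plate passes when isoproterenol wells raise the vehicle-normalized beat
#' rate above 1, propranolol lowers it below 1, sotalol raises the
#' decay-to-rise ratio above 1, and vehicle wells beat spontaneously.
#' Thresholds are directional only: control effect sizes are donor-specific.
#'
#' @param normalized Output of [normalize_to_vehicle()].
#' @param phenotypes Per-well phenotype table (for vehicle spontaneous
#'   beating, `peak_count_treated`).
#' @return Tibble with one row per plate: the three control ratios, vehicle
#'   beating flag and `pass`.
#' @export
control_gate <- function(normalized, phenotypes) {
  check_columns(normalized, c("plate_id", "treatment_type", "chemical_id",
                              "measure", "response_ratio"), "normalized")
  check_columns(phenotypes, c("plate_id", "well", "peak_count_treated"),
                "phenotypes")
  ctrl <- normalized |>
    dplyr::filter(.data$treatment_type == "positive_control") |>
    dplyr::group_by(.data$plate_id, .data$chemical_id, .data$measure) |>
    dplyr::summarise(ratio = mean(.data$response_ratio, na.rm = TRUE),
                     .groups = "drop")
  pull_ratio <- function(chem, meas) {
    ctrl |>
      dplyr::filter(.data$chemical_id == chem, .data$measure == meas) |>
      dplyr::select("plate_id", ratio = "ratio")
  }
  veh_wells <- normalized |>
    dplyr::filter(.data$treatment_type == "vehicle",
                  .data$measure == "beat_rate") |>
    dplyr::distinct(.data$plate_id, .data$well)
  veh_beat <- veh_wells |>
    dplyr::inner_join(phenotypes[c("plate_id", "well", "peak_count_treated")],
                      by = c("plate_id", "well")) |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(vehicle_beating = mean(.data$peak_count_treated > 0) > 0.5,
                     .groups = "drop")
  gate <- tibble::tibble(plate_id = unique(normalized$plate_id)) |>
    dplyr::left_join(dplyr::rename(pull_ratio("isoproterenol", "beat_rate"),
                                   iso_beat_ratio = "ratio"), by = "plate_id") |>
    dplyr::left_join(dplyr::rename(pull_ratio("propranolol", "beat_rate"),
                                   prop_beat_ratio = "ratio"), by = "plate_id") |>
    dplyr::left_join(dplyr::rename(pull_ratio("sotalol", "decay_to_rise"),
                                   sot_dtr_ratio = "ratio"), by = "plate_id") |>
    dplyr::left_join(veh_beat, by = "plate_id")
  gate$vehicle_beating <- dplyr::coalesce(gate$vehicle_beating, FALSE)
  gate$pass <- !is.na(gate$iso_beat_ratio) & gate$iso_beat_ratio > 1 &
    !is.na(gate$prop_beat_ratio) & gate$prop_beat_ratio < 1 &
    !is.na(gate$sot_dtr_ratio) & gate$sot_dtr_ratio > 1 &
    gate$vehicle_beating
  gate
}
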