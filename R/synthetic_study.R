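#' Registry of the 56 screened PFAS with structure-based subclasses
#'
#' The default chemical registry for synthetic studies: 56 per- and
#' poly-fluoroalkyl substances spanning eight structure-based subclasses
#' (17 PFCA, 9 alcohols, 8 PFAN, 7 PFECA, 6 PFSA, 4 n:2 FTOH, 2 n:2 FTS,
#' 3 others).
#'
#' @return Tibble with columns `chemical_id`, `subclass`.
#' @export
pfas_registry <- function() {
  reg <- tibble::tribble(
    ~chemical_id, ~subclass,
    "PFUd2OH", "ALCOHOL", "PFPOH", "ALCOHOL", "PFBOH", "ALCOHOL",
    "AmFPrOH", "ALCOHOL", "PFHp2OH", "ALCOHOL", "7H 6:1 FTOH", "ALCOHOL",
    "C7F3ETOH", "ALCOHOL", "HpFBOH", "ALCOHOL", "CFHx2OH", "ALCOHOL",
    "4:2 FTOH", "n:2 FTOH", "6:1 FTOH", "n:2 FTOH", "6:2 FTOH", "n:2 FTOH",
    "8:2 FTOH", "n:2 FTOH",
    "6:2 FTS", "n:2 FTS", "8:2 FTS", "n:2 FTS",
    "PFHpAM", "PFAN", "PFNAM", "PFAN", "PFOAM", "PFAN", "PFO2AM", "PFAN",
    "PFPAM", "PFAN", "PFHxSA", "PFAN", "MeFOSE", "PFAN", "PFOAMD", "PFAN",
    "4H-PFBA", "PFCA", "5:3 FTCA", "PFCA", "PFIpOA", "PFCA", "TFPrOA", "PFCA",
    "7:3 FTCA", "PFCA", "Cl-PFNA", "PFCA", "NH4PFOA", "PFCA", "PFHx2OA", "PFCA",
    "PFBA", "PFCA", "PFDA", "PFCA", "PFHpA", "PFCA", "PFHxA", "PFCA",
    "PFNA", "PFCA", "PFOA", "PFCA", "PFPeA", "PFCA", "PFPrA", "PFCA",
    "PFUnDA", "PFCA",
    "MePF2ETOA", "PFECA", "PFMBA", "PFECA", "PFPE-6", "PFECA",
    "NFDHA", "PFECA", "PFHx2Et2OA", "PFECA", "PFMPA", "PFECA",
    "PFPE-1", "PFECA",
    "ET-PFBS", "PFSA", "4:2 FTS", "PFSA", "PFBS", "PFSA", "PFHxS", "PFSA",
    "PFOS", "PFSA", "PFBS-K", "PFSA",
    "3:3 FTCA", "Other", "8:2 FTPA", "Other", "PFHx2ON", "Other"
  )
  reg
}

# Hill curves driving the positive-control wells (donor-invariant)
control_truth <- function() {
  tibble::tribble(
    ~chemical_id,    ~measure,        ~direction, ~ec50_uM, ~emax, ~hill_n,
    "isoproterenol", "beat_rate",     "increase", 1.0,      0.8,   1.5,
    "propranolol",   "beat_rate",     "decrease", 0.8,      0.7,   1.5,
    "sotalol",       "decay_to_rise", "increase", 3.0,      0.6,   1.5
  )
}

#' Configuration for a synthetic cardiotoxicity screening study
#'
#' Encodes the stated screening design: 16 donors, 56 chemicals at
#' 0.1/1/10/100 µM on 384-well plates (16 x 24) with 308 interior wells,
#' 15 vehicle and 5 media wells, three positive-control drugs in
#' concentration response, and 6 intra-plate replicate chemicals.
#'
#' @param n_donors Number of iPSC-derived cardiomyocyte donors (>= 2).
#' @param chemicals Registry tibble (`chemical_id`, `subclass`); defaults to
#'   [pfas_registry()].
#' @param concentrations_uM Strictly increasing positive test concentrations.
#' @param plate_rows,plate_cols Plate geometry (384-well default).
#' @param n_vehicle,n_media Vehicle (0.5% DMSO) and media-only wells per plate.
#' @param intra_plate_replicates Chemical ids replicated within each plate
#'   (default: the six replicate chemicals of the screening design).
#' @param phenotype_noise_cv Within-well multiplicative noise CV per phenotype.
#' @param donor_sigma Named log-scale SDs of donor random effects on Hill
#'   parameters, `c(ec50 = ..., emax = ...)`.
#' @param plate_sigma Log-scale SD of the per-plate multiplicative factor.
#' @param trace_noise_sd Additive Gaussian noise SD on synthetic traces
#'   (fraction of unit pulse amplitude).
#' @param p_active Named activity probabilities per measure when Hill truth is
#'   sampled, `c(beat_rate = , decay_to_rise = , nuclei = )`.
#' @param truth Optional Hill truth tibble (`chemical_id`, `measure`,
#'   `direction`, `ec50_uM`, `emax`, `hill_n`); rows absent mean inert. When
#'   `NULL`, truth is sampled from documented default ranges.
#' @param sar_signal List `list(n_informative =, strength =)`; when
#'   `strength > 0` a structure-activity signal is planted: every chemical's
#'   beat-rate log10-EC50 becomes a linear function of informative
#'   substructure descriptors.
#' @param n_descriptors Named counts `c(substructure = , physchem = )`.
#' @param traces Generate per-well calcium traces (long format)?
#' @param seed Root seed; per-stream child seeds are derived deterministically
#'   via [child_seed()].
#' @return A `study_config` list.
#' @export
study_config <- function(n_donors = 16,
                         chemicals = NULL,
                         concentrations_uM = c(0.1, 1, 10, 100),
                         plate_rows = 16, plate_cols = 24,
                         n_vehicle = 15, n_media = 5,
                         intra_plate_replicates = NULL,
                         phenotype_noise_cv = 0.05,
                         donor_sigma = c(ec50 = 0.3, emax = 0.2),
                         plate_sigma = 0.05,
                         trace_noise_sd = 0.02,
                         p_active = c(beat_rate = 0.5, decay_to_rise = 0.3,
                                      nuclei = 0.25),
                         truth = NULL,
                         sar_signal = list(n_informative = 5, strength = 0),
                         n_descriptors = c(substructure = 40, physchem = 10),
                         traces = TRUE,
                         seed = 1L) {
  if (is.null(chemicals)) chemicals <- pfas_registry()
  chemicals <- tibble::as_tibble(chemicals)
  check_columns(chemicals, c("chemical_id", "subclass"), "chemicals")
  if (anyDuplicated(chemicals$chemical_id)) stop("duplicate chemical_id")
  stopifnot(n_donors >= 2,
            all(concentrations_uM > 0),
            all(diff(concentrations_uM) > 0),
            plate_rows >= 4, plate_cols >= 4,
            n_vehicle >= 1, n_media >= 0,
            phenotype_noise_cv >= 0, plate_sigma >= 0, trace_noise_sd >= 0)
  if (is.null(intra_plate_replicates)) {
    defaults <- c("PFOA", "TFPrOA", "PFPE-6", "PFPOH", "7H 6:1 FTOH", "PFHxSA")
    intra_plate_replicates <- intersect(defaults, chemicals$chemical_id)
    if (length(intra_plate_replicates) == 0 && nrow(chemicals) >= 2) {
      intra_plate_replicates <- head(chemicals$chemical_id,
                                     min(6, nrow(chemicals)))
    }
  }
  stopifnot(all(intra_plate_replicates %in% chemicals$chemical_id))
  donor_sigma <- c(ec50 = unname(donor_sigma["ec50"] %||% donor_sigma[[1]]),
                   emax = unname(if (!is.na(donor_sigma["emax"]))
                     donor_sigma[["emax"]] else donor_sigma[[min(2, length(donor_sigma))]]))
  structure(list(
    n_donors = as.integer(n_donors), chemicals = chemicals,
    concentrations_uM = concentrations_uM,
    plate_rows = as.integer(plate_rows), plate_cols = as.integer(plate_cols),
    n_vehicle = as.integer(n_vehicle), n_media = as.integer(n_media),
    intra_plate_replicates = intra_plate_replicates,
    phenotype_noise_cv = phenotype_noise_cv,
    donor_sigma = donor_sigma, plate_sigma = plate_sigma,
    trace_noise_sd = trace_noise_sd, p_active = p_active,
    truth = truth, sar_signal = sar_signal, n_descriptors = n_descriptors,
    traces = traces, seed = as.integer(seed)
  ), class = "study_config")
}

# sample chemical x measure Hill truth from documented default ranges;
# beat-rate curves are decreasing in ~70% of active cases (negative
# chronotropy dominates PFAS effects), with emax up to 1 so that asystole
# (EC95) is reachable for the strongest curves
sample_hill_truth <- function(chemicals, p_active, descriptors = NULL,
                              sar_signal = list(strength = 0)) {
  n <- nrow(chemicals)
  rows <- list()
  for (i in seq_len(n)) {
    id <- chemicals$chemical_id[i]
    if (runif(1) < p_active[["beat_rate"]]) {
      dirn <- if (runif(1) < 0.3) "increase" else "decrease"
      emax <- if (dirn == "decrease") runif(1, 0.2, 1.0) else runif(1, 0.15, 0.6)
      rows[[length(rows) + 1]] <- tibble::tibble(
        chemical_id = id, measure = "beat_rate", direction = dirn,
        ec50_uM = 10^runif(1, log10(0.3), log10(300)),
        emax = emax, hill_n = runif(1, 0.8, 2.5))
    }
    if (runif(1) < p_active[["decay_to_rise"]]) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chemical_id = id, measure = "decay_to_rise", direction = "increase",
        ec50_uM = 10^runif(1, log10(0.3), log10(300)),
        emax = runif(1, 0.15, 0.8), hill_n = runif(1, 0.8, 2.5))
    }
    if (runif(1) < p_active[["nuclei"]]) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chemical_id = id, measure = "nuclei", direction = "decrease",
        ec50_uM = 10^runif(1, log10(1), log10(300)),
        emax = runif(1, 0.15, 0.6), hill_n = runif(1, 0.8, 2.5))
    }
  }
  truth <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(chemical_id = character(), measure = character(),
                   direction = character(), ec50_uM = numeric(),
                   emax = numeric(), hill_n = numeric())
  if (sar_signal$strength > 0 && !is.null(descriptors)) {
    # plant signal: beat-rate potency is a linear function of informative
    # substructure descriptors (more substructure -> lower EC50)
    k <- min(sar_signal$n_informative, ncol(descriptors))
    w <- rnorm(k)
    s <- as.numeric(scale(descriptors[, seq_len(k), drop = FALSE] %*% w))
    planted <- tibble::tibble(
      chemical_id = chemicals$chemical_id, measure = "beat_rate",
      direction = "decrease",
      ec50_uM = 10^(1 - sar_signal$strength * s + rnorm(n, 0, 0.15)),
      emax = 0.6, hill_n = 1.5)
    truth <- dplyr::bind_rows(dplyr::filter(truth, .data$measure != "beat_rate"),
                              planted)
  }
  truth
}

well_name <- function(row, col) paste0(LETTERS[row], sprintf("%02d", col))

# lay out one plate: interior wells shuffled over treatments, edge wells
# marked non-experimental
layout_plate <- function(config, plate_id, donor_id, batch) {
  nr <- config$plate_rows; nc <- config$plate_cols
  all_rc <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  edge <- all_rc$row %in% c(1, nr) | all_rc$col %in% c(1, nc)
  interior <- all_rc[!edge, ]
  concs <- config$concentrations_uM
  test_ids <- c(config$chemicals$chemical_id, config$intra_plate_replicates)
  pc <- control_truth()$chemical_id
  n_needed <- length(test_ids) * length(concs) + config$n_vehicle +
    config$n_media + length(pc) * length(concs)
  if (n_needed > nrow(interior)) {
    stop(sprintf(
      "plate capacity exceeded: %d wells needed but only %d interior wells on a %dx%d plate",
      n_needed, nrow(interior), nr, nc), call. = FALSE)
  }
  treat <- tibble::tibble(
    treatment_type = c(rep("test", length(test_ids) * length(concs)),
                       rep("vehicle", config$n_vehicle),
                       rep("media", config$n_media),
                       rep("positive_control", length(pc) * length(concs))),
    chemical_id = c(rep(test_ids, each = length(concs)),
                    rep(NA_character_, config$n_vehicle + config$n_media),
                    rep(pc, each = length(concs))),
    conc_uM = c(rep(concs, length(test_ids)),
                rep(NA_real_, config$n_vehicle + config$n_media),
                rep(concs, length(pc)))
  )
  pos <- interior[sample.int(nrow(interior), nrow(treat)), ]
  used <- tibble::tibble(
    plate_id = plate_id, well = well_name(pos$row, pos$col),
    row = pos$row, col = pos$col, donor_id = donor_id,
    treatment_type = treat$treatment_type, chemical_id = treat$chemical_id,
    conc_uM = treat$conc_uM, batch = batch)
  spare <- dplyr::anti_join(
    tibble::as_tibble(all_rc), used[c("row", "col")], by = c("row", "col"))
  spare_edge <- spare[spare$row %in% c(1, nr) | spare$col %in% c(1, nc), ]
  spare_int <- spare[!(spare$row %in% c(1, nr) | spare$col %in% c(1, nc)), ]
  unused <- dplyr::bind_rows(
    tibble::tibble(plate_id = plate_id,
                   well = well_name(spare_edge$row, spare_edge$col),
                   row = spare_edge$row, col = spare_edge$col,
                   donor_id = donor_id, treatment_type = "edge",
                   chemical_id = NA_character_, conc_uM = NA_real_,
                   batch = batch),
    tibble::tibble(plate_id = plate_id,
                   well = well_name(spare_int$row, spare_int$col),
                   row = spare_int$row, col = spare_int$col,
                   donor_id = donor_id, treatment_type = "empty",
                   chemical_id = NA_character_, conc_uM = NA_real_,
                   batch = batch))
  dplyr::bind_rows(used, unused)
}

#' Generate a complete synthetic screening study
#'
#' Produces a full study bundle with the statistical structure the analysis
#' assumes: per-well identities, paired baseline/treated calcium traces,
#' nuclei counts, a chemical registry, exposure estimates, toxicokinetic
#' parameters, descriptor matrices, and the complete generative truth. Donor
#' random effects are lognormal (multiplicative) on EC50 and Emax; each plate
#' carries a single multiplicative lognormal technical factor; well-level
#' noise is multiplicative Gaussian with the configured CV.
#'
#' @param config A [study_config()].
#' @return A `study_bundle` list with elements `wells`, `phenotypes_true`,
#'   `traces` (or `NULL`), `nuclei`, `registry`, `exposures`, `tk_params`,
#'   `descriptors` (list of `substructure` and `physchem` matrices), `truth`
#'   and `config`. Identical seeds give identical bundles.
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  chems <- config$chemicals
  n_chem <- nrow(chems)
  donors <- sprintf("donor_%02d", seq_len(config$n_donors))

  # descriptors first so a planted structure-activity signal can reuse them
  set.seed(child_seed(seed, "descriptors"))
  n_sub <- config$n_descriptors[["substructure"]]
  n_phys <- config$n_descriptors[["physchem"]]
  sub <- matrix(rpois(n_chem * n_sub, lambda = 1.2), n_chem, n_sub,
                dimnames = list(chems$chemical_id, sprintf("S%03d", seq_len(n_sub))))
  sub[runif(length(sub)) < 0.35] <- 0
  phys <- matrix(rnorm(n_chem * n_phys), n_chem, n_phys,
                 dimnames = list(chems$chemical_id, sprintf("P%02d", seq_len(n_phys))))

  set.seed(child_seed(seed, "truth"))
  truth_hill <- config$truth %||%
    sample_hill_truth(chems, config$p_active, sub, config$sar_signal)

  set.seed(child_seed(seed, "donor_effects"))
  de <- tidyr::expand_grid(
    chemical_id = chems$chemical_id,
    measure = c("beat_rate", "decay_to_rise", "nuclei"),
    donor_id = donors)
  de$z_ec50 <- rnorm(nrow(de))
  de$z_emax <- rnorm(nrow(de))

  set.seed(child_seed(seed, "baselines"))
  base <- tibble::tibble(
    donor_id = donors,
    beat_rate = pmin(pmax(rnorm(config$n_donors, 25, 6), 12), 40),
    decay_to_rise = pmin(pmax(rnorm(config$n_donors, 2, 0.25), 1.3), 3),
    nuclei = pmax(rnorm(config$n_donors, 1200, 120), 600))

  set.seed(child_seed(seed, "layout"))
  batches <- rep(sprintf("batch_%d", 1:6), length.out = config$n_donors)
  wells <- dplyr::bind_rows(lapply(seq_along(donors), function(i) {
    layout_plate(config, sprintf("plate_%02d", i), donors[i], batches[i])
  }))

  set.seed(child_seed(seed, "plates"))
  plate_ids <- unique(wells$plate_id)
  plate_f <- setNames(exp(rnorm(length(plate_ids), 0, config$plate_sigma)),
                      plate_ids)

  # expected response ratio per experimental well x measure
  all_truth <- dplyr::bind_rows(truth_hill, control_truth())
  exp_wells <- dplyr::filter(wells,
                             .data$treatment_type %in% c("test", "vehicle",
                                                         "media",
                                                         "positive_control"))
  grid <- tidyr::expand_grid(
    exp_wells[c("plate_id", "well", "donor_id", "treatment_type",
                "chemical_id", "conc_uM")],
    measure = c("beat_rate", "decay_to_rise", "nuclei"))
  grid <- dplyr::left_join(grid, all_truth,
                           by = c("chemical_id", "measure"))
  grid <- dplyr::left_join(grid, de,
                           by = c("chemical_id", "measure", "donor_id"))
  sig <- config$donor_sigma
  has_curve <- !is.na(grid$ec50_uM)
  is_control_drug <- grid$chemical_id %in% control_truth()$chemical_id
  ec50_i <- grid$ec50_uM
  emax_i <- grid$emax
  adj <- has_curve & !is_control_drug & !is.na(grid$z_ec50)
  ec50_i[adj] <- ec50_i[adj] * exp(sig[["ec50"]] * grid$z_ec50[adj])
  emax_i[adj] <- emax_i[adj] * exp(sig[["emax"]] * grid$z_emax[adj])
  ratio <- rep(1, nrow(grid))
  idx <- which(has_curve & !is.na(grid$conc_uM))
  for (dirn in c("increase", "decrease")) {
    ii <- idx[grid$direction[idx] == dirn]
    if (length(ii)) {
      frac <- grid$conc_uM[ii]^grid$hill_n[ii] /
        (ec50_i[ii]^grid$hill_n[ii] + grid$conc_uM[ii]^grid$hill_n[ii])
      ratio[ii] <- 1 + (if (dirn == "increase") 1 else -1) * emax_i[ii] * frac
    }
  }
  ratio <- pmax(ratio, 0)
  grid$true_ratio <- ratio

  set.seed(child_seed(seed, "wells"))
  cv <- config$phenotype_noise_cv
  grid <- dplyr::left_join(grid,
                           tidyr::pivot_longer(base, -"donor_id",
                                               names_to = "measure",
                                               values_to = "donor_base"),
                           by = c("donor_id", "measure"))
  pf <- plate_f[grid$plate_id]
  n_g <- nrow(grid)
  grid$value_baseline <- grid$donor_base * pf * (1 + rnorm(n_g, 0, cv))
  grid$value_treated <- grid$donor_base * pf * grid$true_ratio *
    (1 + rnorm(n_g, 0, cv))
  grid$value_baseline <- pmax(grid$value_baseline, 0)
  grid$value_treated <- pmax(grid$value_treated, 0)

  wide <- grid |>
    dplyr::select("plate_id", "well", "measure", "value_baseline",
                  "value_treated") |>
    tidyr::pivot_wider(names_from = "measure",
                       values_from = c("value_baseline", "value_treated"))
  phen <- tibble::tibble(
    plate_id = wide$plate_id, well = wide$well,
    beat_rate_bpm_baseline = wide$value_baseline_beat_rate,
    beat_rate_bpm_treated = wide$value_treated_beat_rate,
    decay_to_rise_baseline = wide$value_baseline_decay_to_rise,
    decay_to_rise_treated = wide$value_treated_decay_to_rise,
    nuclei_count = round(wide$value_treated_nuclei))
  nuclei <- phen[c("plate_id", "well", "nuclei_count")]

  traces <- NULL
  if (isTRUE(config$traces)) {
    set.seed(child_seed(seed, "traces"))
    traces <- synthesize_study_traces(phen, config$trace_noise_sd)
  }

  set.seed(child_seed(seed, "exposures"))
  sig_exp <- runif(n_chem, 0.5, 1.5)
  exposures <- tibble::tibble(
    chemical_id = chems$chemical_id,
    oral_median = 10^runif(n_chem, -8, -3),
    biomonitoring_lo = NA_real_, biomonitoring_hi = NA_real_)
  exposures$oral_upper95 <- exposures$oral_median * exp(qnorm(0.95) * sig_exp)
  exposures <- exposures[c("chemical_id", "oral_median", "oral_upper95",
                           "biomonitoring_lo", "biomonitoring_hi")]

  set.seed(child_seed(seed, "tk"))
  tk_params <- tibble::tibble(
    chemical_id = chems$chemical_id,
    mw = runif(n_chem, 200, 700),
    fup = 10^runif(n_chem, -2.3, -0.3),
    clint = 10^runif(n_chem, -2, 1),
    gfr_perkg = 0.0918,   # 1.53 mL/min/kg
    q_liver_perkg = 1.24)

  structure(list(
    wells = wells,
    phenotypes_true = phen,
    traces = traces,
    nuclei = nuclei,
    registry = chems,
    exposures = exposures,
    tk_params = tk_params,
    descriptors = list(substructure = sub, physchem = phys),
    truth = list(hill = truth_hill, donor_effects = de,
                 donor_baselines = base, plate_factors = plate_f,
                 control_hill = control_truth()),
    config = config
  ), class = "study_bundle")
}

# long trace table for all experimental wells of a generated study
synthesize_study_traces <- function(phen, noise_sd, duration_s = 100,
                                    rate_hz = 8) {
  n_frames <- round(duration_s * rate_hz)
  mk <- function(bpm, dtr) {
    dtr <- ifelse(is.na(dtr) | dtr <= 0, 3, dtr)
    lapply(seq_along(bpm), function(i) {
      synthesize_trace(bpm[i], dtr[i], duration_s, rate_hz, noise_sd)
    })
  }
  tr_base <- mk(phen$beat_rate_bpm_baseline, phen$decay_to_rise_baseline)
  tr_trt <- mk(phen$beat_rate_bpm_treated, phen$decay_to_rise_treated)
  n_w <- nrow(phen)
  tibble::tibble(
    plate_id = rep(phen$plate_id, each = 2 * n_frames),
    well = rep(phen$well, each = 2 * n_frames),
    phase = rep(rep(c("baseline", "treated"), each = n_frames), n_w),
    frame = rep(c(seq_len(n_frames), seq_len(n_frames)) - 1L, n_w),
    value = unlist(lapply(seq_len(n_w), function(i) {
      c(tr_base[[i]], tr_trt[[i]])
    }), use.names = FALSE)
  )
}

#' Synthesize a calcium-flux trace with known beat rate and kinetics
#'
#' Each beat is a fast exponential rise / slower exponential decay transient.
#' Time constants are chosen so that the 10%-of-amplitude crossings sit
#' exactly `rise` seconds before and `decay` seconds after the peak, where
#' `decay / rise = decay_to_rise` and the transient width is
#' `min(1 s, 0.6 x beat period)`. Pulses are evenly spaced so the pulse count
#' equals `round(bpm * duration_s / 60)` exactly.
#'
#' @param bpm Beats per minute (>= 0); 0 gives a flat baseline trace.
#' @param decay_to_rise Ratio of decay time to rise time (> 0).
#' @param duration_s Recording duration in seconds.
#' @param rate_hz Sampling rate in frames per second; `duration_s * rate_hz`
#'   must be a whole number (800 frames at the 8 Hz x 100 s default).
#' @param noise_sd Additive Gaussian noise SD in units of the unit pulse
#'   amplitude (must be >= 0).
#' @return Numeric vector of `duration_s * rate_hz` fluorescence samples.
#' @examples
#' tr <- synthesize_trace(30, 3, 100, 8, 0)
#' length(tr)  # 800
#' @export
synthesize_trace <- function(bpm, decay_to_rise, duration_s = 100,
                             rate_hz = 8, noise_sd = 0) {
  stopifnot(bpm >= 0, decay_to_rise > 0, duration_s > 0, rate_hz > 0)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  n <- duration_s * rate_hz
  if (abs(n - round(n)) > 1e-9) {
    stop("rate_hz * duration_s must be a whole number of frames")
  }
  n <- round(n)
  t <- (seq_len(n) - 1) / rate_hz
  n_pulses <- round(bpm * duration_s / 60)
  if (n_pulses == 0) {
    return(if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n))
  }
  spacing <- duration_s / n_pulses
  width <- min(1, 0.6 * spacing)
  rise <- width / (1 + decay_to_rise)
  decay <- width - rise
  tau_r <- rise / log(10)
  tau_d <- decay / log(10)
  p_idx <- pmin(pmax(ceiling(t / spacing), 1), n_pulses)
  peak_t <- (p_idx - 0.5) * spacing
  dt <- t - peak_t
  v <- ifelse(dt < 0, exp(dt / tau_r), exp(-dt / tau_d))
  if (noise_sd > 0) v <- v + rnorm(n, 0, noise_sd)
  v
}
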