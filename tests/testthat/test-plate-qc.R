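make_norm_fixture <- function() {
  wells <- tibble::tibble(
    plate_id = rep(c("p1", "p2"), each = 4),
    well = rep(c("B02", "B03", "B04", "B05"), 2),
    donor_id = rep(c("d1", "d2"), each = 4),
    treatment_type = rep(c("vehicle", "vehicle", "test", "test"), 2),
    chemical_id = rep(c(NA, NA, "chemA", "chemA"), 2),
    conc_uM = rep(c(NA, NA, 1, 10), 2))
  phen <- tibble::tibble(
    plate_id = wells$plate_id, well = wells$well,
    beat_rate_bpm_treated = c(90, 110, 80, 60, 40, 60, 60, 60))
  list(wells = wells, phen = phen)
}

test_that("normalization divides by the plate's own vehicle mean", {
  fx <- make_norm_fixture()
  norm <- normalize_to_vehicle(fx$phen, fx$wells,
                               measures = c(beat_rate = "beat_rate_bpm_treated"))
  # plate p1 vehicle mean 100, p2 vehicle mean 50
  expect_equal(norm$response_ratio[norm$plate_id == "p1" & norm$well == "B04"],
               0.8)
  # identical raw value 60 on the two plates -> 0.6 and 1.2
  expect_equal(norm$response_ratio[norm$plate_id == "p1" & norm$well == "B05"],
               0.6)
  expect_equal(norm$response_ratio[norm$plate_id == "p2" & norm$well == "B04"],
               1.2)
  # vehicle wells self-normalize to mean 1 per plate
  veh <- dplyr::filter(norm, .data$treatment_type == "vehicle")
  means <- tapply(veh$response_ratio, veh$plate_id, mean)
  expect_equal(as.numeric(means), c(1, 1))
})

test_that("normalization is idempotent and errors on plates without vehicle", {
  fx <- make_norm_fixture()
  norm1 <- normalize_to_vehicle(fx$phen, fx$wells,
                                measures = c(beat_rate = "beat_rate_bpm_treated"))
  renamed <- norm1 |>
    dplyr::select("plate_id", "well", beat_rate_bpm_treated = "response_ratio")
  norm2 <- normalize_to_vehicle(renamed, fx$wells,
                                measures = c(beat_rate = "beat_rate_bpm_treated"))
  expect_equal(norm2$response_ratio, norm1$response_ratio)
  bad_wells <- fx$wells
  bad_wells$treatment_type[bad_wells$plate_id == "p2"] <- "test"
  expect_error(normalize_to_vehicle(fx$phen, bad_wells,
                                    measures = c(beat_rate = "beat_rate_bpm_treated")),
               "p2")
})

test_that("replicate correlation matches hand-computed Pearson values", {
  expect_equal(replicate_correlation(1:5, 1:5)$pearson_r, 1)
  expect_equal(replicate_correlation(c(1, 2, 3), c(3, 2, 1))$pearson_r, -1)
  r <- replicate_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$pearson_r, 0.6)  # cov = 1, sd_x = sd_y = sqrt(5/3)
  flat <- replicate_correlation(c(1, 1, 1), c(1, 2, 3))
  expect_false(flat$defined)
  expect_true(is.na(flat$pearson_r))
})

test_that("variance decomposition recovers planted component ratios", {
  # planted: donor SD 2, residual SD 1 -> fractions 0.8 / 0.2
  res <- vapply(1:10, function(s) {
    vd <- suppressWarnings(decompose_variance(sim_controls(s)))
    c(vd$frac_donor, vd$frac_residual, vd$frac_plate,
      vd$frac_vehicle_vs_media)
  }, numeric(4))
  expect_equal(mean(res[1, ]), 0.8, tolerance = 0.07)
  expect_equal(mean(res[2, ]), 0.2, tolerance = 0.25)
  # fractions always sum to 1
  expect_equal(colSums(res), rep(1, 10), tolerance = 1e-9)
  # equal vehicle and media means -> vehicle_vs_media fraction ~ 0
  expect_lt(mean(res[4, ]), 0.01)
  # a planted plate component is detected
  vd_plate <- suppressWarnings(decompose_variance(sim_controls(2, sd_plate = 2)))
  expect_gt(vd_plate$frac_plate, 0.05)
})

test_that("variance decomposition handles degenerate inputs", {
  flat <- sim_controls(1, sd_donor = 0, sd_resid = 0)
  flat$value <- 25
  vd <- decompose_variance(flat)
  expect_true(vd$zero_variance)
  expect_equal(vd$frac_donor + vd$frac_plate + vd$frac_residual +
                 vd$frac_vehicle_vs_media, 0)
  single <- sim_controls(1)
  single$plate_id <- paste0(single$donor_id, "_p1")
  expect_warning(decompose_variance(single), "plate")
})

test_that("control gate passes generator-encoded plates and fails perturbed ones", {
  cfg <- small_config(n_chem = 2, n_donors = 2, seed = 4)
  b <- generate_study(cfg)
  phen <- tibble::as_tibble(b$phenotypes_true)
  phen$peak_count_treated <- round(phen$beat_rate_bpm_treated * 100 / 60)
  norm <- normalize_to_vehicle(phen, b$wells)
  gate <- control_gate(norm, phen)
  expect_true(all(gate$pass))
  # inverted isoproterenol response -> fail
  norm_bad <- norm
  iso <- norm_bad$chemical_id == "isoproterenol" &
    norm_bad$measure == "beat_rate" & !is.na(norm_bad$chemical_id)
  norm_bad$response_ratio[iso] <- 0.4
  expect_true(all(!control_gate(norm_bad, phen)$pass))
  # non-beating vehicle wells -> fail
  phen_bad <- phen
  veh_wells <- b$wells$well[b$wells$treatment_type == "vehicle" &
                              b$wells$plate_id == "plate_01"]
  idx <- phen_bad$plate_id == "plate_01" & phen_bad$well %in% veh_wells
  phen_bad$peak_count_treated[idx] <- 0
  gate2 <- control_gate(norm, phen_bad)
  expect_false(gate2$pass[gate2$plate_id == "plate_01"])
  expect_true(gate2$pass[gate2$plate_id == "plate_02"])
})
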