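test_that("plate layout has 308 interior wells and 76 edge wells", {
  cfg <- small_config(n_chem = 6, n_donors = 2)
  b <- generate_study(cfg)
  per_plate <- dplyr::count(b$wells, .data$plate_id, .data$treatment_type) |>
    tidyr::pivot_wider(names_from = "treatment_type", values_from = "n",
                       values_fill = 0)
  expect_true(all(per_plate$edge == 76))
  interior <- rowSums(per_plate[setdiff(names(per_plate),
                                        c("plate_id", "edge"))])
  expect_true(all(interior == 308))
  # well-count accounting: interior + edge = rows x cols
  expect_true(all(interior + per_plate$edge == 16 * 24))
  # every chemical x donor sees all four concentrations
  cover <- b$wells |>
    dplyr::filter(.data$treatment_type == "test") |>
    dplyr::distinct(.data$donor_id, .data$chemical_id, .data$conc_uM) |>
    dplyr::count(.data$donor_id, .data$chemical_id)
  expect_true(all(cover$n == 4))
})

test_that("the full 56-chemical design fits one plate; overflow errors", {
  cfg <- study_config(n_donors = 2, traces = FALSE)
  expect_s3_class(generate_study(cfg)$wells, "tbl_df")
  big <- dplyr::bind_rows(pfas_registry(),
                          tibble::tibble(chemical_id = sprintf("X%02d", 1:20),
                                         subclass = "Other"))
  cfg2 <- study_config(n_donors = 2, chemicals = big, traces = FALSE)
  expect_error(generate_study(cfg2), "capacity")
})

test_that("identical seeds give identical bundles", {
  cfg <- small_config(n_chem = 3, n_donors = 2, seed = 7, traces = TRUE)
  b1 <- generate_study(cfg)
  b2 <- generate_study(cfg)
  expect_identical(b1$wells, b2$wells)
  expect_identical(b1$phenotypes_true, b2$phenotypes_true)
  expect_identical(b1$traces, b2$traces)
  expect_identical(b1$descriptors, b2$descriptors)
  expect_identical(b1$truth, b2$truth)
  b3 <- generate_study(small_config(n_chem = 3, n_donors = 2, seed = 8,
                                    traces = TRUE))
  expect_false(identical(b1$phenotypes_true, b3$phenotypes_true))
})

test_that("zero donor variance and zero noise reproduce the Hill truth exactly", {
  truth <- tibble::tibble(chemical_id = "PFOA", measure = "beat_rate",
                          direction = "decrease", ec50_uM = 10, emax = 0.5,
                          hill_n = 1)
  cfg <- study_config(
    n_donors = 2, chemicals = pfas_registry()[pfas_registry()$chemical_id == "PFOA", ],
    intra_plate_replicates = character(0),
    phenotype_noise_cv = 0, donor_sigma = c(ec50 = 0, emax = 0),
    plate_sigma = 0, truth = truth, traces = FALSE, seed = 3)
  b <- generate_study(cfg)
  norm <- normalize_to_vehicle(b$phenotypes_true, b$wells,
                               measures = c(beat_rate = "beat_rate_bpm_treated"))
  test <- dplyr::filter(norm, .data$treatment_type == "test")
  expected <- hill_response(test$conc_uM, 10, 0.5, 1, "decrease")
  expect_equal(unname(test$response_ratio), unname(expected),
               tolerance = 1e-12)
})

test_that("donor-level EC50 random effects have the configured log-SD", {
  # the generator stores standard-normal Z per donor x chemical x measure;
  # donor EC50 = truth * exp(sigma * z), so sd(log EC50) estimates sigma
  cfg <- study_config(n_donors = 16, traces = FALSE, seed = 5,
                      donor_sigma = c(ec50 = 0.4, emax = 0.2))
  b <- generate_study(cfg)
  z <- b$truth$donor_effects$z_ec50
  expect_gte(length(z), 1000)
  sigma_hat <- sd(0.4 * z)
  se <- 0.4 / sqrt(2 * length(z))
  expect_lt(abs(sigma_hat - 0.4), 3 * se)
})

test_that("synthesize_trace honors count, duration and kinetics contracts", {
  tr <- synthesize_trace(30, 3, 100, 8, 0)
  expect_length(tr, 800)
  expect_equal(length(detect_peaks(tr)), 50)
  expect_identical(synthesize_trace(0, 3, 100, 8, 0), numeric(800))
  expect_error(synthesize_trace(30, 3, 100, 8, -0.1), "non-negative")
  expect_error(synthesize_trace(30, 3, 100.1, 8), "whole number")
  # pulse count = round(bpm * duration / 60) across rates
  for (bpm in c(6, 14, 25, 36, 60)) {
    expect_equal(length(detect_peaks(synthesize_trace(bpm, 2, 100, 8, 0))),
                 round(bpm * 100 / 60))
  }
})

test_that("study_config validates its invariants", {
  expect_error(study_config(n_donors = 1))
  expect_error(study_config(concentrations_uM = c(1, 1, 10)))
  expect_error(study_config(concentrations_uM = c(10, 1)))
  expect_error(study_config(concentrations_uM = c(-1, 1)))
})
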