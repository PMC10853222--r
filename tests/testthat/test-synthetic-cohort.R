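test_that("cohorts are bit-identical for identical config and seed", {
  cfg <- cohort_config(list(syndrome_spec("S1", n_cases = 5)),
                       n_background_probes = 100, n_controls = 8,
                       n_vus_per_syndrome = 3, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$betas, b$betas)
  expect_identical(a$detp, b$detp)
  expect_identical(a$sheet, b$sheet)
  c3 <- generate_cohort(cohort_config(list(syndrome_spec("S1", n_cases = 5)),
                                      n_background_probes = 100,
                                      n_controls = 8, n_vus_per_syndrome = 3,
                                      seed = 43))
  expect_false(identical(a$betas, c3$betas))
})

test_that("beta values stay inside [0, 1] even under strong confounding", {
  co <- generate_cohort(cohort_config(
    list(syndrome_spec("S1", delta_beta = 0.4)),
    n_background_probes = 400, n_controls = 10,
    confounder_effects = c(age = 0.01, sex = 0.2, cell = 0.5),
    noise_sd = 1.5, seed = 7))
  expect_gte(min(co$betas), 0)
  expect_lte(max(co$betas), 1)
  expect_true(all(co$detp >= 0 & co$detp <= 1))
})

test_that("zero configured effect leaves per-probe case-control gaps at noise level", {
  co <- generate_cohort(cohort_config(
    list(syndrome_spec("S1", n_cases = 30, delta_beta = 0)),
    n_background_probes = 200, n_controls = 30,
    confounder_effects = c(age = 0, sex = 0, cell = 0), seed = 11))
  case <- co$sheet$role == "case"
  ctl <- co$sheet$role == "control"
  db <- rowMeans(co$betas[, case]) - rowMeans(co$betas[, ctl])
  se <- sqrt(apply(co$betas[, case], 1, var) / sum(case) +
               apply(co$betas[, ctl], 1, var) / sum(ctl))
  expect_gt(mean(abs(db) <= 3 * se), 0.98)
})

test_that("configured delta-beta is recovered empirically at large n", {
  co <- generate_cohort(cohort_config(
    list(syndrome_spec("S1", n_cases = 200, delta_beta = 0.15,
                       n_signature_probes = 100)),
    n_background_probes = 50, n_controls = 200, noise_sd = 0.05,
    confounder_effects = c(age = 0, sex = 0, cell = 0), seed = 5))
  sig <- co$signatures[[1]]$probe_ids
  case <- co$sheet$role == "case"
  ctl <- co$sheet$role == "control"
  db <- rowMeans(co$betas[sig, case]) - rowMeans(co$betas[sig, ctl])
  expect_equal(mean(abs(db)), 0.15, tolerance = 0.02 / 0.15)
  # direction mix: half the probes hyper-, half hypo-methylated
  expect_equal(sum(db > 0), 50)
})

test_that("intermediate and female X-linked carriers express attenuated effects", {
  co <- generate_cohort(cohort_config(
    list(syndrome_spec("SX", n_cases = 120, delta_beta = 0.2,
                       direction_mix = 1, x_linked = TRUE,
                       female_attenuation = 0.5)),
    n_background_probes = 20, n_controls = 60, noise_sd = 0.05,
    confounder_effects = c(age = 0, sex = 0, cell = 0), seed = 9))
  sig <- co$signatures[[1]]$probe_ids
  ctl_mean <- rowMeans(co$betas[sig, co$sheet$role == "control"])
  shift <- colMeans(co$betas[sig, ] - ctl_mean)
  case_m <- co$sheet$role == "case" & co$sheet$sex == "M"
  case_f <- co$sheet$role == "case" & co$sheet$sex == "F"
  expect_equal(mean(shift[case_m]), 0.2, tolerance = 0.1)
  expect_lt(mean(shift[case_f]), 0.75 * mean(shift[case_m]))

  co2 <- generate_cohort(cohort_config(
    list(syndrome_spec("S1", n_cases = 100, delta_beta = 0.2,
                       direction_mix = 1, fraction_intermediate = 0.5)),
    n_background_probes = 20, n_controls = 60, noise_sd = 0.05,
    confounder_effects = c(age = 0, sex = 0, cell = 0), seed = 9))
  expect_equal(sum(co2$sheet$true_effect == 0.5), 50)
})

test_that("VUS carriers draw latent effects from the configured mixture", {
  co <- generate_cohort(cohort_config(
    list(syndrome_spec("S1", n_cases = 2)), n_background_probes = 50,
    n_controls = 3, n_vus_per_syndrome = 40,
    vus_mixture = c(full = 1, half = 1, null = 0), seed = 3))
  vus <- co$sheet[co$sheet$role == "vus", ]
  expect_equal(nrow(vus), 40)
  expect_true(all(vus$true_effect %in% c(0.5, 1)))
})

test_that("invalid configurations are rejected", {
  expect_error(syndrome_spec("S1", delta_beta = 0.6), "delta_beta")
  expect_error(syndrome_spec("S1", female_attenuation = 1.5), "female_attenuation")
  expect_error(cohort_config(list(syndrome_spec("A"), syndrome_spec("A"))),
               "unique")
  expect_error(cohort_config(list(syndrome_spec("A")), noise_sd = 0), "noise_sd")
  expect_error(cohort_config(list(syndrome_spec("A")),
                             detection_fail_rate = 2), "detection_fail_rate")
})

test_that("cohorts round-trip bit-identically through the writers and readers", {
  co <- generate_cohort(cohort_config(
    list(syndrome_spec("S1", n_cases = 3, n_signature_probes = 10)),
    n_background_probes = 25, n_controls = 4, n_vus_per_syndrome = 2,
    seed = 21))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_identical(read_beta_matrix(paths[["betas"]]), co$betas)
  expect_identical(read_detp_matrix(paths[["detp"]]), co$detp)
  sheet2 <- read_sample_sheet(paths[["sheet"]])
  expect_equal(sheet2$sample_id, co$sheet$sample_id)
  expect_equal(sheet2$age_years, co$sheet$age_years)
  expect_equal(sheet2$cell_frac_3, co$sheet$cell_frac_3)
  defs <- load_signatures(paths[["signatures"]])
  expect_equal(defs[[1]]$probe_ids, co$signatures[[1]]$probe_ids)
})

test_that("degenerate cohorts produce valid header-only files", {
  co <- generate_cohort(cohort_config(
    list(syndrome_spec("S1", n_cases = 0)), n_background_probes = 10,
    n_controls = 0, seed = 1))
  expect_equal(ncol(co$betas), 0L)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_equal(nrow(read_sample_sheet(paths[["sheet"]])), 0L)

  co3 <- generate_cohort(cohort_config(
    list(syndrome_spec("S1", n_cases = 2)), n_background_probes = 10,
    n_controls = 1, seed = 1))
  paths3 <- write_cohort(co3, withr::local_tempdir())
  expect_equal(nrow(read_sample_sheet(paths3[["sheet"]])), 3L)
})
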