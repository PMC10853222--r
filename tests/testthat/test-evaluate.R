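test_that("strong-effect cohorts reach perfect sensitivity and specificity at 3/4", {
  co <- strong_cohort(seed = 1)
  res <- residualize(co$betas, co$sheet, fit_samples = control_ids(co$sheet))
  rep <- loo_evaluate(res, co$sheet, co$signatures[[1]], configs = "3/4")
  s <- rep$summary
  expect_equal(s$sens, 1)
  expect_equal(s$spec, 1)
  expect_equal(s$sens_n, 10)
  expect_equal(s$spec_n, 25)
  # report-style display of 10/10 and 25/25 with their exact intervals
  expect_equal(format_ci(s$spec_x, s$spec_n), "100% [86-100%]")
})

test_that("a single-case syndrome has zero leave-one-out sensitivity", {
  ids <- c("lone", paste0("c", 1:5))
  sheet <- toy_sheet(ids, c("case", rep("control", 5)),
                     syndromes = c("Syn", rep(NA, 5)))
  feats <- toy_features(c(5, 0.1, 0.2, 0.3, 0.15, 0.25), ids)
  def <- episignature("Sig", syndrome = "Syn", probe_ids = rownames(feats))
  for (cfg in c("1/1", "2/3")) {
    s <- loo_evaluate(feats, sheet, def, configs = cfg)$summary
    expect_equal(s$sens, 0)
  }
})

test_that("null cohorts give high specificity and near-zero sensitivity", {
  co <- generate_cohort(cohort_config(
    list(syndrome_spec("S1", delta_beta = 0)), n_background_probes = 300,
    n_controls = 50, seed = 1))
  res <- residualize(co$betas, co$sheet, fit_samples = control_ids(co$sheet))
  s <- loo_evaluate(res, co$sheet, co$signatures[[1]], configs = "3/4")$summary
  expect_gte(s$spec, 0.96)
  expect_lte(s$sens, 0.20)
})

test_that("leave-one-out calls equal a naive brute-force reimplementation", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      n <- sample(6:12, 1)
      roles <- c("case", "case", "control",
                 sample(c("case", "control"), n - 3, replace = TRUE))
      syndromes <- ifelse(roles == "case",
                          sample(c("SynA", "SynB"), n, replace = TRUE), NA)
      feats <- matrix(rnorm(8 * n), 8,
                      dimnames = list(paste0("cg", 1:8), paste0("s", 1:n)))
    })
    if (!any(roles == "control")) next
    sheet <- toy_sheet(paste0("s", 1:n), roles, syndromes = syndromes)
    def <- episignature("SigA", syndrome = "SynA", probe_ids = paste0("cg", 1:8))
    labels <- ifelse(roles == "control", "control", syndromes)
    for (cfg in list(c(1, 2), c(2, 3), c(3, 4))) {
      if (cfg[2] >= n) next
      rep <- loo_evaluate(feats, sheet, def,
                          configs = sprintf("%d/%d", cfg[1], cfg[2]))
      oracle <- brute_loo_calls(feats, labels, k = cfg[2], m = cfg[1])
      expect_equal(unname(rep$calls[[4]]), unname(oracle))
    }
  }
})

test_that("sensitivity is non-increasing in the required consensus m", {
  co <- generate_cohort(cohort_config(
    list(syndrome_spec("S1", delta_beta = 0.08, fraction_intermediate = 0.5)),
    n_background_probes = 300, n_controls = 25, noise_sd = 0.5, seed = 1))
  res <- residualize(co$betas, co$sheet, fit_samples = control_ids(co$sheet))
  rep <- loo_evaluate(res, co$sheet, co$signatures[[1]],
                      configs = c("2/4", "3/4", "4/4"))
  s <- rep$summary
  expect_true(s$sens[s$config == "4/4"] <= s$sens[s$config == "3/4"])
  expect_true(s$sens[s$config == "3/4"] <= s$sens[s$config == "2/4"])
  # and the same holds mechanically on every per-sample call
  calls <- rep$calls
  pos4 <- calls[["4/4"]] == "S1"
  pos3 <- calls[["3/4"]] == "S1"
  pos2 <- calls[["2/4"]] == "S1"
  expect_true(all(!pos4 | pos3))
  expect_true(all((!pos3 | pos2)[calls$role == "case"]))
})

test_that("female carriers of X-linked syndromes are excluded unless requested", {
  syn <- syndrome_spec("SX", n_cases = 12, x_linked = TRUE,
                       female_attenuation = 0.3)
  co <- generate_cohort(cohort_config(list(syn), n_background_probes = 200,
                                      n_controls = 20, seed = 4))
  n_male <- sum(co$sheet$role == "case" & co$sheet$sex == "M")
  res <- residualize(co$betas, co$sheet, fit_samples = control_ids(co$sheet))
  s <- loo_evaluate(res, co$sheet, co$signatures[[1]], configs = "3/4")$summary
  expect_equal(s$sens_n, n_male)
  s_all <- loo_evaluate(res, co$sheet, co$signatures[[1]], configs = "3/4",
                        include_female_carriers = TRUE)$summary
  expect_equal(s_all$sens_n, 12)
})

test_that("inter-syndrome specificity counts other carriers not called this syndrome", {
  co <- strong_cohort(seed = 5, n_syndromes = 3)
  res <- residualize(co$betas, co$sheet, fit_samples = control_ids(co$sheet))
  s <- loo_evaluate(res, co$sheet, co$signatures[[1]], configs = "3/4")$summary
  expect_equal(s$inter_spec_n, 20)   # cases of the two other syndromes
  expect_equal(s$inter_spec, 1)
})

test_that("multi-signature evaluation stacks summaries and call tables", {
  co <- strong_cohort(seed = 6, n_syndromes = 2)
  res <- residualize(co$betas, co$sheet, fit_samples = control_ids(co$sheet))
  rep <- evaluate_signatures(res, co$sheet, co$signatures,
                             configs = c("3/4", "4/4"))
  expect_equal(nrow(rep$summary), 4)
  expect_setequal(unique(rep$summary$signature), c("S1", "S2"))
})

test_that("test samples are classified against the full validation set", {
  co <- generate_cohort(cohort_config(
    list(syndrome_spec("S1")), n_background_probes = 200, n_controls = 25,
    n_vus_per_syndrome = 12, seed = 2))
  res <- residualize(co$betas, co$sheet, fit_samples = control_ids(co$sheet))
  val <- co$sheet$role %in% c("case", "control")
  vus <- co$sheet$role == "vus"
  calls <- classify_test_samples(res[, val], co$sheet[val, ], res[, vus],
                                 co$signatures[[1]])
  merged <- merge(calls, co$sheet[vus, c("sample_id", "true_effect")])
  # full-effect carriers duplicate the case cluster; nulls the control cluster
  expect_true(all(merged$call[merged$true_effect == 1] == "S1"))
  expect_true(all(merged$call[merged$true_effect == 0] == "control"))
  # half-effect carriers never get a clean confident control call
  half <- merged[merged$true_effect == 0.5, ]
  expect_true(all(half$call %in% c("S1", "control", "no_call")))
  expect_true(all(half$intermediate | half$call %in% c("S1", "control")))
})

test_that("perfect performance recurs across seeded strong-effect cohorts", {
  perfect <- 0L
  for (seed in 1:20) {
    co <- strong_cohort(seed = seed)
    res <- residualize(co$betas, co$sheet,
                       fit_samples = control_ids(co$sheet))
    s <- loo_evaluate(res, co$sheet, co$signatures[[1]],
                      configs = "3/4")$summary
    perfect <- perfect + (s$sens == 1 && s$spec == 1)
  }
  expect_gte(perfect / 20, 0.95)
})
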