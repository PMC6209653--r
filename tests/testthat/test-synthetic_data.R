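test_that("simulation is deterministic and reorder-reproducible", {
  cfg <- sim_config(k_studies = 6, seed = 99)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$manifest$per_study_or, b$manifest$per_study_or)
  # per-study substreams: study i is the same regardless of which others
  # are generated
  s3_alone <- simulate_study(cfg, 3)
  expect_identical(s3_alone[, names(a$records)], a$records[3, ],
                   ignore_attr = TRUE)
  # simulation does not perturb the caller's RNG stream
  set.seed(5); before <- rnorm(3)
  set.seed(5); invisible(simulate_dataset(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("null model makes case and control genotype distributions identical", {
  # closed form: with psi = 1 the tilt is flat under every inheritance model
  for (inh in c("multiplicative", "dominant", "recessive")) {
    cfg <- sim_config(true_or = 1, inheritance = inh, control_af = 0.3,
                      k_studies = 1, n_cases_range = c(60000, 60000),
                      n_controls_range = c(60000, 60000), seed = 7)
    sim <- simulate_dataset(cfg)$records
    p_case <- c(sim$case_hom_risk, sim$case_het, sim$case_hom_other) / 60000
    p_ctrl <- c(sim$ctrl_hom_risk, sim$ctrl_het, sim$ctrl_hom_other) / 60000
    expect_equal(p_case, p_ctrl, tolerance = 0.02)
  }
})

test_that("case genotype probabilities follow the odds-tilted closed form", {
  q <- 0.5; psi <- 1.6
  cfg <- sim_config(true_or = psi, inheritance = "multiplicative",
                    control_af = q, k_studies = 1,
                    n_cases_range = c(2e5, 2e5),
                    n_controls_range = c(100, 100), seed = 11)
  sim <- simulate_dataset(cfg)$records
  expected <- c(psi^2, 2 * psi, 1) / sum(c(psi^2, 2 * psi, 1))
  observed <- c(sim$case_hom_risk, sim$case_het, sim$case_hom_other) / 2e5
  expect_equal(observed, expected, tolerance = 0.01)
})

test_that("dataset composition matches configured ethnicity weights and ranges", {
  cfg <- sim_config(k_studies = 36, seed = 3,
                    n_cases_range = c(104, 5302),
                    n_controls_range = c(98, 4161),
                    control_af = DEFAULT_AF_MAP)
  sim <- simulate_dataset(cfg)
  recs <- sim$records
  expect_equal(nrow(recs), 36)
  expect_true(all(recs$ethnicity %in% ETHNICITY_LEVELS))
  n_cases <- recs$case_hom_risk + recs$case_het + recs$case_hom_other
  expect_true(all(n_cases >= 104 & n_cases <= 5302))
  expect_length(sim$manifest$per_study_or, 36)
  # per-ethnicity AF map drives control frequencies apart
  col <- as_variant_collection(recs)
  ea <- pooled_af(col[[1]], "East Asian")
  eu <- pooled_af(col[[1]], "European")
  expect_gt(ea$af_controls, eu$af_controls + 0.2)
  # single-study dataset remains usable at study level
  one <- simulate_dataset(sim_config(k_studies = 1, seed = 4))
  expect_equal(nrow(one$records), 1)
  expect_s3_class(study_effect(record_tables(one$records, "allele")[[1]]),
                  "effect_estimate")
})

test_that("simulated controls are consistent with Hardy-Weinberg equilibrium", {
  # type-I behaviour of the HWE diagnostic at the 5% level on HWE draws
  cfg <- sim_config(true_or = 1.3, control_af = 0.4, k_studies = 1,
                    n_cases_range = c(100, 100),
                    n_controls_range = c(2000, 2000))
  rejections <- vapply(1:400, function(r) {
    cfg$seed <- 5000 + r
    sim <- simulate_dataset(cfg)$records
    hwe_test(genotype_counts(sim$ctrl_hom_risk, sim$ctrl_het,
                             sim$ctrl_hom_other))$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.01)
  expect_lt(mean(rejections), 0.10)
})

test_that("model discrimination: recessive-generated data favours the recessive model", {
  cfg <- sim_config(true_or = 1.5, inheritance = "recessive",
                    control_af = 0.4, k_studies = 10,
                    n_cases_range = c(2000, 2000),
                    n_controls_range = c(2000, 2000))
  wins <- vapply(1:60, function(r) {
    cfg$seed <- 7000 + r
    recs <- simulate_dataset(cfg)$records
    p_rec <- pool_tables(record_tables(recs, "recessive"), recs$study_id)$p
    p_dom <- pool_tables(record_tables(recs, "dominant"), recs$study_id)$p
    p_rec < p_dom
  }, logical(1))
  expect_gt(mean(wins), 0.8)
})

test_that("between-study spread triggers heterogeneity detection and random effects", {
  cfg <- sim_config(true_or = 1.3, control_af = 0.4, k_studies = 15,
                    between_study_sd = 0.3,
                    n_cases_range = c(1000, 1000),
                    n_controls_range = c(1000, 1000))
  random_selected <- vapply(1:40, function(r) {
    cfg$seed <- 9000 + r
    recs <- simulate_dataset(cfg)$records
    res <- pool_tables(record_tables(recs, "allele"), recs$study_id)
    res$i_squared > 50 && res$method == "random_DL"
  }, logical(1))
  expect_gt(mean(random_selected), 0.5)
})

test_that("null_calibration rate is exact at alpha = 1 and monotone in alpha", {
  cfg <- sim_config(true_or = 1, k_studies = 5,
                    n_cases_range = c(200, 200),
                    n_controls_range = c(200, 200), seed = 21)
  cal <- null_calibration(cfg, replicates = 50, alpha = 1)
  expect_equal(cal$rate, 1)
  rates <- vapply(c(0.01, 0.05, 0.2, 0.5),
                  function(a) mean(cal$p < a), numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("config validation rejects degenerate parameters", {
  expect_error(sim_config(true_or = -1))
  expect_error(sim_config(control_af = 0), "strictly between")
  expect_error(sim_config(control_af = 1), "strictly between")
  expect_error(sim_config(between_study_sd = -0.1))
  expect_error(sim_config(ethnicity_weights = c(foo = 1)), "named by")
  # degenerate per-ethnicity lookup surfaces as an error at draw time
  cfg <- sim_config(control_af = c("European" = 0.4), k_studies = 1,
                    ethnicity_weights = c("East Asian" = 1), seed = 2)
  expect_error(simulate_dataset(cfg), "degenerate")
})
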