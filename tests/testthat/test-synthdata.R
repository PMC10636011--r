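test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(maf_range = c(0.5, 0.05)), class = "fallmr_config_error")
  expect_error(sim_config(maf_range = c(0, 0.5)), class = "fallmr_config_error")
  expect_error(sim_config(case_prevalence = 0), class = "fallmr_config_error")
  expect_error(sim_config(overlap_fraction = 1.2), class = "fallmr_config_error")
  expect_error(sim_config(n_individuals = 0), class = "fallmr_config_error")
  expect_error(sim_config(within_block_r = 1), class = "fallmr_config_error")
})

test_that("genotype simulation is deterministic and respects its MAF range", {
  cfg <- sim_config(n_individuals = 500, n_variants = 30, seed = 5)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$variants, g2$variants)
  expect_true(all(g1$dosages %in% 0:2))
  # empirical MAF tracks the drawn MAF up to sampling error
  emp <- colMeans(g1$dosages) / 2
  expect_gt(cor(emp, g1$variants$maf), 0.9)
  expect_true(all(g1$variants$info > 0 & g1$variants$info <= 1))
})

test_that("block LD structure is present within and absent between blocks", {
  cfg0 <- sim_config(n_individuals = 10000, n_variants = 40,
                     ld_block_size = 10, within_block_r = 0, seed = 2)
  g0 <- simulate_genotypes(cfg0)
  R0 <- cor(g0$dosages)
  off <- R0[upper.tri(R0)]
  expect_lt(mean(off^2), 0.01)  # independence case

  cfg8 <- sim_config(n_individuals = 10000, n_variants = 40,
                     ld_block_size = 10, within_block_r = 0.8, seed = 2)
  g8 <- simulate_genotypes(cfg8)
  R8 <- cor(g8$dosages)
  within <- R8[1:10, 1:10][upper.tri(diag(10))]
  between <- as.vector(R8[1:10, 11:20])
  expect_gt(mean(within^2), 10 * mean(between^2))
  expect_gt(mean(within^2), 0.2)
})

test_that("trait simulation hits the target prevalence and links count to status", {
  cfg <- sim_config(n_individuals = 50000, n_variants = 20,
                    case_prevalence = 0.10, seed = 8)
  ct <- simulate_traits(simulate_genotypes(cfg))
  frac <- mean(ct$cohort$fall_status == "case")
  expect_lt(abs(frac - 0.10), 0.01)
  # conservation + case <=> count >= 1
  expect_equal(sum(ct$cohort$fall_status == "case") +
                 sum(ct$cohort$fall_status == "control"),
               cfg$n_individuals)
  expect_identical(ct$cohort$fall_count >= 1L,
                   ct$cohort$fall_status == "case")
  expect_lt(abs(sd(ct$cohort$exposure) - 1), 0.01)
})

test_that("null generator yields a null observational association and confounding biases it", {
  cfg0 <- sim_config(n_individuals = 20000, n_variants = 20,
                     true_causal_effect = 0, seed = 3)
  ct0 <- simulate_traits(simulate_genotypes(cfg0))
  om0 <- observational_model(ct0$cohort, "exposure", "fall_status")
  expect_lt(abs(log(om0$estimate)), 3 * (log(om0$ci_high) - log(om0$estimate)) / 1.96)

  cfgc <- sim_config(n_individuals = 20000, n_variants = 20,
                     true_causal_effect = 0, confounder_effect_x = 0.5,
                     confounder_effect_y = 0.5, seed = 3)
  ctc <- simulate_traits(simulate_genotypes(cfgc))
  omc <- observational_model(ctc$cohort, "exposure", "fall_status")
  expect_gt(omc$estimate, 1)     # bias present by construction
  expect_lt(omc$ci_low, omc$estimate)
  expect_gt(omc$ci_low, 1)       # and clearly so
})

test_that("unreachable prevalence raises an informative error", {
  cfg <- sim_config(n_individuals = 200, n_variants = 5,
                    true_causal_effect = 50, case_prevalence = 1e-6, seed = 1)
  g <- simulate_genotypes(cfg)
  expect_error(simulate_traits(g), "achievable range",
               class = "fallmr_config_error")
})

test_that("summary-statistic pair reproduces overlap correlation and the noise-free ratio", {
  # overlap 0: error correlation ~ 0 across replicates
  errs <- vapply(1:40, function(s) {
    cfg <- sim_config(n_variants = 200, overlap_fraction = 0,
                      ld_block_size = 1, selection_pvalue = 1, seed = s)
    pair <- simulate_sumstats_pair(cfg, n_exposure = 1000, n_outcome = 1000)
    ex <- pair$exposure_stats$beta - pair$truth$beta_x_true_all
    ey <- pair$outcome_stats$beta -
      pair$truth$true_causal_effect * pair$truth$beta_x_true_all
    cor(ex, ey)
  }, numeric(1))
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)) + 0.02)

  # full overlap: correlation near the configured rho
  cfg <- sim_config(n_variants = 5000, overlap_fraction = 1,
                    pheno_correlation = 0.4, ld_block_size = 1,
                    selection_pvalue = 1, seed = 1)
  pair <- simulate_sumstats_pair(cfg, n_exposure = 1000, n_outcome = 1000)
  ex <- pair$exposure_stats$beta - pair$truth$beta_x_true_all
  ey <- pair$outcome_stats$beta - pair$truth$beta_y_true_all
  expect_lt(abs(cor(ex, ey) - 0.4), 0.05)
  expect_equal(pair$truth$error_correlation, 0.4)

  # noise-free limit: beta_y/beta_x equals the causal effect exactly
  cfg2 <- sim_config(n_variants = 50, true_causal_effect = 0.25,
                     selection_pvalue = 1, seed = 2)
  p2 <- simulate_sumstats_pair(cfg2, n_exposure = 1e12, n_outcome = 1e12)
  expect_equal(p2$outcome_stats$beta / p2$exposure_stats$beta,
               rep(0.25, 50), tolerance = 2e-3)
})

test_that("threshold selection reproduces the winner's curse", {
  diffs <- vapply(1:20, function(s) {
    cfg <- sim_config(n_variants = 1000, exposure_h2 = 0.05,
                      ld_block_size = 1, selection_pvalue = 1e-4, seed = s)
    pair <- simulate_sumstats_pair(cfg, n_exposure = 20000)
    mean(abs(pair$exposure_stats$beta)) - mean(abs(pair$truth$beta_x_true))
  }, numeric(1))
  expect_gt(mean(diffs), 0)  # estimated effects exceed the truth on average
  expect_gt(mean(diffs > 0), 0.9)

  cfg <- sim_config(n_variants = 20, exposure_h2 = 1e-6,
                    selection_pvalue = 1e-30, seed = 1)
  expect_error(simulate_sumstats_pair(cfg, n_exposure = 100),
               "retained zero", class = "fallmr_config_error")
})

test_that("event-log generation honours counts, no-record flags and round-trips", {
  cfg <- sim_config(n_individuals = 400, n_variants = 10, seed = 6)
  ct <- simulate_traits(simulate_genotypes(cfg))
  el <- simulate_event_log(ct$cohort, seed = 6, no_record_fraction = 0.05)
  codes <- example_code_list()

  # flagged persons emit zero rows
  expect_true(length(el$no_record_persons) > 0)
  expect_false(any(el$events$person_id %in% el$no_record_persons))

  # cases with fall_count = k have >= k distinct fall dates (exactly k here)
  ph <- derive_fall_status(el$events, codes,
                           persons = ct$cohort$person_id)
  withrec <- setdiff(ct$cohort$person_id, el$no_record_persons)
  cmp <- merge(ph[ph$person_id %in% withrec, ],
               ct$cohort[, c("person_id", "fall_status", "fall_count")],
               by = "person_id")
  expect_true(all((cmp$status == "case") == (cmp$fall_status == "case")))
  cases <- cmp[cmp$status == "case", ]
  expect_identical(cases$fall_count.x, cases$fall_count.y)

  # generator refuses a code list without fall codes
  bad <- new_code_list(data.frame(vocabulary = "ICD10", code = "I10",
                                  category = "non_fall"))
  expect_error(simulate_event_log(ct$cohort, bad, seed = 1),
               class = "fallmr_config_error")
})

test_that("sex-specific generator records per-sex n and plants interactions", {
  sx <- simulate_sex_specific(
    sim_config(n_individuals = 30000, n_variants = 50, ld_block_size = 1,
               seed = 5),
    male_effect = 0.2, female_effect = 0.05
  )
  n_m <- sum(sx$cohort$sex == "male")
  expect_true(all(sx$male_stats$n == n_m))
  expect_true(all(sx$female_stats$n == nrow(sx$cohort) - n_m))

  # equal effects: interaction z ~ N(0,1)
  sx0 <- simulate_sex_specific(
    sim_config(n_individuals = 8000, n_variants = 100, ld_block_size = 1,
               seed = 9),
    male_effect = 0.1, female_effect = 0.1
  )
  sel0 <- select_sex_specific_instruments(sx0$male_stats, sx0$female_stats,
                                          interaction_alpha = 0.05,
                                          f_min = 0)
  z <- sel0$interaction$z_int
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)) + 0.05)
  expect_lt(abs(sd(z) - 1), 0.2)
})
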