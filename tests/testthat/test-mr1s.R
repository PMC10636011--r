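test_that("allele scores sum weighted dosages and impute missing values", {
  D <- rbind(c(0, 1, 2), c(2, 2, 0), c(1, 0, 1))
  expect_equal(build_allele_score(D, c(1, 1, 1)), c(3, 4, 2))
  expect_equal(build_allele_score(D, c(0, 0, 0)), c(0, 0, 0))
  expect_error(build_allele_score(D, numeric(0)),
               class = "fallmr_config_error")
  expect_error(build_allele_score(D, c(1, 1)),
               class = "fallmr_config_error")
  # flipping a variant's coding and negating its weight shifts scores by
  # a constant: identical after centring
  D_flip <- D
  D_flip[, 2] <- 2 - D[, 2]
  s1 <- build_allele_score(D, c(0.5, 0.3, 0.2))
  s2 <- build_allele_score(D_flip, c(0.5, -0.3, 0.2))
  expect_equal(s1 - mean(s1), s2 - mean(s2), tolerance = 1e-12)
  # missing dosage imputed to twice the (observed) allele frequency
  D_na <- D
  D_na[1, 1] <- NA
  s3 <- build_allele_score(D_na, c(1, 0, 0))
  expect_equal(s3[1], 2 * mean(D[2:3, 1]) / 2)
})

test_that("two-stage estimation collapses to OLS and the Wald ratio where it must", {
  fx <- fx_confounded_cohort()
  dat <- fx$data
  set.seed(2)
  dat$y_lin <- 0.3 * dat$exposure + 0.6 * dat$confounder + rnorm(nrow(dat))

  # degenerate IV: instrument numerically equal to the exposure
  dat$self <- dat$exposure
  # the self-instrument first stage fits perfectly; lm's summary warns
  tsls_self <- suppressWarnings(
    mr_tsls(dat, "self", "exposure", "y_lin",
            covariates = character(0), family = "linear")
  )
  ols <- coef(lm(y_lin ~ exposure, dat))[2]
  expect_lt(abs(tsls_self$beta - ols), 1e-10)

  # just-identified single-instrument design equals the Wald ratio
  tsls_iv <- mr_tsls(dat, "score", "exposure", "y_lin",
                     covariates = character(0), family = "linear")
  wald <- coef(lm(y_lin ~ score, dat))[2] / coef(lm(exposure ~ score, dat))[2]
  expect_lt(abs(tsls_iv$beta - wald), 1e-8)
  expect_gt(tsls_iv$first_stage_F, 30)
  expect_false(tsls_iv$weak_instrument)
})

test_that("two-stage fits recover the causal effect where OLS is confounded", {
  fx <- fx_confounded_cohort()
  dat <- fx$data
  # logistic second stage on the binary fall outcome
  fit <- mr_tsls(dat, "score", "exposure", "fall_status",
                 family = "logistic")
  expect_lt(abs(fit$beta - 0.3), 3 * fit$se)
  naive <- observational_model(dat, "exposure", "fall_status",
                               standardize = FALSE)
  expect_gt(log(naive$estimate), 0.3 + 3 * fit$se)  # OLS is not consistent

  # covariate invariance: an orthogonal covariate barely moves the estimate
  set.seed(3)
  dat$junk <- rnorm(nrow(dat))
  fit_j <- mr_tsls(dat, "score", "exposure", "fall_status",
                   covariates = c("age", "sex", "junk"),
                   family = "logistic")
  expect_lt(abs(fit_j$beta - fit$beta), 0.02)

  # poisson second stage on counts among cases runs and is finite
  cases <- dat[dat$fall_status == "case", ]
  fit_p <- mr_tsls(cases, "score", "exposure", "fall_count",
                   family = "poisson")
  expect_true(is.finite(fit_p$beta) && fit_p$se > 0)
  expect_error(mr_tsls(dat, "score", "exposure", "exposure",
                       family = "poisson"),
               class = "fallmr_config_error")

  td <- generics::tidy(fit)
  expect_equal(td$estimate, fit$beta)
  gl <- generics::glance(fit)
  expect_equal(gl$first_stage_F, fit$first_stage_F)
})

test_that("never-stratum negative control is null while ever-stratum recovers", {
  cfg <- sim_config(n_individuals = 20000, n_variants = 30,
                    ld_block_size = 1, exposure_h2 = 0.3,
                    true_causal_effect = 0.4, seed = 12)
  g <- simulate_genotypes(cfg)
  ct <- simulate_traits(g, genetic_effect_never_scale = 0)
  dat <- ct$cohort
  dat$score <- build_allele_score(g$dosages, ct$truth$variant_effects)
  set.seed(12)
  dat$y_lin <- 0.4 * dat$exposure + rnorm(nrow(dat))
  sm <- stratified_mr(dat, "stratum", "score", "exposure", "y_lin",
                      family = "linear")
  never <- sm$by_stratum[sm$by_stratum$stratum == "never", ]
  ever <- sm$by_stratum[sm$by_stratum$stratum == "ever", ]
  # the reduced-form instrument-outcome association must be null where the
  # instrument does not act on the exposure
  rf_never <- summary(lm(y_lin ~ score,
                         dat[dat$stratum == "never", ]))$coefficients
  expect_lt(abs(rf_never["score", 1]), 3 * rf_never["score", 2])
  expect_lt(abs(ever$beta - 0.4), 3 * ever$se)
  expect_gt(ever$first_stage_F, 100)
  expect_lt(never$first_stage_F, 30)
  expect_equal(sum(sm$by_stratum$n), nrow(dat))
  expect_true(!is.null(sm$contrast))
  expect_error(stratified_mr(dplyr::mutate(dat, stratum = "only"),
                             "stratum", "score", "exposure", "y_lin"),
               class = "fallmr_config_error")
})

test_that("sex-specific selection applies interaction and strict F thresholds", {
  sx <- simulate_sex_specific(
    sim_config(n_individuals = 30000, n_variants = 50, ld_block_size = 1,
               seed = 5),
    male_effect = 0.2, female_effect = 0.05
  )
  sel <- select_sex_specific_instruments(sx$male_stats, sx$female_stats)
  planted <- sx$truth$sex_specific_variants
  picked <- c(sel$male_set$variant_id, sel$female_set$variant_id)
  # sensitivity and specificity at design effect sizes
  expect_gte(mean(planted %in% picked), 0.95)
  expect_gte(mean(picked %in% planted), 0.95)
  expect_true(all(sel$male_set$f_stat > 15))

  # strict boundary: (beta/se)^2 = 14.9 in the stronger sex is excluded
  m <- tibble::tibble(variant_id = "v", beta = sqrt(14.9) * 0.1, se = 0.1)
  f <- tibble::tibble(variant_id = "v", beta = 0, se = 0.1)
  expect_warning(
    sel_b <- select_sex_specific_instruments(m, f, interaction_alpha = 0.5),
    "no variant"
  )
  expect_equal(nrow(sel_b$male_set) + nrow(sel_b$female_set), 0)
  # and 15.1 passes
  m2 <- tibble::tibble(variant_id = "v", beta = sqrt(15.1) * 0.1, se = 0.1)
  sel_ok <- select_sex_specific_instruments(m2, f, interaction_alpha = 0.5)
  expect_equal(sel_ok$male_set$variant_id, "v")
})

test_that("sex-stratified IVW combines per-sex estimates by inverse variance", {
  set.seed(8)
  k <- 12
  ins <- structure(
    list(
      male_set = tibble::tibble(variant_id = sprintf("v%d", 1:k),
                                beta = runif(k, 0.1, 0.3), se = 0.01,
                                f_stat = 400),
      female_set = tibble::tibble(variant_id = sprintf("w%d", 1:k),
                                  beta = runif(k, 0.1, 0.3), se = 0.01,
                                  f_stat = 400),
      f_threshold_used = 15
    ),
    class = "sex_specific_instruments"
  )
  truth <- 0.25
  mk_out <- function(set) {
    tibble::tibble(variant_id = set$variant_id,
                   beta = truth * set$beta + rnorm(k, 0, 0.02), se = 0.02)
  }
  res <- sex_stratified_mr(ins, mk_out(ins$male_set), mk_out(ins$female_set))
  comb <- res[res$method == "IVW_sex_combined", ]
  per_sex <- res[res$method != "IVW_sex_combined", ]
  w <- 1 / per_sex$se^2
  expect_equal(comb$beta, sum(w * per_sex$beta) / sum(w), tolerance = 1e-12)
  expect_equal(comb$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_lt(abs(comb$beta - truth), 3 * comb$se)

  # identical per-sex data: combined equals either sex, SE / sqrt(2)
  out_m <- mk_out(ins$male_set)
  ins_same <- ins
  ins_same$female_set <- ins$male_set
  res_same <- sex_stratified_mr(ins_same, out_m, out_m)
  comb_s <- res_same[res_same$method == "IVW_sex_combined", ]
  male_s <- res_same[res_same$method == "IVW_male", ]
  expect_equal(comb_s$beta, male_s$beta, tolerance = 1e-12)
  expect_equal(comb_s$se, male_s$se / sqrt(2), tolerance = 1e-12)

  # one empty sex: combined equals the other
  ins_one <- ins
  ins_one$female_set <- ins$female_set[0, ]
  res_one <- sex_stratified_mr(ins_one, out_m, out_m[0, ])
  expect_equal(res_one$beta[res_one$method == "IVW_sex_combined"],
               res_one$beta[res_one$method == "IVW_male"], tolerance = 1e-12)
})
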