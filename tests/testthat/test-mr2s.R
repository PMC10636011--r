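mk_stats <- function(id, ea, oa, eaf, beta, se = 0.02) {
  tibble::tibble(variant_id = id, effect_allele = ea, other_allele = oa,
                 eaf = eaf, beta = beta, se = se)
}

test_that("harmonisation aligns, flips and drops ambiguous palindromes", {
  ex <- mk_stats(c("v1", "v2", "v3", "v4"),
                 c("A", "A", "A", "C"), c("G", "C", "T", "G"),
                 c(0.3, 0.3, 0.50, 0.3), c(0.1, 0.2, 0.3, 0.4))
  out <- dplyr::bind_rows(
    mk_stats("v1", "A", "G", 0.3, 0.05),      # aligned
    mk_stats("v2", "C", "A", 0.7, -0.07),     # swapped alleles
    mk_stats("v3", "A", "T", 0.5, 0.02),      # palindromic, EAF 0.50
    mk_stats("v4", "G", "C", 0.7, 0.03)       # palindromic C/G but EAF 0.3
  )
  h <- harmonise_instruments(ex, out)
  act <- setNames(h$action, h$variant_id)
  expect_equal(act[["v1"]], "kept")
  expect_equal(act[["v2"]], "flipped")
  expect_equal(h$beta_y[h$variant_id == "v2"], 0.07)  # sign negated
  expect_equal(act[["v3"]], "dropped_palindromic")
  expect_equal(act[["v4"]], "flipped")                # unambiguous palindrome
  expect_error(
    harmonise_instruments(ex, mk_stats("zz", "A", "G", 0.3, 0.1)),
    "share no variants", class = "fallmr_config_error"
  )
})

test_that("IVW equals its closed-form oracle and the single-instrument ratio", {
  ins <- fx_instruments()
  w <- 1 / ins$se_y^2
  oracle <- sum(w * ins$beta_x * ins$beta_y) / sum(w * ins$beta_x^2)
  est <- mr_ivw(ins)
  expect_lt(abs(est$beta - oracle), 1e-10)
  se_fixed <- 1 / sqrt(sum(w * ins$beta_x^2))
  Q <- sum(w * (ins$beta_y - oracle * ins$beta_x)^2)
  expect_lt(abs(est$Q - Q), 1e-10)
  expect_equal(est$se, se_fixed * max(1, sqrt(Q / 9)), tolerance = 1e-12)
  expect_equal(mr_ivw(ins, effects = "fixed")$se, se_fixed,
               tolerance = 1e-12)

  # single instrument: Wald ratio with se_y/|beta_x|
  one <- mr_ivw(tibble::tibble(beta_x = 0.5, se_x = 0.02,
                               beta_y = 0.2, se_y = 0.1))
  expect_equal(one$beta, 0.4)
  expect_equal(one$se, 0.2)
  expect_match(one$note, "Wald ratio")
  expect_error(mr_ivw(tibble::tibble(beta_x = 0, se_x = 1,
                                     beta_y = 1, se_y = 1)),
               class = "fallmr_config_error")

  # identical ratios: beta = c, Q = 0
  hom <- tibble::tibble(beta_x = c(0.2, 0.4, 0.6), se_x = 0.01,
                        beta_y = c(0.1, 0.2, 0.3), se_y = 0.05)
  est_h <- mr_ivw(hom)
  expect_equal(est_h$beta, 0.5, tolerance = 1e-12)
  expect_equal(est_h$Q, 0, tolerance = 1e-12)
})

test_that("MR-Egger reproduces an exact linear law and needs 3 instruments", {
  ins <- tibble::tibble(
    beta_x = c(0.1, 0.2, 0.3, 0.4), se_x = 0.01,
    beta_y = 0.1 + 0.3 * c(0.1, 0.2, 0.3, 0.4), se_y = 0.05
  )
  est <- mr_egger(ins)
  expect_equal(est$beta[est$method == "Egger_slope"], 0.3, tolerance = 1e-10)
  expect_equal(est$beta[est$method == "Egger_intercept"], 0.1,
               tolerance = 1e-10)
  expect_error(mr_egger(ins[1:2, ]), class = "fallmr_config_error")
})

test_that("weighted median matches the cumulative-weight interpolation oracle", {
  ins <- fx_instruments()
  ratio <- ins$beta_y / ins$beta_x
  w <- (ins$beta_x / ins$se_y)^2
  expect_equal(mr_weighted_median(ins, n_boot = 50, seed = 1)$beta,
               oracle_weighted_median(ratio, w), tolerance = 1e-12)

  # equal weights, odd k: interpolated middle ratio by hand
  ins5 <- tibble::tibble(beta_x = rep(1, 5), se_x = 0.01,
                         beta_y = c(0.1, 0.3, 0.2, 0.5, 0.4), se_y = 0.05)
  expect_equal(mr_weighted_median(ins5, n_boot = 50, seed = 1)$beta,
               0.3, tolerance = 1e-12)

  # all ratios equal c: estimate c regardless of weights
  insc <- tibble::tibble(beta_x = c(0.2, 0.5, 1), se_x = 0.01,
                         beta_y = 0.7 * c(0.2, 0.5, 1),
                         se_y = c(0.02, 0.09, 0.04))
  expect_equal(mr_weighted_median(insc, n_boot = 50, seed = 1)$beta, 0.7,
               tolerance = 1e-12)

  # bootstrap SE is seeded and reproducible
  a <- mr_weighted_median(ins, n_boot = 200, seed = 9)
  b <- mr_weighted_median(ins, n_boot = 200, seed = 9)
  expect_identical(a$se, b$se)
})

test_that("penalisation is inert without outliers and crushes a gross outlier", {
  clean <- tibble::tibble(beta_x = rep(1, 5), se_x = 0.01,
                          beta_y = c(0.29, 0.30, 0.31, 0.295, 0.305),
                          se_y = 0.05)
  wm <- mr_weighted_median(clean, n_boot = 50, seed = 2)
  pwm <- mr_penalised_weighted_median(clean, n_boot = 50, seed = 2)
  expect_lt(abs(wm$beta - pwm$beta), 1e-10)

  # one instrument with a wildly outlying ratio
  dirty <- tibble::tibble(beta_x = rep(1, 5), se_x = 0.01,
                          beta_y = c(0.30, 0.31, 0.29, 0.30, 3.0),
                          se_y = 0.05)
  ratio <- dirty$beta_y / dirty$beta_x
  w <- (dirty$beta_x / dirty$se_y)^2
  wm0 <- oracle_weighted_median(ratio, w)
  Qj <- w * (ratio - wm0)^2
  pen <- pmin(1, pchisq(Qj, 1, lower.tail = FALSE) / 0.05)
  expect_lt(pen[5], 0.01)           # outlier keeps < 1% of its weight
  expect_equal(pen[1:4], rep(1, 4)) # consistent instruments untouched
  pwm_d <- mr_penalised_weighted_median(dirty, n_boot = 50, seed = 2)
  expect_equal(pwm_d$beta, oracle_weighted_median(ratio, w * pen),
               tolerance = 1e-12)
  expect_lt(abs(pwm_d$beta - 0.30), 0.02)

  # lax-penalty limit reduces PWM to WM
  wm_d <- mr_weighted_median(dirty, n_boot = 50, seed = 2)
  pwm_lax <- mr_penalised_weighted_median(dirty, penalty_alpha = 1e-12,
                                          n_boot = 50, seed = 2)
  expect_equal(pwm_lax$beta, wm_d$beta, tolerance = 1e-12)
})

test_that("estimators share sign-equivariance and exposure-rescaling laws", {
  ins <- fx_instruments()
  neg <- dplyr::mutate(ins, beta_y = -beta_y)
  scaled <- dplyr::mutate(ins, beta_x = 3 * beta_x, se_x = 3 * se_x)
  for (f in list(mr_ivw,
                 function(x) mr_egger(x)[1, ],
                 function(x) mr_weighted_median(x, n_boot = 50, seed = 4),
                 function(x) mr_penalised_weighted_median(x, n_boot = 50,
                                                          seed = 4))) {
    expect_equal(f(neg)$beta, -f(ins)$beta, tolerance = 1e-10)
    expect_equal(f(scaled)$beta, f(ins)$beta / 3, tolerance = 1e-10)
  }
})

test_that("mean F statistic follows its definition", {
  ins <- tibble::tibble(beta_x = 0.5, se_x = 0.1, beta_y = 0.1, se_y = 0.1)
  expect_equal(mean_f_statistic(ins)$mean_f, 25)
  # null instruments: mean F ~ E[chi2_1] = 1
  set.seed(5)
  k <- 4000
  null_ins <- tibble::tibble(beta_x = rnorm(k, 0, 0.1), se_x = 0.1,
                             beta_y = 0, se_y = 1)
  expect_lt(abs(mean_f_statistic(null_ins)$mean_f - 1), 0.1)
  withn <- mean_f_statistic(ins, n_exposure = 10000)
  expect_true(all(c("r2_sum", "f_cragg_donald") %in% names(withn)))
})

test_that("per-doubling scaling multiplies by ln 2 and guards misuse", {
  e <- mr_estimate_from(beta = 1, se = 0.2)
  sc <- scale_per_doubling(e)
  expect_equal(sc$beta, log(2))
  expect_equal(round(sc$beta, 3), 0.693)

  e2 <- mr_estimate_from(beta = 0.2, se = 0.05)
  sc2 <- scale_per_doubling(e2)
  expect_equal(sc2$beta, 0.2 * log(2), tolerance = 1e-12)
  expect_equal(sc2$se, 0.05 * log(2), tolerance = 1e-12)
  expect_equal(round(sc2$beta, 4), 0.1386)
  expect_equal(round(sc2$se, 4), 0.0347)
  expect_equal(sc2$odds_ratio, exp(0.2 * log(2)), tolerance = 1e-12)
  expect_equal(round(sc2$odds_ratio, 3), 1.149)

  zero <- scale_per_doubling(mr_estimate_from(beta = 0, se = 0.1))
  expect_equal(zero$beta, 0)
  expect_error(scale_per_doubling(sc2), "already",
               class = "fallmr_config_error")
  expect_error(scale_per_doubling(e, exposure_type = "continuous"),
               class = "fallmr_config_error")
})

test_that("tidy/glance/plot methods work on estimator output", {
  ins <- fx_instruments()
  res <- mr_all_methods(ins, n_boot = 50, seed = 1)
  td <- generics::tidy(res)
  expect_equal(nrow(td), 5)  # IVW, slope, intercept, WM, PWM
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  gl <- generics::glance(res)
  expect_equal(gl$k_instruments, 10L)
  p1 <- plot_mr_forest(res)
  p2 <- plot_mr_scatter(ins)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
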