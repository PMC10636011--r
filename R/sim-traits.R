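#' Simulate exposure, confounder and fall outcomes for a genotyped cohort
#'
#' Builds a unit-variance polygenic exposure from the genotypes, then a
#' binary fall status from a logistic model on the exposure and a shared
#' standard-normal confounder, and finally a per-case fall count of the
#' form `1 + Poisson` (optionally gamma-over-dispersed) whose log rate
#' carries the same linear predictor. The logistic intercept is tuned
#' numerically so the expected case fraction matches
#' `config$case_prevalence`.
#'
#' Per-variant genetic effects are drawn as N(0, exposure_h2 / n_variants)
#' on standardised dosages (the standard infinitesimal polygenic model),
#' so the exposure's heritable variance is `exposure_h2` by construction.
#'
#' @param genotypes A [simulate_genotypes()] result.
#' @param config The [sim_config()] used (defaults to the one stored in
#'   `genotypes`).
#' @param never_fraction Fraction of persons assigned to the `"never"`
#'   level of the behavioural stratum column (used by negative-control
#'   analyses); the rest are `"ever"`.
#' @param genetic_effect_never_scale Multiplier applied to the genetic
#'   component of the exposure in the `"never"` stratum. Setting it to 0
#'   makes the instrument inert there, the premise of the never-stratum
#'   negative control.
#'
#' @return A list of class `"fallmr_cohort"`:
#'   * `cohort`: tibble with `person_id`, `sex`, `age`, `confounder`,
#'     `stratum`, `exposure`, `fall_status` (`"case"`/`"control"`),
#'     `fall_count`;
#'   * `truth`: the generating parameters actually used, including the
#'     per-variant effects, tuned intercepts and the exposure scale factor.
#' @examples
#' g <- simulate_genotypes(sim_config(n_individuals = 2000, n_variants = 50,
#'                                    seed = 3))
#' ct <- simulate_traits(g)
#' mean(ct$cohort$fall_status == "case")
#' @export
simulate_traits <- function(genotypes, config = genotypes$config,
                            never_fraction = 0.5,
                            genetic_effect_never_scale = 1) {
  stopifnot(inherits(genotypes, "fallmr_genotypes"))
  set.seed(config$seed + 1000L)
  G <- genotypes$dosages
  n <- nrow(G)
  m <- ncol(G)

  Gs <- scale(G)
  Gs[is.nan(Gs)] <- 0  # monomorphic columns contribute nothing
  b <- rnorm(m, 0, sqrt(config$exposure_h2 / m))
  g_score <- drop(Gs %*% b)

  stratum <- sample(c("never", "ever"), n, replace = TRUE,
                    prob = c(never_fraction, 1 - never_fraction))
  g_eff <- ifelse(stratum == "never",
                  genetic_effect_never_scale * g_score, g_score)

  U <- rnorm(n)
  env_sd <- sqrt(max(1 - config$exposure_h2, 1e-8))
  exposure_raw <- g_eff + config$confounder_effect_x * U +
    rnorm(n, 0, env_sd)
  scale_factor <- sd(exposure_raw)
  exposure <- exposure_raw / scale_factor

  lin <- config$true_causal_effect * exposure +
    config$confounder_effect_y * U
  target <- config$case_prevalence
  f <- function(a) mean(plogis(a + lin)) - target
  if (f(-30) > 0 || f(30) < 0) {
    config_error(sprintf(
      "cannot reach case_prevalence %.3f: achievable range is (%.4f, %.4f)",
      target, mean(plogis(-30 + lin)), mean(plogis(30 + lin))
    ))
  }
  intercept <- uniroot(f, c(-30, 30), tol = 1e-10)$root
  p_case <- plogis(intercept + lin)
  fall <- rbinom(n, 1, p_case)

  # per-case extra falls: 1 + Poisson with the same linear predictor in the
  # log rate, tuned so roughly a third of cases have more than one fall;
  # optional gamma frailty supplies over-dispersion
  count_intercept <- log(0.37)
  rate <- exp(count_intercept + lin)
  if (config$count_dispersion > 0) {
    shape <- 1 / config$count_dispersion
    rate <- rate * rgamma(n, shape = shape, rate = shape)
  }
  fall_count <- ifelse(fall == 1L, 1L + rpois(n, rate), 0L)

  cohort <- tibble(
    person_id = sprintf("P%06d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = round(runif(n, 40, 70), 1),
    confounder = U,
    stratum = stratum,
    exposure = exposure,
    fall_status = if_else(fall == 1L, "case", "control"),
    fall_count = as.integer(fall_count)
  )
  truth <- list(
    variant_effects = b,
    exposure_scale_factor = scale_factor,
    logistic_intercept = intercept,
    count_intercept = count_intercept,
    true_causal_effect = config$true_causal_effect,
    confounder_effect_x = config$confounder_effect_x,
    confounder_effect_y = config$confounder_effect_y,
    genetic_effect_never_scale = genetic_effect_never_scale,
    config = config
  )
  structure(list(cohort = cohort, truth = truth, genotypes = genotypes),
            class = "fallmr_cohort")
}

#' Simulate a pair of genetically correlated quantitative traits
#'
#' Draws two polygenic traits on the same genotypes whose per-variant
#' effects are bivariate normal with correlation `rg`, the ground truth
#' for cross-trait LD score regression.
#'
#' @param genotypes A [simulate_genotypes()] result.
#' @param h2_a,h2_b Heritabilities of the two traits.
#' @param rg True genetic correlation in [-1, 1].
#' @param seed Integer seed.
#' @return List with unit-variance trait vectors `trait_a`, `trait_b` and a
#'   `truth` list.
#' @export
simulate_correlated_traits <- function(genotypes, h2_a = 0.2, h2_b = 0.2,
                                       rg = 0.7, seed = 1L) {
  stopifnot(inherits(genotypes, "fallmr_genotypes"))
  if (abs(rg) > 1) config_error("rg must be in [-1, 1]")
  set.seed(seed + 2000L)
  G <- scale(genotypes$dosages)
  G[is.nan(G)] <- 0
  n <- nrow(G); m <- ncol(G)
  z1 <- rnorm(m); z2 <- rnorm(m)
  b_a <- sqrt(h2_a / m) * z1
  b_b <- sqrt(h2_b / m) * (rg * z1 + sqrt(1 - rg^2) * z2)
  trait_a <- drop(G %*% b_a) + rnorm(n, 0, sqrt(max(1 - h2_a, 1e-8)))
  trait_b <- drop(G %*% b_b) + rnorm(n, 0, sqrt(max(1 - h2_b, 1e-8)))
  list(
    trait_a = drop(scale(trait_a)),
    trait_b = drop(scale(trait_b)),
    truth = list(h2_a = h2_a, h2_b = h2_b, rg = rg,
                 effects_a = b_a, effects_b = b_b)
  )
}
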