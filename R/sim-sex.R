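#' Simulate sex-specific genetic effects with per-sex association tables
#'
#' A configurable subset of variants receives different true exposure
#' effects in males and females (e.g. grip strength, whose genetic
#' architecture differs substantially by sex); the remaining variants
#' share a common effect. Per-sex GWAS summary statistics are computed on
#' the respective subsets of the cohort by a fast linear scan.
#'
#' @param config A [sim_config()].
#' @param male_effect,female_effect Per-variant standardised effect sizes
#'   given to the designated sex-specific variants in each sex.
#' @param n_sex_specific How many variants are designated sex-specific
#'   (the first `n_sex_specific` variants).
#' @return A list of class `"fallmr_sex_sim"` with the genotypes, the
#'   cohort tibble (with per-sex exposure), `male_stats` and
#'   `female_stats` summary tables (per-sex `n` recorded), and `truth`.
#' @export
simulate_sex_specific <- function(config, male_effect = 0.1,
                                  female_effect = 0.1,
                                  n_sex_specific = min(10L, config$n_variants)) {
  stopifnot(inherits(config, "sim_config"))
  geno <- simulate_genotypes(config)
  set.seed(config$seed + 5000L)
  G <- scale(geno$dosages)
  G[is.nan(G)] <- 0
  n <- nrow(G); m <- ncol(G)

  sex <- sample(c("male", "female"), n, replace = TRUE)
  if (length(unique(sex)) < 2) {
    config_error("cohort must contain both sexes")
  }
  idx <- seq_len(n_sex_specific)
  b_shared <- rnorm(m, 0, sqrt(config$exposure_h2 / m))
  b_male <- b_shared; b_female <- b_shared
  b_male[idx] <- male_effect
  b_female[idx] <- female_effect

  env <- rnorm(n, 0, sqrt(max(1 - config$exposure_h2, 0.25)))
  exposure <- ifelse(sex == "male",
                     drop(G %*% b_male), drop(G %*% b_female)) + env

  is_m <- sex == "male"
  male_stats <- linear_scan(geno$dosages[is_m, , drop = FALSE],
                            exposure[is_m],
                            variants = geno$variants[, 1:6])
  female_stats <- linear_scan(geno$dosages[!is_m, , drop = FALSE],
                              exposure[!is_m],
                              variants = geno$variants[, 1:6])
  cohort <- tibble(
    person_id = sprintf("P%06d", seq_len(n)),
    sex = sex,
    exposure = exposure
  )
  structure(
    list(
      genotypes = geno, cohort = cohort,
      male_stats = male_stats, female_stats = female_stats,
      truth = list(
        sex_specific_variants = geno$variants$variant_id[idx],
        male_effect = male_effect, female_effect = female_effect,
        b_male = b_male, b_female = b_female
      )
    ),
    class = "fallmr_sex_sim"
  )
}
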