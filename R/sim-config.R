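#' Simulation configuration for the synthetic fall-susceptibility cohort
#'
#' Collects every knob of the synthetic data-generating process in one
#' validated object. The defaults describe the study conditions the package
#' is designed around: a roughly 10% case-prevalence binary fall phenotype
#' with an over-dispersed per-case fall count, a polygenic standardised
#' exposure, block-structured linkage disequilibrium, and optional
#' confounding, pleiotropy, exposure/outcome sample overlap and
#' significance-threshold instrument selection.
#'
#' @param n_individuals Number of persons in individual-level cohorts.
#' @param n_variants Number of variants (also the instrument-candidate count
#'   for summary-statistic pairs).
#' @param maf_range Length-2 numeric, minor-allele-frequency bounds in
#'   (0, 0.5]; per-variant MAFs are drawn uniformly between them.
#' @param ld_block_size Variants per linkage-disequilibrium block.
#' @param within_block_r Latent pairwise correlation of variants within a
#'   block, in [0, 1).
#' @param info_range Range the simulated imputation-quality (INFO) scores are
#'   drawn from, within (0, 1]. The default keeps everything above standard
#'   QC thresholds; lower the floor to exercise QC filtering.
#' @param case_prevalence Target fall case fraction in (0, 1).
#' @param exposure_h2 Narrow-sense heritability of the simulated exposure,
#'   in [0, 1).
#' @param confounder_effect_x,confounder_effect_y Effect of the shared
#'   standard-normal confounder on the exposure (per SD units) and on the
#'   outcome (per SD log-odds).
#' @param true_causal_effect Causal effect of the exposure on the fall
#'   outcome, log-odds per exposure SD.
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`:
#'   direct variant-to-outcome effects bypassing the exposure.
#' @param pleiotropy_sd,pleiotropy_mean SD and mean of the per-variant
#'   pleiotropic effects (mean is forced to 0 unless mode is directional).
#' @param overlap_fraction Fraction of shared participants between the
#'   exposure and outcome GWAS, in [0, 1]; estimation errors of the two
#'   summary-statistic tables are correlated proportionally to it.
#' @param pheno_correlation Phenotypic (confounded) exposure-outcome
#'   correlation among shared participants; the error correlation is
#'   `overlap_fraction * pheno_correlation`.
#' @param selection_pvalue P-value threshold for instrument discovery in the
#'   exposure table; `1` disables selection (no winner's curse).
#' @param count_dispersion Gamma-frailty over-dispersion of the per-case
#'   fall count (variance of a unit-mean multiplicative frailty); `0` gives
#'   a pure Poisson count.
#' @param seed Integer seed; the same config and seed reproduce every
#'   output exactly.
#'
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_individuals = 500, n_variants = 20, seed = 1)
#' cfg$case_prevalence
#' @export
sim_config <- function(n_individuals = 20000,
                       n_variants = 500,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10,
                       within_block_r = 0.3,
                       info_range = c(0.9, 1),
                       case_prevalence = 0.10,
                       exposure_h2 = 0.2,
                       confounder_effect_x = 0,
                       confounder_effect_y = 0,
                       true_causal_effect = 0,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0,
                       pleiotropy_mean = 0,
                       overlap_fraction = 0,
                       pheno_correlation = 0.2,
                       selection_pvalue = 1,
                       count_dispersion = 0.3,
                       seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (n_individuals < 1 || n_variants < 1) {
    config_error("n_individuals and n_variants must be positive")
  }
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    config_error("maf_range must be ordered and inside (0, 0.5]")
  }
  if (length(info_range) != 2 || info_range[1] > info_range[2] ||
      info_range[1] <= 0 || info_range[2] > 1) {
    config_error("info_range must be ordered and inside (0, 1]")
  }
  if (within_block_r < 0 || within_block_r >= 1) {
    config_error("within_block_r must be in [0, 1)")
  }
  if (case_prevalence <= 0 || case_prevalence >= 1) {
    config_error("case_prevalence must be in (0, 1)")
  }
  if (exposure_h2 < 0 || exposure_h2 >= 1) {
    config_error("exposure_h2 must be in [0, 1)")
  }
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    config_error("overlap_fraction must be in [0, 1]")
  }
  if (selection_pvalue <= 0 || selection_pvalue > 1) {
    config_error("selection_pvalue must be in (0, 1]")
  }
  if (count_dispersion < 0) config_error("count_dispersion must be >= 0")
  if (pleiotropy_mode != "directional") pleiotropy_mean <- 0
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      n_variants = as.integer(n_variants),
      maf_range = as.numeric(maf_range),
      ld_block_size = as.integer(ld_block_size),
      within_block_r = as.numeric(within_block_r),
      info_range = as.numeric(info_range),
      case_prevalence = case_prevalence,
      exposure_h2 = exposure_h2,
      confounder_effect_x = confounder_effect_x,
      confounder_effect_y = confounder_effect_y,
      true_causal_effect = true_causal_effect,
      pleiotropy_mode = pleiotropy_mode,
      pleiotropy_sd = pleiotropy_sd,
      pleiotropy_mean = pleiotropy_mean,
      overlap_fraction = overlap_fraction,
      pheno_correlation = pheno_correlation,
      selection_pvalue = selection_pvalue,
      count_dispersion = count_dispersion,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
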