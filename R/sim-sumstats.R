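#' Simulate an exposure/outcome GWAS summary-statistics pair
#'
#' Generates per-variant true exposure effects from the infinitesimal
#' polygenic model (all variants causal, effect variance
#' `exposure_h2 / n_variants` on the standardised scale), outcome effects
#' as `true_causal_effect * beta_x` plus an optional pleiotropy term, and
#' estimated marginal effects with standard errors `1/sqrt(n)`.
#'
#' Variants carry block-structured linkage disequilibrium: within a block
#' of `ld_block_size` variants the pairwise correlation is a per-block
#' draw `r_b ~ U(0, 2 * within_block_r)` (capped at 0.95), so marginal
#' effects are the LD-smeared `R %*% b`, estimation noise is correlated
#' within blocks with the same structure, and the true LD score
#' `1 + (B - 1) * r_b^2` varies across blocks — which is what makes LD
#' score regression on these tables identifiable. The estimation errors
#' of the exposure and outcome tables are additionally correlated across
#' tables with coefficient `overlap_fraction * pheno_correlation`, the
#' summary-statistic signature of shared participants.
#'
#' If `config$selection_pvalue < 1` and `select` is `TRUE`, only
#' variants whose *estimated* exposure association passes the threshold
#' are retained (winner's-curse selection); the full tables are kept in
#' the result alongside the selected ones, and the ground truth of the
#' retained set is recorded.
#'
#' @param config A [sim_config()]. `n_variants` is the candidate-variant
#'   count; `exposure_h2` fixes the total true exposure-effect variance.
#' @param n_exposure,n_outcome GWAS sample sizes of the two tables.
#' @param select Whether to apply the selection threshold (default: yes
#'   whenever `config$selection_pvalue < 1`).
#' @return A list of class `"fallmr_sumstats_pair"`:
#'   * `exposure_stats`, `outcome_stats`: summary-statistics tibbles
#'     (post-selection) sharing the same variant key set (columns
#'     `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'     `eaf`, `beta`, `se`, `pvalue`, `n`, `info`);
#'   * `exposure_stats_full`, `outcome_stats_full`: the unselected
#'     tables (inputs for LD score regression);
#'   * `ld_scores`: tibble of the true per-variant LD scores;
#'   * `truth`: `true_causal_effect`, per-variant true marginal effects,
#'     `pleiotropy`, `error_correlation`, the retained index and sizes.
#' @examples
#' pair <- simulate_sumstats_pair(
#'   sim_config(n_variants = 30, true_causal_effect = 0.3, seed = 2),
#'   n_exposure = 50000, n_outcome = 50000)
#' nrow(pair$exposure_stats)
#' @export
simulate_sumstats_pair <- function(config, n_exposure = 50000,
                                   n_outcome = 50000,
                                   select = config$selection_pvalue < 1) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_variants < 1) config_error("need at least one variant")
  set.seed(config$seed + 3000L)
  m <- config$n_variants
  bs <- max(1L, min(config$ld_block_size, m))
  block <- as.integer((seq_len(m) - 1L) %/% bs + 1L)
  n_blocks <- max(block)
  r_block <- if (config$within_block_r > 0 && bs > 1) {
    pmin(runif(n_blocks, 0, 2 * config$within_block_r), 0.95)
  } else {
    rep(0, n_blocks)
  }
  r_j <- r_block[block]
  block_size_j <- as.integer(table(block))[block]
  ld_true <- 1 + (block_size_j - 1) * r_j^2

  # equicorrelated-within-block linear map: (R x)_j = (1-r) x_j + r * blocksum
  ld_smear <- function(x) {
    bsum <- as.numeric(tapply(x, block, sum)[block])
    (1 - r_j) * x + r_j * bsum
  }
  # noise with within-block equicorrelation r_b and unit variance
  corr_noise <- function(z_iid, z_common) {
    as.numeric(sqrt(1 - r_j) * z_iid + sqrt(r_j) * z_common[block])
  }

  b <- rnorm(m, 0, sqrt(config$exposure_h2 / m))
  pleio <- switch(config$pleiotropy_mode,
    none = rep(0, m),
    balanced = rnorm(m, 0, config$pleiotropy_sd),
    directional = rnorm(m, config$pleiotropy_mean, config$pleiotropy_sd)
  )
  beta_x_true <- ld_smear(b)
  beta_y_true <- config$true_causal_effect * beta_x_true + ld_smear(pleio)

  se_x <- rep(1 / sqrt(n_exposure), m)
  se_y <- rep(1 / sqrt(n_outcome), m)
  rho <- config$overlap_fraction * config$pheno_correlation
  # cross-table correlation rho applies to both the idiosyncratic and the
  # shared-block components, so corr(e_x_j, e_y_j) = rho exactly
  z1 <- rnorm(m); z2 <- rnorm(m)
  c1 <- rnorm(n_blocks); c2 <- rnorm(n_blocks)
  e_x <- corr_noise(z1, c1)
  e_y <- corr_noise(rho * z1 + sqrt(1 - rho^2) * z2,
                    rho * c1 + sqrt(1 - rho^2) * c2)
  beta_x_hat <- beta_x_true + se_x * e_x
  beta_y_hat <- beta_y_true + se_y * e_y

  meta <- tibble(
    variant_id = sprintf("rs%06d", seq_len(m)),
    chrom = 1L,
    pos = seq_len(m) * 1000L,
    effect_allele = "A",
    other_allele = "G",
    eaf = runif(m, config$maf_range[1], config$maf_range[2])
  )
  mk <- function(beta, se, n) {
    meta |>
      mutate(
        beta = beta, se = se,
        pvalue = 2 * pnorm(-abs(beta / se)),
        n = n, info = 1
      )
  }
  exposure_full <- mk(beta_x_hat, se_x, n_exposure)
  outcome_full <- mk(beta_y_hat, se_y, n_outcome)

  keep <- seq_len(m)
  if (isTRUE(select)) {
    keep <- which(exposure_full$pvalue < config$selection_pvalue)
    if (length(keep) == 0) {
      config_error(sprintf(
        "selection_pvalue = %g retained zero of %d variants",
        config$selection_pvalue, m
      ))
    }
  }
  structure(
    list(
      exposure_stats = exposure_full[keep, ],
      outcome_stats = outcome_full[keep, ],
      exposure_stats_full = exposure_full,
      outcome_stats_full = outcome_full,
      ld_scores = tibble(variant_id = meta$variant_id, ld_score = ld_true),
      truth = list(
        true_causal_effect = config$true_causal_effect,
        beta_x_true = beta_x_true[keep],
        beta_x_true_all = beta_x_true,
        beta_y_true_all = beta_y_true,
        pleiotropy = pleio[keep],
        error_correlation = rho,
        retained = keep,
        n_exposure = n_exposure,
        n_outcome = n_outcome,
        config = config
      )
    ),
    class = "fallmr_sumstats_pair"
  )
}
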