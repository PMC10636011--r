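#' LD scores from genotype dosages
#'
#' For each variant j, the LD score is the sum over variants k within a
#' symmetric window (in variant order, including j itself) of the
#' adjusted squared correlation `r2 - (1 - r2)/(n - 2)`, the usual
#' finite-sample-unbiased estimator. With mutually independent variants
#' the scores are ~1 (the self term); perfectly correlated blocks of size
#' B give scores ~B.
#'
#' @param dosages Numeric matrix, persons x variants.
#' @param window Window half-width in variants on each side (the window
#'   covers `2 * window + 1` variants).
#' @return Tibble `variant_id`, `ld_score`.
#' @export
compute_ld_scores <- function(dosages, window = 50L) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (n <= 2) config_error("need more than 2 individuals for LD scores")
  ids <- colnames(dosages) %||% sprintf("v%d", seq_len(m))
  X <- scale(dosages)
  X[is.nan(X)] <- 0
  adj <- function(r2) r2 - (1 - r2) / (n - 2)
  # self term: r2 = 1 exactly
  scores <- rep(adj(1), m)
  for (d in seq_len(min(window, m - 1L))) {
    # correlations at offset d, vectorised over variant pairs
    r <- colSums(X[, 1:(m - d), drop = FALSE] *
                   X[, (1 + d):m, drop = FALSE]) / (n - 1)
    a <- adj(r^2)
    scores[1:(m - d)] <- scores[1:(m - d)] + a
    scores[(1 + d):m] <- scores[(1 + d):m] + a
  }
  tibble(variant_id = ids, ld_score = scores)
}

# shared two-step weighted LDSC regression of y on x (+ intercept).
# Weights 1/(1 + n*h2*l/m)^2, updated once from an unweighted first pass.
ldsc_regression <- function(y, x, ld, n_eff, m) {
  X <- cbind(intercept = 1, x = x)
  fit0 <- wls_fit(X, y, rep(1, length(y)))
  h2_0 <- min(max(fit0$coef[2], 0), 1)
  w <- 1 / (1 + n_eff * h2_0 * ld / m)^2
  list(weights = w, fit = wls_fit(X, y, w))
}

#' SNP heritability by LD score regression
#'
#' Regresses per-variant chi-square statistics `(beta/se)^2` on
#' `ld_score * n / m` with an intercept; the slope estimates the
#' observed-scale SNP heritability and the intercept the confounding /
#' population-structure term (~1 in its absence). Uncertainty is by
#' leave-one-block-out jackknife over contiguous variant blocks.
#'
#' @param sumstats Summary-statistics tibble (`variant_id`, `beta`, `se`,
#'   `n`).
#' @param ldscores Tibble from [compute_ld_scores()].
#' @param n GWAS sample size (default: median of `sumstats$n`).
#' @param m Number of variants the heritability is spread over (default:
#'   rows of `sumstats`).
#' @param n_blocks Jackknife block count (default 20).
#' @return One-row tibble: `h2`, `se_h2`, `intercept`, `se_intercept`,
#'   `n_blocks`, `m`, `n`.
#' @export
estimate_h2 <- function(sumstats, ldscores, n = NULL, m = NULL,
                        n_blocks = 20L) {
  assert_columns(sumstats, c("variant_id", "beta", "se"), "summary stats")
  dat <- inner_join(sumstats, ldscores, by = "variant_id")
  if (nrow(dat) == 0) config_error("no shared variants with LD scores")
  n <- n %||% stats::median(dat$n)
  m <- m %||% nrow(dat)
  if (nrow(dat) < n_blocks) config_error("fewer variants than blocks")
  chi2 <- (dat$beta / dat$se)^2
  x <- n * dat$ld_score / m
  w <- ldsc_regression(chi2, x, dat$ld_score, n, m)$weights
  fit_on <- function(idx) {
    wls_fit(cbind(1, x[idx]), chi2[idx], w[idx])$coef
  }
  blocks <- contiguous_blocks(nrow(dat), n_blocks)
  jk_h2 <- jackknife_se(nrow(dat), blocks, function(i) fit_on(i)[2])
  jk_int <- jackknife_se(nrow(dat), blocks, function(i) fit_on(i)[1])
  tibble(
    h2 = jk_h2$estimate, se_h2 = jk_h2$se,
    intercept = jk_int$estimate, se_intercept = jk_int$se,
    n_blocks = length(blocks), m = m, n = n
  )
}

#' Convert observed-scale heritability to the liability scale
#'
#' @param h2_observed Observed-scale estimate for a binary trait.
#' @param sample_prevalence,population_prevalence Case fractions in the
#'   analysed sample and the target population.
#' @return Liability-scale heritability.
#' @export
h2_liability <- function(h2_observed, sample_prevalence,
                         population_prevalence) {
  K <- population_prevalence
  P <- sample_prevalence
  z <- stats::dnorm(qnorm(1 - K))
  h2_observed * K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
}

#' Cross-trait genetic correlation by LD score regression
#'
#' Regresses the per-variant z-score products of two traits on
#' `sqrt(n_a * n_b) * ld_score / m`; the slope estimates the genetic
#' covariance and the free intercept absorbs correlated estimation error
#' from sample overlap (the cross-trait intercept). The genetic
#' correlation is `gencov / sqrt(h2_a * h2_b)`. The jackknife recomputes
#' all three regressions per deleted block, so the reported SE reflects
#' their joint sampling variability.
#'
#' @param sumstats_a,sumstats_b Summary-statistics tibbles sharing
#'   variant ids.
#' @param ldscores Tibble from [compute_ld_scores()].
#' @param n_a,n_b Sample sizes (defaults: per-table medians).
#' @param n_blocks Jackknife block count.
#' @return One-row tibble: `rg`, `se`, `p`, `gencov`, `cross_intercept`,
#'   `h2_a`, `h2_b`, `n_blocks`, `defined` (FALSE when either h2 is
#'   non-positive, in which case `rg` is `NA`).
#' @export
estimate_rg <- function(sumstats_a, sumstats_b, ldscores,
                        n_a = NULL, n_b = NULL, n_blocks = 20L) {
  dat <- inner_join(
    sumstats_a |> select(variant_id, beta_a = beta, se_a = se, n_a_col = n),
    sumstats_b |> select(variant_id, beta_b = beta, se_b = se, n_b_col = n),
    by = "variant_id"
  ) |>
    inner_join(ldscores, by = "variant_id")
  if (nrow(dat) == 0) config_error("no shared variants")
  if (nrow(dat) < n_blocks) config_error("fewer variants than blocks")
  n_a <- n_a %||% stats::median(dat$n_a_col)
  n_b <- n_b %||% stats::median(dat$n_b_col)
  m <- nrow(dat)
  z_a <- dat$beta_a / dat$se_a
  z_b <- dat$beta_b / dat$se_b
  ld <- dat$ld_score

  x_h2a <- n_a * ld / m
  x_h2b <- n_b * ld / m
  x_cov <- sqrt(n_a * n_b) * ld / m
  w_a <- ldsc_regression(z_a^2, x_h2a, ld, n_a, m)$weights
  w_b <- ldsc_regression(z_b^2, x_h2b, ld, n_b, m)$weights
  w_x <- sqrt(w_a * w_b)

  comp <- function(idx) {
    h2a <- wls_fit(cbind(1, x_h2a[idx]), z_a[idx]^2, w_a[idx])$coef[2]
    h2b <- wls_fit(cbind(1, x_h2b[idx]), z_b[idx]^2, w_b[idx])$coef[2]
    cv <- wls_fit(cbind(1, x_cov[idx]), (z_a * z_b)[idx], w_x[idx])$coef
    c(h2a = h2a, h2b = h2b, gencov = cv[2], cross_int = cv[1])
  }
  full <- comp(seq_len(m))
  defined <- full["h2a"] > 0 && full["h2b"] > 0
  rg_of <- function(v) {
    if (v["h2a"] <= 0 || v["h2b"] <= 0) return(NA_real_)
    unname(v["gencov"] / sqrt(v["h2a"] * v["h2b"]))
  }
  rg <- rg_of(full)
  blocks <- contiguous_blocks(m, n_blocks)
  leave_out <- vapply(blocks, function(b) comp(setdiff(seq_len(m), b)),
                      numeric(4))
  jk_se <- function(vals) {
    B <- length(vals)
    sqrt((B - 1) / B * sum((vals - mean(vals))^2))
  }
  cross_se <- jk_se(leave_out["cross_int", ])
  se <- NA_real_
  p <- NA_real_
  if (defined) {
    rg_i <- apply(leave_out, 2, function(v) {
      r <- rg_of(v)
      if (is.na(r)) rg else r  # degenerate block falls back to the full fit
    })
    se <- jk_se(rg_i)
    p <- 2 * pnorm(-abs(rg / se))
  }
  tibble(
    rg = rg, se = se, p = p,
    gencov = unname(full["gencov"]),
    cross_intercept = unname(full["cross_int"]),
    cross_intercept_se = cross_se,
    h2_a = unname(full["h2a"]), h2_b = unname(full["h2b"]),
    n_blocks = n_blocks, defined = defined
  )
}

#' Annotate correlation results with a Bonferroni significance flag
#'
#' The reporting rule: a result is significant when `p < alpha / n_tests`
#' (strict inequality). The threshold is echoed in the output, both exact
#' and rounded to 4 decimals for display (0.05/12 prints as 0.0042).
#'
#' @param results Tibble with a `p` column.
#' @param n_tests Number of tests corrected for (default 12).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `results` plus `bonferroni_threshold`,
#'   `bonferroni_threshold_display`, `significant_bonferroni`.
#' @export
bonferroni_report <- function(results, n_tests = 12L, alpha = 0.05) {
  if (n_tests < 1) config_error("n_tests must be >= 1")
  thr <- alpha / n_tests
  results |>
    mutate(
      bonferroni_threshold = thr,
      bonferroni_threshold_display = signif(thr, 2),
      significant_bonferroni = !is.na(p) & p < thr
    )
}
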