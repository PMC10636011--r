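#' Overlap-, weak-instrument- and winner's-curse-corrected IVW
#'
#' Computes the naive IVW estimate from instruments selected at
#' `selection_threshold` in the exposure table, then corrects it for the
#' three biases that afflict two-sample MR when the exposure and outcome
#' GWAS share participants and the instruments were discovered in the
#' exposure data itself:
#'
#' 1. *Sample overlap*: the correlation `c` of the two tables' estimation
#'    errors is read off the cross-trait LD score regression intercept,
#'    estimated from the full (pre-selection) summary statistics.
#' 2. *Winner's curse / weak instruments*: under a normal polygenic
#'    effect-size prior with variance `h2/m` (h2 from LD score
#'    regression on the exposure table), the conditional mean of the true
#'    exposure effect given its estimate is the shrunken
#'    `mu_j = s_j * beta_x_hat_j` with `s_j = sigma2/(sigma2 + se_x_j^2)`.
#'    Because threshold selection is a function of the estimate alone,
#'    this conditional expectation is unchanged by selection, which is
#'    what licenses its use on a winner's-curse-selected set.
#' 3. Putting both together, the conditional expectation of the naive IVW
#'    given the observed exposure effects is
#'    `alpha * lambda + B`, with attenuation
#'    `lambda = sum(w s_j bx^2)/sum(w bx^2)` and overlap term
#'    `B = c * sum(w (se_y/se_x)(1 - s_j) bx^2)/sum(w bx^2)`; the
#'    corrected estimate inverts this:
#'    `alpha_corrected = (alpha_observed - B)/lambda`.
#'
#' The observed-vs-corrected difference is tested with a
#' leave-one-instrument-out jackknife SE of the difference (the two
#' estimates are strongly dependent, so naive variance addition would be
#' wrong). When the difference is significant the corrected estimate
#' should be reported as primary.
#'
#' @param exposure_stats,outcome_stats Full summary-statistics tibbles
#'   (before instrument selection), sharing variant ids and alleles.
#' @param ldscores LD score tibble covering the variants; `NULL` withholds
#'   the corrected result (the cross-trait intercept is then
#'   inestimable) and returns the observed estimate flagged.
#' @param n_exposure,n_outcome GWAS sample sizes (defaults: table
#'   medians).
#' @param selection_threshold Exposure p-value threshold for instrument
#'   discovery (default 5e-8).
#' @param shrink_sigma2 Optional override of the prior effect variance
#'   `sigma2` (default: LDSC `h2 / m`). Setting it to `Inf` together with
#'   `force_identity` disables shrinkage.
#' @param force_identity Force `lambda = 1, B = 0` (correction inert);
#'   the corrected estimate then equals the observed IVW exactly.
#' @return A list of class `mr_overlap_corrected`: `observed` and
#'   `corrected` `mr_estimate` rows, `difference` (tibble with the
#'   jackknife z-test), and `correction_inputs` (h2, cross-intercept,
#'   sigma2, mean F, selection threshold, k).
#' @export
mr_corrected_ivw <- function(exposure_stats, outcome_stats, ldscores,
                             n_exposure = NULL, n_outcome = NULL,
                             selection_threshold = 5e-8,
                             shrink_sigma2 = NULL,
                             force_identity = FALSE) {
  assert_columns(exposure_stats, c("variant_id", "beta", "se"),
                 "exposure stats")
  assert_columns(outcome_stats, c("variant_id", "beta", "se"),
                 "outcome stats")
  n_exposure <- n_exposure %||%
    (if ("n" %in% names(exposure_stats)) stats::median(exposure_stats$n)
     else config_error("n_exposure not supplied and no n column"))
  n_outcome <- n_outcome %||%
    (if ("n" %in% names(outcome_stats)) stats::median(outcome_stats$n)
     else config_error("n_outcome not supplied and no n column"))

  sel <- exposure_stats$pvalue < selection_threshold
  if (!any(sel)) {
    config_error(sprintf("selection threshold %g retains zero instruments",
                         selection_threshold))
  }
  ins <- inner_join(
    exposure_stats[sel, ] |>
      select(variant_id, beta_x = beta, se_x = se),
    outcome_stats |> select(variant_id, beta_y = beta, se_y = se),
    by = "variant_id"
  )
  k <- nrow(ins)
  observed <- mr_ivw(ins, effects = "fixed")
  mean_f <- mean((ins$beta_x / ins$se_x)^2)

  if (is.null(ldscores) && !force_identity) {
    return(structure(
      list(
        observed = observed, corrected = NULL, difference = NULL,
        flag = "corrected result withheld: no LD scores for the cross-trait intercept",
        correction_inputs = list(selection_threshold = selection_threshold,
                                 mean_F = mean_f, k = k)
      ),
      class = "mr_overlap_corrected"
    ))
  }

  cross_int_se <- 0
  if (force_identity) {
    h2 <- NA_real_
    cross_int <- 0
    sigma2 <- rep(Inf, k)
  } else {
    nb <- min(20L, max(2L, nrow(exposure_stats) %/% 50L))
    h2_fit <- estimate_h2(exposure_stats, ldscores, n = n_exposure,
                          n_blocks = nb)
    rg_fit <- estimate_rg(exposure_stats, outcome_stats, ldscores,
                          n_a = n_exposure, n_b = n_outcome, n_blocks = nb)
    h2 <- h2_fit$h2
    cross_int <- rg_fit$cross_intercept
    cross_int_se <- rg_fit$cross_intercept_se
    # Prior variance of a variant's *marginal* effect scales with its LD
    # score: sigma2_j = sigma2_base * l_j. The base is estimated from the
    # full (pre-selection) table by moments — E[beta_hat^2] =
    # sigma2_base * l + se^2 — which targets the same quantity as the
    # LDSC slope (h2/m) but cannot blow the attenuation inverse up when a
    # noisy slope estimate lands near zero.
    full_l <- ldscores$ld_score[match(exposure_stats$variant_id,
                                      ldscores$variant_id)]
    ok <- !is.na(full_l)
    sigma2_base <- (mean(exposure_stats$beta[ok]^2) -
                      mean(exposure_stats$se[ok]^2)) / mean(full_l[ok])
    l_ins <- ldscores$ld_score[match(ins$variant_id, ldscores$variant_id)]
    l_ins[is.na(l_ins)] <- 1
    if (!is.null(shrink_sigma2)) {
      sigma2 <- rep(shrink_sigma2, k)
    } else if (!is.finite(sigma2_base) || sigma2_base <= 0) {
      return(structure(
        list(
          observed = observed, corrected = NULL, difference = NULL,
          flag = "corrected result withheld: exposure effect-size variance inestimable (no detectable polygenic signal)",
          correction_inputs = list(
            h2_exposure = h2, ldsc_cross_intercept = cross_int,
            selection_threshold = selection_threshold,
            mean_F = mean_f, k = k
          )
        ),
        class = "mr_overlap_corrected"
      ))
    } else {
      sigma2 <- sigma2_base * l_ins
    }
  }

  s <- ifelse(is.infinite(sigma2), 1, sigma2 / (sigma2 + ins$se_x^2))
  w <- 1 / ins$se_y^2
  corr_of <- function(idx) {
    bx <- ins$beta_x[idx]; by <- ins$beta_y[idx]
    wi <- w[idx]; si <- s[idx]
    sy <- ins$se_y[idx]; sx <- ins$se_x[idx]
    denom <- sum(wi * bx^2)
    obs <- sum(wi * bx * by) / denom
    lambda <- sum(wi * si * bx^2) / denom
    B <- cross_int * sum(wi * (sy / sx) * (1 - si) * bx^2) / denom
    c(obs = obs, corr = (obs - B) / lambda)
  }
  full <- corr_of(seq_len(k))

  lambda_full <- sum(w * s * ins$beta_x^2) / sum(w * ins$beta_x^2)
  # sensitivity of the correction to the estimated cross-trait intercept:
  # corrected = (obs - c * B1)/lambda with B1 = B/c, so the intercept's
  # jackknife variance propagates with factor (B1/lambda)^2 into both the
  # corrected estimate and the observed-corrected difference
  B1 <- sum(w * (ins$se_y / ins$se_x) * (1 - s) * ins$beta_x^2) /
    sum(w * ins$beta_x^2)
  var_c_term <- (B1 / lambda_full)^2 * cross_int_se^2
  # jackknife over instruments: SE of the observed-corrected difference
  # (the two are strongly dependent) and of the corrected estimate; the
  # corrected SE is floored at the observed SE scaled up by 1/attenuation
  if (k >= 3) {
    jk_diff <- jackknife_se(k, as.list(seq_len(k)), function(idx) {
      v <- corr_of(idx)
      unname(v["obs"] - v["corr"])
    })
    jk_corr <- jackknife_se(k, as.list(seq_len(k)),
                            function(idx) unname(corr_of(idx)["corr"]))
    diff_se <- sqrt(jk_diff$se^2 + var_c_term)
    corr_se <- sqrt(max(jk_corr$se, observed$se / lambda_full)^2 +
                      var_c_term)
  } else {
    diff_se <- NA_real_
    corr_se <- sqrt((observed$se / lambda_full)^2 + var_c_term)
  }

  diff <- unname(full["obs"] - full["corr"])
  z <- diff / diff_se
  corrected <- mr_estimate_row("corrected_IVW", unname(full["corr"]),
                               corr_se, k = k)
  structure(
    list(
      observed = observed,
      corrected = corrected,
      difference = tibble(
        difference = diff, se = diff_se, z = z,
        p = 2 * pnorm(-abs(z))
      ),
      flag = NULL,
      correction_inputs = list(
        h2_exposure = h2, ldsc_cross_intercept = cross_int,
        sigma2 = sigma2, mean_F = mean_f,
        selection_threshold = selection_threshold, k = k,
        attenuation = lambda_full
      )
    ),
    class = "mr_overlap_corrected"
  )
}

#' @export
print.mr_overlap_corrected <- function(x, ...) {
  cat("<mr_overlap_corrected>\n  observed IVW: ",
      sprintf("%.4f (se %.4f)", x$observed$beta, x$observed$se), "\n")
  if (!is.null(x$corrected)) {
    cat("  corrected IVW:",
        sprintf("%.4f (se %.4f)", x$corrected$beta, x$corrected$se), "\n")
    cat(sprintf("  observed - corrected = %.4f, p = %.3g\n",
                x$difference$difference, x$difference$p))
  } else {
    cat("  ", x$flag, "\n")
  }
  invisible(x)
}
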