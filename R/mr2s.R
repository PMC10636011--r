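#' Harmonise exposure and outcome summary statistics into an instrument set
#'
#' Aligns the outcome table to the exposure table's effect allele. When a
#' variant's alleles are swapped between the tables the outcome beta is
#' negated (and the EAF complemented); strand flips are resolved by
#' complementing alleles. Palindromic variants (A/T or C/G) whose
#' exposure EAF lies inside the ambiguity window are dropped, as their
#' strand cannot be resolved from frequency. Every per-variant action is
#' recorded.
#'
#' @param exposure_stats,outcome_stats Summary-statistics tibbles with
#'   `variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`.
#' @param palindromic_eaf_window EAF interval inside which palindromic
#'   variants are considered ambiguous (default 0.42-0.58).
#' @return Tibble of class `mr_instruments`: `variant_id`, `beta_x`,
#'   `se_x`, `beta_y`, `se_y`, `eaf`, `action` (`kept`, `flipped`,
#'   `dropped_palindromic`, `dropped_missing`). Dropped variants keep a
#'   row (with NA effects) so the log is complete; estimators use only the
#'   retained rows.
#' @export
harmonise_instruments <- function(exposure_stats, outcome_stats,
                                  palindromic_eaf_window = c(0.42, 0.58)) {
  assert_columns(exposure_stats,
                 c("variant_id", "effect_allele", "other_allele",
                   "eaf", "beta", "se"), "exposure stats")
  assert_columns(outcome_stats,
                 c("variant_id", "effect_allele", "other_allele",
                   "beta", "se"), "outcome stats")
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ex <- exposure_stats |>
    mutate(effect_allele = toupper(effect_allele),
           other_allele = toupper(other_allele))
  out <- outcome_stats |>
    mutate(effect_allele = toupper(effect_allele),
           other_allele = toupper(other_allele)) |>
    select(variant_id, oy_ea = effect_allele, oy_oa = other_allele,
           beta_y = beta, se_y = se)
  joined <- left_join(
    ex |> select(variant_id, ea = effect_allele, oa = other_allele,
                 eaf, beta_x = beta, se_x = se),
    out, by = "variant_id"
  )
  if (all(is.na(joined$beta_y))) {
    config_error("exposure and outcome tables share no variants")
  }
  pal <- joined$ea == unname(comp[joined$oa])
  ambiguous <- pal & !is.na(joined$eaf) &
    joined$eaf > palindromic_eaf_window[1] &
    joined$eaf < palindromic_eaf_window[2]
  same <- joined$oy_ea == joined$ea & joined$oy_oa == joined$oa
  swapped <- joined$oy_ea == joined$oa & joined$oy_oa == joined$ea
  # strand-flipped versions of the same two states
  strand_same <- joined$oy_ea == unname(comp[joined$ea]) &
    joined$oy_oa == unname(comp[joined$oa])
  strand_swapped <- joined$oy_ea == unname(comp[joined$oa]) &
    joined$oy_oa == unname(comp[joined$ea])
  res <- joined |>
    mutate(
      action = case_when(
        is.na(beta_y) ~ "dropped_missing",
        ambiguous ~ "dropped_palindromic",
        same | (strand_same & !pal) ~ "kept",
        swapped | (strand_swapped & !pal) ~ "flipped",
        pal & same ~ "kept",
        pal & swapped ~ "flipped",
        TRUE ~ "dropped_missing"
      ),
      beta_y = case_when(
        action == "flipped" ~ -beta_y,
        action == "kept" ~ beta_y,
        TRUE ~ NA_real_
      ),
      se_y = if_else(action %in% c("kept", "flipped"), se_y, NA_real_)
    ) |>
    select(variant_id, beta_x, se_x, beta_y, se_y, eaf, action)
  class(res) <- c("mr_instruments", class(res))
  res
}

retained_instruments <- function(instruments) {
  assert_columns(instruments, c("beta_x", "se_x", "beta_y", "se_y"),
                 "instrument set")
  out <- instruments
  if ("action" %in% names(out)) {
    out <- filter(out, action %in% c("kept", "flipped"))
  }
  out <- filter(out, !is.na(beta_x), !is.na(beta_y))
  if (any(out$se_x <= 0, na.rm = TRUE) || any(out$se_y <= 0, na.rm = TRUE)) {
    config_error("standard errors must be positive")
  }
  out
}

mr_estimate_row <- function(method, beta, se, p = NULL, k = NA_integer_,
                            Q = NA_real_, Q_df = NA_real_, Q_p = NA_real_,
                            scale = "per_unit", note = "") {
  wc <- wald_cols(beta, se)
  out <- tibble(
    method = method, beta = beta, se = se,
    ci_low = wc$ci_low, ci_high = wc$ci_high,
    p = p %||% wc$p, k = as.integer(k),
    Q = Q, Q_df = Q_df, Q_p = Q_p, scale = scale, note = note
  )
  class(out) <- c("mr_estimate", class(out))
  out
}

#' Inverse-variance-weighted two-sample MR estimate
#'
#' The workhorse estimator:
#' `beta = sum(w * beta_x * beta_y) / sum(w * beta_x^2)` with
#' `w = 1/se_y^2`, equivalent to a weighted through-origin regression of
#' outcome effects on exposure effects. Under the default multiplicative
#' random-effects model the SE is inflated by `max(1, sqrt(Q/(k-1)))`,
#' where Q is Cochran's heterogeneity statistic (reported with its
#' p-value). A single instrument degrades to the Wald ratio
#' `beta_y/beta_x` with `se = se_y/|beta_x|` and a note.
#'
#' @param instruments An `mr_instruments` tibble (or any tibble with
#'   `beta_x`, `se_x`, `beta_y`, `se_y`).
#' @param effects `"multiplicative_random"` (default) or `"fixed"`.
#' @return One-row `mr_estimate` tibble (`method`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `p`, `k`, `Q`, `Q_df`, `Q_p`, `scale`, `note`).
#' @examples
#' ins <- tibble::tibble(beta_x = c(0.5, 0.4, 0.6),
#'                       se_x = 0.02, beta_y = c(0.15, 0.12, 0.18),
#'                       se_y = 0.03)
#' mr_ivw(ins)
#' @export
mr_ivw <- function(instruments,
                   effects = c("multiplicative_random", "fixed")) {
  effects <- match.arg(effects)
  ins <- retained_instruments(instruments)
  k <- nrow(ins)
  if (k == 0) config_error("no retained instruments")
  if (k == 1) {
    if (ins$beta_x == 0) config_error("ratio undefined: beta_x is zero")
    return(mr_estimate_row(
      "IVW", ins$beta_y / ins$beta_x, ins$se_y / abs(ins$beta_x),
      k = 1, note = "single instrument: Wald ratio"
    ))
  }
  w <- 1 / ins$se_y^2
  beta <- sum(w * ins$beta_x * ins$beta_y) / sum(w * ins$beta_x^2)
  se_fixed <- 1 / sqrt(sum(w * ins$beta_x^2))
  Q <- sum(w * (ins$beta_y - beta * ins$beta_x)^2)
  Q_df <- k - 1
  infl <- if (effects == "multiplicative_random") {
    max(1, sqrt(Q / Q_df))
  } else {
    1
  }
  mr_estimate_row(
    "IVW", beta, se_fixed * infl, k = k,
    Q = Q, Q_df = Q_df, Q_p = pchisq(Q, Q_df, lower.tail = FALSE),
    note = effects
  )
}

#' MR-Egger regression: causal slope and pleiotropy intercept
#'
#' Weighted regression of outcome effects on exposure effects *with* a
#' free intercept (weights `1/se_y^2`). The slope is the causal estimate
#' under the InSIDE assumption; the intercept estimates average
#' directional pleiotropy and carries its own p-value (the standard
#' pleiotropy test). Instruments are first re-oriented so every
#' `beta_x >= 0`, a fixed convention that makes the
#' orientation-dependent intercept reproducible. SEs use multiplicative
#' random effects (`max(1, sigma)` inflation).
#'
#' @inheritParams mr_ivw
#' @return Two-row `mr_estimate` tibble: methods `Egger_slope` and
#'   `Egger_intercept`.
#' @export
mr_egger <- function(instruments) {
  ins <- retained_instruments(instruments)
  k <- nrow(ins)
  if (k < 3) config_error("MR-Egger needs at least 3 instruments")
  flip <- sign(ins$beta_x)
  flip[flip == 0] <- 1
  bx <- ins$beta_x * flip
  by <- ins$beta_y * flip
  w <- 1 / ins$se_y^2
  fit <- wls_fit(cbind(intercept = 1, slope = bx), by, w, inflate_se = TRUE)
  Q <- sum(w * fit$resid^2)
  Q_df <- k - 2
  bind_rows(
    mr_estimate_row("Egger_slope", fit$coef[2], fit$se[2], k = k,
                    Q = Q, Q_df = Q_df,
                    Q_p = pchisq(Q, Q_df, lower.tail = FALSE)),
    mr_estimate_row("Egger_intercept", fit$coef[1], fit$se[1], k = k)
  )
}

# weighted median of `values` under `weights` by linear interpolation of
# the cumulative weight function at 50% (midpoint convention)
weighted_median_point <- function(values, weights) {
  ord <- order(values)
  v <- values[ord]
  w <- weights[ord] / sum(weights)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(v[1])
  if (cum[length(cum)] <= 0.5) return(v[length(v)])
  stats::approx(cum, v, xout = 0.5, ties = "ordered")$y
}

wm_core <- function(ins, penalty_alpha = NULL, n_boot = 1000, seed = 1L,
                    method = "WM") {
  k <- nrow(ins)
  ratio <- ins$beta_y / ins$beta_x
  se_ratio <- ins$se_y / abs(ins$beta_x)
  w <- 1 / se_ratio^2
  penalise <- function(w, ratio) {
    if (is.null(penalty_alpha)) return(w)
    est0 <- weighted_median_point(ratio, w)
    Qj <- w * (ratio - est0)^2
    qj <- pchisq(Qj, df = 1, lower.tail = FALSE)
    w * pmin(1, qj / penalty_alpha)
  }
  point <- weighted_median_point(ratio, penalise(w, ratio))
  # parametric bootstrap SE, perturbing both effect columns
  withr_seed <- function(expr) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    expr
  }
  boots <- withr_seed({
    vapply(seq_len(n_boot), function(b) {
      bx <- ins$beta_x + rnorm(k, 0, ins$se_x)
      by <- ins$beta_y + rnorm(k, 0, ins$se_y)
      r <- by / bx
      sr <- ins$se_y / abs(bx)
      wb <- 1 / sr^2
      weighted_median_point(r, penalise(wb, r))
    }, numeric(1))
  })
  mr_estimate_row(method, point, sd(boots), k = k,
                  note = sprintf("bootstrap SE (%d draws)", n_boot))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Weighted-median two-sample MR estimate
#'
#' The 50th percentile of the per-variant ratio estimates
#' `beta_y/beta_x` under inverse-variance weights, found by linear
#' interpolation of the cumulative weights; consistent when at least half
#' the weight comes from valid instruments. SE by seeded parametric
#' bootstrap perturbing both effect columns with their standard errors.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap draws for the SE.
#' @param seed Bootstrap seed.
#' @return One-row `mr_estimate` tibble.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = 1L) {
  ins <- retained_instruments(instruments)
  if (nrow(ins) < 3) config_error("weighted median needs >= 3 instruments")
  wm_core(ins, penalty_alpha = NULL, n_boot = n_boot, seed = seed,
          method = "WM")
}

#' Penalised weighted-median two-sample MR estimate
#'
#' As [mr_weighted_median()], but each instrument's weight is multiplied
#' by `min(1, q_j / penalty_alpha)` where `q_j` is the upper-tail
#' chi-square(1) probability of its contribution to the heterogeneity
#' statistic about the unpenalised weighted median. Outlying instruments
#' (pleiotropic ratios) are thus strongly down-weighted while consistent
#' ones keep their full weight; with no outliers the penalty is inert and
#' PWM equals WM exactly.
#'
#' @inheritParams mr_weighted_median
#' @param penalty_alpha Penalisation constant (default 0.05; smaller
#'   values make the penalty laxer, and in the limit PWM reduces to WM).
#' @return One-row `mr_estimate` tibble.
#' @export
mr_penalised_weighted_median <- function(instruments, penalty_alpha = 0.05,
                                         n_boot = 1000, seed = 1L) {
  ins <- retained_instruments(instruments)
  if (nrow(ins) < 3) config_error("penalised weighted median needs >= 3 instruments")
  wm_core(ins, penalty_alpha = penalty_alpha, n_boot = n_boot, seed = seed,
          method = "PWM")
}

#' Mean instrument F statistic from summary data
#'
#' `mean((beta_x/se_x)^2)` over the instruments — the summary-data
#' instrument-strength diagnostic. When the exposure GWAS sample size is
#' supplied, the Cragg-Donald-style approximation
#' `F = R2 * (n - 2) / (1 - R2)` from the implied variance explained is
#' also reported.
#'
#' @inheritParams mr_ivw
#' @param n_exposure Optional exposure GWAS sample size.
#' @return One-row tibble: `mean_f`, `k`, and (if `n_exposure` given)
#'   `r2_sum`, `f_cragg_donald`.
#' @export
mean_f_statistic <- function(instruments, n_exposure = NULL) {
  ins <- retained_instruments(instruments)
  f <- (ins$beta_x / ins$se_x)^2
  out <- tibble(mean_f = mean(f), k = nrow(ins))
  if (!is.null(n_exposure)) {
    # per-variant R2 implied by z^2/n on the standardised scale
    r2 <- sum(f / n_exposure)
    out$r2_sum <- r2
    out$f_cragg_donald <-
      r2 * (n_exposure - nrow(ins) - 1) / ((1 - r2) * nrow(ins))
  }
  out
}

#' Rescale a binary-exposure MR estimate to per-doubling units
#'
#' Estimates for a binary exposure with log-odds summary statistics are
#' per unit of log-odds; multiplying beta, SE and CI by `ln 2 = 0.693`
#' converts them to the effect per doubling of genetic liability odds,
#' the conventional interpretable scale. Guards against double scaling
#' and against use on continuous exposures.
#'
#' @param estimate An `mr_estimate` row (or tibble of rows).
#' @param exposure_type `"binary_log_odds"` (anything else errors).
#' @return The estimate with `beta`, `se`, `ci_low`, `ci_high` multiplied
#'   by ln 2, `scale` set to `per_doubling_log_odds`, and an
#'   `odds_ratio` column `exp(beta)`.
#' @examples
#' e <- mr_estimate_from(beta = 1, se = 0.2)
#' scale_per_doubling(e)$beta  # 0.6931...
#' @export
scale_per_doubling <- function(estimate, exposure_type = "binary_log_odds") {
  if (!identical(exposure_type, "binary_log_odds")) {
    config_error(
      "per-doubling scaling applies only to binary exposures on the log-odds scale"
    )
  }
  assert_columns(estimate, c("beta", "se", "ci_low", "ci_high", "scale"),
                 "estimate")
  if (any(estimate$scale == "per_doubling_log_odds")) {
    config_error("estimate is already on the per-doubling scale")
  }
  estimate |>
    mutate(
      beta = beta * log(2), se = se * log(2),
      ci_low = ci_low * log(2), ci_high = ci_high * log(2),
      scale = "per_doubling_log_odds",
      odds_ratio = exp(beta)
    )
}

#' Build a bare MR estimate row
#'
#' Convenience constructor for an `mr_estimate` tibble from a beta and
#' SE, e.g. when importing external results for rescaling or plotting.
#'
#' @param beta,se Point estimate and standard error.
#' @param method Method label.
#' @param k Instrument count.
#' @param scale Scale note.
#' @return One-row `mr_estimate` tibble.
#' @export
mr_estimate_from <- function(beta, se, method = "external", k = NA_integer_,
                             scale = "per_unit") {
  mr_estimate_row(method, beta, se, k = k, scale = scale)
}

#' Run the full two-sample estimator suite
#'
#' IVW (main analysis) plus the MR-Egger, weighted-median and penalised
#' weighted-median sensitivity estimators on one instrument set.
#'
#' @inheritParams mr_weighted_median
#' @param penalty_alpha Passed to the penalised weighted median.
#' @return `mr_estimate` tibble with one row per method (Egger
#'   contributes slope and intercept rows).
#' @export
mr_all_methods <- function(instruments, n_boot = 1000, seed = 1L,
                           penalty_alpha = 0.05) {
  bind_rows(
    mr_ivw(instruments),
    mr_egger(instruments),
    mr_weighted_median(instruments, n_boot = n_boot, seed = seed),
    mr_penalised_weighted_median(instruments, penalty_alpha = penalty_alpha,
                                 n_boot = n_boot, seed = seed)
  )
}
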