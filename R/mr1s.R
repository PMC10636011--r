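#' Weighted allele score
#'
#' `score_i = sum_j w_j * dosage_ij`, the aggregate genetic instrument
#' for one-sample MR. Missing dosages are mean-imputed to `2 * EAF`
#' (preserving the score's expectation) before weighting.
#'
#' @param dosages Numeric matrix, persons x variants.
#' @param weights Numeric vector of per-variant weights aligned to the
#'   columns of `dosages`.
#' @param standardize Z-score the result over persons?
#' @return Numeric vector of scores, one per person.
#' @export
build_allele_score <- function(dosages, weights, standardize = FALSE) {
  dosages <- as.matrix(dosages)
  if (length(weights) == 0) config_error("weight vector is empty")
  if (length(weights) != ncol(dosages)) {
    config_error("weights must align with dosage columns")
  }
  if (anyNA(dosages)) {
    eaf <- colMeans(dosages, na.rm = TRUE) / 2
    for (j in which(colSums(is.na(dosages)) > 0)) {
      dosages[is.na(dosages[, j]), j] <- 2 * eaf[j]
    }
  }
  score <- drop(dosages %*% weights)
  if (standardize) score <- drop(scale(score))
  score
}

#' One-sample MR by two-stage estimation
#'
#' First stage: linear regression of the exposure on the instrument
#' (allele score or any numeric instrument) plus covariates. Second
#' stage: regression of the outcome on the first-stage fitted values plus
#' the same covariates, under a linear, logistic or Poisson family
#' matched to the outcome's distribution. Second-stage SEs are robust
#' (HC0 sandwich) treating the first-stage fit as fixed — the usual
#' two-stage practice for binary/count outcomes; the extra
#' generated-regressor uncertainty is not propagated.
#'
#' @param data Cohort data frame.
#' @param instrument,exposure,outcome Column names.
#' @param covariates Character vector of covariate columns (default age
#'   and sex).
#' @param family Second-stage family: `"linear"`, `"logistic"` or
#'   `"poisson"`.
#' @return An object of class `mr_tsls`: list with `beta`, `se`,
#'   `ci_low`, `ci_high`, `p`, `first_stage_F`, `weak_instrument` flag
#'   (F < 1), `n`, `family`, and the two fitted models.
#' @export
mr_tsls <- function(data, instrument, exposure, outcome,
                    covariates = intersect(c("age", "sex"), names(data)),
                    family = c("linear", "logistic", "poisson")) {
  family <- match.arg(family)
  assert_columns(data, c(instrument, exposure, outcome, covariates),
                 "cohort")
  df <- data.frame(
    .z = data[[instrument]],
    .x = data[[exposure]],
    .y = data[[outcome]],
    data[, covariates, drop = FALSE]
  )
  df <- df[complete.cases(df), , drop = FALSE]
  if (family == "logistic") df$.y <- normalise_status(df$.y)
  if (family == "poisson" && any(df$.y != round(df$.y))) {
    config_error("poisson family requires an integer count outcome")
  }
  rhs1 <- paste(c(".z", covariates), collapse = " + ")
  first <- lm(as.formula(paste(".x ~", rhs1)), data = df)
  fs <- summary(first)$coefficients[".z", ]
  f_stat <- unname((fs[1] / fs[2])^2)
  df$.xhat <- predict(first)
  fam <- switch(family, linear = gaussian(), logistic = binomial(),
                poisson = poisson())
  rhs2 <- paste(c(".xhat", covariates), collapse = " + ")
  second <- glm(as.formula(paste(".y ~", rhs2)), data = df, family = fam)
  beta <- coef(second)[".xhat"]
  vc <- sandwich::vcovHC(second, type = "HC0")
  se <- sqrt(vc[".xhat", ".xhat"])
  wc <- wald_cols(beta, se)
  structure(
    list(
      beta = unname(beta), se = se,
      ci_low = wc$ci_low, ci_high = wc$ci_high, p = wc$p,
      first_stage_F = f_stat,
      weak_instrument = f_stat < 1,
      n = nrow(df), family = family,
      covariates = covariates,
      first_stage = first, second_stage = second
    ),
    class = "mr_tsls"
  )
}

#' @export
print.mr_tsls <- function(x, ...) {
  cat(sprintf(
    "<mr_tsls: %s second stage>\n  beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n  first-stage F = %.1f%s, n = %d\n",
    x$family, x$beta, x$se, x$ci_low, x$ci_high, x$p,
    x$first_stage_F, if (x$weak_instrument) " (weak instrument)" else "",
    x$n
  ))
  invisible(x)
}

#' Stratified one-sample MR with a between-stratum contrast
#'
#' Refits the full two-stage model independently within each stratum
#' (including the first stage, since the instrument-exposure relation is
#' exactly what differs between strata in a negative-control design) and
#' reports a z-test contrasting the first two strata's estimates. Empty
#' or undersized strata are skipped with a warning.
#'
#' @inheritParams mr_tsls
#' @param stratum Column name of the stratum labels (e.g. never/ever
#'   drinker).
#' @param min_n Minimum analysable stratum size.
#' @return List with `by_stratum` (tibble of per-stratum estimates) and
#'   `contrast` (one-row tibble: difference, SE, z, p of stratum 1 minus
#'   stratum 2).
#' @export
stratified_mr <- function(data, stratum, instrument, exposure, outcome,
                          covariates = intersect(c("age", "sex"), names(data)),
                          family = c("linear", "logistic", "poisson"),
                          min_n = 50) {
  family <- match.arg(family)
  assert_columns(data, stratum, "cohort")
  levels <- unique(data[[stratum]])
  if (length(levels) < 2) config_error("need at least 2 strata")
  fits <- list()
  for (lv in levels) {
    sub <- data[data[[stratum]] == lv, , drop = FALSE]
    if (nrow(sub) < min_n) {
      warn(sprintf("stratum '%s' has n = %d < %d; skipped", lv,
                   nrow(sub), min_n))
      next
    }
    fits[[as.character(lv)]] <-
      mr_tsls(sub, instrument, exposure, outcome, covariates, family)
  }
  by_stratum <- bind_rows(lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    tibble(stratum = nm, beta = f$beta, se = f$se, ci_low = f$ci_low,
           ci_high = f$ci_high, p = f$p, first_stage_F = f$first_stage_F,
           n = f$n)
  }))
  contrast <- NULL
  if (nrow(by_stratum) >= 2) {
    d <- by_stratum$beta[1] - by_stratum$beta[2]
    sed <- sqrt(by_stratum$se[1]^2 + by_stratum$se[2]^2)
    contrast <- tibble(
      stratum_1 = by_stratum$stratum[1], stratum_2 = by_stratum$stratum[2],
      difference = d, se = sed, z = d / sed, p = 2 * pnorm(-abs(d / sed))
    )
  }
  list(by_stratum = by_stratum, contrast = contrast, fits = fits)
}

#' Select sex-specific instruments by interaction testing
#'
#' Computes a per-variant gene-sex interaction z-statistic
#' `(beta_m - beta_f)/sqrt(se_m^2 + se_f^2)`; variants whose interaction
#' p-value passes `interaction_alpha` are assigned to the sex in which
#' they are stronger (larger `|beta|/se`) and retained only if their
#' per-sex strength `(beta/se)^2` strictly exceeds `f_min` in that sex.
#'
#' @param male_stats,female_stats Summary-statistics tibbles with aligned
#'   `variant_id`, `beta`, `se`.
#' @param interaction_alpha Interaction p-value threshold (default 1e-5).
#' @param f_min Per-sex F-statistic threshold (default 15, strict
#'   inequality).
#' @return List of class `sex_specific_instruments`: `male_set`,
#'   `female_set` (tibbles `variant_id`, `beta`, `se`, `f_stat`),
#'   `interaction` (full per-variant test table), `f_threshold_used`.
#'   Empty sets come with a warning, not an error.
#' @export
select_sex_specific_instruments <- function(male_stats, female_stats,
                                            interaction_alpha = 1e-5,
                                            f_min = 15) {
  assert_columns(male_stats, c("variant_id", "beta", "se"), "male stats")
  assert_columns(female_stats, c("variant_id", "beta", "se"), "female stats")
  dat <- inner_join(
    male_stats |> select(variant_id, beta_m = beta, se_m = se),
    female_stats |> select(variant_id, beta_f = beta, se_f = se),
    by = "variant_id"
  )
  if (nrow(dat) == 0) config_error("no shared variants")
  dat <- dat |>
    mutate(
      z_int = (beta_m - beta_f) / sqrt(se_m^2 + se_f^2),
      interaction_p = 2 * pnorm(-abs(z_int)),
      f_m = (beta_m / se_m)^2,
      f_f = (beta_f / se_f)^2,
      assigned_sex = if_else(f_m >= f_f, "male", "female"),
      selected = interaction_p < interaction_alpha &
        if_else(assigned_sex == "male", f_m > f_min, f_f > f_min)
    )
  male_set <- dat |>
    filter(selected, assigned_sex == "male") |>
    select(variant_id, beta = beta_m, se = se_m, f_stat = f_m)
  female_set <- dat |>
    filter(selected, assigned_sex == "female") |>
    select(variant_id, beta = beta_f, se = se_f, f_stat = f_f)
  if (nrow(male_set) + nrow(female_set) == 0) {
    warn("no variant passed the interaction and F thresholds")
  }
  structure(
    list(male_set = male_set, female_set = female_set,
         interaction = dat, f_threshold_used = f_min,
         interaction_alpha = interaction_alpha),
    class = "sex_specific_instruments"
  )
}

#' Sex-stratified MR with fixed-effect combination across sexes
#'
#' IVW within each sex using that sex's instrument set (sex-specific
#' exposure effects) against sex-specific outcome summary statistics,
#' then a fixed-effect inverse-variance combination of the two per-sex
#' causal estimates. If one sex's set is empty it is skipped and the
#' combined estimate equals the other's.
#'
#' @param instruments A [select_sex_specific_instruments()] result.
#' @param male_outcome_stats,female_outcome_stats Outcome
#'   summary-statistics tibbles (`variant_id`, `beta`, `se`).
#' @return `mr_estimate` tibble with up to three rows: `IVW_male`,
#'   `IVW_female`, `IVW_sex_combined`.
#' @export
sex_stratified_mr <- function(instruments, male_outcome_stats,
                              female_outcome_stats) {
  stopifnot(inherits(instruments, "sex_specific_instruments"))
  one_sex <- function(set, outcome_stats, label) {
    if (nrow(set) == 0) return(NULL)
    ins <- inner_join(
      set |> select(variant_id, beta_x = beta, se_x = se),
      outcome_stats |> select(variant_id, beta_y = beta, se_y = se),
      by = "variant_id"
    )
    if (nrow(ins) == 0) return(NULL)
    est <- mr_ivw(ins)
    est$method <- label
    est
  }
  res <- bind_rows(
    one_sex(instruments$male_set, male_outcome_stats, "IVW_male"),
    one_sex(instruments$female_set, female_outcome_stats, "IVW_female")
  )
  if (nrow(res) == 0) config_error("both per-sex instrument sets are empty")
  w <- 1 / res$se^2
  beta_c <- sum(w * res$beta) / sum(w)
  se_c <- 1 / sqrt(sum(w))
  bind_rows(
    res,
    mr_estimate_row("IVW_sex_combined", beta_c, se_c,
                    k = sum(res$k), note = "fixed-effect combination")
  )
}
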