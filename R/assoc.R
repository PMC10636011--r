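#' Variant quality control on INFO and minor allele frequency
#'
#' A variant is excluded if and only if its imputation quality is strictly
#' below `info_min` or its minor allele frequency — computed as
#' `min(eaf, 1 - eaf)` — is strictly below `maf_min`; boundary values are
#' retained. Variants with missing INFO or EAF are excluded with reason
#' `"missing"`.
#'
#' @param variants Tibble with at least `variant_id`, `eaf`, `info`.
#' @param info_min Minimum imputation quality retained (default 0.3).
#' @param maf_min Minimum minor allele frequency retained (default 0.001,
#'   i.e. 0.1%).
#' @return List with `retained` (the passing subset, same columns) and
#'   `exclusions` (tibble `variant_id`, `reason` in
#'   `info`/`maf`/`missing`).
#' @examples
#' v <- tibble::tibble(variant_id = c("a", "b", "c"),
#'                     eaf = c(0.2, 0.0005, 0.4),
#'                     info = c(0.3, 0.9, 0.1))
#' variant_qc(v)$exclusions
#' @export
variant_qc <- function(variants, info_min = 0.3, maf_min = 0.001) {
  assert_columns(variants, c("variant_id", "eaf", "info"), "variant table")
  maf <- pmin(variants$eaf, 1 - variants$eaf)
  missing <- is.na(variants$info) | is.na(variants$eaf)
  fail_info <- !missing & variants$info < info_min
  fail_maf <- !missing & maf < maf_min
  reason <- case_when(
    missing ~ "missing",
    fail_info ~ "info",
    fail_maf ~ "maf",
    TRUE ~ NA_character_
  )
  excluded <- !is.na(reason)
  list(
    retained = variants[!excluded, , drop = FALSE],
    exclusions = tibble(
      variant_id = variants$variant_id[excluded],
      reason = reason[excluded]
    )
  )
}

# Firth-penalised logistic regression: maximises the Jeffreys-penalised
# log-likelihood l(b) + 0.5*log det I(b) by Newton iterations on the
# modified score, with step halving when the penalised likelihood
# decreases. Returns finite estimates even under complete separation.
# `fix` gives column indices whose coefficients are constrained to zero
# while the penalty keeps the FULL design's information matrix — the
# profile penalised likelihood needed for the penalised LRT (dropping the
# column instead would change the determinant's scale and wreck the test).
firth_logistic <- function(X, y, tol = 1e-8, max_iter = 50,
                           fix = integer(0)) {
  X <- as.matrix(X)
  p_dim <- ncol(X)
  free <- setdiff(seq_len(p_dim), fix)
  beta <- rep(0, p_dim)
  penalised_ll <- function(beta) {
    eta <- drop(X %*% beta)
    pr <- plogis(eta)
    W <- pr * (1 - pr)
    I <- crossprod(X * sqrt(W))
    ll <- sum(y * eta - log1p(exp(eta)))
    ld <- determinant(I, logarithm = TRUE)
    ll + 0.5 * as.numeric(ld$modulus)
  }
  ll_old <- penalised_ll(beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    pr <- plogis(eta)
    W <- pr * (1 - pr)
    XW <- X * sqrt(W)
    I <- crossprod(XW)
    R <- tryCatch(chol(I), error = function(e) NULL)
    if (is.null(R)) break
    I_inv <- chol2inv(R)
    # hat diagonal of W^(1/2) X I^-1 X' W^(1/2), from the full design
    h <- rowSums((XW %*% I_inv) * XW)
    U_star <- drop(crossprod(X, y - pr + h * (0.5 - pr)))
    if (sqrt(sum(U_star[free]^2)) < tol) {
      converged <- TRUE
      break
    }
    step <- rep(0, p_dim)
    Iff <- I[free, free, drop = FALSE]
    Rf <- tryCatch(chol(Iff), error = function(e) NULL)
    if (is.null(Rf)) break
    step[free] <- drop(chol2inv(Rf) %*% U_star[free])
    # step halving on penalised-likelihood decrease
    for (half in 0:10) {
      beta_new <- beta + step / 2^half
      ll_new <- penalised_ll(beta_new)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
    }
    beta <- beta_new
    ll_old <- ll_new
  }
  eta <- drop(X %*% beta)
  pr <- plogis(eta)
  I <- crossprod(X * sqrt(pr * (1 - pr)))
  vc <- tryCatch(chol2inv(chol(I)), error = function(e) {
    matrix(NA_real_, p_dim, p_dim)
  })
  list(
    coefficients = beta, vcov = vc, se = sqrt(diag(vc)),
    logLik_penalised = penalised_ll(beta),
    converged = converged, iterations = iter
  )
}

#' Per-variant Firth logistic association scan
#'
#' Fits a Jeffreys-penalised (Firth) logistic regression of case status on
#' each variant's dosage plus covariates. Penalisation keeps estimates
#' finite under the (quasi-)separation that unbalanced case-control data
#' invite. P-values come from the penalised likelihood-ratio test
#' (refitting without the variant), which is better calibrated than the
#' Wald test in unbalanced designs — the stated motivation for using
#' Firth in the first place.
#'
#' @param dosages Numeric matrix, persons x variants (colnames used as
#'   variant ids when present).
#' @param status Binary vector (0/1 or `"control"`/`"case"`).
#' @param covariates Optional data frame of adjustment covariates (age and
#'   sex in the standard configuration); character/factor columns are
#'   expanded via `model.matrix`.
#' @param alpha Genome-wide significance threshold for `gws_flag`
#'   (strict inequality; default 5e-8).
#' @return Tibble per variant: `variant_id`, `beta` (log-odds per effect
#'   allele), `se`, `p`, `n_cases`, `n_controls`, `converged`,
#'   `monomorphic`, `gws_flag`.
#' @export
firth_scan <- function(dosages, status, covariates = NULL, alpha = 5e-8) {
  dosages <- as.matrix(dosages)
  y <- normalise_status(status)
  if (sum(y) < 2 || sum(1 - y) < 2) {
    config_error("need at least 2 cases and 2 controls")
  }
  base <- matrix(1, nrow(dosages), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    mm <- model.matrix(~., data = as.data.frame(covariates))
    base <- mm
  }
  ids <- colnames(dosages) %||% sprintf("v%d", seq_len(ncol(dosages)))
  res <- lapply(seq_len(ncol(dosages)), function(j) {
    g <- dosages[, j]
    if (length(unique(g)) < 2) {
      return(tibble(
        variant_id = ids[j], beta = NA_real_, se = NA_real_, p = NA_real_,
        n_cases = sum(y), n_controls = sum(1 - y),
        converged = NA, monomorphic = TRUE
      ))
    }
    X <- cbind(base, g = g)
    full <- firth_logistic(X, y)
    red <- firth_logistic(X, y, fix = ncol(X))
    lrt <- 2 * (full$logLik_penalised - red$logLik_penalised)
    tibble(
      variant_id = ids[j],
      beta = full$coefficients[ncol(X)],
      se = full$se[ncol(X)],
      p = pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
      n_cases = sum(y), n_controls = sum(1 - y),
      converged = full$converged, monomorphic = FALSE
    )
  })
  flag_gws(bind_rows(res), alpha = alpha)
}

normalise_status <- function(status) {
  if (is.character(status) || is.factor(status)) {
    as.integer(as.character(status) == "case")
  } else {
    as.integer(status)
  }
}

#' Flag genome-wide significant associations
#'
#' @param results Tibble with a `p` column.
#' @param alpha Significance threshold; the flag uses strict inequality,
#'   so `p` equal to the threshold is not flagged.
#' @return `results` with a logical `gws_flag` column.
#' @export
flag_gws <- function(results, alpha = 5e-8) {
  if (nrow(results) == 0) {
    results$gws_flag <- logical(0)
    return(results)
  }
  mutate(results, gws_flag = !is.na(p) & p < alpha)
}

#' Observational regression of falls on an exposure
#'
#' The descriptive (confounded) association stage: a logistic model for
#' binary fall status or a Poisson model for the fall count, adjusted for
#' covariates (age and sex in the standard configuration). With
#' `standardize = TRUE` the exposure is z-scored first, so the ratio is
#' per SD of the exposure.
#'
#' @param data Cohort data frame.
#' @param exposure,outcome Column names.
#' @param covariates Character vector of covariate column names.
#' @param family `"logistic"`, `"poisson"` or `"linear"`.
#' @param standardize Z-score the exposure before fitting?
#' @return One-row tibble: `exposure`, `scale`
#'   (`per_SD`/`per_unit`), `estimate` (odds or rate ratio; coefficient
#'   for linear), `ci_low`, `ci_high`, `p`, `model`, `covariates`, `n`.
#' @export
observational_model <- function(data, exposure, outcome,
                                covariates = c("age", "sex"),
                                family = c("logistic", "poisson", "linear"),
                                standardize = TRUE) {
  family <- match.arg(family)
  assert_columns(data, c(exposure, outcome, covariates), "cohort")
  y <- data[[outcome]]
  if (family == "logistic") y <- normalise_status(y)
  if (family == "poisson" && any(y != round(y), na.rm = TRUE)) {
    config_error("poisson family requires an integer count outcome")
  }
  x <- data[[exposure]]
  if (standardize) x <- drop(scale(x))
  df <- data.frame(.y = y, .x = x,
                   data[, covariates, drop = FALSE])
  fam <- switch(family, logistic = binomial(), poisson = poisson(),
                linear = gaussian())
  fit <- glm(.y ~ ., data = df, family = fam)
  co <- summary(fit)$coefficients[".x", ]
  wc <- wald_cols(co[1], co[2])
  transf <- if (family == "linear") identity else exp
  tibble(
    exposure = exposure,
    scale = if (standardize) "per_SD" else "per_unit",
    estimate = transf(co[1]),
    ci_low = transf(wc$ci_low),
    ci_high = transf(wc$ci_high),
    p = co[4],
    model = family,
    covariates = paste(covariates, collapse = "+"),
    n = nrow(df)
  )
}
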