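# Internal helpers shared across modules. Nothing here is exported.

# abort with a consistent class so callers/tests can distinguish config
# errors from numerical failures
config_error <- function(msg) {
  abort(msg, class = "fallmr_config_error")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    config_error(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# weighted least squares by hand: y ~ X with weights w.
# Returns coef, se (scaled by max(1, sigma) when inflate_se), sigma2.
# Used by the IVW/Egger/LDSC regressions where we control the variance
# model explicitly rather than relying on lm() defaults.
wls_fit <- function(X, y, w, inflate_se = FALSE) {
  X <- as.matrix(X)
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  XtX <- crossprod(Xw)
  XtY <- crossprod(Xw, yw)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) config_error("weighted regression design is singular")
  coefs <- backsolve(R, backsolve(R, XtY, transpose = TRUE))
  fitted <- drop(X %*% coefs)
  resid <- y - fitted
  df_res <- nrow(X) - ncol(X)
  sigma2 <- if (df_res > 0) sum(w * resid^2) / df_res else NA_real_
  XtX_inv <- chol2inv(R)
  base_var <- diag(XtX_inv)
  infl <- if (inflate_se && is.finite(sigma2)) max(1, sigma2) else 1
  list(
    coef = drop(coefs), se = sqrt(base_var * infl),
    sigma2 = sigma2, fitted = fitted, resid = resid,
    vcov_unit = XtX_inv, df_res = df_res
  )
}

# delete-m-jackknife over a list of index blocks: fn(keep_idx) -> scalar
jackknife_se <- function(n_items, blocks, fn) {
  theta_full <- fn(seq_len(n_items))
  B <- length(blocks)
  pseudo <- vapply(blocks, function(b) {
    fn(setdiff(seq_len(n_items), b))
  }, numeric(1))
  theta_bar <- mean(pseudo)
  se <- sqrt((B - 1) / B * sum((pseudo - theta_bar)^2))
  list(estimate = theta_full, se = se, leave_out = pseudo)
}

# split 1..n into n_blocks contiguous blocks of near-equal size
contiguous_blocks <- function(n, n_blocks) {
  if (n < n_blocks) config_error("fewer items than jackknife blocks")
  split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))
}

# Wald-style summary columns from beta + se
wald_cols <- function(beta, se) {
  z <- beta / se
  list(
    ci_low = beta - 1.959964 * se,
    ci_high = beta + 1.959964 * se,
    p = 2 * pnorm(-abs(z))
  )
}

# fast per-variant linear-regression scan of a quantitative trait:
# beta_j from simple regression of y on dosage column j (covariates
# residualised out of both first). Returns a summary-statistics tibble.
linear_scan <- function(dosages, y, variants = NULL, covariates = NULL) {
  n <- length(y)
  if (!is.null(covariates)) {
    Xc <- cbind(1, as.matrix(covariates))
    qrc <- qr(Xc)
    y <- qr.resid(qrc, y)
    dosages <- qr.resid(qrc, dosages)
    df_adj <- ncol(Xc)
  } else {
    y <- y - mean(y)
    dosages <- sweep(dosages, 2, colMeans(dosages))
    df_adj <- 1
  }
  sxx <- colSums(dosages^2)
  sxy <- drop(crossprod(dosages, y))
  beta <- sxy / sxx
  syy <- sum(y^2)
  rss <- pmax(syy - beta * sxy, 0)
  df_res <- n - df_adj - 1
  se <- sqrt(rss / df_res / sxx)
  z <- beta / se
  out <- tibble(
    beta = beta, se = se, pvalue = 2 * pnorm(-abs(z)), n = n
  )
  if (!is.null(variants)) out <- dplyr::bind_cols(variants, out)
  out
}
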