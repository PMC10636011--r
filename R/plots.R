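#' Forest plot of MR estimates
#'
#' One row per method with the point estimate and 95% CI; a dashed line
#' marks the null. Works on any `mr_estimate` tibble, including
#' multi-method results from [mr_all_methods()].
#'
#' @param estimates An `mr_estimate` tibble.
#' @param exponentiate Plot odds/rate ratios (`exp(beta)`) instead of
#'   betas.
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(estimates, exponentiate = FALSE) {
  dat <- tibble(
    method = factor(estimates$method, levels = rev(unique(estimates$method))),
    est = estimates$beta, lo = estimates$ci_low, hi = estimates$ci_high
  )
  null_at <- 0
  xlab <- "causal estimate (log scale units)"
  if (exponentiate) {
    dat$est <- exp(dat$est); dat$lo <- exp(dat$lo); dat$hi <- exp(dat$hi)
    null_at <- 1
    xlab <- "odds / rate ratio"
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = est, y = method)) +
    ggplot2::geom_vline(xintercept = null_at, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = lo, xmax = hi),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = xlab, y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of an instrument set with fitted MR lines
#'
#' Outcome effects against exposure effects with the IVW (through-origin)
#' and MR-Egger (free-intercept) fits overlaid; the vertical offset of
#' the Egger line at zero visualises directional pleiotropy.
#'
#' @param instruments An `mr_instruments` tibble.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(instruments) {
  ins <- retained_instruments(instruments)
  ivw <- mr_ivw(ins)
  egg <- tryCatch(mr_egger(ins), error = function(e) NULL)
  p <- ggplot2::ggplot(ins, ggplot2::aes(x = beta_x, y = beta_y)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = beta_y - 1.96 * se_y,
                                        ymax = beta_y + 1.96 * se_y),
                           width = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = ivw$beta,
                         colour = "#1b6ca8") +
    ggplot2::labs(x = "exposure effect (per effect allele)",
                  y = "outcome effect (log odds per effect allele)") +
    ggplot2::theme_minimal()
  if (!is.null(egg)) {
    p <- p + ggplot2::geom_abline(
      intercept = egg$beta[egg$method == "Egger_intercept"],
      slope = egg$beta[egg$method == "Egger_slope"],
      colour = "#c23b22", linetype = "longdash"
    )
  }
  p
}

#' @rdname plot_mr_forest
#' @param object An `mr_estimate` tibble.
#' @param ... Passed to [plot_mr_forest()].
#' @export
autoplot.mr_estimate <- function(object, ...) {
  plot_mr_forest(object, ...)
}
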