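#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MR estimate table
#'
#' `mr_estimate` objects are already tidy one-row-per-method tibbles;
#' `tidy()` returns the estimate columns under broom-standard names.
#'
#' @param x An `mr_estimate` tibble.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `p.value`.
#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble(
    term = x$method, estimate = x$beta, std.error = x$se,
    conf.low = x$ci_low, conf.high = x$ci_high, p.value = x$p
  )
}

#' Glance at an MR estimate table
#'
#' @param x An `mr_estimate` tibble.
#' @param ... Unused.
#' @return One-row tibble with instrument count and heterogeneity
#'   summary (from the first row carrying them).
#' @export
glance.mr_estimate <- function(x, ...) {
  i <- which(!is.na(x$Q))[1]
  if (is.na(i)) i <- 1L
  tibble(
    k_instruments = x$k[i], Q = x$Q[i], Q_df = x$Q_df[i], Q_p = x$Q_p[i],
    n_methods = length(unique(x$method))
  )
}

#' Tidy a one-sample two-stage MR fit
#'
#' @param x An `mr_tsls` object.
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `p.value`.
#' @export
tidy.mr_tsls <- function(x, ...) {
  tibble(
    term = sprintf("TSLS_%s", x$family), estimate = x$beta,
    std.error = x$se, conf.low = x$ci_low, conf.high = x$ci_high,
    p.value = x$p
  )
}

#' Glance at a one-sample two-stage MR fit
#'
#' @param x An `mr_tsls` object.
#' @param ... Unused.
#' @return One-row tibble with the first-stage F, weak-instrument flag,
#'   family and n.
#' @export
glance.mr_tsls <- function(x, ...) {
  tibble(
    first_stage_F = x$first_stage_F, weak_instrument = x$weak_instrument,
    family = x$family, nobs = x$n
  )
}
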