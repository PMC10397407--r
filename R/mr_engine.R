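# Wald-ratio and fixed-effect inverse-variance-weighted (IVW) MR
# estimators, normal-theory finalization (CI, two-sided p, odds-ratio
# scale for binary outcomes) and the CI -> SE recovery helper used to
# audit published result tables.

#' Wald ratio (single-instrument MR estimate)
#'
#' `beta = by / bx`. The default standard error is the first-order
#' approximation `sey / |bx|`, which ignores exposure-side uncertainty;
#' under this convention the fixed-effect IVW formula reduces exactly to
#' the Wald ratio for one instrument. The full delta-method SE,
#' `sqrt(sey^2 / bx^2 + by^2 * sex^2 / bx^4)`, which propagates the
#' exposure uncertainty, is available with `se_method = "delta"` and is
#' the appropriate choice when the exposure sample is much smaller than
#' the outcome sample.
#'
#' @param bx,sex Exposure effect and its SE.
#' @param by,sey Outcome effect and its SE.
#' @param se_method `"first_order"` (default) or `"delta"`.
#' @return `list(beta =, se =)`.
#' @export
wald_ratio <- function(bx, sex, by, sey,
                       se_method = c("first_order", "delta")) {
  se_method <- match.arg(se_method)
  if (is.na(bx) || bx == 0)
    abort_tmr("wald_ratio: exposure effect is zero (weak/degenerate instrument)",
              "targetmr_degenerate_instrument")
  beta <- by / bx
  se <- if (se_method == "first_order") {
    sey / abs(bx)
  } else {
    sqrt(sey^2 / bx^2 + by^2 * sex^2 / bx^4)
  }
  list(beta = beta, se = se)
}

#' Fixed-effect inverse-variance-weighted estimator
#'
#' Intercept-free weighted regression of SNP-outcome effects on
#' SNP-exposure effects, weighted by inverse outcome variance:
#' `beta = sum(bx * by / sey^2) / sum(bx^2 / sey^2)`,
#' `se = sqrt(1 / sum(bx^2 / sey^2))`. With a single pair this is exactly
#' the Wald ratio with its first-order SE.
#'
#' @param pairs A `data.frame` of harmonized pairs with columns
#'   `beta_exposure`, `beta_outcome`, `se_outcome` (as produced by
#'   [harmonize()]).
#' @return `list(beta =, se =)`.
#' @export
ivw <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0)
    abort_tmr("ivw: no harmonized instrument pairs", "targetmr_param_error")
  bx <- pairs$beta_exposure
  by <- pairs$beta_outcome
  sey <- pairs$se_outcome
  if (nrow(pairs) == 1) {
    # the single-instrument special case is the Wald ratio, computed by
    # the same arithmetic so the reduction is exact
    if (bx == 0)
      abort_tmr("ivw: exposure effect is zero (weak/degenerate instrument)",
                "targetmr_degenerate_instrument")
    return(list(beta = by / bx, se = sey / abs(bx)))
  }
  w <- 1 / sey^2
  denom <- sum(bx^2 * w)
  if (denom == 0)
    abort_tmr("ivw: all exposure effects are zero",
              "targetmr_degenerate_instrument")
  list(beta = sum(bx * by * w) / denom, se = sqrt(1 / denom))
}

#' Finalize an MR estimate: CI, p-value, odds-ratio scale
#'
#' Normal-theory two-sided p-value `2 * (1 - pnorm(|beta/se|))` and
#' `ci_level` confidence interval `beta +/- z * se` with `z = 1.959964`
#' at the default 95% level. For binary outcomes the estimate and CI are
#' also exponentiated to the odds-ratio scale.
#'
#' @param beta,se Point estimate and standard error (`se > 0`).
#' @param ci_level Confidence level (default 0.95).
#' @param binary Is the outcome binary (estimate on the log-odds scale)?
#' @return A one-row `data.frame` with `beta`, `se`, `ci_lower`,
#'   `ci_upper`, `pvalue` and (for binary outcomes) `odds_ratio`,
#'   `or_ci_lower`, `or_ci_upper`.
#' @export
finalize_estimate <- function(beta, se, ci_level = 0.95, binary = FALSE) {
  if (is.na(se) || se <= 0)
    abort_tmr("finalize_estimate: se must be > 0", "targetmr_param_error")
  zq <- z_quantile(ci_level)
  est <- data.frame(beta = beta, se = se,
                    ci_lower = beta - zq * se,
                    ci_upper = beta + zq * se,
                    pvalue = two_sided_p(beta / se),
                    odds_ratio = NA_real_,
                    or_ci_lower = NA_real_,
                    or_ci_upper = NA_real_)
  if (binary) {
    est$odds_ratio <- exp(beta)
    est$or_ci_lower <- exp(est$ci_lower)
    est$or_ci_upper <- exp(est$ci_upper)
  }
  est
}

#' Recover a standard error from a printed confidence interval
#'
#' `(upper - lower) / (2 * z)` with `z = 1.959964` at the 95% level. For
#' odds-ratio CIs set `log_scale = TRUE`, which applies the formula to the
#' log bounds.
#'
#' @param lower,upper CI bounds (`upper > lower`; both positive when
#'   `log_scale`).
#' @param ci_level Confidence level of the interval (default 0.95).
#' @param log_scale Recover on the log scale (odds-ratio intervals)?
#' @return The recovered standard error.
#' @export
se_from_ci <- function(lower, upper, ci_level = 0.95, log_scale = FALSE) {
  if (any(upper <= lower))
    abort_tmr("se_from_ci: upper must exceed lower", "targetmr_param_error")
  if (log_scale) {
    if (any(lower <= 0))
      abort_tmr("se_from_ci: log-scale bounds must be positive",
                "targetmr_param_error")
    lower <- log(lower); upper <- log(upper)
  }
  (upper - lower) / (2 * z_quantile(ci_level))
}
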