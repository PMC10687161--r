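#' @title Heterogeneity and pleiotropy diagnostics
#' @name sensitivity
#' @description Cochran's Q over the per-variant Wald ratios (heterogeneity)
#'   and the MR-Egger intercept test (average directional pleiotropy).
NULL

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (ratio_j - beta_IVW)^2` with inverse-variance weights
#' `w_j = betaX_j^2 / seY_j^2` and the fixed-effect IVW estimate; under
#' homogeneity Q is chi-squared on `n - 1` df.
#'
#' @param pairs Harmonized pairs (at least 2 usable variants).
#' @return List with `q_stat`, `q_df`, `q_pvalue`.
#' @export
cochran_q <- function(pairs) {
  pairs <- .check_pairs(pairs, 2, "cochran_q")
  re <- ratio_estimates(pairs)
  beta_ivw <- sum(re$weight * re$ratio) / sum(re$weight)
  q <- sum(re$weight * (re$ratio - beta_ivw)^2)
  df <- nrow(re) - 1
  list(q_stat = q, q_df = df,
       q_pvalue = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the MR-Egger regression with its scaled standard error
#' and two-sided t (n - 2 df) p-value; an intercept away from zero indicates
#' average directional pleiotropy of the instrument set.
#'
#' @param pairs Harmonized pairs (at least 3 usable variants).
#' @return List with `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_pvalue`.
#' @export
egger_intercept_test <- function(pairs) {
  pairs <- .check_pairs(pairs, 3, "egger_intercept_test")
  fit <- .egger_fit(pairs)
  list(egger_intercept = fit$intercept,
       egger_intercept_se = fit$intercept_se,
       egger_intercept_pvalue = fit$intercept_p)
}

#' Combined sensitivity diagnostics with decision flags
#'
#' @param pairs Harmonized pairs.
#' @param alpha Flagging threshold (default 0.05).
#' @return List with the Q and intercept fields plus logical
#'   `heterogeneity_detected` and `pleiotropy_detected` (NA when the
#'   corresponding test needs more instruments than available).
#' @export
sensitivity_tests <- function(pairs, alpha = 0.05) {
  usable <- harmonized_kept(pairs)
  out <- list(q_stat = NA_real_, q_df = NA_integer_, q_pvalue = NA_real_,
              egger_intercept = NA_real_, egger_intercept_se = NA_real_,
              egger_intercept_pvalue = NA_real_,
              heterogeneity_detected = NA, pleiotropy_detected = NA)
  if (nrow(usable) >= 2) {
    out[c("q_stat", "q_df", "q_pvalue")] <- cochran_q(usable)
    out$heterogeneity_detected <- out$q_pvalue < alpha
  }
  if (nrow(usable) >= 3) {
    out[c("egger_intercept", "egger_intercept_se",
          "egger_intercept_pvalue")] <- egger_intercept_test(usable)
    out$pleiotropy_detected <- out$egger_intercept_pvalue < alpha
  }
  out
}
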