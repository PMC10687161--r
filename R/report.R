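#' @title Presentation-layer tables
#' @name report
#' @description Renders pipeline output in the conventional epidemiological
#'   presentation: odds ratios with 95\% CIs (2 decimals), mediated
#'   proportions as percentages (1 decimal), and a forest-plot data file.
#'   Rounding happens only at render time; upstream tables keep full
#'   precision.
NULL

#' Odds ratio from a log-odds effect estimate
#' @param beta Log odds ratio(s).
#' @return `exp(beta)`, full precision (rounding is left to the renderers).
#' @export
or_from_beta <- function(beta) exp(beta)

#' Write forest-plot data for a set of MR results
#'
#' Tab-delimited file with one row per result: `label` (exposure -> outcome,
#' method), OR and 95\% CI rounded to 2 decimals, raw and FDR-adjusted
#' p-values, and a significance flag (`fdr_p < 0.05`). Rows are ordered by
#' exposure then outcome.
#'
#' @param results MR results data.frame (needs `exposure`, `outcome`,
#'   `method`, `beta`, `se`, `pvalue`; `fdr_pvalue` optional).
#' @param path Output path.
#' @param alpha Flagging threshold on the FDR-adjusted p.
#' @export
render_forest_data <- function(results, path, alpha = 0.05) {
  header <- c("label", "or", "ci_low", "ci_high", "p", "fdr_p", "significant")
  if (is.null(results) || nrow(results) == 0) {
    writeLines(paste(header, collapse = "\t"), path)
    return(invisible(path))
  }
  if (is.null(results$fdr_pvalue)) results$fdr_pvalue <- NA_real_
  results <- results[order(results$exposure, results$outcome), , drop = FALSE]
  z <- stats::qnorm(0.975)
  out <- data.frame(
    label = sprintf("%s -> %s (%s)", results$exposure, results$outcome,
                    results$method),
    or = sprintf("%.2f", exp(results$beta)),
    ci_low = sprintf("%.2f", exp(results$beta - z * results$se)),
    ci_high = sprintf("%.2f", exp(results$beta + z * results$se)),
    p = formatC(results$pvalue, format = "g", digits = 3),
    fdr_p = ifelse(is.na(results$fdr_pvalue), "NA",
                   formatC(results$fdr_pvalue, format = "g", digits = 3)),
    significant = as.integer(!is.na(results$fdr_pvalue) &
                               results$fdr_pvalue < alpha))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the mediation table
#'
#' Columns `target`, `mediator`, `outcome`, `beta1`, `beta2`, `beta3`,
#' `proportion_pct` with the proportion as a percentage rounded to one
#' decimal (betas keep 6 significant digits).
#'
#' @param mediation Mediation data.frame from [run_two_step()].
#' @param path Output path.
#' @export
render_mediation_table <- function(mediation, path) {
  header <- c("target", "mediator", "outcome", "beta1", "beta2", "beta3",
              "proportion_pct")
  if (is.null(mediation) || nrow(mediation) == 0) {
    writeLines(paste(header, collapse = "\t"), path)
    return(invisible(path))
  }
  out <- data.frame(
    target = mediation$target_label, mediator = mediation$mediator,
    outcome = mediation$outcome,
    beta1 = formatC(signif(mediation$beta1, 6), format = "g", digits = 6),
    beta2 = formatC(signif(mediation$beta2, 6), format = "g", digits = 6),
    beta3 = formatC(signif(mediation$beta3, 6), format = "g", digits = 6),
    proportion_pct = sprintf("%.1f", 100 * mediation$proportion))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
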