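#' @title Two-step MR mediation pipeline
#' @name pipeline
#' @description Orchestrates the full study design: per-target instrument
#'   construction, a positive-control gate, step-1 MR (targets to outcomes
#'   and to mediators), step-2 MR (mediators to outcomes), the reliability
#'   rule, Benjamini-Hochberg FDR control, and mediation proportions.
NULL

#' Study configuration
#'
#' Collects every tunable threshold of the pipeline with the defaults of the
#' study design: a 100-kb cis window, genome-wide significance `5e-8`,
#' clumping at r-squared 0.30 for drug-target instruments and 0.001 for
#' mediator (metabolite/protein) instruments with a 10,000-kb window, an
#' F-statistic cutoff of 10, and a 0.05 significance level.
#'
#' @param targets Data.frame with columns `gene` and `trait`: the
#'   drug-target gene / lipid-trait pairs to instrument.
#' @param window_kb cis-window flank in kb.
#' @param p_threshold Instrument significance threshold (strict `<`).
#' @param r2_instruments Clumping r-squared threshold for drug-target sets.
#' @param r2_metabolites Clumping r-squared threshold for mediator sets.
#' @param clump_window_kb Clumping distance cap (kb).
#' @param f_cutoff Weak-instrument F cutoff.
#' @param alpha Significance level for the gate, reliability rule and
#'   mediation gating.
#' @param seed Master seed for all stochastic components (bootstraps).
#' @param fdr_family How p-values are grouped for FDR adjustment:
#'   `"stage_outcome"` (default; within each analysis stage and outcome,
#'   across targets) or `"stage"` (within stage across all outcomes).
#' @param methods Estimator subset to run for multi-instrument sets.
#' @param n_boot Bootstrap resamples for the median/mode estimators.
#' @param mediation_significance `"raw"` (default) gates mediation on raw
#'   p-values of the three betas; `"fdr"` uses FDR-adjusted ones.
#' @return A list of class `study_config`.
#' @export
study_config <- function(targets, window_kb = 100, p_threshold = 5e-8,
                         r2_instruments = 0.30, r2_metabolites = 0.001,
                         clump_window_kb = 10000, f_cutoff = 10,
                         alpha = 0.05, seed = 20231116,
                         fdr_family = c("stage_outcome", "stage"),
                         methods = c("ivw", "mr_egger", "weighted_median",
                                     "simple_mode", "weighted_mode"),
                         n_boot = 1000,
                         mediation_significance = c("raw", "fdr")) {
  stopifnot(window_kb >= 0, p_threshold > 0, r2_instruments > 0,
            r2_instruments <= 1, r2_metabolites > 0, r2_metabolites <= 1,
            f_cutoff >= 0, alpha > 0, alpha < 1, n_boot > 0)
  targets <- as.data.frame(targets)
  stopifnot(all(c("gene", "trait") %in% names(targets)))
  structure(list(targets = targets, window_kb = window_kb,
                 p_threshold = p_threshold, r2_instruments = r2_instruments,
                 r2_metabolites = r2_metabolites,
                 clump_window_kb = clump_window_kb, f_cutoff = f_cutoff,
                 alpha = alpha, seed = as.integer(seed),
                 fdr_family = match.arg(fdr_family),
                 methods = methods, n_boot = n_boot,
                 mediation_significance = match.arg(mediation_significance)),
            class = "study_config")
}

#' Reliability rule for a causal estimate
#'
#' A result is reliable when the primary estimate (IVW, or the Wald ratio
#' for single-instrument sets) has `p < alpha` and its direction agrees with
#' the MR-Egger estimate. When no Egger fit exists (fewer than 3
#' instruments) only the significance condition applies and the result is
#' flagged direction-unverified.
#'
#' @param primary One-row MR result with method `ivw` or `wald_ratio`.
#' @param egger One-row MR result with method `mr_egger`, or `NULL`.
#' @param alpha Significance level (default 0.05).
#' @return Logical; attribute `"direction_unverified"` is TRUE when no Egger
#'   comparison was possible.
#' @export
reliability_check <- function(primary, egger = NULL, alpha = 0.05) {
  stopifnot(primary$method %in% c("ivw", "wald_ratio"))
  if (is.null(egger) || (is.data.frame(egger) && nrow(egger) == 0)) {
    out <- primary$pvalue < alpha
    attr(out, "direction_unverified") <- TRUE
    return(out)
  }
  stopifnot(egger$method == "mr_egger")
  out <- primary$pvalue < alpha && sign(primary$beta) == sign(egger$beta)
  attr(out, "direction_unverified") <- FALSE
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`adj_i = min_{j >= i} p_(j) * m / j`, capped at
#' 1), returned in the input order. Inputs outside (0, 1] are rejected.
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted p-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Positive-control gate
#'
#' Drug targets whose instruments do not show a reliable, FDR-significant
#' effect on the positive-control outcome are excluded from every later
#' stage (the design's analogue of dropping a target that fails to reproduce
#' an established causal relationship).
#'
#' @param control_results Data.frame with one row per target label and
#'   columns `target_label`, `fdr_pvalue`, `reliable`.
#' @param alpha Significance level.
#' @return Character vector of excluded target labels.
#' @export
positive_control_gate <- function(control_results, alpha = 0.05) {
  stopifnot(all(c("target_label", "fdr_pvalue", "reliable") %in%
                  names(control_results)))
  excl <- control_results$fdr_pvalue >= alpha | !control_results$reliable
  control_results$target_label[excl]
}

#' Mediation proportion from the three MR betas
#'
#' Two-step MR mediation: `beta1` is the exposure-proxy effect on the
#' mediator, `beta2` the mediator effect on the outcome, `beta3` the
#' exposure-proxy effect on the outcome from step-1 MR. The indirect effect
#' is `beta1 * beta2`, the total effect `beta3 + beta1 * beta2`, and the
#' proportion mediated their ratio. The caller is responsible for only
#' requesting the proportion when all three betas are statistically
#' significant; `computed` records that gate.
#'
#' @param beta1,beta2,beta3 The three effect estimates.
#' @param computed Whether the significance gate passed (stored, not
#'   enforced).
#' @return List of class `mediation_result` with `beta1`, `beta2`, `beta3`,
#'   `indirect`, `total`, `proportion` and `computed`.
#' @export
mediation_proportion <- function(beta1, beta2, beta3, computed = TRUE) {
  indirect <- beta1 * beta2
  total <- beta3 + indirect
  if (abs(total) < 1e-12)
    stop("mediation proportion undefined: total effect is zero")
  structure(list(beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 indirect = indirect, total = total,
                 proportion = indirect / total, computed = computed),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation: b1=%.3f b2=%.3f b3=%.3f -> proportion %.1f%%%s\n",
              x$beta1, x$beta2, x$beta3, 100 * x$proportion,
              if (x$computed) "" else " (not significance-gated)"))
  invisible(x)
}

## one MR analysis: harmonize, estimate, diagnose; returns method rows plus
## the primary/egger handles the pipeline logic needs
.analyse <- function(instr_records, outcome_gwas, exposure_label,
                     outcome_label, stage, config, seed) {
  pairs <- harmonize_tables(instr_records, outcome_gwas)
  usable <- harmonized_kept(pairs)
  if (nrow(usable) == 0) return(NULL)
  res <- mr_all_methods(pairs, methods = config$methods,
                        n_boot = config$n_boot, seed = seed,
                        exposure = exposure_label, outcome = outcome_label)
  sens <- sensitivity_tests(pairs, config$alpha)
  res$q_stat <- sens$q_stat
  res$q_pvalue <- sens$q_pvalue
  res$stage <- stage
  primary <- res[res$method %in% c("ivw", "wald_ratio"), , drop = FALSE][1, ]
  egger <- res[res$method == "mr_egger", , drop = FALSE]
  list(rows = res, primary = primary,
       egger = if (nrow(egger)) egger[1, ] else NULL,
       n_used = nrow(usable))
}

## FDR-adjust the primary rows of a stage's analyses and apply reliability
.summarise_stage <- function(analyses, config) {
  if (length(analyses) == 0) return(NULL)
  prim <- do.call(rbind, lapply(analyses, `[[`, "primary"))
  fam <- switch(config$fdr_family,
                stage_outcome = prim$outcome,
                stage = rep("all", nrow(prim)))
  prim$fdr_pvalue <- stats::ave(prim$pvalue, fam, FUN = bh_fdr)
  prim$reliable <- vapply(seq_along(analyses), function(i)
    as.logical(reliability_check(analyses[[i]]$primary,
                                 analyses[[i]]$egger, config$alpha)),
    logical(1))
  prim
}

#' Run the full two-step MR mediation study
#'
#' Stages: (a) per-target instrument construction and MR against the
#' positive-control outcome, with FDR and the reliability rule feeding the
#' positive-control gate; (b) surviving targets against each final outcome;
#' (c) surviving targets against each mediator; (d) each mediator against
#' each outcome using the mediator's own instruments (significance filter
#' plus stringent clumping, no cis restriction); (e) mediation proportions
#' for every (target, mediator, outcome) triple whose three betas pass the
#' significance gate.
#'
#' @param config A [study_config()].
#' @param datasets List with elements `regions` (gene-region data.frame),
#'   `exposures` (named list of GWAS tables, one per lipid trait),
#'   `control` (list with `name` and `gwas`), `outcomes` and `mediators`
#'   (named lists of GWAS tables).
#' @param ld LD r-squared matrix covering all candidate variants.
#' @return List with `instruments` (per-target `instrument_set`s),
#'   `mr_results` (all method rows, all stages), `primary_results` (primary
#'   rows with FDR and reliability), `excluded_targets`, `mediation`
#'   (data.frame), and `manifest`.
#' @export
run_two_step <- function(config, datasets, ld) {
  stopifnot(inherits(config, "study_config"))
  validate_ld_matrix(ld)
  regions <- datasets$regions
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    (config$seed + seed_i) %% .Machine$integer.max
  }

  ## per-target instruments
  labels <- paste(config$targets$gene, config$targets$trait, sep = "|")
  instr <- stats::setNames(vector("list", length(labels)), labels)
  for (i in seq_len(nrow(config$targets))) {
    gene <- config$targets$gene[i]; trait <- config$targets$trait[i]
    region <- regions[regions$gene == gene, , drop = FALSE]
    if (nrow(region) != 1) stop("region table must have one row for ", gene)
    instr[[labels[i]]] <- suppressWarnings(build_instrument_set(
      datasets$exposures[[trait]], region[1, ], trait, ld,
      window_bp = config$window_kb * 1000, p_threshold = config$p_threshold,
      r2_threshold = config$r2_instruments, f_cutoff = config$f_cutoff,
      clump_window_kb = config$clump_window_kb))
  }
  has_iv <- vapply(instr, function(s) nrow(s$records) > 0, logical(1))

  run_stage <- function(stage, exposures, outcome_list) {
    analyses <- list()
    for (ex_label in names(exposures)) {
      for (out_label in names(outcome_list)) {
        a <- .analyse(exposures[[ex_label]], outcome_list[[out_label]],
                      ex_label, out_label, stage, config, next_seed())
        if (!is.null(a)) analyses[[paste(ex_label, out_label, sep = "->")]] <- a
      }
    }
    analyses
  }
  target_records <- lapply(instr[has_iv], `[[`, "records")

  ## (a) positive control
  ctrl <- stats::setNames(list(datasets$control$gwas), datasets$control$name)
  a_ctrl <- run_stage("positive_control", target_records, ctrl)
  s_ctrl <- .summarise_stage(a_ctrl, config)
  ctrl_tab <- data.frame(target_label = s_ctrl$exposure,
                         fdr_pvalue = s_ctrl$fdr_pvalue,
                         reliable = s_ctrl$reliable)
  excluded <- union(positive_control_gate(ctrl_tab, config$alpha),
                    names(instr)[!has_iv])
  surviving <- setdiff(names(target_records), excluded)

  ## (b) targets -> outcomes, (c) targets -> mediators
  a_out <- run_stage("target_outcome", target_records[surviving],
                     datasets$outcomes)
  a_med <- run_stage("target_mediator", target_records[surviving],
                     datasets$mediators)

  ## (d) mediators -> outcomes with the mediators' own instruments
  med_records <- lapply(datasets$mediators, function(gwas) {
    sig <- gwas[gwas$pvalue < config$p_threshold, , drop = FALSE]
    cl <- clump(sig, ld, config$r2_metabolites, config$clump_window_kb)
    if (nrow(cl)) cl[f_statistic(cl$beta, cl$se) > config$f_cutoff, ,
                     drop = FALSE] else cl
  })
  med_records <- med_records[vapply(med_records, nrow, 1L) > 0]
  a_m2o <- run_stage("mediator_outcome", med_records, datasets$outcomes)

  stages <- list(a_ctrl, a_out, a_med, a_m2o)
  prim <- do.call(rbind, lapply(stages, .summarise_stage, config = config))
  all_rows <- do.call(rbind, unlist(lapply(stages, function(s)
    lapply(s, `[[`, "rows")), recursive = FALSE))
  rownames(all_rows) <- rownames(prim) <- NULL
  key <- function(d) paste(d$stage, d$exposure, d$outcome, d$method)
  all_rows$fdr_pvalue <- prim$fdr_pvalue[match(key(all_rows), key(prim))]
  all_rows$reliable <- prim$reliable[match(key(all_rows), key(prim))]

  ## (e) mediation
  gate_p <- if (config$mediation_significance == "raw") "pvalue" else "fdr_pvalue"
  med_rows <- list()
  for (t_label in surviving) for (m in names(med_records))
    for (o in names(datasets$outcomes)) {
      b1 <- prim[prim$stage == "target_mediator" & prim$exposure == t_label &
                   prim$outcome == m, , drop = FALSE]
      b2 <- prim[prim$stage == "mediator_outcome" & prim$exposure == m &
                   prim$outcome == o, , drop = FALSE]
      b3 <- prim[prim$stage == "target_outcome" & prim$exposure == t_label &
                   prim$outcome == o, , drop = FALSE]
      if (!nrow(b1) || !nrow(b2) || !nrow(b3)) next
      ok <- b1[[gate_p]] < config$alpha && b2[[gate_p]] < config$alpha &&
        b3[[gate_p]] < config$alpha
      if (!ok) next
      mp <- mediation_proportion(b1$beta, b2$beta, b3$beta, computed = TRUE)
      med_rows[[length(med_rows) + 1L]] <- data.frame(
        target_label = t_label, mediator = m, outcome = o,
        beta1 = mp$beta1, beta2 = mp$beta2, beta3 = mp$beta3,
        indirect = mp$indirect, total = mp$total,
        proportion = mp$proportion, stringsAsFactors = FALSE)
    }
  mediation <- if (length(med_rows)) do.call(rbind, med_rows) else
    data.frame(target_label = character(0), mediator = character(0),
               outcome = character(0), beta1 = numeric(0), beta2 = numeric(0),
               beta3 = numeric(0), indirect = numeric(0), total = numeric(0),
               proportion = numeric(0))

  manifest <- list(
    config = unclass(config)[setdiff(names(config), "targets")],
    targets = labels,
    excluded_targets = excluded,
    instrument_counts = vapply(instr, function(s) nrow(s$records), 1L),
    mediator_instrument_counts = vapply(med_records, nrow, 1L),
    n_analyses = nrow(prim),
    n_mediation = nrow(mediation))

  list(instruments = instr, mr_results = all_rows, primary_results = prim,
       excluded_targets = excluded, mediation = mediation,
       manifest = manifest)
}
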