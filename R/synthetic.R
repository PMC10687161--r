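#' @title Synthetic GWAS summary statistics with known causal structure
#' @name synthetic_data
#' @description Summary-statistic-level simulation of a cis region for an
#'   exposure trait, a mediator trait and a binary outcome, with AR(1)
#'   linkage disequilibrium, configurable instrument strength and
#'   pleiotropy, and a known exposure -> mediator -> outcome causal chain.
#'   Every latent quantity is returned in a truth record so estimators can
#'   be checked against the generative model.
NULL

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

.allele_pairs <- list(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))
.palindromic_pairs <- list(c("A", "T"), c("C", "G"))

#' Simulation configuration for one cis region
#'
#' Defaults emulate a drug-target cis region for a lipid exposure measured
#' in a large GWAS, a mediator measured in a much smaller one, and a binary
#' disease outcome: 100 SNPs with AR(1) LD (rho = 0.8), 20 causal SNPs with
#' standardized effects of sd 0.05, exposure/outcome sample sizes 200,000
#' (30\% cases for the outcome) and mediator sample size 20,000. The default
#' causal chain is `beta1 = 0.24` (exposure to mediator, SD per SD),
#' `beta2 = -0.08` (mediator to outcome, log-odds per SD) and a direct
#' exposure-outcome effect of -0.20 log-odds per SD, so the generative
#' mediated proportion is `beta1*beta2 / (direct + beta1*beta2)` (about
#' 8.8\%).
#'
#' @param n_snps Number of variants in the region.
#' @param maf_range Minor-allele-frequency range (uniform draw).
#' @param ld_rho AR(1) correlation parameter in \[0, 1); pairwise r-squared
#'   is `rho^(2|i-j|)`.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes.
#' @param case_fraction Case fraction of the binary outcome GWAS.
#' @param causal_beta_exposure_outcome Direct exposure effect on the outcome
#'   (log-odds per SD).
#' @param beta1_true Exposure effect on the mediator (SD per SD).
#' @param beta2_true Mediator effect on the outcome (log-odds per SD).
#' @param n_causal_snps Number of SNPs with nonzero standardized exposure
#'   effects.
#' @param gamma_sd Scale of the per-SNP standardized effects.
#' @param pleiotropy_mean,pleiotropy_sd Direct SNP-to-outcome effects
#'   bypassing the exposure (directional when the mean is nonzero).
#' @param mediator_noise_sd Mediator-specific per-SNP effect noise.
#' @param palindromic_fraction Fraction of variants given A/T or C/G allele
#'   pairs.
#' @param chromosome,pos_start,spacing_bp,variant_prefix Region layout.
#' @param seed RNG seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_snps = 100, maf_range = c(0.05, 0.5),
                              ld_rho = 0.8, n_exposure = 2e5,
                              n_mediator = 2e4, n_outcome = 2e5,
                              case_fraction = 0.3,
                              causal_beta_exposure_outcome = -0.20,
                              beta1_true = 0.24, beta2_true = -0.08,
                              n_causal_snps = min(20, n_snps),
                              gamma_sd = 0.05,
                              pleiotropy_mean = 0, pleiotropy_sd = 0,
                              mediator_noise_sd = 0,
                              palindromic_fraction = 0,
                              chromosome = "2", pos_start = 21e6,
                              spacing_bp = 1000, variant_prefix = "rsA",
                              seed = 20231116) {
  stopifnot(n_snps >= 1, n_causal_snps <= n_snps, ld_rho >= 0, ld_rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            n_exposure > 0, n_mediator > 0, n_outcome > 0,
            case_fraction > 0, case_fraction < 1,
            palindromic_fraction >= 0, palindromic_fraction <= 1)
  structure(as.list(environment()), class = "simulation_config")
}

.gwas_table <- function(cfg, beta_obs, se, n, maf, alleles) {
  p <- pmax(2 * stats::pnorm(-abs(beta_obs / se)), .Machine$double.xmin)
  data.frame(
    variant_id = sprintf("%s%04d", cfg$variant_prefix, seq_len(cfg$n_snps)),
    chromosome = cfg$chromosome,
    position = cfg$pos_start + (seq_len(cfg$n_snps) - 1) * cfg$spacing_bp,
    effect_allele = alleles$effect, other_allele = alleles$other,
    eaf = maf, beta = beta_obs, se = se, pvalue = p, n = n,
    stringsAsFactors = FALSE)
}

#' Simulate one cis region's summary statistics for three traits
#'
#' Generative model: MAFs uniform on `maf_range`; SNP correlations
#' `r_ij = rho^|i-j|`; standardized exposure effects `gamma` are nonzero for
#' `n_causal_snps` randomly chosen SNPs; the marginal (LD-convolved) effects
#' are `beta_marginal = R gamma`. The mediator's true effects are
#' `beta1_true * beta_marginal` plus optional mediator-specific noise; the
#' outcome's are `(direct + beta1_true*beta2_true) * beta_marginal` plus
#' per-SNP pleiotropy. Observed betas are the true values plus normal noise
#' with the analytic GWAS standard error
#' `se = 1/sqrt(2 maf (1-maf) n)` (quantitative) or
#' `se = 1/sqrt(2 maf (1-maf) n cf (1-cf))` (binary outcome, case fraction
#' `cf`); p-values come from the observed z-scores.
#'
#' @param config A [simulation_config()].
#' @return List with `exposure`, `mediator`, `outcome` (GWAS data.frames),
#'   `ld` (r-squared matrix) and `truth` (all latent quantities, including
#'   `total_effect` and `proportion_true`).
#' @export
simulate_region <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  .with_seed(cfg$seed, {
    m <- cfg$n_snps
    maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    R <- cfg$ld_rho^abs(outer(seq_len(m), seq_len(m), "-"))
    gamma <- numeric(m)
    causal <- sample.int(m, cfg$n_causal_snps)
    gamma[causal] <- stats::rnorm(cfg$n_causal_snps, 0, cfg$gamma_sd)
    beta_marginal <- drop(R %*% gamma)
    mediator_true <- cfg$beta1_true * beta_marginal +
      if (cfg$mediator_noise_sd > 0)
        stats::rnorm(m, 0, cfg$mediator_noise_sd) else 0
    pleio <- if (cfg$pleiotropy_sd > 0 || cfg$pleiotropy_mean != 0)
      stats::rnorm(m, cfg$pleiotropy_mean, cfg$pleiotropy_sd) else numeric(m)
    total_effect <- cfg$causal_beta_exposure_outcome +
      cfg$beta1_true * cfg$beta2_true
    outcome_true <- total_effect * beta_marginal + pleio

    v <- 2 * maf * (1 - maf)
    se_x <- 1 / sqrt(v * cfg$n_exposure)
    se_m <- 1 / sqrt(v * cfg$n_mediator)
    se_y <- 1 / sqrt(v * cfg$n_outcome * cfg$case_fraction *
                       (1 - cfg$case_fraction))

    n_pal <- round(cfg$palindromic_fraction * m)
    pick <- c(sample(.palindromic_pairs, n_pal, replace = TRUE),
              sample(.allele_pairs, m - n_pal, replace = TRUE))
    pick <- pick[sample.int(m)]
    alleles <- list(effect = vapply(pick, `[`, "", 1),
                    other = vapply(pick, `[`, "", 2))

    bx <- stats::rnorm(m, beta_marginal, se_x)
    bm <- stats::rnorm(m, mediator_true, se_m)
    by <- stats::rnorm(m, outcome_true, se_y)

    ld <- R^2
    ids <- sprintf("%s%04d", cfg$variant_prefix, seq_len(m))
    dimnames(ld) <- list(ids, ids)

    list(exposure = .gwas_table(cfg, bx, se_x, cfg$n_exposure, maf, alleles),
         mediator = .gwas_table(cfg, bm, se_m, cfg$n_mediator, maf, alleles),
         outcome = .gwas_table(cfg, by, se_y, cfg$n_outcome, maf, alleles),
         ld = ld,
         truth = list(config = cfg, maf = maf, gamma = gamma,
                      causal_index = sort(causal),
                      beta_marginal = beta_marginal,
                      mediator_true = mediator_true,
                      outcome_true = outcome_true, pleiotropy = pleio,
                      se_exposure = se_x, se_mediator = se_m,
                      se_outcome = se_y, total_effect = total_effect,
                      proportion_true = (cfg$beta1_true * cfg$beta2_true) /
                        total_effect))
  })
}

## block-diagonal assembly of per-region r2 matrices
.block_ld <- function(...) {
  mats <- list(...)
  ids <- unlist(lapply(mats, rownames))
  out <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  at <- 1
  for (m in mats) {
    idx <- at:(at + nrow(m) - 1)
    out[idx, idx] <- m
    at <- at + nrow(m)
  }
  out
}

#' Simulate a complete two-step MR study
#'
#' Builds the multi-region dataset [run_two_step()] consumes: a drug-target
#' cis region driving the exposure trait (with downstream effects on the
#' mediator, the positive-control outcome and the disease outcome), and a
#' separate cis region where the mediator has its own strong instruments
#' whose only path to the outcome is `beta2` — without this second region,
#' step-2 MR through the target's SNPs would recover
#' `(direct + beta1*beta2)/beta1` rather than `beta2`. Optionally adds a
#' second, null drug target whose instruments affect neither the
#' positive-control outcome nor the disease outcome, to exercise the
#' positive-control gate.
#'
#' @param seed RNG seed for the whole study.
#' @param target_config [simulation_config()] for the drug-target region
#'   (defaults as documented there).
#' @param mediator_config [simulation_config()] for the mediator's own
#'   instrument region; the defaults give a small region of strong cis
#'   effects (gamma_sd 0.4) measured at the mediator's sample size.
#' @param beta_control True effect of the exposure on the positive-control
#'   outcome (log-odds per SD); the null target always has 0.
#' @param n_control,control_case_fraction Positive-control GWAS size/case mix.
#' @param include_null_target Add the null drug target.
#' @return List with `datasets` (as required by [run_two_step()]), `ld`,
#'   `targets` (data.frame for [study_config()]) and `truth`.
#' @export
simulate_study <- function(seed = 20231116,
                           target_config = simulation_config(seed = seed),
                           mediator_config = simulation_config(
                             n_snps = 40, n_causal_snps = 10, ld_rho = 0.8,
                             gamma_sd = 0.4,
                             n_exposure = target_config$n_mediator,
                             n_outcome = target_config$n_outcome,
                             case_fraction = target_config$case_fraction,
                             causal_beta_exposure_outcome =
                               target_config$beta2_true,
                             beta1_true = 0, beta2_true = 0,
                             chromosome = "10", pos_start = 76e6,
                             variant_prefix = "rsB", seed = seed + 1L),
                           beta_control = 0.45, n_control = 87000,
                           control_case_fraction = 0.35,
                           include_null_target = FALSE) {
  regA <- simulate_region(target_config)
  regB <- simulate_region(mediator_config)

  ctrl_tab <- function(reg, effect, offset) {
    truth <- reg$truth
    se_c <- 1 / sqrt(2 * truth$maf * (1 - truth$maf) * n_control *
                       control_case_fraction * (1 - control_case_fraction))
    b <- .with_seed(seed + offset,
                    stats::rnorm(length(se_c), effect * truth$beta_marginal,
                                 se_c))
    tab <- reg$exposure
    tab$beta <- b; tab$se <- se_c
    tab$pvalue <- pmax(2 * stats::pnorm(-abs(b / se_c)), .Machine$double.xmin)
    tab$n <- n_control
    tab
  }
  control <- ctrl_tab(regA, beta_control, 101L)

  regions <- data.frame(
    gene = "APOB", chromosome = target_config$chromosome,
    start = min(regA$exposure$position), end = max(regA$exposure$position),
    stringsAsFactors = FALSE)
  targets <- data.frame(gene = "APOB", trait = "ApoB",
                        stringsAsFactors = FALSE)
  exposure_gwas <- regA$exposure
  outcome_gwas <- rbind(regA$outcome, regB$outcome)
  mediator_gwas <- rbind(regA$mediator, regB$exposure)
  ld <- .block_ld(regA$ld, regB$ld)
  truth <- list(target = regA$truth, mediator_region = regB$truth,
                beta_control = beta_control,
                total_effect = regA$truth$total_effect,
                proportion_true = regA$truth$proportion_true)

  if (include_null_target) {
    null_cfg <- simulation_config(
      n_snps = target_config$n_snps,
      n_causal_snps = target_config$n_causal_snps,
      ld_rho = target_config$ld_rho, gamma_sd = target_config$gamma_sd,
      n_exposure = target_config$n_exposure,
      n_mediator = target_config$n_mediator,
      n_outcome = target_config$n_outcome,
      case_fraction = target_config$case_fraction,
      causal_beta_exposure_outcome = 0, beta1_true = 0, beta2_true = 0,
      chromosome = "1", pos_start = 62.5e6, variant_prefix = "rsC",
      seed = seed + 2L)
    regC <- simulate_region(null_cfg)
    exposure_gwas <- rbind(exposure_gwas, regC$exposure)
    outcome_gwas <- rbind(outcome_gwas, regC$outcome)
    control <- rbind(control, ctrl_tab(regC, 0, 102L))
    ld <- .block_ld(regA$ld, regB$ld, regC$ld)
    regions <- rbind(regions, data.frame(
      gene = "ANGPTL3", chromosome = "1",
      start = min(regC$exposure$position), end = max(regC$exposure$position),
      stringsAsFactors = FALSE))
    targets <- rbind(targets, data.frame(gene = "ANGPTL3", trait = "ApoB",
                                         stringsAsFactors = FALSE))
    truth$null_target <- regC$truth
  }

  list(datasets = list(regions = regions,
                       exposures = list(ApoB = exposure_gwas),
                       control = list(name = "CHD", gwas = control),
                       outcomes = list(lung_cancer_ever_smokers = outcome_gwas),
                       mediators = list(neutral_ceramidase = mediator_gwas)),
       ld = ld, targets = targets, truth = truth)
}

#' Write a deterministic fixture suite
#'
#' Writes small seeded fixtures exercising each awkward corner of the
#' pipeline: `strong/` (a well-powered cis region), `weak/` (variants with F
#' statistics straddling the cutoff of 10), `palindromic/` (A/T and C/G
#' variants), `swapped/` (outcome file with effect/other alleles swapped
#' relative to the exposure), and `null_control/` (a two-target study where
#' one target is null on the positive-control outcome). Running twice with
#' the same seed produces byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed.
#' @return `out_dir`, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 20231116) {
  sub <- function(name) {
    d <- file.path(out_dir, name)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  }
  write_region <- function(reg, d, region_row) {
    write_gwas(reg$exposure, file.path(d, "exposure.tsv"))
    write_gwas(reg$outcome, file.path(d, "outcome.tsv"))
    write_ld_matrix(reg$ld, file.path(d, "ld.tsv"))
    utils::write.table(region_row, file.path(d, "regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  region_row <- function(gene, reg) data.frame(
    gene = gene, chromosome = reg$exposure$chromosome[1],
    start = min(reg$exposure$position), end = max(reg$exposure$position))

  strong <- simulate_region(simulation_config(n_snps = 20, n_causal_snps = 8,
                                              gamma_sd = 0.15, seed = seed))
  write_region(strong, sub("strong"), region_row("APOB", strong))

  weak <- simulate_region(simulation_config(n_snps = 12, n_causal_snps = 12,
                                            gamma_sd = 0.004, ld_rho = 0,
                                            n_exposure = 5e5,
                                            seed = seed + 1L))
  # force p under the genome-wide threshold while leaving F straddling 10,
  # so the F filter (not the significance filter) decides
  weak$exposure$pvalue <- rep(1e-9, nrow(weak$exposure))
  write_region(weak, sub("weak"), region_row("WEAK1", weak))

  pal <- simulate_region(simulation_config(n_snps = 12, n_causal_snps = 6,
                                           gamma_sd = 0.15,
                                           palindromic_fraction = 0.5,
                                           maf_range = c(0.4, 0.5),
                                           seed = seed + 2L))
  write_region(pal, sub("palindromic"), region_row("PAL1", pal))

  sw <- simulate_region(simulation_config(n_snps = 10, n_causal_snps = 5,
                                          gamma_sd = 0.15, seed = seed + 3L))
  out_sw <- sw$outcome
  ea <- out_sw$effect_allele
  out_sw$effect_allele <- out_sw$other_allele
  out_sw$other_allele <- ea
  out_sw$beta <- -out_sw$beta
  out_sw$eaf <- 1 - out_sw$eaf
  sw$outcome <- out_sw
  write_region(sw, sub("swapped"), region_row("SWAP1", sw))

  study <- simulate_study(seed = seed + 4L,
                          target_config = simulation_config(
                            n_snps = 30, n_causal_snps = 10, gamma_sd = 0.1,
                            seed = seed + 4L),
                          include_null_target = TRUE)
  d <- sub("null_control")
  write_gwas(study$datasets$exposures$ApoB, file.path(d, "exposure.tsv"))
  write_gwas(study$datasets$control$gwas, file.path(d, "control.tsv"))
  write_gwas(study$datasets$outcomes[[1]], file.path(d, "outcome.tsv"))
  write_gwas(study$datasets$mediators[[1]], file.path(d, "mediator.tsv"))
  write_ld_matrix(study$ld, file.path(d, "ld.tsv"))
  utils::write.table(study$datasets$regions, file.path(d, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
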