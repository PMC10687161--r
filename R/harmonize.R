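#' @title Allele harmonization between exposure and outcome statistics
#' @name harmonize
#' @description Aligns outcome effect sizes to the exposure's effect allele,
#'   resolving swapped alleles and strand flips, and dropping palindromic
#'   variants whose strand cannot be inferred from allele frequency.
NULL

.complement <- function(a) chartr("ACGT", "TGCA", a)

.is_palindromic <- function(ea, oa) ea == .complement(oa)

#' Harmonize one exposure/outcome record pair
#'
#' Rules, applied in order: if the outcome alleles match the exposure's the
#' pair is `kept`; if they are swapped, the outcome beta is negated and its
#' eaf replaced by `1 - eaf` (`flipped`); if they only match after A<->T /
#' C<->G complementation, the complement is taken first (reported strand
#' differs, effect unchanged); otherwise the pair is `dropped_mismatch`.
#' Palindromic variants (A/T or C/G) cannot be resolved by allele labels:
#' they are kept only when both allele frequencies lie on the same side of
#' 0.5 and both minor-allele frequencies are below `palindromic_eaf_limit`;
#' otherwise `dropped_palindromic`. Dropped pairs carry `NA` outcome betas so
#' they can never reach an estimator.
#'
#' @param exposure,outcome One-row GWAS data.frames (same `variant_id`).
#' @param palindromic_eaf_limit Maximum minor-allele frequency at which
#'   strand inference from frequency is trusted (default 0.42).
#' @return One-row data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta_exposure`, `se_exposure`, `eaf_exposure`,
#'   `beta_outcome`, `se_outcome`, `eaf_outcome`, `status`.
#' @export
harmonize_pair <- function(exposure, outcome, palindromic_eaf_limit = 0.42) {
  if (exposure$variant_id != outcome$variant_id)
    stop("harmonize_pair called on different variants: ",
         exposure$variant_id, " vs ", outcome$variant_id)
  ea <- exposure$effect_allele; oa <- exposure$other_allele
  ea_o <- outcome$effect_allele; oa_o <- outcome$other_allele
  b_o <- outcome$beta; eaf_o <- outcome$eaf

  done <- function(status, b = NA_real_, eaf = NA_real_) {
    drop <- startsWith(status, "dropped")
    data.frame(variant_id = exposure$variant_id,
               effect_allele = ea, other_allele = oa,
               beta_exposure = if (drop) NA_real_ else exposure$beta,
               se_exposure = if (drop) NA_real_ else exposure$se,
               eaf_exposure = if (drop) NA_real_ else exposure$eaf,
               beta_outcome = if (drop) NA_real_ else b,
               se_outcome = if (drop) NA_real_ else outcome$se,
               eaf_outcome = if (drop) NA_real_ else eaf,
               status = status, stringsAsFactors = FALSE)
  }

  if (.is_palindromic(ea, oa)) {
    # outcome must carry the same base pair; complementing a palindromic
    # pair is indistinguishable from swapping, so orient by labels, then
    # require frequency agreement
    if (!setequal(c(ea_o, oa_o), c(ea, oa))) return(done("dropped_mismatch"))
    if (ea_o == ea) { status <- "kept" } else {
      status <- "flipped"; b_o <- -b_o
      eaf_o <- if (is.na(eaf_o)) NA_real_ else 1 - eaf_o
    }
    eaf_e <- exposure$eaf
    if (is.na(eaf_e) || is.na(eaf_o)) return(done("dropped_palindromic"))
    same_side <- (eaf_e - 0.5) * (eaf_o - 0.5) > 0
    inferable <- min(eaf_e, 1 - eaf_e) < palindromic_eaf_limit &&
      min(eaf_o, 1 - eaf_o) < palindromic_eaf_limit
    if (!(same_side && inferable)) return(done("dropped_palindromic"))
    return(done(status, b_o, eaf_o))
  }

  if (ea_o == ea && oa_o == oa) return(done("kept", b_o, eaf_o))
  if (ea_o == oa && oa_o == ea)
    return(done("flipped", -b_o, if (is.na(eaf_o)) NA_real_ else 1 - eaf_o))
  ea_c <- .complement(ea_o); oa_c <- .complement(oa_o)
  if (ea_c == ea && oa_c == oa) return(done("kept", b_o, eaf_o))
  if (ea_c == oa && oa_c == ea)
    return(done("flipped", -b_o, if (is.na(eaf_o)) NA_real_ else 1 - eaf_o))
  done("dropped_mismatch")
}

#' Harmonize two summary-statistics tables
#'
#' Joins on `variant_id` (string equality; variants absent from either table
#' are omitted) and applies [harmonize_pair()] row-wise.
#'
#' @param exposure,outcome GWAS data.frames.
#' @inheritParams harmonize_pair
#' @return Data.frame of harmonized pairs, one row per shared variant, in
#'   exposure order, including dropped rows (with `NA` betas).
#' @export
harmonize_tables <- function(exposure, outcome, palindromic_eaf_limit = 0.42) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  exposure <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  outcome <- outcome[match(shared, outcome$variant_id), , drop = FALSE]
  if (length(shared) == 0)
    return(data.frame(variant_id = character(0), effect_allele = character(0),
                      other_allele = character(0), beta_exposure = numeric(0),
                      se_exposure = numeric(0), eaf_exposure = numeric(0),
                      beta_outcome = numeric(0), se_outcome = numeric(0),
                      eaf_outcome = numeric(0), status = character(0)))
  rows <- lapply(seq_along(shared), function(i)
    harmonize_pair(exposure[i, ], outcome[i, ], palindromic_eaf_limit))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Retain only the harmonized pairs usable by estimators
#' @param pairs Output of [harmonize_tables()].
#' @return The `kept`/`flipped` rows.
#' @export
harmonized_kept <- function(pairs) {
  pairs[pairs$status %in% c("kept", "flipped"), , drop = FALSE]
}
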