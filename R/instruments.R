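#' @title Drug-target instrument construction
#' @name instruments
#' @description Builds cis instrument sets for a drug-target gene: restrict to
#'   a window around the gene, keep genome-wide-significant variants, thin by
#'   greedy LD clumping, and drop weak instruments by F-statistic.
NULL

#' Restrict variants to the cis window of a gene and a significance threshold
#'
#' Keeps variants on the region's chromosome with position inside
#' `[start - window_bp, end + window_bp]` (left edge clamped at 1) and
#' `pvalue < p_threshold` (strict). Input order is preserved.
#'
#' @param records GWAS summary-statistics data.frame (see [read_gwas()]).
#' @param region One-row data.frame or list with `gene`, `chromosome`,
#'   `start`, `end` (1-based inclusive).
#' @param window_bp Flank size in base pairs (default 100 kb).
#' @param p_threshold Significance threshold, strict inequality
#'   (default 5e-8).
#' @return The retained rows of `records`.
#' @export
select_cis_variants <- function(records, region, window_bp = 1e5,
                                p_threshold = 5e-8) {
  stopifnot(window_bp >= 0, p_threshold > 0)
  lo <- max(1, region$start - window_bp)
  hi <- region$end + window_bp
  keep <- records$chromosome == as.character(region$chromosome) &
    records$position >= lo & records$position <= hi &
    records$pvalue < p_threshold
  records[keep, , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Standard greedy thinning: order variants by p-value (ties broken by
#' variant id, lexicographically), repeatedly retain the most significant
#' remaining variant and discard every remaining variant with
#' `r^2 >= r2_threshold` to it that lies within `window_kb` kilobases of it.
#'
#' @param records GWAS data.frame; every `variant_id` must index `ld`.
#' @param ld Square r-squared matrix with variant-id dimnames.
#' @param r2_threshold Clumping threshold in (0, 1].
#' @param window_kb Maximum distance (kb) between an index variant and a
#'   variant it can discard (default 10,000 kb).
#' @return Retained rows of `records`, sorted by position.
#' @export
clump <- function(records, ld, r2_threshold, window_kb = 10000) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  if (nrow(records) == 0) return(records)
  absent <- setdiff(records$variant_id, rownames(ld))
  if (length(absent))
    stop("variant(s) absent from LD matrix: ", paste(absent, collapse = ", "))
  ord <- order(records$pvalue, records$variant_id)
  queue <- records[ord, , drop = FALSE]
  kept <- character(0)
  while (nrow(queue) > 0) {
    idx <- queue[1, ]
    kept <- c(kept, idx$variant_id)
    if (nrow(queue) == 1) break
    rest <- queue[-1, , drop = FALSE]
    r2 <- ld[idx$variant_id, rest$variant_id]
    near <- abs(rest$position - idx$position) <= window_kb * 1000
    queue <- rest[!(r2 >= r2_threshold & near), , drop = FALSE]
  }
  out <- records[records$variant_id %in% kept, , drop = FALSE]
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-variant instrument-strength F-statistic
#'
#' The single-variant approximation `F = (beta / se)^2`; values above 10 are
#' conventionally taken to indicate a non-weak instrument.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), all > 0.
#' @return Numeric vector of F values.
#' @export
f_statistic <- function(beta, se) {
  stopifnot(all(se > 0))
  (beta / se)^2
}

#' Build a drug-target instrument set
#'
#' Composition of the selection stages: cis-window + significance filter,
#' greedy LD clumping, then removal of variants with `F <= f_cutoff`. A
#' per-stage count log is attached so instrument attrition is auditable.
#'
#' @inheritParams select_cis_variants
#' @inheritParams clump
#' @param trait Name of the exposure trait the betas refer to.
#' @param f_cutoff Weak-instrument cutoff; variants with `(beta/se)^2 <=
#'   f_cutoff` are dropped. Set to `NULL` to skip the filter.
#' @param clump_window_kb Clumping distance cap in kb.
#' @return An object of class `instrument_set`: a list with `label`
#'   (`"<gene>|<trait>"`), `region`, `trait`, `records`, `r2_threshold`,
#'   `f_stats`, and `stage_log` (counts after each stage).
#' @export
build_instrument_set <- function(records, region, trait, ld,
                                 window_bp = 1e5, p_threshold = 5e-8,
                                 r2_threshold = 0.30, f_cutoff = 10,
                                 clump_window_kb = 10000) {
  cis <- select_cis_variants(records, region, window_bp, p_threshold)
  clumped <- clump(cis, ld, r2_threshold, clump_window_kb)
  f <- if (nrow(clumped)) f_statistic(clumped$beta, clumped$se) else numeric(0)
  if (!is.null(f_cutoff)) {
    keep <- f > f_cutoff
    final <- clumped[keep, , drop = FALSE]
    f <- f[keep]
  } else {
    final <- clumped
  }
  rownames(final) <- NULL
  set <- structure(list(
    label = paste(region$gene, trait, sep = "|"),
    region = region, trait = trait,
    records = final, r2_threshold = r2_threshold,
    f_stats = stats::setNames(f, final$variant_id),
    stage_log = c(input = nrow(records), cis_significant = nrow(cis),
                  clumped = nrow(clumped), strong = nrow(final))
  ), class = "instrument_set")
  if (nrow(final) == 0)
    warning("instrument set ", set$label, " is empty after filtering")
  set
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set", x$label, "\n")
  cat("  stages:",
      paste(names(x$stage_log), x$stage_log, sep = "=", collapse = " -> "),
      "\n")
  if (length(x$f_stats))
    cat("  mean F:", format(mean(x$f_stats), digits = 4), "\n")
  invisible(x)
}
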