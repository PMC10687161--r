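#' @title GWAS summary-statistic input/output
#' @name gwas_io
#' @description Readers and writers for the tab-delimited tables the pipeline
#'   consumes: per-variant association summaries, gene regions (1-based
#'   inclusive coordinates) and square LD (r-squared) matrices.
NULL

## canonical column order for a summary-statistics table
.gwas_cols <- c("variant_id", "chromosome", "position", "effect_allele",
                "other_allele", "eaf", "beta", "se", "pvalue", "n")

.num_or_fail <- function(x, col, optional = FALSE) {
  # "NA" is the only permitted missing token, and only for optional columns
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !(optional & x == "NA")
  list(value = out, bad = which(bad))
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited file with one row per variant and validates every
#' row: alleles must be single bases A/C/G/T and differ, `se > 0`,
#' `pvalue` in (0, 1], `position >= 1`, and `eaf` in \[0, 1\] when present.
#' `eaf` and `n` may be the literal string `NA`; any other non-numeric token
#' in a numeric column is an error (no silent coercion).
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param column_map Optional named character vector mapping canonical names
#'   (`variant_id`, `chromosome`, `position`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pvalue`, `n`) to the column names used in the file.
#' @param on_invalid `"error"` (default) stops with a message listing the
#'   offending data rows; `"drop"` removes them and attaches the itemized
#'   rejections as attribute `"rejections"` (a data.frame with `row` and
#'   `reason`).
#' @return A data.frame with the canonical columns, rows in file order.
#' @export
read_gwas <- function(path, column_map = NULL, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  map <- stats::setNames(.gwas_cols, .gwas_cols)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), .gwas_cols)
    if (length(unknown))
      stop("column_map refers to unknown canonical column(s): ",
           paste(unknown, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  missing <- map[!map %in% names(raw)]
  if (length(missing))
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  dat <- raw[, map, drop = FALSE]
  names(dat) <- .gwas_cols
  n_rows <- nrow(dat)

  reasons <- character(0); rows <- integer(0)
  note <- function(idx, why) {
    rows <<- c(rows, idx); reasons <<- c(reasons, rep(why, length(idx)))
  }
  for (col in c("position", "beta", "se", "pvalue")) {
    parsed <- .num_or_fail(dat[[col]], col)
    if (length(parsed$bad)) note(parsed$bad, paste0("non-numeric ", col))
    dat[[col]] <- parsed$value
  }
  for (col in c("eaf", "n")) {
    parsed <- .num_or_fail(dat[[col]], col, optional = TRUE)
    if (length(parsed$bad)) note(parsed$bad, paste0("invalid token in ", col))
    dat[[col]] <- parsed$value
  }
  bases <- c("A", "C", "G", "T")
  note(which(!dat$effect_allele %in% bases), "non-ACGT effect_allele")
  note(which(!dat$other_allele %in% bases), "non-ACGT other_allele")
  note(which(dat$effect_allele == dat$other_allele), "identical alleles")
  note(which(!is.na(dat$se) & dat$se <= 0), "se <= 0")
  note(which(!is.na(dat$pvalue) & (dat$pvalue <= 0 | dat$pvalue > 1)),
       "pvalue outside (0, 1]")
  note(which(!is.na(dat$position) & dat$position < 1), "position < 1")
  note(which(!is.na(dat$eaf) & (dat$eaf < 0 | dat$eaf > 1)),
       "eaf outside [0, 1]")

  if (length(rows)) {
    rej <- data.frame(row = rows, reason = reasons)
    rej <- rej[order(rej$row), , drop = FALSE]
    rej <- rej[!duplicated(rej$row), , drop = FALSE]
    rownames(rej) <- NULL
    if (on_invalid == "error")
      stop("invalid row(s) in ", path, ": ",
           paste(sprintf("row %d (%s)", rej$row, rej$reason), collapse = "; "))
    dat <- dat[-rej$row, , drop = FALSE]
    rownames(dat) <- NULL
    attr(dat, "rejections") <- rej
  }
  stopifnot(nrow(dat) + length(unique(rows)) == n_rows)
  dat
}

#' Write a GWAS summary-statistics table
#'
#' Inverse of [read_gwas()]: tab-delimited, canonical header, numeric fields
#' serialized with 6 significant digits, missing `eaf`/`n` written as `NA`.
#'
#' @param gwas Data.frame with the canonical columns.
#' @param path Output path.
#' @export
write_gwas <- function(gwas, path) {
  stopifnot(all(.gwas_cols %in% names(gwas)))
  out <- gwas[, .gwas_cols, drop = FALSE]
  for (col in c("position", "eaf", "beta", "se", "pvalue", "n"))
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         formatC(signif(out[[col]], 6), format = "g",
                                 digits = 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-region table
#'
#' Tab-delimited `gene chromosome start end`, coordinates 1-based inclusive.
#'
#' @param path Path to the table.
#' @return Data.frame with columns `gene`, `chromosome`, `start`, `end`.
#' @export
read_regions <- function(path) {
  dat <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "numeric"))
  need <- c("gene", "chromosome", "start", "end")
  if (!all(need %in% names(dat)))
    stop("region table must have columns: ", paste(need, collapse = ", "))
  bad <- which(dat$start > dat$end | dat$start < 1)
  if (length(bad))
    stop("invalid region row(s): ", paste(bad, collapse = ", "))
  dat[, need]
}

#' Read a pairwise LD (r-squared) matrix
#'
#' Square tab-delimited table whose first column and header are variant ids.
#' The matrix must be symmetric (tolerance 1e-8), have unit diagonal
#' (tolerance 1e-8) and entries in \[0, 1\].
#'
#' @param path Path to the table.
#' @return A numeric matrix with variant ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  dat <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(dat)
  if (nrow(m) != ncol(m))
    stop("LD matrix is not square: ", nrow(m), " x ", ncol(m))
  if (!identical(rownames(m), colnames(m)))
    stop("LD matrix row ids do not match column ids")
  validate_ld_matrix(m)
}

#' Validate an LD matrix held in memory
#'
#' @param m Numeric square matrix of r-squared values with variant-id dimnames.
#' @param tol Symmetry/diagonal tolerance.
#' @return `m`, invisibly unchanged, after validation.
#' @export
validate_ld_matrix <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || !is.numeric(m)) stop("LD matrix must be numeric")
  if (nrow(m) != ncol(m)) stop("LD matrix is not square")
  if (any(abs(m - t(m)) > tol))
    stop("LD matrix is asymmetric beyond tolerance ", tol)
  if (any(abs(diag(m) - 1) > tol))
    stop("LD matrix diagonal differs from 1 beyond tolerance ", tol)
  if (any(m < -tol | m > 1 + tol))
    stop("LD matrix entries must lie in [0, 1]")
  m
}

#' Write an LD matrix
#' @param m LD matrix with variant-id dimnames.
#' @param path Output path.
#' @export
write_ld_matrix <- function(m, path) {
  out <- data.frame(variant_id = rownames(m),
                    formatC(m, format = "g", digits = 10),
                    check.names = FALSE)
  names(out) <- c("variant_id", colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## fixed column layout of the results table
.result_cols <- c("exposure", "outcome", "method", "n_snps", "beta", "se",
                  "or_", "ci_low", "ci_high", "pvalue", "fdr_pvalue",
                  "q_stat", "q_pvalue", "egger_intercept",
                  "egger_intercept_pvalue", "reliable")

#' Write an MR results table
#'
#' One row per (exposure, outcome, method), fixed column set, floats with 6
#' significant digits, rows ordered lexicographically by exposure, outcome,
#' method so output is deterministic.
#'
#' @param results Data.frame of MR results (missing columns are filled with NA).
#' @param path Output path.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    writeLines(paste(.result_cols, collapse = "\t"), path)
    return(invisible(path))
  }
  for (col in .result_cols)
    if (!col %in% names(results)) results[[col]] <- NA
  out <- results[order(results$exposure, results$outcome, results$method),
                 .result_cols, drop = FALSE]
  numcols <- setdiff(.result_cols,
                     c("exposure", "outcome", "method", "n_snps", "reliable"))
  for (col in numcols)
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         formatC(signif(as.numeric(out[[col]]), 6),
                                 format = "g", digits = 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an MR results table written by [write_results_table()]
#' @param path Path to the table.
#' @return Data.frame with the fixed result columns.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
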