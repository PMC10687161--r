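region <- list(gene = "GENE1", chromosome = "1", start = 1e6, end = 1.05e6)

test_that("cis-window selection applies boundary arithmetic and a strict p threshold", {
  recs <- gwas_table(
    gwas_row("rs_in_flank", position = 950000, pvalue = 1e-9),
    gwas_row("rs_outside", position = 1160000, pvalue = 1e-20),
    gwas_row("rs_at_threshold", position = 1020000, pvalue = 5.0e-8),
    gwas_row("rs_wrong_chr", chromosome = "2", position = 1020000, pvalue = 1e-9))
  got <- select_cis_variants(recs, region, window_bp = 1e5, p_threshold = 5e-8)
  expect_equal(got$variant_id, "rs_in_flank")
})

test_that("window 0 reduces to a gene-body filter and clamping holds at position 1", {
  recs <- gwas_table(gwas_row("rs_body", position = 1.02e6),
                     gwas_row("rs_flank", position = 999999))
  expect_equal(select_cis_variants(recs, region, 0, 5e-8)$variant_id, "rs_body")
  near_start <- list(gene = "G", chromosome = "1", start = 10, end = 20)
  expect_equal(select_cis_variants(gwas_row("rs1", position = 1),
                                   near_start, 100, 5e-8)$variant_id, "rs1")
})

abc_ld <- function() {
  m <- matrix(c(1, 0.5, 0.1, 0.5, 1, 0.2, 0.1, 0.2, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m
}
abc_records <- function() gwas_table(
  gwas_row("A", position = 1000, pvalue = 1e-10),
  gwas_row("B", position = 2000, pvalue = 1e-9),
  gwas_row("C", position = 3000, pvalue = 1e-8))

test_that("greedy clumping keeps the most significant variant of each LD cluster", {
  got <- clump(abc_records(), abc_ld(), r2_threshold = 0.30)
  expect_equal(got$variant_id, c("A", "C"))
  expect_equal(sort(got$variant_id), oracle_clump(abc_records(), abc_ld(), 0.30))
  got001 <- clump(abc_records(), abc_ld(), r2_threshold = 0.001)
  expect_equal(got001$variant_id, "A")
  expect_equal(sort(got001$variant_id),
               oracle_clump(abc_records(), abc_ld(), 0.001))
})

test_that("clumping retains everything when LD is absent or the threshold is 1", {
  m <- abc_ld(); m[upper.tri(m)] <- 0; m[lower.tri(m)] <- 0
  expect_equal(nrow(clump(abc_records(), m, 0.30)), 3)
  expect_equal(nrow(clump(abc_records(), abc_ld(), 1.0)), 3)
})

test_that("clumping matches the brute-force oracle on random instances and is idempotent and order-invariant", {
  set.seed(42)
  for (rep in 1:40) {
    k <- sample(3:12, 1)
    ids <- sprintf("v%02d", 1:k)
    r <- stats::cov2cor(crossprod(matrix(rnorm(k * k), k)))
    ld <- r^2; dimnames(ld) <- list(ids, ids)
    recs <- do.call(rbind, lapply(1:k, function(i)
      gwas_row(ids[i], position = i * 1000,
               pvalue = sample(c(1e-10, 1e-9, 1e-8), 1))))  # deliberate ties
    thr <- runif(1, 0.05, 0.9)
    got <- clump(recs, ld, thr)
    expect_equal(sort(got$variant_id), oracle_clump(recs, ld, thr))
    # idempotence
    again <- clump(got, ld, thr)
    expect_equal(again$variant_id, got$variant_id)
    # input-order invariance (ties broken lexicographically)
    shuffled <- recs[sample.int(k), ]
    expect_equal(clump(shuffled, ld, thr)$variant_id, got$variant_id)
  }
})

test_that("the clumping window caps which variants an index can discard", {
  recs <- gwas_table(gwas_row("A", position = 1e6, pvalue = 1e-10),
                     gwas_row("B", position = 1e6 + 2e7, pvalue = 1e-9))
  ld <- matrix(c(1, 0.9, 0.9, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  # high r2 but 20 Mb apart: outside the 10,000-kb window, both kept
  expect_equal(nrow(clump(recs, ld, 0.3, window_kb = 10000)), 2)
  expect_equal(nrow(clump(recs, ld, 0.3, window_kb = 30000)), 1)
})

test_that("clumping refuses variants missing from the LD matrix, naming them", {
  ld <- abc_ld()[1:2, 1:2]
  expect_error(clump(abc_records(), ld, 0.3), "C")
})

test_that("F-statistic is (beta/se)^2 and flags weakness at the cutoff", {
  expect_equal(f_statistic(0.1, 0.01), 100)
  expect_equal(f_statistic(0, 5), 0)
  f <- f_statistic(0.0316, 0.01)
  expect_equal(f, 9.98560, tolerance = 1e-5)
  expect_true(f < 10)
})

test_that("build_instrument_set composes the stages and honours all invariants", {
  set.seed(202)
  cfg <- simulation_config(n_snps = 50, n_causal_snps = 25, ld_rho = 0.9,
                           gamma_sd = 0.12, seed = 303)
  reg <- simulate_region(cfg)
  region50 <- list(gene = "G", chromosome = cfg$chromosome,
                   start = min(reg$exposure$position),
                   end = max(reg$exposure$position))
  set <- build_instrument_set(reg$exposure, region50, "lipid", reg$ld,
                              r2_threshold = 0.30)
  expect_s3_class(set, "instrument_set")
  expect_gt(nrow(set$records), 1)
  # no retained pair at or above the clumping threshold, checked exhaustively
  sub <- reg$ld[set$records$variant_id, set$records$variant_id]
  expect_true(all(sub[upper.tri(sub)] < 0.30))
  # every record inside the window, significant, and strong
  expect_true(all(set$records$pvalue < 5e-8))
  expect_true(all(set$f_stats > 10))
  expect_equal(unname(set$stage_log["input"]), 50)
})

test_that("a set where every variant is weak comes back empty with a stage log", {
  recs <- gwas_table(gwas_row("A", beta = 0.02, se = 0.01, position = 1.01e6),
                     gwas_row("B", beta = -0.01, se = 0.01, position = 1.02e6))
  ld <- diag(2); dimnames(ld) <- list(c("A", "B"), c("A", "B"))
  expect_warning(
    set <- build_instrument_set(recs, region, "lipid", ld),
    "empty")
  expect_equal(nrow(set$records), 0)
  expect_equal(unname(set$stage_log[c("clumped", "strong")]), c(2L, 0L))
})

test_that("inputs engineered so one variant survives give a singleton set", {
  recs <- gwas_table(gwas_row("A", beta = 0.1, se = 0.01, position = 1.01e6),
                     gwas_row("B", beta = 0.1, se = 0.01, position = 1.02e6,
                              pvalue = 1e-7))  # fails 5e-8
  ld <- diag(2); dimnames(ld) <- list(c("A", "B"), c("A", "B"))
  set <- build_instrument_set(recs, region, "lipid", ld)
  expect_equal(set$records$variant_id, "A")
})
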