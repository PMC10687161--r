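exp_rec <- gwas_row("rs1", ea = "A", oa = "G", beta = 0.1, eaf = 0.3)

test_that("matching alleles are kept unchanged", {
  out <- gwas_row("rs1", ea = "A", oa = "G", beta = 0.05, eaf = 0.3)
  h <- harmonize_pair(exp_rec, out)
  expect_equal(h$status, "kept")
  expect_equal(h$beta_outcome, 0.05)
})

test_that("swapped alleles flip the outcome beta and eaf", {
  out <- gwas_row("rs1", ea = "G", oa = "A", beta = 0.05, eaf = 0.3)
  h <- harmonize_pair(exp_rec, out)
  expect_equal(h$status, "flipped")
  expect_equal(h$beta_outcome, -0.05)
  expect_equal(h$eaf_outcome, 0.7)
})

test_that("strand complements are resolved before declaring mismatch", {
  kept <- harmonize_pair(exp_rec, gwas_row("rs1", ea = "T", oa = "C",
                                           beta = 0.05, eaf = 0.3))
  expect_equal(kept$status, "kept")
  expect_equal(kept$beta_outcome, 0.05)
  flip <- harmonize_pair(exp_rec, gwas_row("rs1", ea = "C", oa = "T",
                                           beta = 0.05, eaf = 0.3))
  expect_equal(flip$status, "flipped")
  expect_equal(flip$beta_outcome, -0.05)
  mism <- harmonize_pair(exp_rec, gwas_row("rs1", ea = "A", oa = "C"))
  expect_equal(mism$status, "dropped_mismatch")
})

test_that("palindromic variants follow the frequency-inference rule", {
  pal_exp <- function(eaf) gwas_row("rs1", ea = "A", oa = "T", beta = 0.1, eaf = eaf)
  pal_out <- function(eaf, ea = "A", oa = "T")
    gwas_row("rs1", ea = ea, oa = oa, beta = 0.05, eaf = eaf)

  # eaf 0.5 on both sides: strand undecidable
  expect_equal(harmonize_pair(pal_exp(0.5), pal_out(0.5))$status,
               "dropped_palindromic")
  # clearly minor on both sides: kept
  h <- harmonize_pair(pal_exp(0.2), pal_out(0.25))
  expect_equal(h$status, "kept")
  expect_equal(h$beta_outcome, 0.05)
  # opposite sides of 0.5: dropped rather than guessed
  expect_equal(harmonize_pair(pal_exp(0.2), pal_out(0.8))$status,
               "dropped_palindromic")
  # near-0.5 frequencies exceed the inference limit
  expect_equal(harmonize_pair(pal_exp(0.45), pal_out(0.45))$status,
               "dropped_palindromic")
  expect_equal(harmonize_pair(pal_exp(0.45), pal_out(0.45),
                              palindromic_eaf_limit = 0.49)$status, "kept")
  # missing frequency: undecidable
  expect_equal(harmonize_pair(pal_exp(NA), pal_out(0.2))$status,
               "dropped_palindromic")
  # swapped palindromic labels with mirrored frequency: flipped and kept
  h2 <- harmonize_pair(pal_exp(0.2), pal_out(0.8, ea = "T", oa = "A"))
  expect_equal(h2$status, "flipped")
  expect_equal(h2$beta_outcome, -0.05)
  expect_equal(h2$eaf_outcome, 0.2)
})

test_that("harmonizing a doubly-swapped outcome is an involution", {
  out <- gwas_row("rs1", ea = "C", oa = "G", beta = 0.05, eaf = 0.25)
  exp2 <- gwas_row("rs1", ea = "C", oa = "G", beta = 0.1, eaf = 0.25)
  swap_once <- function(r) {
    s <- r
    s$effect_allele <- r$other_allele; s$other_allele <- r$effect_allele
    s$beta <- -r$beta; s$eaf <- 1 - r$eaf
    s
  }
  twice <- swap_once(swap_once(out))
  expect_equal(harmonize_pair(exp2, twice)[, c("beta_outcome", "eaf_outcome")],
               harmonize_pair(exp2, out)[, c("beta_outcome", "eaf_outcome")])
})

test_that("the Wald ratio is invariant to which allele is the effect allele", {
  out <- gwas_row("rs1", ea = "A", oa = "G", beta = 0.05, se = 0.02, eaf = 0.3)
  h1 <- harmonize_pair(exp_rec, out)
  recoded <- gwas_row("rs1", ea = "G", oa = "A", beta = -0.1, se = 0.01,
                      eaf = 0.7)
  h2 <- harmonize_pair(recoded, out)
  w1 <- mr_wald_ratio(h1); w2 <- mr_wald_ratio(h2)
  expect_equal(w1$beta, w2$beta)
  expect_equal(w1$se, w2$se)
})

test_that("mismatched variant ids are a usage error", {
  expect_error(harmonize_pair(exp_rec, gwas_row("rs2", ea = "A", oa = "G")),
               "different variants")
})

test_that("dropped pairs carry no betas and never reach an estimator", {
  exposure <- gwas_table(
    gwas_row("rs1", ea = "A", oa = "G", beta = 0.2, eaf = 0.3),
    gwas_row("rs2", ea = "A", oa = "T", beta = 0.3, eaf = 0.5),
    gwas_row("rs3", ea = "A", oa = "G", beta = 0.4, eaf = 0.3))
  outcome <- gwas_table(
    gwas_row("rs1", ea = "A", oa = "G", beta = 0.1, eaf = 0.3),
    gwas_row("rs2", ea = "A", oa = "T", beta = 0.15, eaf = 0.5),
    gwas_row("rs3", ea = "A", oa = "C", beta = 0.2, eaf = 0.3))
  h <- harmonize_tables(exposure, outcome)
  expect_equal(h$status, c("kept", "dropped_palindromic", "dropped_mismatch"))
  expect_true(all(is.na(h$beta_outcome[h$status != "kept"])))
  expect_equal(nrow(harmonized_kept(h)), 1)
  expect_equal(mr_all_methods(h)$method, "wald_ratio")
})
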