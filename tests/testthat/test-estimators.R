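test_that("Wald ratio matches its closed form", {
  cases <- list(list(bx = 1, by = 0.5, sy = 0.1, beta = 0.5, se = 0.1),
                list(bx = -1, by = 0.5, sy = 0.1, beta = -0.5, se = 0.1),
                list(bx = 0.2, by = 0.1, sy = 0.05, beta = 0.5, se = 0.25))
  for (cs in cases) {
    w <- mr_wald_ratio(make_pairs(cs$bx, cs$by, cs$sy))
    expect_equal(w$beta, cs$beta)
    expect_equal(w$se, cs$se)
    expect_equal(w$pvalue, 2 * pnorm(-abs(cs$beta / cs$se)))
  }
  expect_error(mr_wald_ratio(make_pairs(0, 0.1, 0.05)), "degenerate")
})

ivw_example <- make_pairs(c(0.2, 0.4, 0.3), c(0.1, 0.18, 0.16), rep(0.05, 3))

test_that("IVW reproduces the worked weighted-regression example", {
  r <- mr_ivw(ivw_example)
  expect_equal(r$beta, 56 / 116, tolerance = 1e-12)
  expect_equal(r$n_snps, 3L)
  expect_true(r$ci_low < r$or_ && r$or_ < r$ci_high)
})

test_that("IVW equals a brute-force weighted-least-squares oracle to 1e-10", {
  set.seed(7)
  for (rep in 1:60) {
    k <- sample(2:15, 1)
    pairs <- make_pairs(runif(k, 0.05, 0.5) * sample(c(-1, 1), k, TRUE),
                        rnorm(k, 0, 0.1), runif(k, 0.01, 0.2))
    fit <- lm(beta_outcome ~ 0 + beta_exposure, data = pairs,
              weights = 1 / pairs$se_outcome^2)
    r <- mr_ivw(pairs)
    expect_equal(r$beta, unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("a single instrument duplicated k times collapses every estimator to its Wald ratio", {
  k <- 5
  pairs <- make_pairs(rep(0.25, k), rep(0.1, k), rep(0.04, k),
                      sx = rep(0.01, k))
  wald <- 0.1 / 0.25
  expect_equal(mr_ivw(pairs)$beta, wald, tolerance = 1e-12)
  expect_equal(mr_weighted_median(pairs, n_boot = 50, seed = 1)$beta, wald)
  expect_equal(mr_mode(pairs, weighted = FALSE, n_boot = 50, seed = 1)$beta, wald)
  expect_equal(mr_mode(pairs, weighted = TRUE, n_boot = 50, seed = 1)$beta, wald)
})

test_that("all-null outcome betas give a zero IVW estimate", {
  pairs <- make_pairs(c(0.2, 0.3, 0.4), c(0, 0, 0), rep(0.05, 3))
  expect_equal(mr_ivw(pairs)$beta, 0)
})

test_that("estimates are invariant to jointly negating every beta pair", {
  set.seed(21)
  pairs <- make_pairs(runif(8, 0.05, 0.4), rnorm(8, 0.1, 0.05),
                      runif(8, 0.02, 0.1), sx = runif(8, 0.005, 0.02))
  neg <- pairs
  neg$beta_exposure <- -neg$beta_exposure
  neg$beta_outcome <- -neg$beta_outcome
  for (fun in list(
    mr_ivw,
    mr_egger,
    function(p) mr_weighted_median(p, n_boot = 50, seed = 3),
    function(p) mr_mode(p, weighted = FALSE, n_boot = 50, seed = 3),
    function(p) mr_mode(p, weighted = TRUE, n_boot = 50, seed = 3))) {
    expect_equal(fun(neg)$beta, fun(pairs)$beta, tolerance = 1e-12)
  }
})

test_that("MR-Egger recovers exact linear and affine relationships", {
  bx <- c(0.1, 0.2, 0.35, 0.5)
  line <- make_pairs(bx, 0.5 * bx, rep(0.03, 4))
  r <- mr_egger(line)
  expect_equal(r$beta, 0.5, tolerance = 1e-10)
  expect_equal(r$egger_intercept, 0, tolerance = 1e-10)

  affine <- make_pairs(bx, 0.02 + 0.5 * bx, rep(1e-4, 4))
  r2 <- mr_egger(affine)
  expect_equal(r2$beta, 0.5, tolerance = 1e-8)
  expect_equal(r2$egger_intercept, 0.02, tolerance = 1e-8)
  expect_lt(r2$egger_intercept_pvalue, 1e-3)  # t on n-2 = 2 df limits the tail
})

test_that("MR-Egger needs 3+ instruments and non-collinear exposure betas", {
  expect_error(mr_egger(make_pairs(c(0.1, 0.2), c(0.05, 0.1), c(0.02, 0.02))),
               "at least 3")
  same <- make_pairs(rep(0.2, 4), rnorm(4, 0.1, 0.01), rep(0.02, 4))
  expect_error(mr_egger(same), "collinear")
})

test_that("MR-Egger intercept estimates directional pleiotropy in simulation", {
  cfg <- simulation_config(n_snps = 20, n_causal_snps = 20, ld_rho = 0,
                           gamma_sd = 0.15, pleiotropy_mean = 0.03,
                           pleiotropy_sd = 0.005, seed = 99)
  reg <- simulate_region(cfg)
  r <- mr_egger(harmonize_tables(reg$exposure, reg$outcome))
  expect_lt(abs(r$egger_intercept - 0.03), 2 * r$egger_intercept_se)
})

test_that("weighted median interpolates the cumulative-weight midpoints", {
  # ratios 0.45 (w 64), 0.5 (w 16), 0.5333 (w 36): hand-interpolated 0.4825
  pairs <- make_pairs(c(0.4, 0.2, 0.3), c(0.45 * 0.4, 0.5 * 0.2, 0.16),
                      rep(0.05, 3))
  re <- ratio_estimates(pairs)
  est <- mr_weighted_median(pairs, n_boot = 50, seed = 5)$beta
  expect_equal(est, oracle_weighted_median(re$ratio, re$weight),
               tolerance = 1e-10)
  expect_equal(est, 0.4825, tolerance = 1e-3)

  # equal weights, ratios {0.1, 0.2, 0.9}: lands exactly on the middle ratio
  eq <- make_pairs(c(1, 1, 1), c(0.1, 0.2, 0.9), rep(1, 3))
  expect_equal(mr_weighted_median(eq, n_boot = 50, seed = 5)$beta, 0.2)
})

test_that("weighted median matches the interpolation oracle on random instances", {
  set.seed(13)
  for (rep in 1:50) {
    k <- sample(3:20, 1)
    pairs <- make_pairs(runif(k, 0.05, 0.5), rnorm(k, 0.05, 0.05),
                        runif(k, 0.01, 0.1))
    re <- ratio_estimates(pairs)
    expect_equal(mr_weighted_median(pairs, n_boot = 2, seed = 1)$beta,
                 oracle_weighted_median(re$ratio, re$weight),
                 tolerance = 1e-6)
  }
})

test_that("mode estimators ignore a minority outlier and respect weights", {
  pairs <- make_pairs(c(1, 1, 1, 1), c(0.5, 0.5, 0.5, 5.0), rep(0.1, 4),
                      sx = rep(0.01, 4))
  sm <- mr_mode(pairs, weighted = FALSE, n_boot = 50, seed = 2)
  expect_equal(sm$beta, 0.5, tolerance = 0.05)

  # one ratio carries ~99% of the weight
  wp <- make_pairs(c(1, 0.05, 0.05), c(0.3, 0.02, 0.04),
                   c(0.05, 0.05, 0.05), sx = rep(0.01, 3))
  re <- ratio_estimates(wp)
  expect_gt(re$weight[1] / sum(re$weight), 0.98)
  wm <- mr_mode(wp, weighted = TRUE, n_boot = 50, seed = 2)
  expect_equal(wm$beta, 0.3, tolerance = 0.15)

  # all ratios identical: the common ratio, with a finite bootstrap se
  same <- make_pairs(c(0.1, 0.2, 0.4), c(0.05, 0.1, 0.2), rep(0.05, 3),
                     sx = rep(0.01, 3))
  r <- mr_mode(same, n_boot = 50, seed = 2)
  expect_equal(r$beta, 0.5)
  expect_true(is.finite(r$se) && r$se > 0)
})

test_that("bootstrap standard errors are seed-reproducible and leave the RNG alone", {
  pairs <- make_pairs(c(0.2, 0.4, 0.3), c(0.1, 0.18, 0.16), rep(0.05, 3),
                      sx = rep(0.01, 3))
  set.seed(555); before <- runif(1)
  set.seed(555)
  a <- mr_weighted_median(pairs, n_boot = 200, seed = 77)
  after <- runif(1)
  b <- mr_weighted_median(pairs, n_boot = 200, seed = 77)
  expect_identical(a$se, b$se)
  expect_identical(before, after)  # estimator did not consume the global stream
})

test_that("method minima are enforced and single-instrument sets fall back to Wald", {
  expect_error(mr_ivw(make_pairs(0.2, 0.1, 0.05)), "at least 2")
  one <- make_pairs(0.2, 0.1, 0.05)
  expect_equal(mr_all_methods(one)$method, "wald_ratio")
  three <- make_pairs(c(0.2, 0.3, 0.4), c(0.1, 0.15, 0.2), rep(0.05, 3),
                      sx = rep(0.01, 3))
  res <- mr_all_methods(three, n_boot = 20, seed = 1)
  expect_setequal(res$method, c("ivw", "mr_egger", "weighted_median",
                                "simple_mode", "weighted_mode"))
})
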