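#' @title Two-sample MR estimators
#' @name estimators
#' @description The five summary-data causal estimators used throughout the
#'   pipeline — Wald ratio, inverse-variance weighted (IVW), MR-Egger,
#'   weighted median and the two mode-based estimators — written from their
#'   closed forms. Effects on binary outcomes are log odds ratios; each
#'   result carries the OR with a 95\% CI.
NULL

.z975 <- stats::qnorm(0.975)

.mr_result <- function(method, n_snps, beta, se, pvalue,
                       egger_intercept = NA_real_,
                       egger_intercept_se = NA_real_,
                       egger_intercept_pvalue = NA_real_,
                       exposure = "", outcome = "") {
  data.frame(exposure = exposure, outcome = outcome, method = method,
             n_snps = as.integer(n_snps), beta = beta, se = se,
             pvalue = pvalue, or_ = exp(beta),
             ci_low = exp(beta - .z975 * se),
             ci_high = exp(beta + .z975 * se),
             egger_intercept = egger_intercept,
             egger_intercept_se = egger_intercept_se,
             egger_intercept_pvalue = egger_intercept_pvalue,
             stringsAsFactors = FALSE)
}

.check_pairs <- function(pairs, minimum, method) {
  pairs <- harmonized_kept(pairs)
  if (nrow(pairs) < minimum)
    stop(method, " requires at least ", minimum, " harmonized variants, got ",
         nrow(pairs))
  if (any(pairs$beta_exposure == 0))
    stop(method, ": degenerate instrument with zero exposure beta")
  if (any(pairs$se_outcome <= 0)) stop(method, ": non-positive outcome se")
  pairs
}

#' Per-variant Wald ratio estimates and inverse-variance weights
#'
#' `ratio_j = betaY_j / betaX_j`, first-order delta-method
#' `se_j = seY_j / |betaX_j|`, and the IVW weight `w_j = betaX_j^2 / seY_j^2`
#' (the inverse of the first-order ratio variance).
#'
#' @param pairs Harmonized pairs (see [harmonize_tables()]).
#' @return Data.frame with `variant_id`, `ratio`, `ratio_se`, `weight`.
#' @export
ratio_estimates <- function(pairs) {
  pairs <- .check_pairs(pairs, 1, "ratio_estimates")
  data.frame(variant_id = pairs$variant_id,
             ratio = pairs$beta_outcome / pairs$beta_exposure,
             ratio_se = pairs$se_outcome / abs(pairs$beta_exposure),
             weight = pairs$beta_exposure^2 / pairs$se_outcome^2,
             stringsAsFactors = FALSE)
}

#' Wald ratio estimator (single instrument)
#'
#' @param pairs Harmonized pairs containing exactly one usable variant.
#' @param exposure,outcome Labels copied into the result.
#' @return One-row MR result data.frame.
#' @export
mr_wald_ratio <- function(pairs, exposure = "", outcome = "") {
  pairs <- .check_pairs(pairs, 1, "wald_ratio")
  if (nrow(pairs) != 1)
    stop("wald_ratio is a single-instrument method, got ", nrow(pairs))
  beta <- pairs$beta_outcome / pairs$beta_exposure
  se <- pairs$se_outcome / abs(pairs$beta_exposure)
  .mr_result("wald_ratio", 1, beta, se, 2 * stats::pnorm(-abs(beta / se)),
             exposure = exposure, outcome = outcome)
}

#' Inverse-variance-weighted estimator
#'
#' Weighted regression of outcome betas on exposure betas through the origin
#' with weights `1/seY^2`; equivalently the inverse-variance-weighted mean of
#' the per-variant Wald ratios. The standard error uses multiplicative
#' random effects: the fixed-effect se is scaled by
#' `max(1, sqrt(Q / (n - 1)))` where `Q` is Cochran's heterogeneity
#' statistic, so heterogeneity inflates but never deflates uncertainty.
#' P-values are two-sided normal.
#'
#' @inheritParams mr_wald_ratio
#' @return One-row MR result data.frame.
#' @export
mr_ivw <- function(pairs, exposure = "", outcome = "") {
  pairs <- .check_pairs(pairs, 2, "ivw")
  bx <- pairs$beta_exposure; by <- pairs$beta_outcome; sy <- pairs$se_outcome
  w <- 1 / sy^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  n <- length(bx)
  q <- sum((bx^2 / sy^2) * (by / bx - beta)^2)
  se <- se_fixed * max(1, sqrt(q / (n - 1)))
  .mr_result("ivw", n, beta, se, 2 * stats::pnorm(-abs(beta / se)),
             exposure = exposure, outcome = outcome)
}

## weighted least squares of by on bx with intercept, weights 1/sy^2;
## residual scale floored at 1; returns the pieces both mr_egger and the
## intercept test need
.egger_fit <- function(pairs) {
  bx <- pairs$beta_exposure; by <- pairs$beta_outcome; sy <- pairs$se_outcome
  # orient so all exposure betas are non-negative (Egger is not invariant
  # to per-variant allele recoding; this is the standard convention)
  flip <- bx < 0
  bx[flip] <- -bx[flip]; by[flip] <- -by[flip]
  if (stats::var(bx) == 0)
    stop("mr_egger: exposure betas collinear after orientation")
  w <- 1 / sy^2
  n <- length(bx)
  X <- cbind(1, bx)
  xtwx_inv <- solve(crossprod(X, w * X))
  coef <- drop(xtwx_inv %*% crossprod(X, w * by))
  resid <- by - drop(X %*% coef)
  sigma2 <- sum(w * resid^2) / (n - 2)
  scale <- max(1, sqrt(sigma2))
  se <- sqrt(diag(xtwx_inv)) * scale
  tval <- coef / se
  pval <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(n = n, intercept = unname(coef[1]), slope = unname(coef[2]),
       intercept_se = unname(se[1]), slope_se = unname(se[2]),
       intercept_p = unname(pval[1]), slope_p = unname(pval[2]))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with an intercept
#' (weights `1/seY^2`), after orienting every variant so its exposure beta is
#' non-negative. The slope is a pleiotropy-adjusted causal estimate; the
#' intercept estimates average directional pleiotropy. Standard errors are
#' scaled by `max(1, sigma_hat)` where `sigma_hat^2` is the weighted residual
#' variance on `n - 2` df; p-values use the t distribution on `n - 2` df.
#'
#' @inheritParams mr_wald_ratio
#' @return One-row MR result data.frame including the intercept fields.
#' @export
mr_egger <- function(pairs, exposure = "", outcome = "") {
  pairs <- .check_pairs(pairs, 3, "mr_egger")
  fit <- .egger_fit(pairs)
  .mr_result("mr_egger", fit$n, fit$slope, fit$slope_se, fit$slope_p,
             egger_intercept = fit$intercept,
             egger_intercept_se = fit$intercept_se,
             egger_intercept_pvalue = fit$intercept_p,
             exposure = exposure, outcome = outcome)
}

## interpolated weighted median of `ratio` with weights `w`:
## with sorted ratios and normalized weights w', the cumulative midpoints are
## s_j = sum_{i<=j} w'_i - w'_j/2; the estimate interpolates linearly to s=0.5
.weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]; wn <- w[ord] / sum(w)
  s <- cumsum(wn) - wn / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  below <- max(which(s < 0.5))
  r[below] + (r[below + 1] - r[below]) * (0.5 - s[below]) /
    (s[below + 1] - s[below])
}

## parametric bootstrap over both sets of betas; `point_fun(ratio, w)` maps a
## resampled instrument set to an estimate
.bootstrap_se <- function(pairs, point_fun, n_boot, seed) {
  if (any(is.na(pairs$se_exposure)) || any(pairs$se_exposure <= 0))
    stop("parametric bootstrap requires positive exposure standard errors")
  k <- nrow(pairs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  bx <- matrix(stats::rnorm(n_boot * k, mean = rep(pairs$beta_exposure, each = n_boot),
                            sd = rep(pairs$se_exposure, each = n_boot)), n_boot, k)
  by <- matrix(stats::rnorm(n_boot * k, mean = rep(pairs$beta_outcome, each = n_boot),
                            sd = rep(pairs$se_outcome, each = n_boot)), n_boot, k)
  sy <- matrix(rep(pairs$se_outcome, each = n_boot), n_boot, k)
  est <- vapply(seq_len(n_boot), function(i) {
    point_fun(by[i, ] / bx[i, ], bx[i, ]^2 / sy[i, ]^2)
  }, numeric(1))
  stats::sd(est)
}

#' Weighted median estimator
#'
#' The interpolated weighted median of the per-variant Wald ratios with
#' inverse-variance weights; consistent when at least half of the total
#' weight comes from valid instruments. The standard error comes from a
#' parametric bootstrap: exposure and outcome betas are resampled from
#' normal distributions centred on their estimates, and the estimator is
#' recomputed each time.
#'
#' @inheritParams mr_wald_ratio
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap (mandatory; keeps runs reproducible
#'   without touching the caller's RNG state).
#' @return One-row MR result data.frame.
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed = 20231116,
                               exposure = "", outcome = "") {
  pairs <- .check_pairs(pairs, 3, "weighted_median")
  re <- ratio_estimates(pairs)
  beta <- .weighted_median_point(re$ratio, re$weight)
  se <- .bootstrap_se(pairs, .weighted_median_point, n_boot, seed)
  .mr_result("weighted_median", nrow(pairs), beta, se,
             2 * stats::pnorm(-abs(beta / se)),
             exposure = exposure, outcome = outcome)
}

## mode of a weighted gaussian kernel density over the ratios, argmax on a
## 512-point grid spanning [min - 3h, max + 3h]
.mode_point <- function(ratio, w, bandwidth_factor) {
  spread <- min(stats::sd(ratio), stats::IQR(ratio) / 1.349)
  if (spread == 0) spread <- stats::sd(ratio)  # degenerate IQR, spread by sd
  h <- bandwidth_factor * 0.9 * spread * length(ratio)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(ratio[1])  # all ratios identical
  d <- stats::density(ratio, weights = w / sum(w), bw = h, kernel = "gaussian",
                      n = 512, from = min(ratio) - 3 * h,
                      to = max(ratio) + 3 * h)
  d$x[which.max(d$y)]
}

#' Mode-based estimators (simple and weighted)
#'
#' The mode of the smoothed empirical density of the per-variant Wald
#' ratios: consistent when the largest homogeneous cluster of instruments is
#' valid, so a minority of outliers cannot move it. `weighted = FALSE` gives
#' the simple mode (equal kernel weights); `weighted = TRUE` weights each
#' ratio by its inverse variance. Bandwidth is
#' `bandwidth_factor * 0.9 * min(sd, IQR/1.349) * n^(-1/5)`; the density is
#' evaluated on a fixed 512-point grid. Standard error by the same
#' parametric bootstrap as the weighted median.
#'
#' @inheritParams mr_weighted_median
#' @param weighted Use inverse-variance weights (weighted mode) instead of
#'   equal weights (simple mode).
#' @param bandwidth_factor Multiplier on the rule-of-thumb bandwidth
#'   (default 1).
#' @return One-row MR result data.frame.
#' @export
mr_mode <- function(pairs, weighted = FALSE, bandwidth_factor = 1,
                    n_boot = 1000, seed = 20231116,
                    exposure = "", outcome = "") {
  pairs <- .check_pairs(pairs, 3, "mode")
  re <- ratio_estimates(pairs)
  pf <- if (weighted) {
    function(ratio, w) .mode_point(ratio, w, bandwidth_factor)
  } else {
    function(ratio, w) .mode_point(ratio, rep(1, length(ratio)),
                                   bandwidth_factor)
  }
  beta <- pf(re$ratio, re$weight)
  se <- .bootstrap_se(pairs, pf, n_boot, seed)
  .mr_result(if (weighted) "weighted_mode" else "simple_mode",
             nrow(pairs), beta, se, 2 * stats::pnorm(-abs(beta / se)),
             exposure = exposure, outcome = outcome)
}

#' Run the full estimator suite on one harmonized instrument set
#'
#' With a single usable variant only the Wald ratio is reported; otherwise
#' the requested subset of \{ivw, mr_egger, weighted_median, simple_mode,
#' weighted_mode\} (methods whose minimum instrument count exceeds the data
#' are skipped silently).
#'
#' @inheritParams mr_weighted_median
#' @param methods Character vector of method names to run when more than one
#'   instrument is available.
#' @return Data.frame of MR results, one row per method run.
#' @export
mr_all_methods <- function(pairs, methods = c("ivw", "mr_egger",
                                              "weighted_median",
                                              "simple_mode", "weighted_mode"),
                           n_boot = 1000, seed = 20231116,
                           exposure = "", outcome = "") {
  usable <- harmonized_kept(pairs)
  k <- nrow(usable)
  if (k == 0) stop("no usable harmonized variants for ", exposure, " -> ", outcome)
  if (k == 1)
    return(mr_wald_ratio(usable, exposure = exposure, outcome = outcome))
  out <- list()
  if ("ivw" %in% methods)
    out$ivw <- mr_ivw(usable, exposure = exposure, outcome = outcome)
  if (k >= 3) {
    if ("mr_egger" %in% methods)
      out$egger <- mr_egger(usable, exposure = exposure, outcome = outcome)
    if ("weighted_median" %in% methods)
      out$wm <- mr_weighted_median(usable, n_boot, seed, exposure, outcome)
    if ("simple_mode" %in% methods)
      out$sm <- mr_mode(usable, FALSE, 1, n_boot, seed, exposure, outcome)
    if ("weighted_mode" %in% methods)
      out$wmode <- mr_mode(usable, TRUE, 1, n_boot, seed, exposure, outcome)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
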