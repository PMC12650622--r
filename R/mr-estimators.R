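#' Per-SNP Wald ratio estimates
#'
#' The shared kernel of all summary-data MR estimators: for each harmonised
#' SNP, `ratio = beta_out / beta_exp` with first-order delta-method
#' standard error `se_out / |beta_exp|`.  SNPs with `beta_exp == 0` are
#' excluded with a logged reason.
#'
#' @param h harmonised instrument table (see [harmonise]), or any
#'   data.frame with `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @return data.frame `snp`, `ratio`, `se`; attribute `excluded` lists
#'   zero-exposure SNPs.
#' @export
wald_ratios <- function(h) {
  zero <- h$beta_exp == 0
  kept <- h[!zero, , drop = FALSE]
  out <- data.frame(snp = kept$snp %||% seq_len(nrow(kept)),
                    ratio = kept$beta_out / kept$beta_exp,
                    se = kept$se_out / abs(kept$beta_exp),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- if (any(zero)) h$snp[zero] else character(0)
  out
}

# Weighted-mean kernel of the IVW estimator.  Valid down to a single
# ratio, where it reduces to the Wald ratio itself (the panel requires
# >= 2 SNPs by policy; this internal path has no such floor).
ivw_point <- function(ratio, se) {
  w <- 1 / se^2
  beta <- sum(w * ratio) / sum(w)
  list(estimate = beta, se = 1 / sqrt(sum(w)),
       q = sum(w * (ratio - beta)^2))
}

#' Inverse-variance weighted estimate
#'
#' The primary causal estimate: the precision-weighted mean of the Wald
#' ratios, `sum(w r) / sum(w)` with `w = 1/se(r)^2`.  The fixed-effect
#' standard error is `1/sqrt(sum(w))`; when Cochran's Q signals
#' heterogeneity (`q_pval < 0.05`) the standard error is inflated
#' multiplicatively by `sqrt(Q / (n - 1))`, floored at 1 (the
#' multiplicative random-effects model).  P-values are two-sided normal.
#'
#' @param h harmonised instrument table with at least 2 SNPs.
#' @param q_alpha heterogeneity level switching to random effects.
#' @return list: `estimate`, `se`, `pval`, `n_snp`, `model`
#'   (`fixed`/`random`), `cochran_q`, `q_df`, `q_pval`.
#' @export
mr_ivw <- function(h, q_alpha = 0.05) {
  r <- wald_ratios(h)
  assert_that(nrow(r) >= 2, "IVW needs >= 2 SNPs (got %d)", nrow(r))
  pt <- ivw_point(r$ratio, r$se)
  beta <- pt$estimate
  se_fixed <- pt$se
  q <- pt$q
  q_df <- nrow(r) - 1L
  q_pval <- stats::pchisq(q, q_df, lower.tail = FALSE)
  model <- if (q_pval < q_alpha) "random" else "fixed"
  se <- if (model == "random") se_fixed * max(1, sqrt(q / q_df)) else se_fixed
  list(estimate = beta, se = se, pval = 2 * stats::pnorm(-abs(beta / se)),
       n_snp = nrow(r), model = model,
       cochran_q = q, q_df = q_df, q_pval = q_pval)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j (r_j - beta_hat)^2)` over the Wald ratios, chi-square with
#' `n - 1` degrees of freedom under homogeneity.
#'
#' @param h harmonised instrument table (>= 2 SNPs).
#' @param beta_hat pooled estimate (fixed-effect IVW); computed internally
#'   when omitted.
#' @return list `q`, `df`, `pval`.
#' @export
cochran_q <- function(h, beta_hat = NULL) {
  r <- wald_ratios(h)
  assert_that(nrow(r) >= 2, "Cochran's Q needs >= 2 SNPs")
  w <- 1 / r$se^2
  if (is.null(beta_hat)) beta_hat <- sum(w * r$ratio) / sum(w)
  q <- sum(w * (r$ratio - beta_hat)^2)
  df <- nrow(r) - 1L
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' unconstrained intercept (weights `1/se_out^2`), after orienting every
#' exposure effect to be non-negative (sign-flipping both members of a
#' pair when needed).  The slope is the causal estimate; a non-zero
#' intercept indicates directional pleiotropy.  Inference uses the
#' regression t-distribution with `n - 2` degrees of freedom.
#'
#' @param h harmonised instrument table with at least 3 SNPs.
#' @return list: `estimate`, `se`, `pval` (slope); `intercept`,
#'   `intercept_se`, `intercept_pval`; `n_snp`.  A degenerate design (all
#'   oriented exposure effects equal) returns `NULL` estimates with
#'   `status = "degenerate_design"`.
#' @export
mr_egger <- function(h) {
  assert_that(nrow(h) >= 3, "MR-Egger needs >= 3 SNPs (got %d)", nrow(h))
  flip <- sign(h$beta_exp)
  flip[flip == 0] <- 1
  bx <- h$beta_exp * flip
  by <- h$beta_out * flip
  if (stats::sd(bx) == 0)
    return(list(estimate = NA_real_, se = NA_real_, pval = NA_real_,
                intercept = NA_real_, intercept_se = NA_real_,
                intercept_pval = NA_real_, n_snp = nrow(h),
                status = "degenerate_design"))
  fit <- stats::lm(by ~ bx, weights = 1 / h$se_out^2)
  cf <- summary(fit)$coefficients
  list(estimate = cf["bx", "Estimate"], se = cf["bx", "Std. Error"],
       pval = cf["bx", "Pr(>|t|)"],
       intercept = cf["(Intercept)", "Estimate"],
       intercept_se = cf["(Intercept)", "Std. Error"],
       intercept_pval = cf["(Intercept)", "Pr(>|t|)"],
       n_snp = nrow(h), status = "ok")
}

# Interpolated weighted median of ratios b with weights w.
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]; w <- w[o]
  cs <- (cumsum(w) - 0.5 * w) / sum(w)
  if (cs[1] >= 0.5) return(b[1])
  if (all(cs < 0.5)) return(b[length(b)])
  below <- max(which(cs < 0.5))
  b[below] + (b[below + 1] - b[below]) *
    (0.5 - cs[below]) / (cs[below + 1] - cs[below])
}

#' Weighted median estimate
#'
#' The Wald ratio at the point where the normalised cumulative
#' inverse-variance weight crosses one half, with linear interpolation
#' between the bracketing ratios.  Consistent as long as at least half of
#' the total weight comes from valid instruments.  The standard error is
#' estimated by a seeded parametric bootstrap, resampling exposure and
#' outcome effects from their reported normal distributions.
#'
#' @param h harmonised instrument table with at least 3 SNPs.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap (required when `n_boot > 0`).
#' @return list: `estimate`, `se`, `pval`, `n_snp`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  assert_that(nrow(h) >= 3, "weighted median needs >= 3 SNPs (got %d)", nrow(h))
  r <- wald_ratios(h)
  est <- weighted_median_point(r$ratio, 1 / r$se^2)
  se <- if (n_boot > 0) {
    assert_that(!is.null(seed), "mr_weighted_median: seed required for bootstrap")
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(nrow(h), h$beta_exp, h$se_exp)
      by <- stats::rnorm(nrow(h), h$beta_out, h$se_out)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok], (abs(bx[ok]) / h$se_out[ok])^2)
    }, numeric(1)))
    stats::sd(boots)
  } else NA_real_
  list(estimate = est, se = se,
       pval = if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(est / se)),
       n_snp = nrow(h))
}

# Argmax of a normal-kernel density over ratios; bandwidth from a
# rule-of-thumb spread measure of the ratios.
mode_point <- function(ratios, bandwidth_factor) {
  if (length(unique(ratios)) == 1L) return(ratios[1])
  spread <- min(stats::sd(ratios),
                if (stats::mad(ratios) > 0) stats::mad(ratios)
                else stats::sd(ratios))
  bw <- bandwidth_factor * 0.9 * spread * length(ratios)^(-1 / 5)
  d <- stats::density(ratios, bw = bw, n = 1024)
  d$x[which.max(d$y)]
}

#' Simple mode estimate
#'
#' The mode of the unweighted kernel-smoothed empirical density of the Wald
#' ratios (normal kernel; bandwidth `bandwidth_factor` times a
#' rule-of-thumb spread measure).  Consistent when the largest group of
#' instruments sharing a ratio value is valid (the ZEMPA assumption).
#' Standard error by seeded parametric bootstrap.
#'
#' @param h harmonised instrument table with at least 3 SNPs.
#' @param bandwidth_factor multiplier on the rule-of-thumb bandwidth.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return list: `estimate`, `se`, `pval`, `n_snp`.
#' @export
mr_simple_mode <- function(h, bandwidth_factor = 1, n_boot = 1000,
                           seed = NULL) {
  assert_that(nrow(h) >= 3, "simple mode needs >= 3 SNPs (got %d)", nrow(h))
  r <- wald_ratios(h)
  est <- mode_point(r$ratio, bandwidth_factor)
  se <- if (n_boot > 0) {
    assert_that(!is.null(seed), "mr_simple_mode: seed required for bootstrap")
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(nrow(h), h$beta_exp, h$se_exp)
      by <- stats::rnorm(nrow(h), h$beta_out, h$se_out)
      ok <- bx != 0
      mode_point(by[ok] / bx[ok], bandwidth_factor)
    }, numeric(1)))
    stats::sd(boots)
  } else NA_real_
  list(estimate = est, se = se,
       pval = if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(est / se)),
       n_snp = nrow(h))
}
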