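test_that("select_instruments applies p/MAF/F filters with provenance", {
  expo <- make_exposure(
    snp = c("rs_keep", "rs_weak", "rs_rare", "rs_nsig"),
    ea = c("A", "A", "A", "A"), oa = c("G", "G", "G", "G"),
    beta = c(0.1, 0.1, 0.1, 0.001),
    se = c(0.02, 0.04, 0.02, 0.02),
    eaf = c(0.3, 0.3, 0.005, 0.3))
  # default thresholds make the p filter subsume the F filter (p < 5e-6
  # implies F > 20.8), so a looser p isolates the weak-instrument rule
  inst <- select_instruments(expo, p_threshold = 0.05)
  # F = (0.1/0.02)^2 = 25 retained; F = 6.25 excluded; MAF 0.5% excluded;
  # p ~ 0.96 excluded
  expect_equal(inst$snps$snp, "rs_keep")
  expect_equal(inst$snps$f_stat, 25)
  expect_setequal(inst$provenance$snp[inst$provenance$stage == "f_stat"],
                  "rs_weak")
  expect_setequal(inst$provenance$snp[inst$provenance$stage == "maf"],
                  "rs_rare")
  expect_setequal(inst$provenance$snp[inst$provenance$stage == "pval"],
                  "rs_nsig")
  expect_equal(inst$status, "insufficient_instruments")
})

test_that("greedy LD pruning equals the enumeration oracle", {
  # two correlated SNPs: the stronger association survives
  expo <- make_exposure(snp = c("rs1", "rs2"), ea = c("A", "A"),
                        oa = c("G", "G"), beta = c(0.12, 0.10),
                        se = c(0.02, 0.02), eaf = c(0.3, 0.3))
  ld <- data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.5)
  inst <- select_instruments(expo, ld)
  expect_equal(inst$snps$snp, "rs1")

  # randomised fixtures vs an oracle that enumerates every keep-set and
  # picks the greedy-by-p one
  greedy_oracle <- function(snps, pvals, r2_of, thr) {
    kept <- character(0)
    for (s in snps[order(pvals)])
      if (all(vapply(kept, function(k) r2_of(s, k), 1) < thr))
        kept <- c(kept, s)
    kept
  }
  set.seed(17)
  for (rep in 1:5) {
    n <- 8
    expo <- make_exposure(snp = sprintf("s%d", 1:n), ea = rep("A", n),
                          oa = rep("G", n),
                          beta = runif(n, 0.12, 0.2),  # all pass p < 5e-6
                          se = rep(0.02, n), eaf = rep(0.3, n))
    prs <- t(combn(sprintf("s%d", 1:n), 2))
    ld <- data.frame(snp_a = prs[, 1], snp_b = prs[, 2],
                     r2 = ifelse(runif(nrow(prs)) < 0.3,
                                 runif(nrow(prs), 0.3, 1), 0))
    inst <- select_instruments(expo, ld)
    want <- greedy_oracle(expo$records$snp, expo$records$pval,
                          pdmr:::ld_lookup(ld), 0.3)
    expect_setequal(inst$snps$snp, want)
  }
})

test_that("harmonisation: flips, palindromes, reverse causation, idempotence", {
  ea <- c("A", "A", "A", "C", "A", "A")
  oa <- c("G", "G", "T", "G", "G", "G")
  expo <- make_exposure(
    snp = c("rs_keep", "rs_swap", "rs_pal", "rs_palCG", "rs_rev", "rs_bad"),
    ea = ea, oa = oa,
    beta = rep(0.1, 6), se = rep(0.02, 6),
    eaf = c(0.3, 0.3, 0.45, 0.30, 0.3, 0.3))
  outc <- make_outcome(
    snp = c("rs_keep", "rs_swap", "rs_pal", "rs_palCG", "rs_rev", "rs_bad"),
    ea = c("A", "G", "A", "C", "A", "A"),
    oa = c("G", "A", "T", "G", "G", "C"),
    beta = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
    se = rep(0.02, 6),
    eaf = c(0.3, 0.7, 0.45, 0.30, 0.3, 0.3),
    pval = c(0.2, 0.2, 0.2, 0.2, 1e-7, 0.2))
  h <- harmonise(as_instruments(expo), outc)
  excl <- attr(h, "exclusions")
  # swapped alleles: sign and frequency flipped
  expect_equal(h$beta_out[h$snp == "rs_swap"], -0.05)
  expect_equal(h$eaf_out[h$snp == "rs_swap"], 0.3)
  # untouched exact match
  expect_equal(h$beta_out[h$snp == "rs_keep"], 0.05)
  # palindromic A/T with exposure MAF 0.45 > 0.42: excluded
  expect_match(excl$reason[excl$snp == "rs_pal"], "palindromic")
  # palindromic C/G at MAF 0.30 <= 0.42: retained, frequencies agree -> kept
  expect_true("rs_palCG" %in% h$snp)
  expect_equal(h$action[h$snp == "rs_palCG"], "kept")
  # reverse causation: outcome p = 1e-7 < 5e-6 and < exposure p
  expect_match(excl$reason[excl$snp == "rs_rev"], "reverse")
  # irreconcilable alleles A/G vs A/C
  expect_match(excl$reason[excl$snp == "rs_bad"], "allele_mismatch")

  # idempotence: harmonising the already-aligned records changes nothing
  h2 <- harmonise(pdmr:::harmonised_as_instruments(h),
                  pdmr:::harmonised_as_outcome(h))
  expect_equal(h2$beta_out, h$beta_out)
  expect_equal(h2$eaf_out, h$eaf_out)
  expect_true(all(h2$action == "kept"))
  expect_equal(nrow(attr(h2, "exclusions")), 0L)
})

test_that("harmonisation resolves complementary-strand records", {
  expo <- make_exposure(snp = c("rs_c1", "rs_c2"), ea = c("A", "A"),
                        oa = c("G", "G"), beta = c(0.1, 0.1),
                        se = c(0.02, 0.02), eaf = c(0.3, 0.3))
  # outcome on the other strand: T/C ~ A/G (kept), C/T ~ G/A (flip)
  outc <- make_outcome(snp = c("rs_c1", "rs_c2"),
                       ea = c("T", "C"), oa = c("C", "T"),
                       beta = c(0.05, 0.05), se = c(0.02, 0.02),
                       eaf = c(0.3, 0.7))
  h <- harmonise(as_instruments(expo), outc)
  expect_equal(h$beta_out[h$snp == "rs_c1"], 0.05)
  expect_equal(h$beta_out[h$snp == "rs_c2"], -0.05)
})

test_that("Wald ratios and delta-method SE match a Monte-Carlo oracle", {
  h <- make_harmonised(beta_exp = c(0.1, 0.2), beta_out = c(0.02, 0),
                       se_exp = 1e-6, se_out = 0.05)
  r <- wald_ratios(h)
  expect_equal(r$ratio, c(0.2, 0))
  expect_equal(r$se, c(0.5, 0.25))
  # zero exposure beta excluded with a log
  h0 <- make_harmonised(beta_exp = c(0.1, 0), beta_out = c(0.02, 0.01))
  r0 <- wald_ratios(h0)
  expect_equal(nrow(r0), 1L)
  expect_equal(attr(r0, "excluded"), "s2")
  # Monte-Carlo error propagation (exposure error negligible by design)
  mc <- pdmr:::with_seed(42, {
    by <- rnorm(2e5, 0.02, 0.05)
    sd(by / 0.1)
  })
  expect_equal(r$se[1], mc, tolerance = 0.02)
})

test_that("IVW equals its closed form, including the single-SNP limit", {
  # two SNPs, ratios 0.1 and 0.3, equal SE 0.1
  h <- make_harmonised(beta_exp = c(1, 1), beta_out = c(0.1, 0.3),
                       se_exp = 1e-8, se_out = 0.1)
  est <- mr_ivw(h)
  expect_equal(est$estimate, 0.2)
  expect_equal(est$se, sqrt(1 / 200), tolerance = 1e-12)
  expect_equal(est$cochran_q, 2.0)
  expect_equal(est$q_df, 1L)
  # identical ratios: Q = 0, fixed model, estimate equals the ratio
  h2 <- make_harmonised(beta_exp = c(1, 2), beta_out = c(0.2, 0.4),
                        se_exp = 1e-8, se_out = 0.1)
  est2 <- mr_ivw(h2)
  expect_equal(est2$estimate, 0.2)
  expect_equal(est2$model, "fixed")
  # standalone Q agrees and reproduces the hand computation
  q <- cochran_q(h)
  expect_equal(q$q, 2.0)
  expect_equal(q$df, 1L)
  expect_equal(q$pval, pchisq(2, 1, lower.tail = FALSE))
  expect_equal(cochran_q(h2)$q, 0)
  expect_equal(cochran_q(h2)$pval, 1)
  # single-instrument limit via the internal kernel
  one <- pdmr:::ivw_point(0.37, 0.1)
  expect_equal(one$estimate, 0.37)
  expect_equal(one$se, 0.1)
  expect_error(mr_ivw(make_harmonised(0.1, 0.02)), ">= 2")
})

test_that("random-effects inflation triggers exactly on Q p < 0.05", {
  h <- make_harmonised(beta_exp = rep(1, 4), beta_out = c(0, 1, 2, 3),
                       se_exp = 1e-8, se_out = 0.1)
  est <- mr_ivw(h)
  expect_lt(est$q_pval, 0.05)
  expect_equal(est$model, "random")
  expect_equal(est$se, (1 / sqrt(4 / 0.01)) *
                 sqrt(est$cochran_q / est$q_df), tolerance = 1e-12)
})

test_that("MR-Egger: exact on collinear data, recovers planted pleiotropy", {
  # three collinear points: exact line, zero residual
  h <- make_harmonised(beta_exp = c(0.1, 0.2, 0.3),
                       beta_out = 0.05 + 0.2 * c(0.1, 0.2, 0.3),
                       se_exp = 1e-8, se_out = 0.05)
  eg <- mr_egger(h)
  expect_equal(eg$estimate, 0.2, tolerance = 1e-8)
  expect_equal(eg$intercept, 0.05, tolerance = 1e-8)
  # simulated intercept 0.05, slope 0.2, 200 SNPs: recovered within 3 SE
  sim <- pdmr:::with_seed(13, {
    bx <- runif(200, 0.05, 0.3)
    by <- 0.05 + 0.2 * bx + rnorm(200, 0, 0.02)
    make_harmonised(bx, by, se_exp = 1e-8, se_out = 0.02)
  })
  eg2 <- mr_egger(sim)
  expect_lt(abs(eg2$estimate - 0.2), 3 * eg2$se)
  expect_lt(abs(eg2$intercept - 0.05), 3 * eg2$intercept_se)
  # degenerate design: all oriented exposure betas equal
  hd <- make_harmonised(beta_exp = c(0.1, 0.1, -0.1),
                        beta_out = c(0.01, 0.02, 0.03))
  expect_equal(mr_egger(hd)$status, "degenerate_design")
  expect_error(mr_egger(make_harmonised(c(0.1, 0.2), c(0, 0))), ">= 3")
})

test_that("Egger intercept p is calibrated under balanced pleiotropy", {
  rej <- vapply(1:60, function(s) pdmr:::with_seed(700 + s, {
    bx <- runif(50, 0.05, 0.3)
    by <- 0.2 * bx + rnorm(50, 0, 0.05)  # balanced: no directional effect
    mr_egger(make_harmonised(bx, by, se_exp = 1e-8,
                             se_out = 0.05))$intercept_pval < 0.05
  }), logical(1))
  expect_lte(mean(rej), 0.15)
})

test_that("weighted median: interpolation, robustness, bootstrap stability", {
  # 3 equal-weight ratios {0.1, 0.2, 0.9} -> 0.2
  h <- make_harmonised(beta_exp = rep(1, 3), beta_out = c(0.1, 0.2, 0.9),
                       se_exp = 1e-8, se_out = 0.1)
  wm <- mr_weighted_median(h, n_boot = 0)
  expect_equal(wm$estimate, 0.2)
  # 60% valid at theta = 0.2, 40% shifted by +0.5, equal weights
  ests <- vapply(1:10, function(s) pdmr:::with_seed(800 + s, {
    n <- 100
    ratio_shift <- rep(c(0, 0.5), c(60, 40))
    bx <- rep(0.15, n)
    by <- (0.2 + ratio_shift) * bx + rnorm(n, 0, 0.005)
    mr_weighted_median(make_harmonised(bx, by, se_exp = 1e-8,
                                       se_out = 0.005), n_boot = 0)$estimate
  }), numeric(1))
  expect_lt(abs(mean(ests) - 0.2), 0.05)
  # bootstrap SE stable across seeds within 10%
  h2 <- make_harmonised(beta_exp = rep(0.15, 20),
                        beta_out = 0.2 * 0.15 + seq(-0.02, 0.02,
                                                    length.out = 20),
                        se_exp = 0.01, se_out = 0.01)
  se_a <- mr_weighted_median(h2, n_boot = 1000, seed = 1)$se
  se_b <- mr_weighted_median(h2, n_boot = 1000, seed = 2)$se
  expect_lt(abs(se_a - se_b) / se_a, 0.1)
})

test_that("simple mode finds the majority cluster and tracks IVW when clean", {
  h <- make_harmonised(beta_exp = rep(1, 4),
                       beta_out = c(0.2, 0.2, 0.2, 0.9),
                       se_exp = 1e-8, se_out = 0.05)
  sm <- mr_simple_mode(h, n_boot = 0)
  expect_equal(sm$estimate, 0.2, tolerance = 0.02)
  # bimodal with the larger cluster at theta
  sim <- pdmr:::with_seed(31, {
    n <- 60
    shift <- rep(c(0, 0.6), c(40, 20))
    bx <- rep(0.15, n)
    by <- (0.2 + shift) * bx + rnorm(n, 0, 0.004)
    make_harmonised(bx, by, se_exp = 1e-8, se_out = 0.004)
  })
  expect_lt(abs(mr_simple_mode(sim, n_boot = 0)$estimate - 0.2), 0.05)
  # single cluster: mode ~ IVW
  sim2 <- pdmr:::with_seed(32, {
    bx <- runif(80, 0.1, 0.3)
    by <- 0.2 * bx + rnorm(80, 0, 0.01)
    make_harmonised(bx, by, se_exp = 1e-8, se_out = 0.01)
  })
  expect_lt(abs(mr_simple_mode(sim2, n_boot = 0)$estimate -
                  mr_ivw(sim2)$estimate), 0.05)
})

test_that("all four estimators are scale-equivariant in the exposure", {
  sim <- pdmr:::with_seed(55, {
    bx <- runif(30, 0.1, 0.3)
    by <- 0.25 * bx + rnorm(30, 0, 0.01)
    make_harmonised(bx, by, se_exp = 1e-8, se_out = 0.01)
  })
  c_fac <- 4
  sim2 <- sim
  sim2$beta_exp <- sim$beta_exp * c_fac
  sim2$se_exp <- sim$se_exp * c_fac
  sim2$f_stat <- (sim2$beta_exp / sim2$se_exp)^2
  expect_equal(mr_ivw(sim2)$estimate, mr_ivw(sim)$estimate / c_fac,
               tolerance = 1e-10)
  expect_equal(mr_egger(sim2)$estimate, mr_egger(sim)$estimate / c_fac,
               tolerance = 1e-10)
  expect_equal(mr_weighted_median(sim2, n_boot = 0)$estimate,
               mr_weighted_median(sim, n_boot = 0)$estimate / c_fac,
               tolerance = 1e-10)
  expect_equal(mr_simple_mode(sim2, n_boot = 0)$estimate,
               mr_simple_mode(sim, n_boot = 0)$estimate / c_fac,
               tolerance = 1e-3)
})

test_that("run_mr_panel: FDR identity, reporting, OR consistency", {
  ss <- gen_summary_stats(n_genes = 1, n_snps = 30, theta = 0.2, seed = 77)
  cfg <- mr_config(seed = 9, n_boot = 100)
  panel <- run_mr_panel(ss$exposures, ss$outcome, ss$ld, cfg)
  # single-gene panel: fdr equals the IVW p (BH identity at m = 1)
  expect_equal(panel$fdr, panel$ivw_pval)
  expect_true(all(panel$or_lo < panel$or & panel$or < panel$or_hi))
  expect_equal(panel$or, exp(panel$ivw_beta))
  expect_equal(panel$ivw_model,
               ifelse(panel$q_pval < 0.05, "random", "fixed"))
  long <- mr_results_long(panel)
  expect_setequal(unique(long$method),
                  c("ivw", "egger", "weighted_median", "simple_mode"))
  forest <- mr_forest_table(panel)
  expect_true(all(forest$direction %in% c("risk", "protective", "ns")))

  # a gene with too few instruments is reported, not dropped
  weak <- make_exposure(snp = c("w1", "w2"), ea = c("A", "A"),
                        oa = c("G", "G"), beta = c(0.001, 0.001),
                        se = c(0.02, 0.02), eaf = c(0.3, 0.3),
                        trait = "weak_gene")
  panel2 <- run_mr_panel(c(ss$exposures, list(weak)), ss$outcome, ss$ld, cfg)
  expect_equal(panel2$status[panel2$gene == "weak_gene"],
               "insufficient_instruments")
  expect_error(run_mr_panel(list(), ss$outcome), "empty")
})
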