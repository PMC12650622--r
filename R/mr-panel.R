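#' Default configuration for the MR panel
#'
#' Thresholds follow the summary-data MR conventions used throughout the
#' package: suggestive-significance instruments (p < 5e-6), LD pruning at
#' r2 < 0.3, MAF > 1%, F > 10; palindromic SNPs dropped above MAF 0.42;
#' reverse-causation exclusion at outcome p < 5e-6 stronger than exposure;
#' fixed-effect IVW unless Cochran's Q p < 0.05.
#'
#' @param ... overrides for any default element.
#' @return named list of configuration values.
#' @export
mr_config <- function(...) {
  cfg <- list(p_threshold = 5e-6, r2_threshold = 0.3, maf_threshold = 0.01,
              f_threshold = 10, palindrome_maf_threshold = 0.42,
              outcome_p_threshold = 5e-6, reverse_causation_filter = TRUE,
              palindrome_filter = TRUE, q_alpha = 0.05,
              bandwidth_factor = 1, n_boot = 1000, alpha = 0.05,
              tissue = "blood", seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  assert_that(length(unknown) == 0, "unknown mr_config field(s): %s",
              paste(unknown, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Run the full per-gene Mendelian randomisation panel
#'
#' For every exposure gene: instrument selection, harmonisation against the
#' outcome, then the inverse-variance weighted (primary), MR-Egger,
#' weighted median and simple mode estimators with Cochran's Q and the
#' Egger intercept pleiotropy test.  Benjamini-Hochberg FDR is applied to
#' the IVW p-values across all analysed genes of the tissue.  Genes with
#' fewer than two surviving instruments are reported with a reason, never
#' silently dropped.  Odds ratios per standard-deviation increase in
#' genetically proxied expression are `exp(beta)` with normal 95% CIs.
#'
#' @param exposures list of `pdmr_sumstat_study`, one per gene.
#' @param outcome outcome `pdmr_sumstat_study`.
#' @param ld LD table (`snp_a`, `snp_b`, `r2`) or NULL.
#' @param config list from [mr_config].
#' @return data.frame, one row per gene: instrument counts before/after
#'   harmonisation, per-method estimates/SEs/p-values, heterogeneity and
#'   pleiotropy diagnostics, OR with CI, `fdr` (on IVW p), `status` and
#'   `reason`.  Attribute `tissue` carries the tissue label.
#' @export
run_mr_panel <- function(exposures, outcome, ld = NULL, config = mr_config()) {
  assert_that(length(exposures) >= 1, "empty gene list")
  rows <- lapply(exposures, function(expo) {
    gene <- expo$trait
    base <- data.frame(gene = gene, tissue = config$tissue,
                       n_snps_selected = NA_integer_, n_snps = NA_integer_,
                       ivw_beta = NA_real_, ivw_se = NA_real_,
                       ivw_pval = NA_real_, ivw_model = NA_character_,
                       cochran_q = NA_real_, q_df = NA_integer_,
                       q_pval = NA_real_,
                       egger_beta = NA_real_, egger_se = NA_real_,
                       egger_pval = NA_real_, egger_intercept = NA_real_,
                       egger_intercept_pval = NA_real_,
                       wmedian_beta = NA_real_, wmedian_se = NA_real_,
                       wmedian_pval = NA_real_,
                       smode_beta = NA_real_, smode_se = NA_real_,
                       smode_pval = NA_real_,
                       mean_f_stat = NA_real_,
                       or = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
                       fdr = NA_real_, status = "ok", reason = "",
                       stringsAsFactors = FALSE)
    inst <- select_instruments(expo, ld,
                               p_threshold = config$p_threshold,
                               r2_threshold = config$r2_threshold,
                               maf_threshold = config$maf_threshold,
                               f_threshold = config$f_threshold)
    base$n_snps_selected <- nrow(inst$snps)
    if (inst$status != "ok") {
      base$status <- "insufficient_instruments"
      base$reason <- sprintf("%d SNP(s) after selection", nrow(inst$snps))
      return(base)
    }
    h <- harmonise(inst, outcome,
                   palindrome_maf_threshold = config$palindrome_maf_threshold,
                   outcome_p_threshold = config$outcome_p_threshold,
                   reverse_causation_filter = config$reverse_causation_filter,
                   palindrome_filter = config$palindrome_filter)
    base$n_snps <- nrow(h)
    if (nrow(h) < 2) {
      base$status <- "insufficient_instruments"
      base$reason <- sprintf("%d SNP(s) after harmonisation", nrow(h))
      return(base)
    }
    base$mean_f_stat <- mean(h$f_stat)
    ivw <- mr_ivw(h, q_alpha = config$q_alpha)
    base$ivw_beta <- ivw$estimate; base$ivw_se <- ivw$se
    base$ivw_pval <- ivw$pval; base$ivw_model <- ivw$model
    base$cochran_q <- ivw$cochran_q; base$q_df <- ivw$q_df
    base$q_pval <- ivw$q_pval
    if (nrow(h) >= 3) {
      eg <- mr_egger(h)
      base$egger_beta <- eg$estimate; base$egger_se <- eg$se
      base$egger_pval <- eg$pval
      base$egger_intercept <- eg$intercept
      base$egger_intercept_pval <- eg$intercept_pval
      wm <- mr_weighted_median(h, n_boot = config$n_boot,
                               seed = split_seed(config$seed,
                                                 paste0("wm:", gene)))
      base$wmedian_beta <- wm$estimate; base$wmedian_se <- wm$se
      base$wmedian_pval <- wm$pval
      sm <- mr_simple_mode(h, bandwidth_factor = config$bandwidth_factor,
                           n_boot = config$n_boot,
                           seed = split_seed(config$seed, paste0("sm:", gene)))
      base$smode_beta <- sm$estimate; base$smode_se <- sm$se
      base$smode_pval <- sm$pval
    }
    z <- stats::qnorm(0.975)
    base$or <- exp(ivw$estimate)
    base$or_lo <- exp(ivw$estimate - z * ivw$se)
    base$or_hi <- exp(ivw$estimate + z * ivw$se)
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  analysed <- out$status == "ok"
  out$fdr[analysed] <- bh_adjust(out$ivw_pval[analysed])
  attr(out, "tissue") <- config$tissue
  out
}

#' Forest-plot-ready summary of an MR panel
#'
#' @param panel data.frame from [run_mr_panel].
#' @param alpha FDR significance threshold for the direction label.
#' @return data.frame `gene`, `or`, `ci_low`, `ci_high`, `fdr`,
#'   `direction` (risk / protective / ns).
#' @export
mr_forest_table <- function(panel, alpha = 0.05) {
  ok <- panel[panel$status == "ok", , drop = FALSE]
  data.frame(gene = ok$gene, or = ok$or, ci_low = ok$or_lo,
             ci_high = ok$or_hi, fdr = ok$fdr,
             direction = ifelse(ok$fdr >= alpha, "ns",
                                ifelse(ok$or > 1, "risk", "protective")),
             stringsAsFactors = FALSE)
}

#' Long (gene x method) view of an MR panel
#'
#' @param panel data.frame from [run_mr_panel].
#' @return data.frame `gene`, `tissue`, `method`, `n_snps`, `beta`, `se`,
#'   `pval`.
#' @export
mr_results_long <- function(panel) {
  methods <- c(ivw = "ivw", egger = "egger", wmedian = "weighted_median",
               smode = "simple_mode")
  out <- do.call(rbind, lapply(names(methods), function(m) {
    data.frame(gene = panel$gene, tissue = panel$tissue,
               method = methods[[m]], n_snps = panel$n_snps,
               beta = panel[[paste0(m, "_beta")]],
               se = panel[[paste0(m, "_se")]],
               pval = panel[[paste0(m, "_pval")]],
               stringsAsFactors = FALSE)
  }))
  out[order(out$gene, out$method), ]
}
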