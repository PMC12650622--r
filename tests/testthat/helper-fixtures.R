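# Fixture builders and independent oracles shared across the suite.

# A harmonised-instrument table built directly (bypassing selection /
# harmonisation) for estimator-level tests.
make_harmonised <- function(beta_exp, beta_out, se_exp = 0.01,
                            se_out = 0.05) {
  n <- length(beta_exp)
  h <- data.frame(
    snp = sprintf("s%d", seq_len(n)),
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = rep_len(se_exp, n),
    pval_exp = 2 * pnorm(-abs(beta_exp / rep_len(se_exp, n))),
    eaf_exp = 0.3,
    beta_out = beta_out, se_out = rep_len(se_out, n),
    pval_out = 2 * pnorm(-abs(beta_out / rep_len(se_out, n))),
    eaf_out = 0.3, f_stat = (beta_exp / rep_len(se_exp, n))^2,
    action = "kept", stringsAsFactors = FALSE)
  attr(h, "gene_id") <- "fixture_gene"
  class(h) <- c("pdmr_harmonised", "data.frame")
  h
}

# One-record exposure study for harmonisation fixtures.
make_exposure <- function(snp = "rs1", ea = "A", oa = "G", beta = 0.1,
                          se = 0.02, eaf = 0.3, trait = "geneX") {
  pdmr:::new_sumstat_study(
    study_id = paste0("eqtl_", trait), trait = trait,
    records = data.frame(snp = snp, chr = 1L, pos = seq_along(snp) * 100L,
                         effect_allele = ea, other_allele = oa,
                         beta = beta, se = se,
                         pval = 2 * pnorm(-abs(beta / se)),
                         eaf = eaf, n = 30000, stringsAsFactors = FALSE))
}

make_outcome <- function(snp, ea, oa, beta, se = 0.02, eaf = 0.3,
                         pval = NULL) {
  pdmr:::new_sumstat_study(
    study_id = "gwas", trait = "PD",
    records = data.frame(snp = snp, chr = 1L, pos = seq_along(snp) * 100L,
                         effect_allele = ea, other_allele = oa,
                         beta = beta, se = se,
                         pval = pval %||% 2 * pnorm(-abs(beta / se)),
                         eaf = eaf, n = 5e5, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_instruments <- function(exposure) {
  rec <- exposure$records
  rec$f_stat <- (rec$beta / rec$se)^2
  structure(list(gene_id = exposure$trait, snps = rec,
                 provenance = data.frame(), status = "ok"),
            class = "pdmr_instrument_set")
}

# Brute-force AUC oracle: exhaustive pair counting with half-credit ties.
pair_count_auc <- function(scores, labels) {
  x <- scores[labels == "case"]; y <- scores[labels == "control"]
  tot <- 0
  for (xi in x) for (yj in y)
    tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  tot / (length(x) * length(y))
}

# Exact upper-tail hypergeometric by direct enumeration over choose().
enum_hyper_tail <- function(k, set_size, universe, query) {
  js <- k:min(set_size, query)
  sum(choose(set_size, js) * choose(universe - set_size, query - js)) /
    choose(universe, query)
}

# Brute-force shared/concordant set algebra over DegRecord data.frames.
brute_shared <- function(deg_df, min_datasets = 2) {
  out <- list()
  for (g in unique(deg_df$gene)) {
    d <- deg_df[deg_df$gene == g, ]
    if (length(unique(d$direction)) > 1) next
    if (nrow(d) >= min_datasets) out[[g]] <- d$direction[1]
  }
  out
}
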