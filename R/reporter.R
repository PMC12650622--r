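#' Reporter-metabolite scoring on a genome-scale metabolic model
#'
#' Implements the reporter algorithm: each gene's differential-expression
#' p-value is converted to a Z-score, `Z_g = qnorm(1 - p_g)`; for each
#' metabolite the Z-scores of its distinct neighbouring genes (the union of
#' genes in the GPR rules of reactions that produce or consume it) are
#' aggregated as `z_raw = sum(Z_g) / sqrt(k)`; the score is centred and
#' scaled against a seeded background of `n_background` random size-k gene
#' draws from all scored model genes, giving
#' `z_corrected = (z_raw - mu_k) / sigma_k` and `p = 1 - pnorm(z_corrected)`
#' with Benjamini-Hochberg control across metabolites.  Scoring is
#' direction-agnostic (two-sided evidence, no up/down sign).
#'
#' @param model a [pdmr_metabolic_model].
#' @param gene_pvals named numeric vector of gene p-values in (0, 1];
#'   zeros are clipped to the smallest positive double with a message.
#' @param n_background background draws per distinct neighbourhood size
#'   (default 10000).
#' @param seed integer seed for the background sampling (required).
#' @param exclude currency metabolites (ids) to drop before scoring.
#' @return data.frame sorted by `z_corrected` descending: `metabolite`,
#'   `k`, `z_raw`, `z_corrected`, `pval`, `fdr`; attribute `skipped` lists
#'   metabolites with no scored neighbour genes.
#' @export
reporter_scores <- function(model, gene_pvals, n_background = 10000, seed,
                            exclude = character(0)) {
  assert_that(!missing(seed), "reporter_scores: seed is required")
  assert_that(all(gene_pvals <= 1), "gene p-values must lie in (0, 1]")
  if (any(gene_pvals <= 0)) {
    message(sprintf("reporter_scores: %d p-value(s) of 0 clipped",
                    sum(gene_pvals <= 0)))
    gene_pvals[gene_pvals <= 0] <- .Machine$double.xmin
  }
  scored <- intersect(model$genes, names(gene_pvals))
  assert_that(length(scored) > 0, "no scored gene maps into the model")
  # upper-tail form keeps precision for very small p (1 - p would round to 1)
  z_of <- stats::setNames(stats::qnorm(gene_pvals[scored], lower.tail = FALSE),
                          scored)

  rxn_genes <- lapply(model$reactions, function(r)
    if (nzchar(r$gpr)) gpr_genes(parse_gpr(r$gpr)) else character(0))
  mets <- setdiff(model$metabolites$id, exclude)
  neigh <- lapply(stats::setNames(mets, mets), function(m) {
    adj <- vapply(model$reactions,
                  function(r) m %in% names(r$stoichiometry) &&
                    r$stoichiometry[[m]] != 0, logical(1))
    intersect(unique(unlist(rxn_genes[adj])), scored)
  })
  k_vec <- lengths(neigh)
  skipped <- names(neigh)[k_vec == 0]
  neigh <- neigh[k_vec > 0]; k_vec <- k_vec[k_vec > 0]
  assert_that(length(neigh) > 0, "no metabolite has scored neighbour genes")

  # background mean/sd of sum(Z)/sqrt(k) per distinct k, sampled from the
  # scored model genes (the algorithm's own background convention)
  bg <- with_seed(split_seed(seed, "reporter_bg"), {
    out <- list()
    for (k in sort(unique(k_vec))) {
      draws <- vapply(seq_len(n_background), function(i)
        sum(z_of[sample.int(length(z_of), k)]) / sqrt(k), numeric(1))
      out[[as.character(k)]] <- c(mu = mean(draws), sigma = stats::sd(draws))
    }
    out
  })
  z_raw <- vapply(neigh, function(g) sum(z_of[g]) / sqrt(length(g)),
                  numeric(1))
  z_corr <- vapply(seq_along(neigh), function(i) {
    b <- bg[[as.character(k_vec[i])]]
    # degenerate background (e.g. all gene evidence identical) has sd 0
    if (b[["sigma"]] == 0) {
      d <- z_raw[i] - b[["mu"]]
      if (d == 0) 0 else sign(d) * Inf
    } else (z_raw[i] - b[["mu"]]) / b[["sigma"]]
  }, numeric(1))
  out <- data.frame(metabolite = names(neigh), k = unname(k_vec),
                    z_raw = unname(z_raw), z_corrected = z_corr,
                    pval = 1 - stats::pnorm(z_corr),
                    stringsAsFactors = FALSE)
  out$fdr <- bh_adjust(out$pval)
  out <- out[order(-out$z_corrected), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Subsystem enrichment of DE-linked reactions
#'
#' The universe is every reaction with a non-empty GPR; a reaction is
#' DE-linked iff any gene in its rule is differentially expressed
#' (OR-collapse, see [evaluate_gpr]).  Each subsystem is tested with the
#' upper-tail hypergeometric against that universe, BH-corrected across
#' subsystems.  Subsystems with no GPR-bearing reactions are excluded.
#'
#' @param model a [pdmr_metabolic_model].
#' @param de_genes character vector of differentially expressed genes.
#' @return data.frame `subsystem`, `n_reactions`, `n_de_linked`, `pval`,
#'   `fdr`, sorted by p.
#' @export
subsystem_enrichment <- function(model, de_genes) {
  assert_that(length(intersect(de_genes, model$genes)) > 0,
              "no DE gene maps into the model")
  flags <- stats::setNames(rep(TRUE, length(de_genes)), de_genes)
  has_gpr <- vapply(model$reactions, function(r) nzchar(r$gpr), logical(1))
  uni <- model$reactions[has_gpr]
  linked <- vapply(uni, function(r) evaluate_gpr(r$gpr, flags), logical(1))
  subsystem <- vapply(uni, `[[`, "", "subsystem")
  n_u <- length(uni); n_link <- sum(linked)
  rows <- lapply(unique(subsystem), function(s) {
    in_s <- subsystem == s
    k <- sum(linked & in_s)
    data.frame(subsystem = s, n_reactions = sum(in_s), n_de_linked = k,
               pval = stats::phyper(k - 1, n_link, n_u - n_link, sum(in_s),
                                    lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$pval)
  out <- out[order(out$pval), ]
  rownames(out) <- NULL
  out
}

#' Run both PD-subtype contrasts through the reporter pipeline
#'
#' Applies [reporter_scores] and [subsystem_enrichment] to the
#' GBA1-associated and sporadic contrasts under one seed policy, then
#' labels every metabolite and subsystem `shared` (significant in both),
#' `GBA1_specific`, `sporadic_specific` or `neither` at the configured FDR.
#'
#' @param model a [pdmr_metabolic_model].
#' @param de_tables named list with elements `GBA1_PD` and `sporadic_PD`,
#'   each a data.frame `gene`, `pval`, `log2fc` (an `fdr` column is
#'   computed by BH when absent).
#' @param seed integer seed (shared by both contrasts).
#' @param fdr_threshold significance level for the comparison labels.
#' @param de_fdr_threshold,de_lfc_threshold thresholds defining the DE
#'   flags fed to the subsystem test.
#' @param n_background,exclude passed to [reporter_scores].
#' @return list with `reporter` and `subsystem` (named lists of per-contrast
#'   tables) plus `reporter_comparison` / `subsystem_comparison` label
#'   tables.
#' @export
run_contrasts <- function(model, de_tables, seed, fdr_threshold = 0.05,
                          de_fdr_threshold = 0.05, de_lfc_threshold = 1,
                          n_background = 10000, exclude = character(0)) {
  assert_that(all(c("GBA1_PD", "sporadic_PD") %in% names(de_tables)),
              "both contrasts (GBA1_PD, sporadic_PD) must be supplied")
  contrasts <- c("GBA1_PD", "sporadic_PD")
  rep_out <- list(); sub_out <- list()
  for (ct in contrasts) {
    tab <- de_tables[[ct]]
    if (!"fdr" %in% names(tab)) tab$fdr <- bh_adjust(tab$pval)
    pv <- stats::setNames(tab$pval, tab$gene)
    rep_out[[ct]] <- reporter_scores(model, pv, n_background = n_background,
                                     seed = seed, exclude = exclude)
    de <- tab$gene[tab$fdr < de_fdr_threshold &
                     abs(tab$log2fc) >= de_lfc_threshold]
    sub_out[[ct]] <- if (length(intersect(de, model$genes)))
      subsystem_enrichment(model, de)
    else data.frame(subsystem = character(0), n_reactions = integer(0),
                    n_de_linked = integer(0), pval = numeric(0),
                    fdr = numeric(0), stringsAsFactors = FALSE)
  }
  label_of <- function(a_sig, b_sig) ifelse(
    a_sig & b_sig, "shared",
    ifelse(a_sig, "GBA1_specific",
           ifelse(b_sig, "sporadic_specific", "neither")))
  cmp_tab <- function(tabs, key) {
    ids <- unique(c(tabs$GBA1_PD[[key]], tabs$sporadic_PD[[key]]))
    sig <- function(t) ids %in% t[[key]][t$fdr < fdr_threshold]
    data.frame(id = ids, label = label_of(sig(tabs$GBA1_PD),
                                          sig(tabs$sporadic_PD)),
               stringsAsFactors = FALSE)
  }
  list(reporter = rep_out, subsystem = sub_out,
       reporter_comparison = cmp_tab(rep_out, "metabolite"),
       subsystem_comparison = cmp_tab(sub_out, "subsystem"))
}
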