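#' Simulate multi-dataset case/control RNA-seq counts with planted DEGs
#'
#' Emulates a collection of independent transcriptomic datasets across the
#' three study conditions (Gaucher disease, GBA1-associated Parkinson's
#' disease, sporadic Parkinson's disease).  Counts follow a negative-binomial
#' model with log-normal gene-wise baseline means and a single dispersion;
#' a configurable fraction of genes is planted as differentially expressed,
#' either shared across all conditions (same direction everywhere) or
#' specific to one condition.  Every dataset carries a per-gene truth table.
#'
#' @param n_datasets datasets per condition (named vector or single number).
#' @param n_genes number of genes (>= 10).
#' @param n_case,n_control samples per arm in every dataset (>= 2 each).
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param frac_planted fraction of genes planted as DEGs, in `[0, 1]`.
#' @param frac_shared fraction of planted genes that are DE in all three
#'   conditions with a common direction; the rest are split evenly across
#'   conditions as condition-specific DEGs.
#' @param lfc absolute planted log2 fold change (case vs control).
#' @param base_mean_log,base_mean_sdlog meanlog/sdlog of the log-normal
#'   baseline expression means.
#' @param conditions condition labels.
#' @param seed integer master seed (required).
#' @return list of `pdmr_expr_dataset` objects, each with elements
#'   `dataset_id`, `condition`, `counts` (gene x sample integer matrix),
#'   `sample_labels` (factor case/control) and `truth` (data.frame with
#'   `gene`, `status` in up/down/null, `log2fc`).
#' @export
gen_expression_datasets <- function(n_datasets = 3, n_genes = 2000,
                                    n_case = 10, n_control = 10,
                                    dispersion = 0.1,
                                    frac_planted = 0.05, frac_shared = 0.5,
                                    lfc = 2,
                                    base_mean_log = log(100),
                                    base_mean_sdlog = 1,
                                    conditions = c("GD", "GBA1_PD", "sporadic_PD"),
                                    seed) {
  assert_that(!missing(seed), "gen_expression_datasets: seed is required")
  assert_that(n_genes >= 10, "n_genes must be >= 10")
  assert_that(n_case >= 2 && n_control >= 2,
              "need >= 2 samples per arm (got %d/%d)", n_case, n_control)
  assert_that(frac_planted >= 0 && frac_planted <= 1,
              "frac_planted must lie in [0, 1]")
  assert_that(dispersion > 0, "dispersion must be positive")
  if (length(n_datasets) == 1L)
    n_datasets <- stats::setNames(rep(n_datasets, length(conditions)), conditions)

  genes <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))

  # Plant the truth once, on the gene universe: shared genes are DE in every
  # condition with one common direction; specific genes in one condition only.
  plan <- with_seed(split_seed(seed, "plant"), {
    n_pl <- round(frac_planted * n_genes)
    planted <- sample(genes, n_pl)
    n_sh <- round(frac_shared * n_pl)
    shared <- planted[seq_len(n_sh)]
    specific <- planted[setdiff(seq_len(n_pl), seq_len(n_sh))]
    spec_cond <- if (length(specific))
      sample(rep(conditions, length.out = length(specific))) else character(0)
    dir_of <- stats::setNames(sample(c("up", "down"), n_pl, replace = TRUE), planted)
    truth <- lapply(stats::setNames(conditions, conditions), function(cond) {
      status <- stats::setNames(rep("null", n_genes), genes)
      status[shared] <- dir_of[shared]
      sp <- specific[spec_cond == cond]
      status[sp] <- dir_of[sp]
      status
    })
    list(truth = truth, shared = shared,
         specific = split(specific, factor(spec_cond, levels = conditions)),
         dir_of = dir_of)
  })

  base_mu <- with_seed(split_seed(seed, "mu"),
                       stats::rlnorm(n_genes, base_mean_log, base_mean_sdlog))
  names(base_mu) <- genes

  out <- list()
  for (cond in conditions) {
    status <- plan$truth[[cond]]
    lfc_vec <- ifelse(status == "up", lfc, ifelse(status == "down", -lfc, 0))
    for (d in seq_len(n_datasets[[cond]])) {
      id <- sprintf("%s_ds%d", cond, d)
      ds <- with_seed(split_seed(seed, paste0("counts:", id)), {
        n_s <- n_case + n_control
        labels <- factor(rep(c("case", "control"), c(n_case, n_control)),
                         levels = c("case", "control"))
        mu <- matrix(base_mu, n_genes, n_s)
        mu[, labels == "case"] <- mu[, labels == "case"] * 2^lfc_vec
        counts <- matrix(stats::rnbinom(n_genes * n_s, mu = mu,
                                        size = 1 / dispersion),
                         n_genes, n_s,
                         dimnames = list(genes, sprintf("%s_s%02d", id, 1:n_s)))
        list(counts = counts, labels = labels)
      })
      out[[id]] <- structure(list(
        dataset_id = id, condition = cond,
        counts = ds$counts, sample_labels = ds$labels,
        truth = data.frame(gene = genes, status = unname(status),
                           log2fc = unname(lfc_vec),
                           stringsAsFactors = FALSE)),
        class = "pdmr_expr_dataset")
    }
  }
  attr(out, "plan") <- plan
  out
}

#' Simulate paired cis-eQTL / GWAS summary statistics with known causal effects
#'
#' Generates, for each gene, an exposure study of cis-eQTL associations (on
#' the per-standard-deviation-of-expression scale) and one shared outcome
#' study of disease associations (log-odds scale), with a known per-gene
#' causal effect `theta`, optional invalid (pleiotropic) instruments and
#' declared LD blocks.  For a valid SNP j with true exposure effect b_j the
#' observed outcome effect is `theta * b_j + e`, `e ~ N(0, se_out^2)`;
#' invalid SNPs additionally receive a direct (pleiotropic) effect.
#'
#' Two pleiotropy constructions are supported and may be combined:
#' `pleiotropy_intercept`/`pleiotropy_sd` add a constant-plus-noise direct
#' effect to the outcome (the InSIDE-compatible construction the Egger
#' intercept detects), while `pleiotropy_shift` adds `shift * b_j`, i.e. a
#' constant shift of the invalid SNPs' Wald ratios (the construction used to
#' probe the weighted median's breakdown point).
#'
#' @param n_genes number of exposure genes.
#' @param n_snps instruments simulated per gene (>= 2).
#' @param theta true causal effect(s); scalar or length `n_genes`.
#' @param maf_range range the effect-allele frequency is drawn from
#'   (frequencies above 0.5 arise by allele labelling).
#' @param beta_exp_range range of absolute true exposure effects per allele,
#'   in SD-of-expression units.
#' @param beta_exp_sign `"increasing"` (default) codes every effect allele
#'   as the expression-increasing allele, the convention under which
#'   cis-eQTL instruments are extracted and the one required for a
#'   directional pleiotropy intercept to be identifiable by Egger
#'   regression after its non-negative orientation step; `"random"` draws
#'   signs at random.
#' @param n_exposure,n_case_out,n_control_out sample sizes governing the
#'   exposure SE and the (effective-n) outcome SE.
#' @param invalid_fraction fraction of SNPs per gene that are invalid.
#' @param pleiotropy_intercept,pleiotropy_sd mean and SD of the additive
#'   direct effect given to invalid SNPs.
#' @param pleiotropy_shift Wald-ratio shift given to invalid SNPs.
#' @param swap_fraction fraction of outcome records stored with effect/other
#'   alleles swapped (and the sign flipped), to exercise harmonisation.
#' @param ld_blocks optional list of blocks, each `list(snps = <indices into
#'   1..n_snps>, r2 = <value>)`, declared identically for every gene.
#' @param seed integer master seed (required).
#' @return list with `exposures` (list of `pdmr_sumstat_study`, one per
#'   gene), `outcome` (one `pdmr_sumstat_study` covering all SNPs), `ld`
#'   (data.frame `snp_a`, `snp_b`, `r2`) and `truth` (per-gene theta and
#'   per-SNP validity flags).
#' @export
gen_summary_stats <- function(n_genes = 1, n_snps = 50, theta = 0,
                              maf_range = c(0.1, 0.5),
                              beta_exp_range = c(0.05, 0.2),
                              n_exposure = 31684,
                              n_case_out = 33674, n_control_out = 482730,
                              invalid_fraction = 0,
                              pleiotropy_intercept = 0, pleiotropy_sd = 0,
                              pleiotropy_shift = 0,
                              beta_exp_sign = c("increasing", "random"),
                              swap_fraction = 0.3,
                              ld_blocks = NULL, seed) {
  beta_exp_sign <- match.arg(beta_exp_sign)
  assert_that(!missing(seed), "gen_summary_stats: seed is required")
  assert_that(n_snps >= 2, "n_snps must be >= 2 to exercise the estimators")
  assert_that(all(is.finite(theta)), "theta must be finite")
  assert_that(invalid_fraction >= 0 && invalid_fraction <= 1,
              "invalid_fraction must lie in [0, 1]")
  theta <- rep_len(theta, n_genes)
  gene_ids <- sprintf("gene%0*d", nchar(n_genes), seq_len(n_genes))
  n_eff_out <- 4 / (1 / n_case_out + 1 / n_control_out)

  exposures <- vector("list", n_genes)
  names(exposures) <- gene_ids
  out_records <- vector("list", n_genes)
  truth_valid <- vector("list", n_genes)

  for (g in seq_len(n_genes)) {
    sim <- with_seed(split_seed(seed, paste0("gene:", gene_ids[g])), {
      snp <- sprintf("%s_snp%0*d", gene_ids[g], nchar(n_snps), seq_len(n_snps))
      eaf <- stats::runif(n_snps, maf_range[1], maf_range[2])
      # effect/other alleles: two distinct bases; palindromic pairs can occur
      al <- t(vapply(seq_len(n_snps),
                     function(i) sample(c("A", "C", "G", "T"), 2),
                     character(2)))
      b_true <- stats::runif(n_snps, beta_exp_range[1], beta_exp_range[2])
      if (beta_exp_sign == "random")
        b_true <- b_true * sample(c(-1, 1), n_snps, replace = TRUE)
      se_exp <- 1 / sqrt(2 * eaf * (1 - eaf) * n_exposure)
      beta_exp <- b_true + stats::rnorm(n_snps, 0, se_exp)
      se_out <- 1 / sqrt(2 * eaf * (1 - eaf) * n_eff_out)
      n_inv <- round(invalid_fraction * n_snps)
      invalid <- seq_len(n_snps) %in% sample.int(n_snps, n_inv)
      alpha <- ifelse(invalid,
                      pleiotropy_intercept +
                        stats::rnorm(n_snps, 0, pleiotropy_sd) +
                        pleiotropy_shift * b_true,
                      0)
      beta_out <- theta[g] * b_true + alpha + stats::rnorm(n_snps, 0, se_out)
      swap <- stats::runif(n_snps) < swap_fraction
      list(snp = snp, eaf = eaf, al = al, beta_exp = beta_exp,
           se_exp = se_exp, beta_out = beta_out, se_out = se_out,
           invalid = invalid, swap = swap)
    })
    pv <- function(b, s) pmax(2 * stats::pnorm(-abs(b / s)),
                              .Machine$double.xmin)
    chr <- rep(1L, n_snps); pos <- seq_len(n_snps) * 1000L + g * 10L
    exposures[[g]] <- new_sumstat_study(
      study_id = paste0("eqtl_", gene_ids[g]), trait = gene_ids[g],
      records = data.frame(
        snp = sim$snp, chr = chr, pos = pos,
        effect_allele = sim$al[, 1], other_allele = sim$al[, 2],
        beta = sim$beta_exp, se = sim$se_exp,
        pval = pv(sim$beta_exp, sim$se_exp),
        eaf = sim$eaf, n = n_exposure, stringsAsFactors = FALSE))
    out_records[[g]] <- data.frame(
      snp = sim$snp, chr = chr, pos = pos,
      effect_allele = ifelse(sim$swap, sim$al[, 2], sim$al[, 1]),
      other_allele = ifelse(sim$swap, sim$al[, 1], sim$al[, 2]),
      beta = ifelse(sim$swap, -sim$beta_out, sim$beta_out),
      se = sim$se_out, pval = pv(sim$beta_out, sim$se_out),
      eaf = ifelse(sim$swap, 1 - sim$eaf, sim$eaf),
      n = n_case_out + n_control_out, stringsAsFactors = FALSE)
    truth_valid[[g]] <- stats::setNames(!sim$invalid, sim$snp)
  }

  ld <- data.frame(snp_a = character(0), snp_b = character(0),
                   r2 = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(ld_blocks)) {
    for (g in seq_len(n_genes)) {
      snp <- exposures[[g]]$records$snp
      for (bl in ld_blocks) {
        idx <- bl$snps
        prs <- utils::combn(idx, 2)
        ld <- rbind(ld, data.frame(snp_a = snp[prs[1, ]], snp_b = snp[prs[2, ]],
                                   r2 = bl$r2, stringsAsFactors = FALSE))
      }
    }
  }

  outcome <- new_sumstat_study(study_id = "pd_gwas", trait = "PD",
                               records = do.call(rbind, out_records))
  list(exposures = exposures, outcome = outcome, ld = ld,
       truth = list(theta = stats::setNames(theta, gene_ids),
                    valid = truth_valid))
}

# Constructor + invariant check for a summary-statistic study.
new_sumstat_study <- function(study_id, trait, records) {
  needed <- c("snp", "chr", "pos", "effect_allele", "other_allele",
              "beta", "se", "pval", "eaf", "n")
  assert_that(all(needed %in% names(records)),
              "summary-statistic records missing columns: %s",
              paste(setdiff(needed, names(records)), collapse = ", "))
  assert_that(all(records$eaf > 0 & records$eaf < 1), "eaf must lie in (0, 1)")
  assert_that(all(records$se > 0), "se must be positive")
  assert_that(all(records$pval > 0 & records$pval <= 1),
              "pval must lie in (0, 1]")
  assert_that(all(records$effect_allele %in% c("A", "C", "G", "T") &
                    records$other_allele %in% c("A", "C", "G", "T")),
              "alleles must be single bases in A/C/G/T")
  structure(list(study_id = study_id, trait = trait, records = records),
            class = "pdmr_sumstat_study")
}

#' Simulate labelled case/control expression for classifier evaluation
#'
#' Gaussian expression on `n_case + n_control` samples by `n_genes` genes;
#' the named genes in `informative` have their case-arm mean shifted by the
#' given effect (in the same units as `noise_sd`), all other genes are pure
#' noise.  The closed-form univariable AUC for a shifted gene is
#' `pnorm(effect / (noise_sd * sqrt(2)))`.
#'
#' @param n_genes number of genes.
#' @param n_case,n_control samples per class (>= 1 each).
#' @param informative named numeric vector, gene -> case-minus-control mean
#'   shift; names must be gene ids (`g1`, ... by default) or NULL for a pure
#'   noise matrix.
#' @param noise_sd within-class standard deviation.
#' @param seed integer master seed (required).
#' @return list with `x` (samples x genes matrix), `labels` (factor
#'   case/control) and `truth` (data.frame `gene`, `effect`).
#' @export
gen_case_control_expression <- function(n_genes = 20, n_case = 50,
                                        n_control = 50, informative = NULL,
                                        noise_sd = 1, seed) {
  assert_that(!missing(seed), "gen_case_control_expression: seed is required")
  assert_that(n_case >= 1 && n_control >= 1,
              "need at least one case and one control")
  genes <- sprintf("g%d", seq_len(n_genes))
  effect <- stats::setNames(rep(0, n_genes), genes)
  if (!is.null(informative) && length(informative)) {
    assert_that(!is.null(names(informative)) &&
                  all(names(informative) %in% genes),
                "informative genes must name genes present in the matrix")
    effect[names(informative)] <- informative
  }
  x <- with_seed(split_seed(seed, "casecontrol"), {
    n_s <- n_case + n_control
    m <- matrix(stats::rnorm(n_s * n_genes, 0, noise_sd), n_s, n_genes,
                dimnames = list(sprintf("s%03d", seq_len(n_s)), genes))
    m[seq_len(n_case), ] <- m[seq_len(n_case), ] +
      matrix(effect, n_case, n_genes, byrow = TRUE)
    m
  })
  labels <- factor(rep(c("case", "control"), c(n_case, n_control)),
                   levels = c("case", "control"))
  list(x = x, labels = labels,
       truth = data.frame(gene = genes, effect = unname(effect),
                          stringsAsFactors = FALSE))
}

#' Simulate a toy genome-scale metabolic model with a planted hotspot
#'
#' Builds a small connected stoichiometric network with one-gene-per-clause
#' boolean GPR rules and subsystem labels, plants one "hot" metabolite whose
#' neighbouring reactions' genes receive small p-values (signal drawn from
#' `Uniform(0, 1/contrast)`) while background genes draw from `Uniform(0,1)`.
#' The hotspot reactions share the subsystem label `"planted_pathway"`.
#'
#' @param n_metabolites number of metabolites (>= 3).
#' @param n_reactions number of reactions (must cover the connectivity chain:
#'   `n_reactions >= n_metabolites - 1 + hotspot_size`).
#' @param genes_per_reaction genes in each reaction's GPR (joined by `or`).
#' @param hotspot_size number of reactions adjacent to the planted metabolite.
#' @param contrast signal strength; signal p-values are drawn from
#'   `Uniform(0, 1/contrast)`, so `contrast = 1` means no signal.
#' @param n_subsystems number of background subsystem labels.
#' @param seed integer master seed (required).
#' @return list with `model` (a [pdmr_metabolic_model]), `gene_pvals`
#'   (named numeric) and `truth` (`hot_metabolite`, `hotspot_genes`,
#'   `hotspot_reactions`).
#' @export
gen_toy_metabolic_model <- function(n_metabolites = 20, n_reactions = 30,
                                    genes_per_reaction = 2, hotspot_size = 4,
                                    contrast = 1000, n_subsystems = 4, seed) {
  assert_that(!missing(seed), "gen_toy_metabolic_model: seed is required")
  assert_that(n_metabolites >= 3, "need >= 3 metabolites")
  assert_that(hotspot_size >= 1 && hotspot_size <= n_reactions,
              "hotspot_size must lie in [1, n_reactions]")
  n_chain <- n_metabolites - 1
  assert_that(n_reactions >= n_chain + hotspot_size,
              "n_reactions too small for a connected network plus hotspot")
  mets <- sprintf("m%02d", seq_len(n_metabolites))
  with_seed(split_seed(seed, "toymodel"), {
    hot <- mets[1]
    rxn_pairs <- list()
    # hotspot: reactions consuming the hot metabolite
    for (i in seq_len(hotspot_size))
      rxn_pairs[[length(rxn_pairs) + 1L]] <-
        c(hot, sample(mets[-1], 1))
    # connectivity chain over every metabolite
    for (i in seq_len(n_chain))
      rxn_pairs[[length(rxn_pairs) + 1L]] <- c(mets[i], mets[i + 1])
    # random extra edges
    while (length(rxn_pairs) < n_reactions)
      rxn_pairs[[length(rxn_pairs) + 1L]] <- sample(mets[-1], 2)
    n_genes <- n_reactions * genes_per_reaction
    genes <- sprintf("tg%03d", seq_len(n_genes))
    gene_of_rxn <- split(genes, rep(seq_len(n_reactions),
                                    each = genes_per_reaction))
    subsys_bg <- sprintf("pathway_%d", seq_len(n_subsystems))
    reactions <- lapply(seq_len(n_reactions), function(i) {
      list(id = sprintf("r%03d", i),
           stoichiometry = stats::setNames(c(-1, 1), rxn_pairs[[i]]),
           gpr = paste(gene_of_rxn[[i]], collapse = " or "),
           subsystem = if (i <= hotspot_size) "planted_pathway"
                       else sample(subsys_bg, 1))
    })
    model <- new_metabolic_model(
      metabolites = data.frame(id = mets, name = mets, compartment = "c",
                               stringsAsFactors = FALSE),
      reactions = reactions, genes = genes)
    hot_rxns <- vapply(model$reactions,
                       function(r) hot %in% names(r$stoichiometry),
                       logical(1))
    hotspot_genes <- unique(unlist(gene_of_rxn[hot_rxns]))
    p <- stats::setNames(stats::runif(n_genes), genes)
    p[hotspot_genes] <- stats::runif(length(hotspot_genes)) / contrast
    p <- pmax(p, .Machine$double.xmin)
    list(model = model, gene_pvals = p,
         truth = list(hot_metabolite = hot, hotspot_genes = hotspot_genes,
                      hotspot_reactions = vapply(model$reactions[hot_rxns],
                                                 `[[`, "", "id")))
  })
}
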