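#' Select cis-eQTL instruments for one gene
#'
#' Filters an exposure study's records to valid instruments, in order:
#' association p-value, minor allele frequency, instrument strength
#' (F = beta^2 / se^2), then greedy LD pruning (sort by p ascending, keep a
#' SNP iff its declared r-squared with every already-kept SNP is below the
#' threshold; SNP pairs absent from the LD table are assumed independent).
#' Every exclusion is recorded in a provenance log.  The filter order is a
#' package convention (chosen so the pruner only sees eligible SNPs) and is
#' fully auditable through the log.
#'
#' @param exposure a `pdmr_sumstat_study` for one gene (exposure side).
#' @param ld data.frame `snp_a`, `snp_b`, `r2` of declared LD; may be empty.
#' @param p_threshold association p-value cutoff (default 5e-6).
#' @param r2_threshold LD pruning cutoff (default 0.3, exclusive).
#' @param maf_threshold minor-allele-frequency cutoff (default 0.01,
#'   exclusive: MAF must exceed it).
#' @param f_threshold instrument-strength cutoff (default 10, exclusive).
#' @return a `pdmr_instrument_set`: list with `gene_id`, `snps` (retained
#'   records with an `f_stat` column), `provenance` (data.frame `snp`,
#'   `stage`, `reason`), and `status` (`"ok"` or
#'   `"insufficient_instruments"` when fewer than two SNPs survive).
#' @export
select_instruments <- function(exposure, ld = NULL, p_threshold = 5e-6,
                               r2_threshold = 0.3, maf_threshold = 0.01,
                               f_threshold = 10) {
  rec <- exposure$records
  log <- data.frame(snp = character(0), stage = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  drop <- function(snps, stage, reason) {
    if (length(snps))
      log <<- rbind(log, data.frame(snp = snps, stage = stage,
                                    reason = reason, stringsAsFactors = FALSE))
  }
  fail <- rec$pval >= p_threshold
  drop(rec$snp[fail], "pval", sprintf("p >= %g", p_threshold))
  rec <- rec[!fail, , drop = FALSE]

  maf <- pmin(rec$eaf, 1 - rec$eaf)
  fail <- maf <= maf_threshold
  drop(rec$snp[fail], "maf", sprintf("MAF <= %g", maf_threshold))
  rec <- rec[!fail, , drop = FALSE]

  f_stat <- (rec$beta / rec$se)^2
  fail <- f_stat <= f_threshold
  drop(rec$snp[fail], "f_stat", sprintf("F <= %g", f_threshold))
  rec <- rec[!fail, , drop = FALSE]
  rec$f_stat <- f_stat[!fail]

  # greedy LD pruning, strongest association first
  if (nrow(rec) > 1) {
    r2_of <- ld_lookup(ld)
    ord <- order(rec$pval)
    kept <- integer(0)
    for (i in ord) {
      r2s <- vapply(kept, function(j) r2_of(rec$snp[i], rec$snp[j]), numeric(1))
      if (all(r2s < r2_threshold)) kept <- c(kept, i)
      else drop(rec$snp[i], "ld",
                sprintf("r2 >= %g with %s", r2_threshold,
                        rec$snp[kept[which(r2s >= r2_threshold)[1]]]))
    }
    rec <- rec[sort(kept), , drop = FALSE]
  }
  rownames(rec) <- NULL
  structure(list(gene_id = exposure$trait, snps = rec, provenance = log,
                 status = if (nrow(rec) >= 2) "ok"
                          else "insufficient_instruments"),
            class = "pdmr_instrument_set")
}

# Closure returning declared r2 for a SNP pair (0 when undeclared).
ld_lookup <- function(ld) {
  if (is.null(ld) || nrow(ld) == 0) return(function(a, b) 0)
  keys <- c(paste(ld$snp_a, ld$snp_b, sep = "\r"),
            paste(ld$snp_b, ld$snp_a, sep = "\r"))
  vals <- c(ld$r2, ld$r2)
  env <- new.env(parent = emptyenv(), size = length(keys))
  for (i in seq_along(keys)) assign(keys[i], vals[i], envir = env)
  function(a, b) {
    v <- mget(paste(a, b, sep = "\r"), envir = env, ifnotfound = 0)[[1]]
    v
  }
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Harmonise exposure instruments against outcome summary statistics
#'
#' Aligns each instrument's outcome record to the exposure's effect allele:
#' exact allele matches are kept as-is, swapped alleles flip the outcome
#' beta and allele frequency, complementary-strand records are complemented
#' then aligned.  Palindromic (A/T, C/G) SNPs are excluded when the
#' exposure minor allele frequency exceeds `palindrome_maf_threshold`
#' (their strand cannot be resolved); retained palindromic SNPs are
#' oriented by comparing exposure and outcome allele frequencies.  SNPs
#' whose outcome association is both genome-wide suggestive
#' (`pval_out < outcome_p_threshold`) and stronger than their exposure
#' association are excluded as reverse-causation candidates.  SNPs absent
#' from the outcome are dropped with a logged count.
#'
#' Harmonisation is idempotent: re-running it on its own retained records
#' (whose alleles are reported in exposure orientation) changes nothing.
#'
#' @param instruments a `pdmr_instrument_set` from [select_instruments].
#' @param outcome a `pdmr_sumstat_study` (outcome side).
#' @param palindrome_maf_threshold exposure-MAF cutoff above which
#'   palindromic SNPs are dropped (default 0.42).
#' @param outcome_p_threshold reverse-causation outcome p cutoff
#'   (default 5e-6).
#' @param reverse_causation_filter,palindrome_filter toggles for the two
#'   exclusion rules.
#' @return data.frame of harmonised instruments with columns `snp`,
#'   `effect_allele`, `other_allele` (exposure orientation), `beta_exp`,
#'   `se_exp`, `pval_exp`, `eaf_exp`, `beta_out`, `se_out`, `pval_out`,
#'   `eaf_out`, `f_stat`, `action` (`kept` or `flipped`); attribute
#'   `exclusions` logs every excluded SNP with its reason, attribute
#'   `gene_id` carries the gene.
#' @export
harmonise <- function(instruments, outcome, palindrome_maf_threshold = 0.42,
                      outcome_p_threshold = 5e-6,
                      reverse_causation_filter = TRUE,
                      palindrome_filter = TRUE) {
  exp_rec <- instruments$snps
  out_rec <- outcome$records
  idx <- match(exp_rec$snp, out_rec$snp)
  excl <- data.frame(snp = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(exp_rec))) {
    e <- exp_rec[i, ]
    if (is.na(idx[i])) {
      excl <- rbind(excl, data.frame(snp = e$snp, reason = "absent_from_outcome"))
      next
    }
    o <- out_rec[idx[i], ]
    e_eff <- e$effect_allele; e_oth <- e$other_allele
    o_eff <- o$effect_allele; o_oth <- o$other_allele
    pal <- is_palindromic(e_eff, e_oth)
    action <- NULL
    if (pal) {
      maf <- min(e$eaf, 1 - e$eaf)   # exposure EAF governs
      if (palindrome_filter && maf > palindrome_maf_threshold) {
        excl <- rbind(excl, data.frame(
          snp = e$snp, reason = sprintf("palindromic_maf_%.3f", maf)))
        next
      }
      same_pair <- (o_eff == e_eff && o_oth == e_oth) ||
        (o_eff == e_oth && o_oth == e_eff)
      if (!same_pair) {
        excl <- rbind(excl, data.frame(snp = e$snp, reason = "allele_mismatch"))
        next
      }
      # orient by allele frequency: both studies should agree on which
      # allele is minor once aligned
      action <- if ((e$eaf - 0.5) * (o$eaf - 0.5) < 0) "flipped" else "kept"
    } else {
      if (o_eff == e_eff && o_oth == e_oth) action <- "kept"
      else if (o_eff == e_oth && o_oth == e_eff) action <- "flipped"
      else {
        oc_eff <- unname(COMPLEMENT[o_eff]); oc_oth <- unname(COMPLEMENT[o_oth])
        if (oc_eff == e_eff && oc_oth == e_oth) action <- "kept"
        else if (oc_eff == e_oth && oc_oth == e_eff) action <- "flipped"
        else {
          excl <- rbind(excl, data.frame(snp = e$snp, reason = "allele_mismatch"))
          next
        }
      }
    }
    beta_out <- if (action == "flipped") -o$beta else o$beta
    eaf_out <- if (action == "flipped") 1 - o$eaf else o$eaf
    if (reverse_causation_filter &&
        o$pval < outcome_p_threshold && o$pval < e$pval) {
      excl <- rbind(excl, data.frame(snp = e$snp, reason = "reverse_causation"))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      snp = e$snp, effect_allele = e_eff, other_allele = e_oth,
      beta_exp = e$beta, se_exp = e$se, pval_exp = e$pval, eaf_exp = e$eaf,
      beta_out = beta_out, se_out = o$se, pval_out = o$pval,
      eaf_out = eaf_out,
      f_stat = if ("f_stat" %in% names(e)) e$f_stat else (e$beta / e$se)^2,
      action = action, stringsAsFactors = FALSE)
  }
  h <- if (length(rows)) do.call(rbind, rows) else data.frame(
    snp = character(0), effect_allele = character(0),
    other_allele = character(0), beta_exp = numeric(0), se_exp = numeric(0),
    pval_exp = numeric(0), eaf_exp = numeric(0), beta_out = numeric(0),
    se_out = numeric(0), pval_out = numeric(0), eaf_out = numeric(0),
    f_stat = numeric(0), action = character(0), stringsAsFactors = FALSE)
  rownames(h) <- NULL
  attr(h, "exclusions") <- excl
  attr(h, "gene_id") <- instruments$gene_id
  class(h) <- c("pdmr_harmonised", "data.frame")
  h
}

# Rebuild study/instrument-set views of a harmonised table, used for the
# idempotence property and by callers that already hold aligned records.
harmonised_as_instruments <- function(h) {
  structure(list(
    gene_id = attr(h, "gene_id"),
    snps = data.frame(snp = h$snp, chr = NA_integer_, pos = NA_integer_,
                      effect_allele = h$effect_allele,
                      other_allele = h$other_allele, beta = h$beta_exp,
                      se = h$se_exp, pval = h$pval_exp, eaf = h$eaf_exp,
                      n = NA_real_, f_stat = h$f_stat,
                      stringsAsFactors = FALSE),
    provenance = data.frame(snp = character(0), stage = character(0),
                            reason = character(0)),
    status = if (nrow(h) >= 2) "ok" else "insufficient_instruments"),
    class = "pdmr_instrument_set")
}

harmonised_as_outcome <- function(h, study_id = "outcome") {
  new_sumstat_study(study_id, "outcome", data.frame(
    snp = h$snp, chr = 1L, pos = seq_len(nrow(h)),
    effect_allele = h$effect_allele, other_allele = h$other_allele,
    beta = h$beta_out, se = h$se_out, pval = h$pval_out, eaf = h$eaf_out,
    n = NA_real_, stringsAsFactors = FALSE))
}
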