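#' Per-gene differential expression on a synthetic dataset
#'
#' A deliberately simple internal test used only for synthetic data: Welch's
#' t-test per gene on `log2(CPM + 1)` with Benjamini-Hochberg adjustment.
#' Real-data users supply externally produced differential-expression tables
#' (one per dataset) instead; cross-platform meta-analysis of merged
#' matrices is deliberately avoided, matching the dataset-specific design of
#' the source studies.
#'
#' @param dataset a `pdmr_expr_dataset` (see [gen_expression_datasets]),
#'   or any list with `counts`, `sample_labels`, `dataset_id`, `condition`.
#' @return a `DeTable` data.frame with columns `gene`, `log2fc` (case minus
#'   control mean on the log2 scale), `pval`, `fdr`; attributes `dataset_id`
#'   and `condition`.  Genes with zero variance in both arms get `pval = 1`.
#' @export
differential_expression <- function(dataset) {
  counts <- dataset$counts
  labels <- dataset$sample_labels
  assert_that(sum(labels == "case") >= 2 && sum(labels == "control") >= 2,
              "differential_expression needs >= 2 samples per arm")
  libsize <- colSums(counts)
  assert_that(all(libsize > 0), "library with zero total counts")
  logcpm <- log2(sweep(counts, 2, libsize / 1e6, "/") + 1)
  a <- logcpm[, labels == "case", drop = FALSE]
  b <- logcpm[, labels == "control", drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  sed2 <- va / na + vb / nb
  t_stat <- (ma - mb) / sqrt(sed2)
  # Welch-Satterthwaite df
  df <- sed2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  pval <- 2 * stats::pt(-abs(t_stat), df)
  pval[!is.finite(t_stat) | sed2 == 0] <- 1   # zero-variance genes
  out <- data.frame(gene = rownames(counts), log2fc = ma - mb,
                    pval = pval, fdr = bh_adjust(pval),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "dataset_id") <- dataset$dataset_id
  attr(out, "condition") <- dataset$condition
  out
}

#' Call differentially expressed genes from a DE table
#'
#' A pure threshold filter: a gene is a DEG iff `fdr < fdr_threshold` and
#' `|log2fc| >= lfc_threshold`, tagged up or down by the sign of its fold
#' change.
#'
#' @param table DE table (data.frame with `gene`, `log2fc`, `pval`, `fdr`);
#'   attributes `dataset_id`/`condition` are carried through if present.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param lfc_threshold minimum absolute log2 fold change (default 1).
#' @return data.frame of `DegRecord`s: `gene`, `dataset_id`, `condition`,
#'   `direction` (up/down), `log2fc`, `fdr`.
#' @export
call_degs <- function(table, fdr_threshold = 0.05, lfc_threshold = 1) {
  assert_that(fdr_threshold > 0 && lfc_threshold > 0,
              "thresholds must be positive")
  keep <- table$fdr < fdr_threshold & abs(table$log2fc) >= lfc_threshold
  hits <- table[keep, , drop = FALSE]
  n <- nrow(hits)
  data.frame(gene = hits$gene,
             dataset_id = rep_len(attr(table, "dataset_id") %||%
                                    NA_character_, n),
             condition = rep_len(attr(table, "condition") %||%
                                   NA_character_, n),
             direction = ifelse(hits$log2fc > 0, "up", "down"),
             log2fc = hits$log2fc, fdr = hits$fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Shared, directionally concordant DEGs per condition
#'
#' A gene enters a condition's shared set iff it is called a DEG with the
#' same direction in at least `min_datasets` of that condition's datasets.
#' A gene that qualifies in two or more datasets but shows the opposite
#' direction in any other qualifying dataset of the same condition is
#' excluded (strict concordance).
#'
#' @param deg_lists list of DegRecord data.frames (one per dataset, from
#'   [call_degs]).
#' @param condition_map named character vector, dataset_id -> condition;
#'   defaults to the `condition` column carried in the records.
#' @param min_datasets minimum supporting datasets (default 2).
#' @return named list of `SharedDegSet`s, one per condition: each a
#'   data.frame `gene`, `direction`, `n_support`, `datasets`
#'   (comma-separated supporting dataset ids).  A condition with fewer
#'   datasets than `min_datasets` yields an empty set with a warning.
#' @export
shared_degs <- function(deg_lists, condition_map = NULL, min_datasets = 2) {
  recs <- do.call(rbind, deg_lists)
  all_ids <- unique(unlist(lapply(deg_lists, function(d)
    unique(d$dataset_id))))
  if (!is.null(condition_map)) {
    assert_that(all(all_ids %in% names(condition_map) | is.na(all_ids)),
                "every dataset must be mapped to exactly one condition")
    recs$condition <- unname(condition_map[recs$dataset_id])
    conds <- unique(unname(condition_map))
    n_ds_cond <- table(factor(unname(condition_map), levels = conds))
  } else {
    conds <- unique(recs$condition)
    # number of datasets per condition as seen in the supplied lists
    ds_cond <- unique(data.frame(
      d = unlist(lapply(deg_lists, function(d) d$dataset_id[1])),
      c = unlist(lapply(deg_lists, function(d) d$condition[1]))))
    n_ds_cond <- table(factor(ds_cond$c, levels = conds))
  }
  out <- list()
  for (cond in conds) {
    if (n_ds_cond[[cond]] < min_datasets) {
      warning(sprintf(
        "condition '%s' has %d dataset(s) < min_datasets = %d; empty set",
        cond, n_ds_cond[[cond]], min_datasets))
      out[[cond]] <- empty_shared_set(cond)
      next
    }
    rc <- recs[recs$condition == cond, , drop = FALSE]
    if (!nrow(rc)) { out[[cond]] <- empty_shared_set(cond); next }
    rows <- lapply(split(rc, rc$gene), function(gr) {
      n_up <- sum(gr$direction == "up"); n_dn <- sum(gr$direction == "down")
      if (n_up > 0 && n_dn > 0) return(NULL)        # direction conflict
      if (nrow(gr) < min_datasets) return(NULL)
      data.frame(gene = gr$gene[1], direction = gr$direction[1],
                 n_support = nrow(gr),
                 datasets = paste(sort(gr$dataset_id), collapse = ","),
                 stringsAsFactors = FALSE)
    })
    set <- do.call(rbind, rows)
    set <- if (is.null(set)) empty_shared_set(cond)
           else set[order(set$gene), , drop = FALSE]
    attr(set, "condition") <- cond
    rownames(set) <- NULL
    out[[cond]] <- set
  }
  out
}

empty_shared_set <- function(cond) {
  s <- data.frame(gene = character(0), direction = character(0),
                  n_support = integer(0), datasets = character(0),
                  stringsAsFactors = FALSE)
  attr(s, "condition") <- cond
  s
}

#' Pairwise and three-way concordant gene sets across conditions
#'
#' A gene enters a condition pair's set iff it is present in both
#' conditions' shared sets with identical direction; the three-way set is
#' the analogous intersection over all conditions.
#'
#' @param sets named list of SharedDegSets (from [shared_degs]).
#' @return list with one element per condition pair (named `"A|B"`) plus
#'   `"all"` for the full intersection; each a data.frame `gene`,
#'   `direction`, `datasets` (supporting datasets from every member
#'   condition, concatenated).
#' @export
pairwise_concordant <- function(sets) {
  assert_that(length(sets) >= 2, "need at least two condition sets")
  conds <- names(sets)
  intersect_sets <- function(members) {
    base <- sets[[members[1]]]
    keep <- base[, c("gene", "direction"), drop = FALSE]
    support <- stats::setNames(as.list(base$datasets), base$gene)
    for (m in members[-1]) {
      s <- sets[[m]]
      i <- match(keep$gene, s$gene)
      ok <- !is.na(i) & s$direction[i] == keep$direction
      matched <- i[ok]
      keep <- keep[ok, , drop = FALSE]
      support <- support[keep$gene]
      support <- Map(paste, support, s$datasets[matched], MoreArgs = list(sep = ","))
    }
    data.frame(gene = keep$gene, direction = keep$direction,
               datasets = unlist(support, use.names = FALSE) %||% character(0),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- list()
  prs <- utils::combn(conds, 2, simplify = FALSE)
  for (p in prs) out[[paste(p, collapse = "|")]] <- intersect_sets(p)
  if (length(conds) > 2) out[["all"]] <- intersect_sets(conds)
  out
}

#' Read / write DE tables and shared sets
#'
#' DE tables are TSV with header `gene log2fc pval fdr`; shared sets are TSV
#' with header `gene direction n_support datasets`.
#'
#' @param path file path.
#' @param dataset_id,condition metadata attached to a read DE table.
#' @return data.frame.
#' @export
read_de_table <- function(path, dataset_id = NA_character_,
                          condition = NA_character_) {
  x <- read_tsv_strict(path)
  assert_that(all(c("gene", "log2fc", "pval", "fdr") %in% names(x)),
              "DE table must have columns gene/log2fc/pval/fdr")
  attr(x, "dataset_id") <- dataset_id
  attr(x, "condition") <- condition
  x
}
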