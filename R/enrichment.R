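#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name description
#' member...`.  Duplicate members within a set are dropped.
#'
#' @param path GMT file.
#' @param universe background gene vector (e.g. the union of genes tested
#'   in the contributing DE tables).
#' @return a `GeneSetCollection`: list with `sets` (named list of member
#'   vectors) and `universe`.
#' @export
read_gmt <- function(path, universe) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f)
    unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  gene_set_collection(sets, universe)
}

#' @rdname read_gmt
#' @param sets named list of member gene vectors.
#' @export
gene_set_collection <- function(sets, universe) {
  assert_that(length(universe) > 0, "universe must be non-empty")
  universe <- unique(universe)
  structure(list(sets = lapply(sets, unique), universe = universe),
            class = "pdmr_gene_sets")
}

#' Over-representation analysis with the exact hypergeometric tail
#'
#' One-sided (enrichment-only) test per gene set: the p-value is the exact
#' upper-tail hypergeometric probability of observing at least the attained
#' overlap when `query_size` genes are drawn from the universe, equivalent
#' to a one-sided Fisher exact test.  Gene ratio is overlap over query size
#' (overlap divided by the total number of query genes).  Query genes
#' outside the universe are dropped with a message; set members outside the
#' universe are ignored.
#'
#' @param query character vector of query genes (e.g. a shared DEG set).
#' @param collection a `GeneSetCollection` ([gene_set_collection]).
#' @return data.frame sorted by p: `set_name`, `overlap_count`, `set_size`,
#'   `query_size`, `universe_size`, `pval`, `fdr`, `gene_ratio`,
#'   `overlap_genes` (comma-separated).
#' @export
overrepresentation_test <- function(query, collection) {
  universe <- collection$universe
  dropped <- setdiff(query, universe)
  if (length(dropped))
    message(sprintf("overrepresentation_test: %d query gene(s) outside the universe dropped",
                    length(dropped)))
  query <- intersect(unique(query), universe)
  assert_that(length(query) > 0, "query empty after universe intersection")
  n_u <- length(universe); n_q <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe)
    ov <- intersect(query, members)
    k <- length(ov); m <- length(members)
    # P(X >= k), X ~ Hypergeometric(m successes, n_u - m failures, n_q draws)
    p <- stats::phyper(k - 1, m, n_u - m, n_q, lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = k, set_size = m,
               query_size = n_q, universe_size = n_u, pval = p,
               gene_ratio = k / n_q,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$pval)
  out <- out[order(out$pval), c("set_name", "overlap_count", "set_size",
                                "query_size", "universe_size", "pval", "fdr",
                                "gene_ratio", "overlap_genes")]
  rownames(out) <- NULL
  out
}
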