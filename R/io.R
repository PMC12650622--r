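#' Write / read a summary-statistic study as TSV
#'
#' Header: `snp chr pos effect_allele other_allele beta se pval eaf n`.
#'
#' @param study a `pdmr_sumstat_study`.
#' @param path file path.
#' @return `path` invisibly (write) or a `pdmr_sumstat_study` (read).
#' @export
write_sumstat_study <- function(study, path) {
  write_tsv_strict(study$records, path)
}

#' @rdname write_sumstat_study
#' @param study_id,trait metadata for the study being read.
#' @export
read_sumstat_study <- function(path, study_id = basename(path),
                               trait = study_id) {
  new_sumstat_study(study_id, trait, read_tsv_strict(path))
}

#' Write an expression dataset to disk
#'
#' Counts as CSV (genes x samples), sample sheet as TSV (`sample label`),
#' truth as TSV.
#'
#' @param dataset a `pdmr_expr_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_expression_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$counts,
                   file.path(dir, paste0(dataset$dataset_id, "_counts.csv")))
  write_tsv_strict(
    data.frame(sample = colnames(dataset$counts),
               label = as.character(dataset$sample_labels)),
    file.path(dir, paste0(dataset$dataset_id, "_samples.tsv")))
  write_tsv_strict(dataset$truth,
                   file.path(dir, paste0(dataset$dataset_id, "_truth.tsv")))
  invisible(dir)
}

#' Read an expression dataset written by [write_expression_dataset]
#'
#' @param dir directory holding the three files.
#' @param dataset_id dataset identifier (file prefix).
#' @param condition condition label.
#' @return a `pdmr_expr_dataset`.
#' @export
read_expression_dataset <- function(dir, dataset_id,
                                    condition = NA_character_) {
  counts <- as.matrix(utils::read.csv(
    file.path(dir, paste0(dataset_id, "_counts.csv")), row.names = 1,
    check.names = FALSE))
  sheet <- read_tsv_strict(file.path(dir, paste0(dataset_id, "_samples.tsv")))
  truth_path <- file.path(dir, paste0(dataset_id, "_truth.tsv"))
  truth <- if (file.exists(truth_path)) read_tsv_strict(truth_path) else NULL
  structure(list(dataset_id = dataset_id, condition = condition,
                 counts = counts,
                 sample_labels = factor(sheet$label,
                                        levels = c("case", "control")),
                 truth = truth),
            class = "pdmr_expr_dataset")
}
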