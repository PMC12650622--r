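#' @keywords internal
"_PACKAGE"

# All generators and resampling procedures draw their randomness from one
# integer master seed.  Child seeds are derived deterministically from
# (seed, key) so pipeline stages can be re-run in isolation yet remain
# byte-reproducible.  Kept below 2^31 - 1 (R integers are 32-bit).
split_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(as.character(key))
  h <- as.double(seed %% 2147483647)
  for (ch in chars) h <- (h * 31 + ch) %% 2147483647
  as.integer(h %% 2147483563 + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pdmr <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) if (!isTRUE(cond)) stop_pdmr(...)

# Benjamini-Hochberg, NA-tolerant (NAs propagate, others corrected among
# themselves) -- thin wrapper so the adjustment used package-wide is one call.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Read a tab-separated table with a header
#'
#' All on-disk interchange in this package is plain TSV; this helper pins
#' the options (no factors, no quoting surprises) in one place.
#'
#' @param path file path.
#' @return data.frame
#' @export
read_tsv_strict <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a data.frame as TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_strict <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
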