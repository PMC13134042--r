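## Shared tabular IO. Every output file carries `# key=value` header lines
## recording the parameters and seed of the run that produced it; readers
## skip any leading comment lines.

#' Write a data frame as tab-separated values with a parameter header
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param params Optional named list; each entry becomes a `# key=value`
#'   comment line before the column header.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path, params = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(params) && length(params) > 0L) {
    writeLines(sprintf("# %s=%s", names(params),
                       vapply(params, function(x) paste(format(x), collapse = ","),
                              character(1))), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a tab-separated table, skipping `#` comment header lines
#'
#' @param path Input path.
#' @param ... Passed on to [utils::read.delim()].
#' @return A data frame.
#' @export
readTsv <- function(path, ...) {
  if (!file.exists(path)) {
    stop("input file not found: ", path)
  }
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

## Deterministic per-stage substream of a global seed, so stages can be
## regenerated independently. Kept below 2^31 - 1.
stageSeed <- function(seed, stage) {
  offsets <- c(host = 101L, go = 211L, symbiont = 307L, pangenome = 401L,
               hits = 503L, loci = 601L, alignments = 701L, misc = 809L)
  if (!stage %in% names(offsets)) {
    stop("unknown stage: ", stage)
  }
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}
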