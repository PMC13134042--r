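#' Read per-gene trimmed protein alignments
#'
#' @param paths Named character vector of FASTA paths (names = gene ids;
#'   unnamed paths use the file base name without extension).
#' @return Named list of [Biostrings::AAStringSet] objects, each validated
#'   to have equal-width rows.
#' @export
readGeneAlignments <- function(paths) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  }
  out <- lapply(paths, function(p) {
    aln <- Biostrings::readAAStringSet(p)
    if (length(unique(Biostrings::width(aln))) > 1L) {
      stop("rows of ", p, " are not aligned (unequal widths)")
    }
    aln
  })
  out
}

#' Retain organisms present in at least a minimum number of gene alignments
#'
#' Organisms bearing fewer than `minGenes` genes are discarded (strict:
#' exactly `minGenes` occurrences is kept). Matching is by exact sequence
#' name.
#'
#' @param alignments Named list of [Biostrings::AAStringSet] alignments.
#' @param minGenes Minimum number of alignments an organism must appear in
#'   (default 3).
#' @return Character vector of retained organism names, sorted.
#' @export
filterTaxa <- function(alignments, minGenes = 3) {
  counts <- table(unlist(lapply(alignments, names), use.names = FALSE))
  sort(names(counts)[counts >= minGenes])
}

#' Concatenate gene alignments into a supermatrix
#'
#' Genes are concatenated in lexicographic order of their names for
#' determinism; an organism absent from a gene is padded with gap
#' characters (`-`) over that gene's columns. A partition table records
#' each gene's 1-based inclusive column range.
#'
#' @param alignments Named list of [Biostrings::AAStringSet] alignments.
#' @param retained Organisms to include (default: [filterTaxa()] with its
#'   default threshold). Must be non-empty.
#' @return List with `alignment` (an [Biostrings::AAStringSet], one row
#'   per retained organism) and `partitions` (data frame `gene`, `start`,
#'   `end`).
#' @export
concatenateAlignments <- function(alignments, retained = filterTaxa(alignments)) {
  if (length(retained) == 0L) stop("no organisms retained")
  for (g in names(alignments)) {
    if (anyDuplicated(names(alignments[[g]]))) {
      stop("duplicate organism name within alignment '", g, "'")
    }
  }
  genes <- sort(names(alignments))
  widths <- vapply(genes, function(g) {
    if (length(alignments[[g]]) == 0L) 0L else Biostrings::width(alignments[[g]])[1L]
  }, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  rows <- vapply(retained, function(org) {
    paste(vapply(genes, function(g) {
      aln <- alignments[[g]]
      if (org %in% names(aln)) {
        as.character(aln[[org]])
      } else {
        strrep("-", widths[[g]])
      }
    }, character(1)), collapse = "")
  }, character(1))
  list(
    alignment = Biostrings::AAStringSet(stats::setNames(rows, retained)),
    partitions = data.frame(gene = genes, start = starts, end = ends,
                            row.names = NULL, stringsAsFactors = FALSE)
  )
}

#' Write a supermatrix and its partition file
#'
#' The partition file uses the widely understood `GENE = start-end` text
#' format, one gene per line.
#'
#' @param supermatrix List from [concatenateAlignments()].
#' @param fastaPath Output FASTA path.
#' @param partitionPath Output partition-file path.
#' @return Invisibly, a character vector of the two paths.
#' @export
writeSupermatrix <- function(supermatrix, fastaPath, partitionPath) {
  Biostrings::writeXStringSet(supermatrix$alignment, fastaPath)
  writeLines(sprintf("%s = %d-%d", supermatrix$partitions$gene,
                     supermatrix$partitions$start, supermatrix$partitions$end),
             partitionPath)
  invisible(c(fastaPath, partitionPath))
}
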