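#' Refine pangenome partitions into core / soft-core / shell / cloud
#'
#' The upstream pangenome tool assigns each gene family to one of three
#' frequency partitions (persistent, shell, cloud). The persistent
#' partition is refined here: families present in every genome become
#' `core`, the remaining persistent families `soft_core`; shell and cloud
#' pass through unchanged. A non-persistent family present in all genomes
#' is passed through with a warning, since that combination usually
#' signals an upstream labelling oddity.
#'
#' @param matrix Data frame with columns `family`, `partition`
#'   (`persistent`/`shell`/`cloud`) and one logical/0-1 column per genome.
#' @return Data frame `family`, `partition`, `n_present`, `n_genomes`,
#'   `refined` (`core`/`soft_core`/`shell`/`cloud`).
#' @export
refinePartitions <- function(matrix) {
  stopifnot(is.data.frame(matrix), all(c("family", "partition") %in% names(matrix)))
  part <- as.character(matrix$partition)
  bad <- setdiff(unique(part), c("persistent", "shell", "cloud"))
  if (length(bad) > 0L) {
    stop("unknown partition label(s): ", paste(bad, collapse = ", "))
  }
  genomeCols <- setdiff(names(matrix), c("family", "partition"))
  if (length(genomeCols) == 0L) stop("no genome presence/absence columns")
  pres <- as.matrix(matrix[, genomeCols, drop = FALSE]) != 0
  nPresent <- rowSums(pres)
  if (any(nPresent == 0)) {
    stop("every family must be present in at least one genome")
  }
  nGenomes <- length(genomeCols)
  refined <- part
  isPersist <- part == "persistent"
  refined[isPersist & nPresent == nGenomes] <- "core"
  refined[isPersist & nPresent < nGenomes] <- "soft_core"
  oddball <- !isPersist & nPresent == nGenomes
  if (any(oddball)) {
    warning(sum(oddball), " non-persistent familie(s) present in all genomes; ",
            "partition label passed through unchanged")
  }
  data.frame(
    family = matrix$family, partition = part, n_present = nPresent,
    n_genomes = nGenomes, refined = refined,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Filter genomes on single-copy-ortholog completeness and duplication
#'
#' Keeps a genome when its completeness exceeds `minComplete` percent and
#' its duplication rate is below `maxDup` percent, both strict
#' inequalities.
#'
#' @param summaries Data frame with columns `genome`, `complete_single`
#'   and `duplicated` (percentages in \[0, 100\]).
#' @param minComplete Completeness cutoff (default 80, strict `>`).
#' @param maxDup Duplication cutoff (default 2, strict `<`).
#' @return Character vector of retained genome identifiers.
#' @export
qualityFilter <- function(summaries, minComplete = 80, maxDup = 2) {
  stopifnot(all(c("genome", "complete_single", "duplicated") %in% names(summaries)))
  if (any(summaries$complete_single < 0 | summaries$complete_single > 100) ||
      any(summaries$duplicated < 0 | summaries$duplicated > 100)) {
    stop("percentages must lie in [0, 100]")
  }
  keep <- summaries$complete_single > minComplete & summaries$duplicated < maxDup
  as.character(summaries$genome[keep])
}

#' Read a gene-family presence/absence matrix
#'
#' @param path TSV with columns `family`, `partition`, then one 0/1 column
#'   per genome.
#' @return The data frame, validated for use with [refinePartitions()].
#' @export
readPresenceAbsence <- function(path) {
  tab <- readTsv(path)
  stopifnot(all(c("family", "partition") %in% names(tab)))
  tab
}

#' Per-gene refined pangenome labels for enrichment
#'
#' Joins refined family partitions onto genes via a gene-to-family map, in
#' the shape [classificationEnrichment()] expects.
#'
#' @param refined Data frame from [refinePartitions()].
#' @param geneFamilies Data frame `gene`, `family`; if NULL, families are
#'   assumed to be named after single genes.
#' @return Data frame `gene`, `category` (refined partition label).
#' @export
pangenomeGeneLabels <- function(refined, geneFamilies = NULL) {
  if (is.null(geneFamilies)) {
    return(data.frame(gene = refined$family, category = refined$refined,
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(c("gene", "family") %in% names(geneFamilies)))
  idx <- match(geneFamilies$family, refined$family)
  if (any(is.na(idx))) {
    stop("gene-to-family map references unknown families")
  }
  data.frame(gene = geneFamilies$gene, category = refined$refined[idx],
             stringsAsFactors = FALSE)
}
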