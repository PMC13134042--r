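#' Read tabular protein-homology hits with subject taxon ids
#'
#' Parses the 13-column tab-separated dialect produced by a protein search
#' with output format "6 std staxids": the 12 standard columns plus a
#' final column of subject taxon ids, semicolon-separated when a subject
#' maps to several taxa.
#'
#' @param path Path to the hit table.
#' @return Data frame with the standard columns (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`) plus `staxids`, a list column
#'   of integer taxon-id vectors.
#' @export
readBlastHits <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(qseqid = character(0), sseqid = character(0),
                      evalue = numeric(0), bitscore = numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 13L)) {
    bad <- which(nf != 13L)[1L]
    stop("line ", bad, " has ", nf[bad], " columns; expected 13 ",
         "(12 standard + staxids)")
  }
  m <- do.call(rbind, fields)
  out <- data.frame(
    qseqid = m[, 1L], sseqid = m[, 2L],
    pident = as.numeric(m[, 3L]), length = as.integer(m[, 4L]),
    mismatch = as.integer(m[, 5L]), gapopen = as.integer(m[, 6L]),
    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
    sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$evalue)) || any(out$evalue < 0)) {
    stop("invalid E-value field(s)")
  }
  out$staxids <- lapply(strsplit(m[, 13L], ";", fixed = TRUE), as.integer)
  out
}

#' Alien Index of each query from ingroup/outgroup best E-values
#'
#' For each query the best (smallest) E-value among ingroup hits and among
#' outgroup hits is found; a side with no hit defaults to E = 1. The Alien
#' Index is `AI = ln(best_ingroup_E + 1e-200) - ln(best_outgroup_E +
#' 1e-200)`: large positive values mean the gene resembles outgroup
#' sequences far more than ingroup ones, the signature of horizontal
#' acquisition. A hit counts as ingroup when any of its subject taxon ids
#' is in the ingroup set; taxonomic expansion of the ingroup to its
#' descendant taxa is the caller's responsibility.
#'
#' @param hits Data frame from [readBlastHits()].
#' @param ingroup Non-empty integer vector of ingroup taxon ids.
#' @param genes Optional character vector of the full query universe;
#'   queries without hits get `ai = 0`.
#' @param exclude Optional taxon ids whose hits are dropped entirely
#'   before scoring (an excluded-genome pool); NULL (default) excludes
#'   nothing.
#' @param dropSelf If TRUE, hits whose subject id equals the query id are
#'   dropped (off by default).
#' @return Data frame `query`, `best_in_e`, `best_out_e`, `ai`.
#' @export
alienIndex <- function(hits, ingroup, genes = NULL, exclude = NULL,
                       dropSelf = FALSE) {
  if (length(ingroup) == 0L) stop("'ingroup' must be non-empty")
  ingroup <- as.integer(ingroup)
  if (nrow(hits) > 0L) {
    if (dropSelf) {
      hits <- hits[hits$sseqid != hits$qseqid, , drop = FALSE]
    }
    if (!is.null(exclude)) {
      excl <- vapply(hits$staxids, function(tx) any(tx %in% exclude), logical(1))
      hits <- hits[!excl, , drop = FALSE]
    }
  }
  queries <- unique(hits$qseqid)
  if (!is.null(genes)) {
    missing <- setdiff(queries, genes)
    if (length(missing) > 0L) {
      stop("hits reference queries outside the gene universe: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    queries <- genes
  }
  isIn <- if (nrow(hits) > 0L) {
    vapply(hits$staxids, function(tx) any(tx %in% ingroup), logical(1))
  } else logical(0)
  bestIn <- rep(1, length(queries))
  bestOut <- rep(1, length(queries))
  names(bestIn) <- names(bestOut) <- queries
  if (nrow(hits) > 0L) {
    inBest <- tapply(hits$evalue[isIn], hits$qseqid[isIn], min)
    outBest <- tapply(hits$evalue[!isIn], hits$qseqid[!isIn], min)
    bestIn[names(inBest)] <- inBest
    bestOut[names(outBest)] <- outBest
  }
  eps <- 1e-200
  ai <- log(bestIn + eps) - log(bestOut + eps)
  data.frame(
    query = queries, best_in_e = unname(bestIn), best_out_e = unname(bestOut),
    ai = unname(ai), row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Call horizontal-gene-transfer candidates from Alien Index records
#'
#' @param records Data frame from [alienIndex()].
#' @param threshold AI threshold (default 45, strict `ai > threshold`).
#' @return `records` with an added logical `candidate` column.
#' @export
callCandidates <- function(records, threshold = 45) {
  records$candidate <- records$ai > threshold
  records
}

#' Read gene loci from a GFF3 file
#'
#' Imports `gene` features (falling back to `CDS` when no gene rows exist)
#' as genomic ranges keyed by their `ID` attribute.
#'
#' @param path Path to a GFF3 file.
#' @return A [GenomicRanges::GRanges] with names set to gene identifiers.
#' @export
readGeneLoci <- function(path) {
  gr <- rtracklayer::import(path)
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    genes <- gr[gr$type == "gene"]
    if (length(genes) == 0L) genes <- gr[gr$type == "CDS"]
  } else {
    genes <- gr
  }
  ids <- S4Vectors::mcols(genes)$ID
  if (is.null(ids)) stop("GFF3 gene features carry no ID attribute")
  names(genes) <- ids
  genes
}

#' Colocation blocks of a gene set along the genome
#'
#' Sorts all annotated genes by contig and start coordinate and reports
#' the maximal runs of `geneSet` members that are consecutive in that
#' order (no intervening annotated gene), together with each block's
#' strand pattern. A six-gene run with five genes on one strand and the
#' last on the other, for example, yields one block with pattern
#' `"+++++-"`.
#'
#' @param loci A [GenomicRanges::GRanges] of all annotated genes (names =
#'   gene ids), e.g. from [readGeneLoci()].
#' @param geneSet Character vector of gene ids of interest; must all be
#'   present in `loci`.
#' @return Data frame `block`, `contig`, `n_genes`, `genes`
#'   (comma-separated, genome order), `strands` (pattern string),
#'   `same_strand` (logical).
#' @export
operonBlocks <- function(loci, geneSet) {
  if (is.null(names(loci))) stop("'loci' must be named by gene id")
  geneSet <- unique(as.character(geneSet))
  missing <- setdiff(geneSet, names(loci))
  if (length(missing) > 0L) {
    stop("gene(s) absent from loci: ", paste(missing, collapse = ", "))
  }
  ord <- order(as.character(GenomicRanges::seqnames(loci)),
               GenomicRanges::start(loci))
  loci <- loci[ord]
  contig <- as.character(GenomicRanges::seqnames(loci))
  inSet <- names(loci) %in% geneSet
  ## run ids: consecutive inSet genes on one contig with no gap in the
  ## annotated gene order
  newBlock <- inSet & (!c(FALSE, inSet[-length(inSet)]) |
                         c(TRUE, contig[-1L] != contig[-length(contig)]))
  blockId <- cumsum(newBlock)
  blockId[!inSet] <- NA
  keep <- which(inSet)
  if (length(keep) == 0L) {
    return(data.frame(block = integer(0), contig = character(0),
                      n_genes = integer(0), genes = character(0),
                      strands = character(0), same_strand = logical(0)))
  }
  strands <- as.character(GenomicRanges::strand(loci))
  out <- do.call(rbind, lapply(split(keep, blockId[keep]), function(idx) {
    data.frame(
      contig = contig[idx[1L]], n_genes = length(idx),
      genes = paste(names(loci)[idx], collapse = ","),
      strands = paste(strands[idx], collapse = ""),
      same_strand = length(unique(strands[idx])) == 1L,
      stringsAsFactors = FALSE
    )
  }))
  out <- cbind(block = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
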