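#' Transcripts-per-million from counts and effective lengths
#'
#' `tpm_i = (c_i / l_i) / sum_j(c_j / l_j) * 1e6`, so the vector sums to
#' one million and a gene has TPM 0 exactly when it has zero reads.
#'
#' @param readCounts Named non-negative integer vector of per-gene read
#'   counts (not all zero).
#' @param effectiveLengths Positive per-gene effective lengths (bases), in
#'   the same order (or named identically).
#' @return Data frame `gene`, `read_count`, `effective_length`, `tpm`.
#' @export
computeTpm <- function(readCounts, effectiveLengths) {
  if (length(readCounts) != length(effectiveLengths)) {
    stop("counts and lengths must have equal length")
  }
  if (any(effectiveLengths <= 0)) stop("effective lengths must be positive")
  if (any(readCounts < 0)) stop("read counts must be non-negative")
  if (all(readCounts == 0)) stop("all-zero read counts: TPM undefined")
  genes <- names(readCounts)
  if (is.null(genes)) genes <- paste0("gene", seq_along(readCounts))
  rate <- readCounts / effectiveLengths
  data.frame(
    gene = genes, read_count = as.numeric(readCounts),
    effective_length = as.numeric(effectiveLengths),
    tpm = rate / sum(rate) * 1e6,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Merge replicate count vectors
#'
#' Element-wise sum over replicates sharing one gene universe; TPM should
#' then be recomputed on the merged vector (see [computeTpm()]).
#'
#' @param replicates A named-list of named count vectors, or a gene x
#'   replicate matrix.
#' @return Named numeric vector of summed counts.
#' @export
mergeReplicates <- function(replicates) {
  if (is.matrix(replicates)) {
    return(rowSums(replicates))
  }
  stopifnot(is.list(replicates), length(replicates) >= 1L)
  genes <- names(replicates[[1L]])
  for (r in replicates) {
    if (!identical(sort(names(r)), sort(genes))) {
      stop("replicates do not share one gene universe")
    }
  }
  out <- Reduce(`+`, lapply(replicates, function(r) r[genes]))
  stats::setNames(as.numeric(out), genes)
}

#' Classify genes as transcriptionally active or inactive
#'
#' Active means strictly `tpm > 0`; inactive means `tpm = 0`.
#'
#' @param tpm Data frame from [computeTpm()] (columns `gene`, `tpm`), or a
#'   named numeric TPM vector.
#' @return Data frame `gene`, `tpm`, `activity` (`active`/`inactive`).
#' @export
classifyActivity <- function(tpm) {
  if (!is.data.frame(tpm)) {
    tpm <- data.frame(gene = names(tpm), tpm = as.numeric(tpm),
                      stringsAsFactors = FALSE)
  }
  if (any(tpm$tpm < 0)) stop("negative TPM values")
  data.frame(
    gene = tpm$gene, tpm = tpm$tpm,
    activity = ifelse(tpm$tpm > 0, "active", "inactive"),
    stringsAsFactors = FALSE
  )
}

#' Stratify active genes into expression-level percentiles
#'
#' Thresholds are the 25th and 75th percentiles of the active genes' TPM
#' values ([quantileThreshold()]): high means strictly above the 75th
#' percentile, low strictly below the 25th, moderate everything in between
#' with boundary values inclusive to moderate.
#'
#' @param activeTpm Named numeric TPM vector, or data frame with `gene`
#'   and `tpm`, of active genes only (all values > 0).
#' @param qLow,qHigh Percentile fractions (defaults 0.25 and 0.75).
#' @return Data frame `gene`, `tpm`, `stratum` (`high`/`moderate`/`low`)
#'   with thresholds attached as attributes `q_low` and `q_high`.
#' @export
stratifyExpression <- function(activeTpm, qLow = 0.25, qHigh = 0.75) {
  if (!is.data.frame(activeTpm)) {
    activeTpm <- data.frame(gene = names(activeTpm), tpm = as.numeric(activeTpm),
                            stringsAsFactors = FALSE)
  }
  if (nrow(activeTpm) == 0L) stop("empty active gene set")
  if (any(activeTpm$tpm <= 0)) {
    stop("stratification expects transcriptionally active genes (tpm > 0) only")
  }
  thrLow <- quantileThreshold(activeTpm$tpm, qLow)
  thrHigh <- quantileThreshold(activeTpm$tpm, qHigh)
  stratum <- rep("moderate", nrow(activeTpm))
  stratum[activeTpm$tpm > thrHigh] <- "high"
  stratum[activeTpm$tpm < thrLow] <- "low"
  out <- data.frame(gene = activeTpm$gene, tpm = activeTpm$tpm,
                    stratum = stratum, stringsAsFactors = FALSE)
  attr(out, "q_low") <- thrLow
  attr(out, "q_high") <- thrHigh
  out
}

#' Classify a symbiont TPM vector into activity and expression strata
#'
#' Convenience wrapper combining [classifyActivity()] and
#' [stratifyExpression()]: inactive genes get stratum `none`.
#'
#' @param tpm Data frame from [computeTpm()] or named TPM vector.
#' @param qLow,qHigh Percentile fractions for the strata.
#' @return Data frame `gene`, `tpm`, `activity`, `stratum`.
#' @export
classifySymbiont <- function(tpm, qLow = 0.25, qHigh = 0.75) {
  act <- classifyActivity(tpm)
  act$stratum <- "none"
  idx <- act$activity == "active"
  if (any(idx)) {
    strat <- stratifyExpression(act[idx, c("gene", "tpm")], qLow, qHigh)
    act$stratum[idx] <- strat$stratum[match(act$gene[idx], strat$gene)]
  }
  act
}

#' Rarefaction curve of detected genes versus sequencing depth
#'
#' Expected number of distinct genes observed in a random subsample of
#' reads. In `"exact"` mode the analytical hypergeometric expectation
#' `E[S(m)] = sum_i (1 - choose(N - n_i, m) / choose(N, m))` is computed
#' via [vegan::rarefy()]; in `"montecarlo"` mode reads are subsampled
#' without replacement and the mean and standard deviation over replicates
#' are reported.
#'
#' @param readCounts Named non-negative integer per-gene read counts.
#' @param depths Subsample sizes; each must be at most the total read
#'   count.
#' @param mode `"exact"` (default) or `"montecarlo"`.
#' @param nrep Monte-Carlo replicates (default 100).
#' @param seed Optional seed for Monte-Carlo subsampling.
#' @return Data frame `depth`, `expected_genes`, `mc_sd` (`NA` in exact
#'   mode).
#' @export
rarefactionCurve <- function(readCounts, depths,
                             mode = c("exact", "montecarlo"),
                             nrep = 100L, seed = NULL) {
  mode <- match.arg(mode)
  counts <- round(readCounts)
  if (any(abs(counts - readCounts) > 1e-8)) {
    warning("non-integer read counts rounded to nearest integer")
  }
  if (any(counts < 0)) stop("read counts must be non-negative")
  N <- sum(counts)
  depths <- as.numeric(depths)
  if (any(depths < 0) || any(depths > N)) {
    stop("depths must lie in [0, total reads] (total = ", N, ")")
  }
  if (mode == "exact") {
    eg <- vapply(depths, function(m) {
      if (m == 0) return(0)
      ## vegan warns about singleton-free vectors; that is expected here
      withCallingHandlers(
        unname(vegan::rarefy(counts, sample = m)),
        warning = function(w) {
          if (grepl("most observed count data", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }
      )
    }, numeric(1))
    sdv <- rep(NA_real_, length(depths))
  } else {
    if (!is.null(seed)) set.seed(seed)
    pos <- which(counts > 0)
    cum <- cumsum(counts[pos])
    draws <- lapply(depths, function(m) {
      vapply(seq_len(nrep), function(r) {
        if (m == 0) return(0)
        picked <- sample.int(N, m)
        length(unique(findInterval(picked - 1, c(0, cum), rightmost.closed = FALSE,
                                   left.open = FALSE) ))
      }, numeric(1))
    })
    eg <- vapply(draws, mean, numeric(1))
    sdv <- vapply(draws, stats::sd, numeric(1))
  }
  data.frame(depth = depths, expected_genes = eg, mc_sd = sdv)
}

#' Judge sequencing depth from the tail of a rarefaction curve
#'
#' Depth is adequate when the relative gain in expected detected genes
#' over the final depth step is below `relGain`, i.e. the curve has
#' flattened and deeper sequencing would reveal few additional genes.
#'
#' @param curve Data frame from [rarefactionCurve()] with at least two
#'   depths, the largest being the full depth.
#' @param relGain Relative-gain threshold (default 0.01, i.e. 1%).
#' @return `TRUE` if adequate, `FALSE` otherwise.
#' @export
saturationCheck <- function(curve, relGain = 0.01) {
  stopifnot(nrow(curve) >= 2L)
  curve <- curve[order(curve$depth), , drop = FALSE]
  k <- nrow(curve)
  prev <- curve$expected_genes[k - 1L]
  last <- curve$expected_genes[k]
  if (prev == 0) return(last == 0)
  (last - prev) / prev < relGain
}

#' Enrichment of functional and pangenome categories across expression classes
#'
#' Runs the category enrichment for both symbiont classifications. For the
#' activity classification the foregrounds are the active and the inactive
#' gene sets and the background is all (annotated) genes; for the
#' expression-level classification the foregrounds are the high, moderate
#' and low strata and the background is restricted to the active genes
#' (genes with TPM = 0 are excluded). COG runs consider only genes with at
#' least one COG letter, multi-letter genes being expanded to one unit per
#' letter; pangenome runs use the single refined partition label per gene.
#' Each foreground x category-system combination is one independent
#' [enrichCategories()] call with its own BH correction.
#'
#' @param classified Data frame from [classifySymbiont()] (columns `gene`,
#'   `activity`, `stratum`).
#' @param cogAnnotation Data frame `gene`, `category` (COG letter, one row
#'   per letter), or NULL to skip COG runs.
#' @param pangenomeLabels Data frame `gene`, `category` (refined partition
#'   label), or NULL to skip pangenome runs.
#' @param alpha Significance threshold (default 0.05).
#' @return Data frame with `classification` (`activity`/`expression_level`),
#'   `system` (`COG`/`pangenome`), `foreground` (class label) and the
#'   [enrichCategories()] columns.
#' @export
classificationEnrichment <- function(classified, cogAnnotation = NULL,
                                     pangenomeLabels = NULL, alpha = 0.05) {
  stopifnot(all(c("gene", "activity", "stratum") %in% names(classified)))
  known <- classified$stratum %in% c("high", "moderate", "low", "none")
  if (!all(known)) {
    stop("unknown stratum label(s): ",
         paste(unique(classified$stratum[!known]), collapse = ", "))
  }
  systems <- list()
  if (!is.null(cogAnnotation)) systems$COG <- cogAnnotation
  if (!is.null(pangenomeLabels)) systems$pangenome <- pangenomeLabels
  out <- list()
  for (sysName in names(systems)) {
    ann <- systems[[sysName]]
    stopifnot(all(c("gene", "category") %in% names(ann)))
    annotated <- intersect(classified$gene, unique(ann$gene))
    activeAnn <- intersect(classified$gene[classified$activity == "active"],
                           annotated)
    runs <- list(
      list(classification = "activity", foreground = "active",
           genes = classified$gene[classified$activity == "active"],
           background = annotated),
      list(classification = "activity", foreground = "inactive",
           genes = classified$gene[classified$activity == "inactive"],
           background = annotated)
    )
    for (s in c("high", "moderate", "low")) {
      runs[[length(runs) + 1L]] <- list(
        classification = "expression_level", foreground = s,
        genes = classified$gene[classified$stratum == s],
        background = activeAnn
      )
    }
    for (r in runs) {
      fg <- intersect(r$genes, r$background)
      res <- suppressWarnings(
        enrichCategories(fg, r$background, ann, alpha = alpha)
      )
      if (nrow(res) > 0L) {
        out[[length(out) + 1L]] <- cbind(
          classification = r$classification, system = sysName,
          foreground = r$foreground, res, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame())
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read per-replicate symbiont counts with effective lengths
#'
#' @param path TSV with columns `gene`, `effective_length`, then one column
#'   per replicate.
#' @return List with `counts` (gene x replicate matrix) and `lengths`
#'   (named vector).
#' @export
readSymbiontCounts <- function(path) {
  tab <- readTsv(path)
  stopifnot(all(c("gene", "effective_length") %in% names(tab)))
  m <- as.matrix(tab[, setdiff(names(tab), c("gene", "effective_length")),
                     drop = FALSE])
  rownames(m) <- tab$gene
  list(counts = m,
       lengths = stats::setNames(tab$effective_length, tab$gene))
}

#' Read a gene-to-COG-letter annotation table
#'
#' Accepts multi-letter assignments (e.g. `"KT"` or `"K;T"`) and expands
#' them to one row per letter.
#'
#' @param path TSV with columns `gene` and `cog`.
#' @return Data frame `gene`, `category`, one row per (gene, letter).
#' @export
readCogAnnotation <- function(path) {
  tab <- readTsv(path)
  stopifnot(all(c("gene", "cog") %in% names(tab)))
  letters <- strsplit(gsub("[;,]", "", as.character(tab$cog)), "")
  data.frame(
    gene = rep(tab$gene, lengths(letters)),
    category = unlist(letters, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}
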