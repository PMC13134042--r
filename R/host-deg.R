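#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

#' Host count matrix with condition design
#'
#' An S4 container for the host gene x sample count matrix, extending
#' [SummarizedExperiment::SummarizedExperiment]. Column data carry the
#' sample condition (symbiont-positive / symbiont-negative) and the
#' reference condition is stored in the metadata; fold changes are reported
#' as non-reference over reference, so a positive log2 fold change means
#' higher expression in the symbiont-positive strain when the
#' symbiont-negative strain is the reference.
#'
#' @slot .Data inherited SummarizedExperiment slots; the single assay
#'   `"counts"` holds non-negative integer counts.
#' @export
setClass("HostCountSet", contains = "SummarizedExperiment")

setValidity("HostCountSet", function(object) {
  msg <- NULL
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(is.na(cts)) || any(cts < 0) || any(cts != round(cts))) {
    msg <- c(msg, "counts must be non-negative integers")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"condition" %in% names(cd)) {
    msg <- c(msg, "colData must contain a 'condition' column")
  } else {
    cond <- as.character(cd$condition)
    tab <- table(cond)
    if (length(tab) != 2L) {
      msg <- c(msg, "exactly two conditions are required")
    }
    if (any(tab < 2L)) {
      msg <- c(msg, "each condition needs at least two replicate samples")
    }
    ref <- S4Vectors::metadata(object)$reference
    if (is.null(ref) || !ref %in% cond) {
      msg <- c(msg, "metadata 'reference' must name one of the conditions")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a HostCountSet
#'
#' @param counts Gene x sample matrix of non-negative integer counts, with
#'   row and column names.
#' @param condition Character or factor of per-sample condition labels, two
#'   levels, at least two samples each.
#' @param reference The reference condition (the denominator of fold
#'   changes; conventionally the symbiont-negative strain). Defaults to the
#'   first condition level.
#' @return A [HostCountSet-class] object.
#' @examples
#' m <- matrix(rpois(60, 50), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' hcs <- HostCountSet(m, rep(c("minus", "plus"), each = 3), reference = "minus")
#' @export
HostCountSet <- function(counts, condition, reference = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  condition <- as.character(condition)
  if (length(condition) != ncol(counts)) {
    stop("'condition' must have one label per sample")
  }
  if (is.null(reference)) {
    reference <- sort(unique(condition))[1L]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(condition = condition,
                                   row.names = colnames(counts)),
    metadata = list(reference = reference)
  )
  obj <- methods::new("HostCountSet", se)
  methods::validObject(obj)
  obj
}

#' @describeIn HostCountSet the reference (denominator) condition.
#' @param object A `HostCountSet`.
#' @export
setGeneric("referenceCondition", function(object) standardGeneric("referenceCondition"))

#' @export
setMethod("referenceCondition", "HostCountSet", function(object) {
  S4Vectors::metadata(object)$reference
})

#' @export
setMethod("show", "HostCountSet", function(object) {
  cond <- SummarizedExperiment::colData(object)$condition
  cat("HostCountSet:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  conditions:", paste(sprintf("%s (n=%d)", names(table(cond)), table(cond)),
                             collapse = ", "), "\n")
  cat("  reference :", referenceCondition(object), "\n")
})

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the reference profile is the geometric
#' mean across samples over genes with positive counts in every sample, and
#' each sample's factor is the median of its count ratios to that profile.
#' If no gene is positive in all samples the method falls back to
#' total-count scaling (factors proportional to library size, geometric
#' mean 1), with a warning.
#'
#' @param object A [HostCountSet-class].
#' @return Named numeric vector of positive factors, one per sample.
#' @importFrom BiocGenerics sizeFactors
#' @exportMethod sizeFactors
setMethod("sizeFactors", "HostCountSet", function(object) {
  cts <- SummarizedExperiment::assay(object, "counts")
  allPos <- rowSums(cts > 0) == ncol(cts)
  if (!any(allPos)) {
    warning("no gene with positive counts in all samples; ",
            "falling back to total-count scaling")
    libs <- colSums(cts)
    if (any(libs == 0)) {
      stop("cannot normalize: a sample has zero total counts")
    }
    sf <- libs / exp(mean(log(libs)))
    return(sf)
  }
  sub <- cts[allPos, , drop = FALSE]
  ref <- exp(rowMeans(log(sub)))
  sf <- apply(sub / ref, 2, stats::median)
  sf
})

#' Normalized counts
#'
#' @param object A [HostCountSet-class].
#' @return Matrix of counts divided column-wise by the size factors.
#' @export
normalizedCounts <- function(object) {
  cts <- SummarizedExperiment::assay(object, "counts")
  sf <- BiocGenerics::sizeFactors(object)
  sweep(cts, 2, sf, "/")
}

#' Negative-binomial Wald test for two-condition differential expression
#'
#' A transparent two-group NB test: counts are normalized by
#' median-of-ratios size factors; the log2 fold change contrasts the
#' non-reference condition against the reference with a pseudo-count for
#' stability at low counts; the per-gene dispersion is a method-of-moments
#' estimate from the pooled within-group variance with a floor; and the
#' Wald standard error on the log scale follows the NB mean-variance
#' relation Var = mu + alpha mu^2. P-values refer the Wald statistic to a
#' t distribution with the within-group degrees of freedom
#' (n1 + n2 - 2), which keeps the null rejection rate close to nominal at
#' the small replicate numbers typical of these designs.
#'
#' @param object A [HostCountSet-class].
#' @param pseudoCount Pseudo-count added to normalized group means before
#'   the log2 ratio (default 0.5).
#' @param dispersionFloor Lower bound on the per-gene dispersion estimate
#'   (default 0.01).
#' @return A data frame with one row per gene: `gene`, `mean_norm`
#'   (normalized mean over all samples), `log2fc`, `p_raw`, and `p_adj`
#'   (BH across genes with any nonzero count; genes that are all-zero in
#'   both conditions get `log2fc = 0`, `p_raw = 1` and `p_adj = NA` and
#'   are excluded from the correction).
#' @export
nbTest <- function(object, pseudoCount = 0.5, dispersionFloor = 0.01) {
  stopifnot(methods::is(object, "HostCountSet"))
  norm <- normalizedCounts(object)
  cond <- as.character(SummarizedExperiment::colData(object)$condition)
  ref <- referenceCondition(object)
  other <- setdiff(unique(cond), ref)
  idxRef <- cond == ref
  idxOth <- cond == other
  n1 <- sum(idxOth)
  n0 <- sum(idxRef)
  m1 <- rowMeans(norm[, idxOth, drop = FALSE])
  m0 <- rowMeans(norm[, idxRef, drop = FALSE])
  ## pooled within-group variance, df = n1 + n0 - 2
  ss <- rowSums((norm[, idxOth, drop = FALSE] - m1)^2) +
    rowSums((norm[, idxRef, drop = FALSE] - m0)^2)
  df <- n1 + n0 - 2L
  s2 <- ss / df
  mu <- rowMeans(norm)
  alpha <- pmax((s2 - mu) / mu^2, dispersionFloor)
  lfc <- log2((m1 + pseudoCount) / (m0 + pseudoCount))
  ## delta-method variance of log group means under Var = mu + alpha mu^2
  v1 <- (1 / (m1 + pseudoCount) + alpha) / n1
  v0 <- (1 / (m0 + pseudoCount) + alpha) / n0
  seLog <- sqrt(v1 + v0)
  z <- log((m1 + pseudoCount) / (m0 + pseudoCount)) / seLog
  p <- 2 * stats::pt(-abs(z), df = df)
  allZero <- m1 == 0 & m0 == 0
  lfc[allZero] <- 0
  p[allZero] <- 1
  pAdj <- rep(NA_real_, length(p))
  pAdj[!allZero] <- bhAdjust(p[!allZero])
  data.frame(
    gene = rownames(norm), mean_norm = mu, log2fc = lfc,
    p_raw = p, p_adj = pAdj, row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Call differentially expressed genes
#'
#' Applies the strict thresholds `p_adj < alpha` and `|log2fc| > lfc`:
#' genes passing with a positive fold change are `up` (higher in the
#' non-reference, symbiont-positive condition), with a negative fold change
#' `down`, everything else `not_de`. Genes with `p_adj = NA` (all-zero,
#' excluded from correction) are `not_de`.
#'
#' @param results Data frame from [nbTest()] (columns `gene`, `log2fc`,
#'   `p_adj`).
#' @param alpha FDR threshold (default 0.05, strict `<`).
#' @param lfc Absolute log2-fold-change threshold (default 1, strict `>`).
#' @return `results` with an added `call` column (`up`/`down`/`not_de`).
#' @export
callDegs <- function(results, alpha = 0.05, lfc = 1.0) {
  stopifnot(all(c("gene", "log2fc", "p_adj") %in% names(results)))
  sig <- !is.na(results$p_adj) & results$p_adj < alpha
  call <- rep("not_de", nrow(results))
  call[sig & results$log2fc > lfc] <- "up"
  call[sig & results$log2fc < -lfc] <- "down"
  results$call <- call
  results
}

#' Summarize DEG calls
#'
#' @param degTable Data frame with a `call` column from [callDegs()].
#' @return Named list with `up`, `down` gene-identifier vectors and counts
#'   `n_up`, `n_down`, `n_total` (total DEGs, up + down).
#' @export
degSummary <- function(degTable) {
  up <- degTable$gene[degTable$call == "up"]
  down <- degTable$gene[degTable$call == "down"]
  list(up = up, down = down, n_up = length(up), n_down = length(down),
       n_total = length(up) + length(down))
}

#' Read a count matrix and sample sheet into a HostCountSet
#'
#' @param countsPath TSV of counts: first column gene identifiers, one
#'   column per sample.
#' @param samplesPath Sample sheet TSV with columns `sample` and
#'   `condition`.
#' @param reference Reference condition label; default first level.
#' @return A [HostCountSet-class].
#' @export
readHostCounts <- function(countsPath, samplesPath, reference = NULL) {
  tab <- readTsv(countsPath)
  genes <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- genes
  sheet <- readTsv(samplesPath)
  stopifnot(all(c("sample", "condition") %in% names(sheet)))
  if (!all(colnames(m) %in% sheet$sample)) {
    stop("sample sheet is missing samples present in the count matrix")
  }
  cond <- sheet$condition[match(colnames(m), sheet$sample)]
  HostCountSet(m, cond, reference = reference)
}

#' Volcano-plot coordinates for a DEG table
#'
#' @param degTable Data frame from [callDegs()].
#' @return Data frame `gene`, `log2fc`, `neg_log10_padj`, `call` suitable
#'   for a volcano plot (the y axis is -log10 adjusted p).
#' @export
volcanoData <- function(degTable) {
  data.frame(
    gene = degTable$gene, log2fc = degTable$log2fc,
    neg_log10_padj = -log10(degTable$p_adj), call = degTable$call,
    stringsAsFactors = FALSE
  )
}
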