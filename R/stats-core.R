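#' One-sided Fisher exact test for category over-representation
#'
#' Computes the hypergeometric upper-tail probability of observing at least
#' `inFore` category members among the foreground draw, given a 2x2
#' contingency table partitioning the background into foreground /
#' non-foreground and in-category / out-of-category cells. This is the
#' one-sided (greater) Fisher exact test used throughout the enrichment
#' stages: only over-representation is scored.
#'
#' @param table A 2x2 numeric matrix `rbind(c(inFore, outFore), c(inBack,
#'   outBack))`, where `inFore`/`outFore` count foreground units in/out of
#'   the category and `inBack`/`outBack` count the remaining background
#'   units (background minus foreground) in/out of the category.
#' @return The upper-tail p-value, in (0, 1].
#' @examples
#' fisherOneSided(rbind(c(2, 0), c(0, 2))) # 1/6
#' @export
fisherOneSided <- function(table) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L))) {
    stop("'table' must be a 2x2 matrix")
  }
  if (any(is.na(table)) || any(table < 0)) {
    stop("all cells of 'table' must be non-negative")
  }
  if (any(table != round(table))) {
    stop("all cells of 'table' must be integral counts")
  }
  .hyperUpperTail(table[1L, 1L], table[1L, 2L], table[2L, 1L], table[2L, 2L])
}

## Vectorised hypergeometric upper tail P(X >= a) for cells (a, b, c, d):
## N = a+b+c+d total units, K = a+c in category, n = a+b foreground draws.
.hyperUpperTail <- function(a, b, c, d) {
  K <- a + c
  n <- a + b
  nOther <- b + d
  p <- stats::phyper(a - 1, K, nOther, n, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Benjamini-Hochberg adjustment of a p-value vector
#'
#' Step-up false-discovery-rate adjustment. Thin validating wrapper around
#' [stats::p.adjust()] with `method = "BH"` so that every enrichment stage
#' shares a single corrected entry point.
#'
#' @param raw Numeric vector of raw p-values, all in \[0, 1\].
#' @return Adjusted p-values in the input order, capped at 1.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(raw) {
  if (length(raw) == 0L) {
    return(numeric(0))
  }
  if (any(is.na(raw)) || any(raw < 0) || any(raw > 1)) {
    stop("all raw p-values must lie in [0, 1]")
  }
  stats::p.adjust(raw, method = "BH")
}

#' Linear-interpolation quantile threshold
#'
#' Quantile of a numeric vector under the common linear-interpolation rule
#' between order statistics at position h = (n - 1) q + 1 (type 7 in
#' [stats::quantile()]). Used for the 25th/75th-percentile expression
#' strata of the symbiont transcriptome.
#'
#' @param values Non-empty numeric vector.
#' @param q Quantile fraction in \[0, 1\].
#' @return The interpolated threshold, between `min(values)` and
#'   `max(values)`.
#' @examples
#' quantileThreshold(1:8, 0.75) # 6.25
#' @export
quantileThreshold <- function(values, q) {
  if (length(values) == 0L) {
    stop("'values' must be non-empty")
  }
  if (any(is.na(values))) {
    stop("'values' must not contain NA")
  }
  if (length(q) != 1L || is.na(q) || q < 0 || q > 1) {
    stop("'q' must be a single fraction in [0, 1]")
  }
  unname(stats::quantile(values, probs = q, type = 7))
}

#' Category enrichment by one-sided Fisher tests with BH correction
#'
#' Scores every category present in the background for over-representation
#' in a foreground gene set. The counting units are the rows of
#' `annotation`: a gene carrying k category labels contributes k units, one
#' per label, so multi-category genes are treated as that many separate
#' genes. One BH correction is applied across the categories tested in this
#' single call.
#'
#' @param foreground Character vector of foreground gene identifiers; must
#'   be a subset of `background`.
#' @param background Character vector of background gene identifiers. Only
#'   annotation rows whose gene is in the background are counted.
#' @param annotation Data frame with columns `gene` and `category`, one row
#'   per (gene, category) assignment.
#' @param alpha Significance threshold on the BH-adjusted p-value
#'   (default 0.05).
#' @return A data frame with one row per category: `category`, `in_fore`,
#'   `fore_size`, `in_back`, `back_size`, `odds_ratio`, `p_raw`, `p_adj`,
#'   `enriched`. `in_back` counts category units among background-minus-
#'   foreground genes; `back_size` is the total number of background units.
#' @export
enrichCategories <- function(foreground, background, annotation, alpha = 0.05) {
  stopifnot(is.data.frame(annotation), all(c("gene", "category") %in% names(annotation)))
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  if (!all(foreground %in% background)) {
    stop("'foreground' must be a subset of 'background'")
  }
  ann <- annotation[annotation$gene %in% background, c("gene", "category"), drop = FALSE]
  ann <- unique(ann)
  empty <- data.frame(
    category = character(0), in_fore = integer(0), fore_size = integer(0),
    in_back = integer(0), back_size = integer(0), odds_ratio = numeric(0),
    p_raw = numeric(0), p_adj = numeric(0), enriched = logical(0),
    stringsAsFactors = FALSE
  )
  if (length(foreground) == 0L) {
    warning("empty foreground: no enrichment computed")
    return(empty)
  }
  if (nrow(ann) == 0L) {
    return(empty)
  }
  isFore <- ann$gene %in% foreground
  nFore <- sum(isFore)
  nTot <- nrow(ann)
  cats <- sort(unique(as.character(ann$category)))
  inForeK <- vapply(cats, function(k) sum(isFore & ann$category == k), integer(1))
  totK <- vapply(cats, function(k) sum(ann$category == k), integer(1))
  a <- inForeK
  b <- nFore - inForeK
  c <- totK - inForeK
  d <- (nTot - nFore) - c
  oddsRatio <- ifelse(a * d == 0 & b * c == 0, 1, (a * d) / (b * c))
  pRaw <- .hyperUpperTail(a, b, c, d)
  pAdj <- bhAdjust(pRaw)
  data.frame(
    category = cats, in_fore = a, fore_size = nFore, in_back = c,
    back_size = nTot, odds_ratio = oddsRatio, p_raw = pRaw, p_adj = pAdj,
    enriched = pAdj < alpha, row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write an enrichment-result table as TSV
#'
#' @param result Data frame as returned by [enrichCategories()].
#' @param path Output file path.
#' @param params Optional named list written as `# key=value` header lines.
#' @return `path`, invisibly.
#' @export
writeEnrichment <- function(result, path, params = NULL) {
  writeTsv(result, path, params = params)
  invisible(path)
}
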