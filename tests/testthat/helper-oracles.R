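## Independent oracles used across test files. These deliberately avoid the
## package's own code paths: the Fisher oracle enumerates hypergeometric
## outcomes term by term, the BH oracle is the step-up definition written
## out directly, and the rarefaction oracle enumerates read subsets.

oracleFisherUpper <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c
  n <- a + b
  ks <- a:min(K, n)
  ks <- ks[n - ks <= N - K]
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(sorted[i:m] * m / (i:m), 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

## Expected distinct genes in a subsample of size m, by full enumeration of
## all read subsets (feasible for total reads <= 12).
oracleRarefaction <- function(counts, m) {
  reads <- rep(seq_along(counts), counts)
  subsets <- utils::combn(length(reads), m)
  mean(apply(subsets, 2, function(idx) length(unique(reads[idx]))))
}

## Toy ontology shared by GO tests: three namespaces are not needed for
## unit checks, one suffices; builders for specific shapes live in the
## tests themselves.
chainDag <- function(n) {
  ids <- paste0("GO:", sprintf("%07d", seq_len(n + 1)))
  terms <- data.frame(id = ids, name = ids, namespace = "biological_process",
                      stringsAsFactors = FALSE)
  parents <- c(list(character(0)), as.list(ids[-(n + 1)]))
  names(parents) <- ids
  GoOntology(terms, parents)
}

## GRanges builder for colocation tests: genes laid left to right on one
## contig with the given strands.
lociTrack <- function(genes, strands, contig = "c1", gap = 100, width = 500) {
  starts <- seq(1, by = width + gap, length.out = length(genes))
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = starts, width = width),
    strand = strands
  )
  names(gr) <- genes
  gr$type <- "gene"
  gr$ID <- genes
  gr
}
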