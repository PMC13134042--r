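hitLine <- function(q, s, e, tax) {
  paste(q, s, "50.0", "100", "40", "2", "1", "100", "1", "100",
        format(e, scientific = TRUE), "200.5", tax, sep = "\t")
}

test_that("the 13-column hit dialect is parsed, multi-taxids included", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hitLine("q1", "s1", 1e-30, "988779"),
               hitLine("q1", "s2", 1e-10, "562;624")), path)
  hits <- readBlastHits(path)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$staxids[[2]], c(562L, 624L))
  expect_equal(hits$evalue, c(1e-30, 1e-10))
})

test_that("lines with the wrong column count are rejected with a line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hitLine("q1", "s1", 1e-30, "988779"),
               paste(rep("x", 12), collapse = "\t")), path)
  expect_error(readBlastHits(path), "line 2.*12 columns")
})

test_that("Alien Index follows the log-ratio of best E-values", {
  mk <- function(q, e, tax) {
    h <- data.frame(qseqid = q, sseqid = paste0("s", seq_along(q)),
                    evalue = e, bitscore = 100)
    h$staxids <- lapply(tax, as.integer)
    h
  }
  # no hits at all: both sides default to 1, AI = 0
  noHits <- data.frame(qseqid = character(0), sseqid = character(0),
                       evalue = numeric(0), bitscore = numeric(0))
  noHits$staxids <- list()
  rec0 <- alienIndex(noHits, ingroup = 988779, genes = "lonely")
  expect_equal(rec0$ai, 0)
  rec1 <- alienIndex(mk(c("g", "g"), c(1e-5, 1e-50), list(988779, 42)),
                     ingroup = 988779)
  expect_equal(rec1$ai, log(1e-5 + 1e-200) - log(1e-50 + 1e-200))
  expect_equal(rec1$ai, 103.6, tolerance = 1e-3)
  rec2 <- alienIndex(mk(c("g", "g"), c(1e-80, 1e-60), list(988779, 42)),
                     ingroup = 988779)
  expect_equal(rec2$ai, -46.05, tolerance = 1e-3)
  # ingroup-only hits can never yield a candidate
  rec3 <- alienIndex(mk("g", 1e-40, list(988779)), ingroup = 988779)
  expect_lte(rec3$ai, 0)
  # a hit spanning ingroup and outgroup taxa counts as ingroup
  rec4 <- alienIndex(mk("g", 1e-40, list(c(988779, 42))), ingroup = 988779)
  expect_equal(rec4$best_in_e, 1e-40)
  expect_equal(rec4$best_out_e, 1)
})

test_that("AI is antisymmetric and invariant to hit order and weak hits", {
  mk <- function(e, tax) {
    h <- data.frame(qseqid = "g", sseqid = paste0("s", seq_along(e)),
                    evalue = e, bitscore = 100)
    h$staxids <- lapply(tax, as.integer)
    h
  }
  a <- alienIndex(mk(c(1e-12, 1e-33), list(1, 2)), ingroup = 1)$ai
  b <- alienIndex(mk(c(1e-33, 1e-12), list(1, 2)), ingroup = 1)$ai
  expect_equal(a, -b)
  shuffled <- alienIndex(mk(c(1e-33, 1e-12), list(2, 1)), ingroup = 1)$ai
  expect_equal(a, shuffled)
  withWeak <- alienIndex(mk(c(1e-12, 1e-33, 1e-4, 1e-2), list(1, 2, 1, 2)),
                         ingroup = 1)$ai
  expect_equal(a, withWeak)
})

test_that("candidate calling is strict at the threshold", {
  rec <- data.frame(query = c("a", "b", "c"), ai = c(45, 46, -100))
  out <- callCandidates(rec)
  expect_equal(out$candidate, c(FALSE, TRUE, FALSE))
  expect_equal(callCandidates(rec, threshold = 40)$candidate,
               c(TRUE, TRUE, FALSE))
})

test_that("planted HGT profiles are recovered exactly", {
  cfg <- simulationConfig(seed = 47, nSymbiontGenes = 200, nHitQueries = 80,
                          nHgtGenes = 6, symbiontDepth = 10000)
  sym <- simulateSymbiont(cfg)
  hx <- simulateHits(cfg, sym$genes, sym$hgt_genes)
  rec <- callCandidates(alienIndex(hx$hits, ingroup = cfg$ingroupTaxid,
                                   genes = sym$genes))
  expect_setequal(rec$query[rec$candidate], sym$hgt_genes)
  # generator arithmetic and package arithmetic agree to numerical precision
  merged <- merge(rec, hx$truth, by.x = "query", by.y = "gene")
  expect_equal(merged$ai, merged$planted_ai, tolerance = 1e-9)
})

test_that("operon blocks report consecutive runs with strand patterns", {
  loci <- lociTrack(paste0("g", 1:10),
                    c("+", "+", "+", "+", "+", "-", "+", "-", "+", "+"))
  # six adjacent genes, five on + and the last on -
  blocks <- operonBlocks(loci, paste0("g", 1:6))
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$strands, "+++++-")
  expect_false(blocks$same_strand)
  # an intervening non-set gene splits a run
  blocks2 <- operonBlocks(loci, c("g1", "g2", "g4", "g5"))
  expect_equal(nrow(blocks2), 2L)
  expect_equal(blocks2$n_genes, c(2L, 2L))
  # a singleton forms its own block
  blocks3 <- operonBlocks(loci, "g9")
  expect_equal(blocks3$n_genes, 1L)
  expect_equal(blocks3$strands, "+")
  expect_error(operonBlocks(loci, "missing"), "absent")
})

test_that("blocks never span contigs", {
  loci <- suppressWarnings(
    c(lociTrack(paste0("a", 1:3), rep("+", 3), contig = "c1"),
      lociTrack(paste0("b", 1:3), rep("+", 3), contig = "c2"))
  )
  blocks <- operonBlocks(loci, c("a3", "b1"))
  expect_equal(nrow(blocks), 2L)
})

test_that("GFF3 loci round-trip preserves order, strand and identifiers", {
  cfg <- simulationConfig(seed = 53, nSymbiontGenes = 60, nHitQueries = 30,
                          nHgtGenes = 4, symbiontDepth = 5000)
  sym <- simulateSymbiont(cfg)
  path <- withr::local_tempfile(fileext = ".gff3")
  rtracklayer::export(sym$loci, path, format = "gff3")
  back <- readGeneLoci(path)
  expect_setequal(names(back), names(sym$loci))
  common <- names(sym$loci)
  expect_equal(as.character(GenomicRanges::strand(back[common])),
               as.character(GenomicRanges::strand(sym$loci[common])))
  expect_equal(GenomicRanges::start(back[common]),
               GenomicRanges::start(sym$loci[common]))
})
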