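test_that("TPM normalization follows the per-base-rate definition", {
  tpm <- computeTpm(c(a = 5, b = 5, c = 5, d = 5), rep(1000, 4))
  expect_equal(tpm$tpm, rep(2.5e5, 4))
  tpm2 <- computeTpm(c(a = 10, b = 20), c(1000, 2000))
  expect_equal(tpm2$tpm, c(5e5, 5e5))
  set.seed(4)
  tpm3 <- computeTpm(rpois(50, 30), runif(50, 200, 3000))
  expect_equal(sum(tpm3$tpm), 1e6, tolerance = 1e-6)
  expect_true(all((tpm3$tpm == 0) == (tpm3$read_count == 0)))
  expect_error(computeTpm(c(0, 0), c(100, 100)), "all-zero")
  expect_error(computeTpm(c(1, 2), c(100, 0)), "positive")
})

test_that("replicate merging sums counts and preserves TPM under scaling", {
  r <- c(g1 = 10, g2 = 0, g3 = 5)
  merged <- mergeReplicates(list(r, r, r))
  expect_equal(merged, 3 * r)
  expect_equal(computeTpm(merged, c(100, 200, 300))$tpm,
               computeTpm(r, c(100, 200, 300))$tpm)
  withEmpty <- mergeReplicates(list(r, c(g1 = 0, g2 = 0, g3 = 0)))
  expect_equal(withEmpty, r)
  expect_error(mergeReplicates(list(r, c(g1 = 1, gX = 2, g3 = 3))),
               "gene universe")
  # merged detection is at least each replicate's detection
  set.seed(12)
  reps <- lapply(1:3, function(i) {
    setNames(as.vector(rmultinom(1, 200, rep(1, 100))), paste0("g", 1:100))
  })
  m <- mergeReplicates(reps)
  for (r in reps) expect_gte(sum(m > 0), sum(r > 0))
})

test_that("activity classification uses a strict zero test", {
  cls <- classifyActivity(c(g1 = 0, g2 = 1e-9, g3 = 12))
  expect_equal(cls$activity, c("inactive", "active", "active"))
  expect_error(classifyActivity(c(g1 = -1)), "negative")
  allActive <- classifyActivity(c(a = 1, b = 2))
  expect_false(any(allActive$activity == "inactive"))
})

test_that("expression strata respect strict above/below percentile wording", {
  s <- stratifyExpression(setNames(as.numeric(1:8), paste0("g", 1:8)))
  expect_setequal(s$gene[s$stratum == "high"], c("g7", "g8"))
  expect_setequal(s$gene[s$stratum == "low"], c("g1", "g2"))
  expect_setequal(s$gene[s$stratum == "moderate"], paste0("g", 3:6))
  expect_equal(attr(s, "q_high"), 6.25)
  expect_equal(attr(s, "q_low"), 2.75)
  # constant vector: nothing strictly above or below the threshold
  s2 <- stratifyExpression(setNames(rep(3, 5), paste0("g", 1:5)))
  expect_true(all(s2$stratum == "moderate"))
  # a value exactly at the 75th percentile stays moderate
  s3 <- stratifyExpression(setNames(c(1, 2, 3, 4, 4), paste0("g", 1:5)))
  q75 <- quantileThreshold(c(1, 2, 3, 4, 4), 0.75)
  expect_equal(q75, 4)
  expect_true(all(s3$stratum[s3$tpm == 4] == "moderate"))
  expect_error(stratifyExpression(numeric(0)), "empty")
  expect_error(stratifyExpression(c(g1 = 0, g2 = 2)), "active")
})

test_that("stratification is invariant to positive rescaling", {
  set.seed(31)
  v <- setNames(rlnorm(200), paste0("g", 1:200))
  expect_equal(stratifyExpression(v)$stratum,
               stratifyExpression(v * 1234.5)$stratum)
})

test_that("strata and activity classes partition the gene universe", {
  set.seed(8)
  tpm <- setNames(c(rep(0, 40), rlnorm(160)), paste0("g", 1:200))
  cls <- classifySymbiont(tpm)
  expect_equal(sum(cls$activity == "active") + sum(cls$activity == "inactive"),
               200L)
  act <- cls[cls$activity == "active", ]
  expect_equal(sum(act$stratum == "high") + sum(act$stratum == "moderate") +
                 sum(act$stratum == "low"), nrow(act))
  expect_true(all(cls$stratum[cls$activity == "inactive"] == "none"))
})

test_that("exact rarefaction matches subset enumeration and is concave", {
  expect_equal(rarefactionCurve(c(2, 1, 1), 2)$expected_genes, 11 / 6)
  set.seed(14)
  for (i in 1:5) {
    counts <- as.vector(rmultinom(1, sample(6:12, 1), rep(1, 4)))
    N <- sum(counts)
    for (m in 1:N) {
      expect_equal(rarefactionCurve(counts, m)$expected_genes,
                   oracleRarefaction(counts, m), tolerance = 1e-9)
    }
  }
  # full depth recovers all detected genes; curve monotone and concave
  counts <- c(5, 3, 0, 2, 9, 1)
  cur <- rarefactionCurve(counts, 1:sum(counts))
  expect_equal(cur$expected_genes[sum(counts)], sum(counts > 0))
  expect_true(all(diff(cur$expected_genes) > -1e-12))
  expect_true(all(diff(diff(cur$expected_genes)) < 1e-12))
  expect_error(rarefactionCurve(counts, sum(counts) + 1), "depths")
})

test_that("Monte-Carlo rarefaction agrees with the exact expectation", {
  set.seed(3)
  counts <- setNames(as.vector(rmultinom(1, 500, rlnorm(40))), paste0("g", 1:40))
  depths <- c(50, 200, 400)
  ex <- rarefactionCurve(counts, depths, mode = "exact")
  mc <- rarefactionCurve(counts, depths, mode = "montecarlo", nrep = 200,
                         seed = 77)
  se <- mc$mc_sd / sqrt(200)
  expect_true(all(abs(mc$expected_genes - ex$expected_genes) <= 3 * se + 1e-9))
})

test_that("saturation verdicts reproduce the replicate-merge decision", {
  flat <- data.frame(depth = c(50, 100), expected_genes = c(80, 80.1),
                     mc_sd = NA)
  expect_true(saturationCheck(flat))
  # an undersampled library full of singletons keeps climbing
  singletons <- setNames(rep(1, 400), paste0("g", 1:400))
  cur <- rarefactionCurve(singletons, c(200, 400))
  expect_false(saturationCheck(cur))
  # three shallow replicates are inadequate; their merge is adequate
  set.seed(1)
  ab <- rlnorm(400, 0, 1); prob <- ab / sum(ab)
  reps <- lapply(1:3, function(i) {
    setNames(as.vector(rmultinom(1, 2500, prob)), paste0("g", 1:400))
  })
  curveOf <- function(cts) {
    N <- sum(cts)
    rarefactionCurve(cts, round(seq(N / 10, N, length.out = 10)))
  }
  for (r in reps) expect_false(saturationCheck(curveOf(r)))
  expect_true(saturationCheck(curveOf(mergeReplicates(reps))))
})

test_that("classification enrichment applies the paper's background rules", {
  # planted: active genes 4x enriched in one COG letter
  cfg <- simulationConfig(seed = 37, nSymbiontGenes = 800, nHitQueries = 100,
                          symbiontDepth = 60000)
  sym <- simulateSymbiont(cfg)
  tpm <- computeTpm(mergeReplicates(sym$counts), sym$lengths)
  cls <- classifySymbiont(tpm)
  res <- classificationEnrichment(cls, cogAnnotation = sym$cog)
  hit <- res[res$classification == "activity" & res$foreground == "active" &
               res$category == cfg$plantedCog, ]
  expect_true(hit$enriched)
  # a category carried only by inactive genes never enters the
  # expression-level background
  inact <- cls$gene[cls$activity == "inactive"][1:5]
  cog2 <- rbind(sym$cog[!sym$cog$gene %in% inact, ],
                data.frame(gene = inact, category = "Z"))
  res2 <- classificationEnrichment(cls, cogAnnotation = cog2)
  expr <- res2[res2$classification == "expression_level", ]
  expect_false("Z" %in% expr$category)
  expect_true("Z" %in% res2$category[res2$classification == "activity"])
  # degenerate: everything active in a single stratum flags nothing
  oneClass <- data.frame(gene = paste0("g", 1:50),
                         tpm = 1, activity = "active", stratum = "moderate")
  ann <- data.frame(gene = paste0("g", 1:50),
                    category = rep(c("A", "B"), 25))
  res3 <- classificationEnrichment(oneClass, cogAnnotation = ann)
  expect_false(any(res3$enriched))
  # unknown stratum labels are rejected
  bad <- oneClass; bad$stratum[1] <- "extreme"
  expect_error(classificationEnrichment(bad, cogAnnotation = ann), "stratum")
})

test_that("symbiont counts and COG tables round-trip through their readers", {
  cfg <- simulationConfig(seed = 41, nSymbiontGenes = 100, nHitQueries = 50,
                          symbiontDepth = 5000)
  sym <- simulateSymbiont(cfg)
  dir <- withr::local_tempdir()
  writeTsv(data.frame(gene = sym$genes, effective_length = unname(sym$lengths),
                      sym$counts, check.names = FALSE),
           file.path(dir, "sc.tsv"))
  back <- readSymbiontCounts(file.path(dir, "sc.tsv"))
  expect_equal(back$counts, sym$counts)
  expect_equal(back$lengths, sym$lengths)
  writeTsv(sym$cog_table, file.path(dir, "cog.tsv"))
  cog <- readCogAnnotation(file.path(dir, "cog.tsv"))
  expect_setequal(paste(cog$gene, cog$category),
                  paste(sym$cog$gene, sym$cog$category))
})
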