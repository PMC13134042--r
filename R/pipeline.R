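#' Analysis thresholds for the end-to-end pipeline
#'
#' Defaults equal the study's printed thresholds, so a bare run reproduces
#' the published settings: FDR 0.05 and |log2FC| > 1 for host DEGs, Alien
#' Index > 45 for HGT candidates, 25th/75th percentiles for expression
#' strata, at least 3 genes for the concatenation taxon filter, and the
#' genome-quality cutoffs (over 80% complete, under 2% duplicated).
#'
#' @param alpha FDR significance threshold.
#' @param lfc Absolute log2-fold-change threshold.
#' @param aiThreshold Alien Index threshold.
#' @param qLow,qHigh Percentile fractions for expression strata.
#' @param minGenes Minimum genes per organism for concatenation.
#' @param minComplete,maxDup Genome-quality cutoffs (percent).
#' @param goLevels GO hierarchy levels analysed.
#' @param relGain Rarefaction saturation threshold (relative gain).
#' @return A validated list of class `symbioseqConfig`.
#' @export
pipelineConfig <- function(alpha = 0.05, lfc = 1.0, aiThreshold = 45,
                           qLow = 0.25, qHigh = 0.75, minGenes = 3L,
                           minComplete = 80, maxDup = 2,
                           goLevels = c(3L, 4L), relGain = 0.01) {
  stopifnot(alpha > 0, alpha < 1, lfc >= 0, qLow >= 0, qHigh <= 1,
            qLow < qHigh, minGenes >= 1, minComplete >= 0, minComplete <= 100,
            maxDup >= 0, maxDup <= 100, relGain > 0)
  cfg <- list(alpha = alpha, lfc = lfc, aiThreshold = aiThreshold,
              qLow = qLow, qHigh = qHigh, minGenes = minGenes,
              minComplete = minComplete, maxDup = maxDup,
              goLevels = goLevels, relGain = relGain)
  class(cfg) <- "symbioseqConfig"
  cfg
}

.stageParams <- function(config, seed, extra = NULL) {
  c(list(seed = seed), config[c("alpha", "lfc", "aiThreshold", "qLow",
                                "qHigh", "minGenes", "minComplete",
                                "maxDup", "relGain")], extra)
}

#' Host differential-expression stage
#'
#' Reads counts and sample sheet, runs the NB Wald test and DEG calling,
#' and writes the DEG table and volcano-plot coordinates.
#'
#' @param countsPath,samplesPath Input TSVs (see [readHostCounts()]).
#' @param outDir Output directory.
#' @param config A [pipelineConfig()].
#' @param reference Reference condition (default: first level).
#' @param seed Seed recorded in output headers.
#' @return The DEG table, invisibly.
#' @export
stageHostDeg <- function(countsPath, samplesPath, outDir,
                         config = pipelineConfig(), reference = NULL,
                         seed = NA) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hcs <- readHostCounts(countsPath, samplesPath, reference = reference)
  res <- callDegs(nbTest(hcs), alpha = config$alpha, lfc = config$lfc)
  p <- .stageParams(config, seed, list(reference = referenceCondition(hcs)))
  writeTsv(res, file.path(outDir, "host_degs.tsv"), params = p)
  writeTsv(volcanoData(res), file.path(outDir, "host_volcano.tsv"), params = p)
  invisible(res)
}

#' GO enrichment stage
#'
#' @param oboPath OBO ontology file.
#' @param annotationPath Gene-to-term TSV (`gene`, `term`).
#' @param degTable DEG table from [stageHostDeg()] (or its TSV re-read).
#' @param outDir Output directory.
#' @param config A [pipelineConfig()].
#' @param seed Seed recorded in output headers.
#' @return The combined enrichment table, invisibly.
#' @export
stageGoEnrich <- function(oboPath, annotationPath, degTable, outDir,
                          config = pipelineConfig(), seed = NA) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dag <- readOBO(oboPath)
  ann <- readTsv(annotationPath)
  s <- degSummary(degTable)
  res <- hostGoEnrichment(dag, ann, s$up, s$down, levels = config$goLevels,
                          alpha = config$alpha)
  writeTsv(res, file.path(outDir, "go_enrichment.tsv"),
           params = .stageParams(config, seed))
  ## dot-plot data: term, direction, namespace, count, adjusted p
  if (nrow(res) > 0L) {
    dot <- res[res$enriched,
               c("category", "direction", "namespace", "level", "in_fore", "p_adj")]
    names(dot)[names(dot) == "category"] <- "term"
    names(dot)[names(dot) == "in_fore"] <- "count"
    writeTsv(dot, file.path(outDir, "go_dotplot.tsv"),
             params = .stageParams(config, seed))
  }
  invisible(res)
}

#' Symbiont classification stage
#'
#' Merges replicates, recomputes TPM on the merged read set, and writes
#' the activity/stratum classification.
#'
#' @param symbiontCountsPath TSV (see [readSymbiontCounts()]).
#' @param outDir Output directory.
#' @param config A [pipelineConfig()].
#' @param seed Seed recorded in output headers.
#' @return List with `tpm` and `classified`, invisibly.
#' @export
stageSymbiontClassify <- function(symbiontCountsPath, outDir,
                                  config = pipelineConfig(), seed = NA) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sc <- readSymbiontCounts(symbiontCountsPath)
  merged <- mergeReplicates(sc$counts)
  tpm <- computeTpm(merged, sc$lengths[rownames(sc$counts)])
  classified <- classifySymbiont(tpm, qLow = config$qLow, qHigh = config$qHigh)
  writeTsv(classified, file.path(outDir, "symbiont_classification.tsv"),
           params = .stageParams(config, seed))
  invisible(list(tpm = tpm, classified = classified))
}

#' Rarefaction stage
#'
#' Exact rarefaction curves for each replicate and for the merged read
#' set, plus the saturation verdicts.
#'
#' @param symbiontCountsPath TSV (see [readSymbiontCounts()]).
#' @param outDir Output directory.
#' @param config A [pipelineConfig()].
#' @param nDepths Number of evenly spaced depths per curve (default 10).
#' @param seed Seed recorded in output headers.
#' @return List with `curves` and `saturation`, invisibly.
#' @export
stageRarefy <- function(symbiontCountsPath, outDir,
                        config = pipelineConfig(), nDepths = 10L, seed = NA) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sc <- readSymbiontCounts(symbiontCountsPath)
  sets <- c(
    stats::setNames(lapply(seq_len(ncol(sc$counts)),
                           function(j) sc$counts[, j]),
                    colnames(sc$counts)),
    list(merged = mergeReplicates(sc$counts))
  )
  curves <- list()
  sat <- data.frame(read_set = names(sets), total_reads = NA_real_,
                    detected_genes = NA_real_, adequate = NA)
  for (i in seq_along(sets)) {
    counts <- sets[[i]]
    N <- sum(counts)
    depths <- unique(round(seq(N / nDepths, N, length.out = nDepths)))
    cur <- rarefactionCurve(counts, depths, mode = "exact")
    cur <- cbind(read_set = names(sets)[i], cur)
    curves[[i]] <- cur
    sat$total_reads[i] <- N
    sat$detected_genes[i] <- sum(counts > 0)
    sat$adequate[i] <- saturationCheck(cur, relGain = config$relGain)
  }
  curves <- do.call(rbind, curves)
  writeTsv(curves, file.path(outDir, "rarefaction_curves.tsv"),
           params = .stageParams(config, seed))
  writeTsv(sat, file.path(outDir, "rarefaction_saturation.tsv"),
           params = .stageParams(config, seed))
  invisible(list(curves = curves, saturation = sat))
}

#' Pangenome refinement stage
#'
#' Applies the genome-quality filter, refines persistent families into
#' core and soft-core, and writes per-gene refined labels for the
#' enrichment stage.
#'
#' @param pangenomePath Presence/absence TSV (see [readPresenceAbsence()]).
#' @param qualityPath Quality summary TSV (`genome`, `complete_single`,
#'   `duplicated`).
#' @param geneFamiliesPath Optional gene-to-family TSV.
#' @param outDir Output directory.
#' @param config A [pipelineConfig()].
#' @param seed Seed recorded in output headers.
#' @return List with `refined`, `kept_genomes` and `gene_labels`,
#'   invisibly.
#' @export
stagePangenome <- function(pangenomePath, qualityPath, geneFamiliesPath = NULL,
                           outDir, config = pipelineConfig(), seed = NA) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  mat <- readPresenceAbsence(pangenomePath)
  quality <- readTsv(qualityPath)
  kept <- qualityFilter(quality, minComplete = config$minComplete,
                        maxDup = config$maxDup)
  genomeCols <- setdiff(names(mat), c("family", "partition"))
  dropped <- setdiff(genomeCols, kept)
  if (length(dropped) > 0L) {
    warning("dropping genome column(s) failing the quality filter: ",
            paste(dropped, collapse = ", "))
    mat <- mat[, c("family", "partition", intersect(genomeCols, kept))]
  }
  refined <- refinePartitions(mat)
  fams <- if (!is.null(geneFamiliesPath)) readTsv(geneFamiliesPath) else NULL
  labels <- pangenomeGeneLabels(refined, fams)
  p <- .stageParams(config, seed, list(kept_genomes = length(kept)))
  writeTsv(refined, file.path(outDir, "pangenome_refined.tsv"), params = p)
  writeTsv(labels, file.path(outDir, "pangenome_gene_labels.tsv"), params = p)
  invisible(list(refined = refined, kept_genomes = kept, gene_labels = labels))
}

#' Symbiont category-enrichment stage
#'
#' @param classified Classification table from [stageSymbiontClassify()].
#' @param cogPath COG annotation TSV (`gene`, `cog`).
#' @param pangenomeLabels Per-gene refined partition labels from
#'   [stagePangenome()] (or NULL to skip).
#' @param outDir Output directory.
#' @param config A [pipelineConfig()].
#' @param seed Seed recorded in output headers.
#' @return The enrichment table, invisibly.
#' @export
stageEnrich <- function(classified, cogPath, pangenomeLabels = NULL, outDir,
                        config = pipelineConfig(), seed = NA) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cog <- readCogAnnotation(cogPath)
  res <- classificationEnrichment(classified, cogAnnotation = cog,
                                  pangenomeLabels = pangenomeLabels,
                                  alpha = config$alpha)
  writeTsv(res, file.path(outDir, "symbiont_enrichment.tsv"),
           params = .stageParams(config, seed))
  invisible(res)
}

#' Alien Index stage
#'
#' @param hitsPath 13-column homology-hit table.
#' @param genes Full query universe (genes without hits get AI 0).
#' @param ingroup Ingroup taxon id(s).
#' @param outDir Output directory.
#' @param config A [pipelineConfig()].
#' @param seed Seed recorded in output headers.
#' @return The AI record table with candidate calls, invisibly.
#' @export
stageAlienIndex <- function(hitsPath, genes, ingroup, outDir,
                            config = pipelineConfig(), seed = NA) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hits <- readBlastHits(hitsPath)
  rec <- callCandidates(alienIndex(hits, ingroup = ingroup, genes = genes),
                        threshold = config$aiThreshold)
  p <- .stageParams(config, seed, list(ingroup = paste(ingroup, collapse = ",")))
  writeTsv(rec, file.path(outDir, "alien_index.tsv"), params = p)
  writeTsv(data.frame(gene = rec$query[rec$candidate]),
           file.path(outDir, "hgt_candidates.tsv"), params = p)
  invisible(rec)
}

#' Operon colocation stage
#'
#' @param gffPath GFF3 gene map.
#' @param geneSet Genes of interest (e.g. HGT candidates).
#' @param outDir Output directory.
#' @param config A [pipelineConfig()].
#' @param seed Seed recorded in output headers.
#' @return The block table, invisibly.
#' @export
stageOperons <- function(gffPath, geneSet, outDir,
                         config = pipelineConfig(), seed = NA) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  loci <- readGeneLoci(gffPath)
  blocks <- operonBlocks(loci, geneSet)
  writeTsv(blocks, file.path(outDir, "operon_blocks.tsv"),
           params = .stageParams(config, seed))
  invisible(blocks)
}

#' Concatenation stage
#'
#' @param alignmentDir Directory of per-gene FASTA alignments (`*.faa` or
#'   `*.fasta`).
#' @param outDir Output directory.
#' @param config A [pipelineConfig()].
#' @param seed Seed recorded in output headers (unused by the
#'   computation, which is deterministic).
#' @return The supermatrix list, invisibly.
#' @export
stageConcat <- function(alignmentDir, outDir, config = pipelineConfig(),
                        seed = NA) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list.files(alignmentDir, pattern = "\\.(faa|fa|fasta)$",
                      full.names = TRUE)
  if (length(paths) == 0L) stop("no alignments found in ", alignmentDir)
  alns <- readGeneAlignments(paths)
  retained <- filterTaxa(alns, minGenes = config$minGenes)
  sm <- concatenateAlignments(alns, retained)
  writeSupermatrix(sm, file.path(outDir, "supermatrix.faa"),
                   file.path(outDir, "supermatrix_partitions.txt"))
  invisible(sm)
}

#' Run the full synthetic-to-results pipeline
#'
#' Simulates a complete study under one seed, writes every input file,
#' reads them all back through the package's own readers, and runs every
#' analysis stage, writing the full artifact set under `outDir`. Rerunning
#' with the same seed and configuration reproduces every output byte for
#' byte.
#'
#' @param outDir Output directory.
#' @param seed Global seed.
#' @param simConfig A [simulationConfig()] (defaults to one built on
#'   `seed`).
#' @param config A [pipelineConfig()].
#' @param verbose Emit progress messages.
#' @return Invisibly, a list of key stage results.
#' @export
runPipeline <- function(outDir, seed = 1L,
                        simConfig = simulationConfig(seed = seed),
                        config = pipelineConfig(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  inDir <- file.path(outDir, "inputs")
  say("simulating inputs")
  sim <- simulateAll(simConfig)
  writeSimulation(sim, inDir)
  say("host differential expression")
  degs <- stageHostDeg(file.path(inDir, "host_counts.tsv"),
                       file.path(inDir, "samples.tsv"), outDir,
                       config = config, reference = "Mminus", seed = seed)
  say("GO enrichment")
  go <- stageGoEnrich(file.path(inDir, "go.obo"),
                      file.path(inDir, "go_annotation.tsv"),
                      degs, outDir, config = config, seed = seed)
  say("symbiont classification")
  cls <- stageSymbiontClassify(file.path(inDir, "symbiont_counts.tsv"),
                               outDir, config = config, seed = seed)
  say("rarefaction")
  rar <- stageRarefy(file.path(inDir, "symbiont_counts.tsv"), outDir,
                     config = config, seed = seed)
  say("pangenome refinement")
  pan <- stagePangenome(file.path(inDir, "pangenome.tsv"),
                        file.path(inDir, "busco.tsv"),
                        file.path(inDir, "gene_families.tsv"),
                        outDir, config = config, seed = seed)
  say("symbiont enrichment")
  enr <- stageEnrich(cls$classified, file.path(inDir, "cog.tsv"),
                     pan$gene_labels, outDir, config = config, seed = seed)
  say("alien index")
  ai <- stageAlienIndex(file.path(inDir, "hits.tsv"), sim$symbiont$genes,
                        ingroup = simConfig$ingroupTaxid, outDir,
                        config = config, seed = seed)
  say("operon blocks")
  ops <- stageOperons(file.path(inDir, "loci.gff3"),
                      ai$query[ai$candidate], outDir,
                      config = config, seed = seed)
  say("concatenation")
  sm <- stageConcat(file.path(inDir, "alignments"), outDir,
                    config = config, seed = seed)
  invisible(list(sim = sim, degs = degs, go = go, classified = cls$classified,
                 rarefaction = rar, pangenome = pan, enrichment = enr,
                 alien = ai, operons = ops, supermatrix = sm))
}
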