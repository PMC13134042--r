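#' Configuration for the synthetic dual RNA-Seq study
#'
#' Bundles every parameter of the seeded generator that emulates the study
#' design: a two-condition (symbiont-positive vs symbiont-negative) host
#' experiment with three replicates per condition, a symbiont transcriptome
#' of 1755 protein-coding genes of which roughly 78.5% are transcriptionally
#' active, a 13-genome pangenome, and a homology-hit screen with a handful
#' of planted horizontally transferred genes arranged as an operon-like
#' block. One global seed fans out to per-stage substreams so each stage
#' can be regenerated independently.
#'
#' @param seed Global integer seed.
#' @param nHostGenes Number of host genes (desk-scale default 5000).
#' @param nSymbiontGenes Number of symbiont genes (default 1755).
#' @param replicates Replicates per condition (default 3).
#' @param degFraction Fraction of host genes differentially expressed
#'   (default 0.1), split evenly between up and down.
#' @param degLog2fc Absolute planted log2 fold change for DE genes
#'   (default 3).
#' @param nbDispersion Negative-binomial dispersion of host counts
#'   (default 0.05).
#' @param baseMeanMeanlog,baseMeanSdlog Log-normal parameters of host
#'   baseline means (defaults log(200) and 1).
#' @param baseMeanConstant If non-NULL, all baseline means are set to this
#'   constant instead of being drawn.
#' @param libSizeRange Range of per-sample library-size multipliers
#'   (default 0.8-1.25).
#' @param goEnrichFactor Frequency multiplier of the planted GO term among
#'   up-regulated genes (default 10).
#' @param goTermsPerGene Annotated terms drawn per annotated gene
#'   (default 2).
#' @param goAnnotatedFraction Fraction of host genes carrying GO
#'   annotation (default 0.8).
#' @param plantedCog COG letter planted as enriched among active symbiont
#'   genes (default "M").
#' @param cogEnrichFactor Frequency multiplier of the planted COG letter
#'   among active genes (default 4).
#' @param zeroFraction Fraction of symbiont genes with zero expression
#'   (default 378/1755, i.e. about 21.5% inactive).
#' @param symbiontDepth Reads per symbiont replicate (default 150000).
#' @param nGenomes Genomes in the pangenome (default 13; the first is the
#'   focal genome, always present).
#' @param coreFraction Fraction of persistent families present in every
#'   genome (default 0.6).
#' @param nHgtGenes Planted horizontally transferred genes, arranged
#'   consecutively with the last one on the opposite strand (default 6).
#' @param nHitQueries Symbiont genes with homology hits (default 300,
#'   always including the HGT genes).
#' @param ingroupTaxid Ingroup taxon id for the Alien Index screen
#'   (default 988779).
#' @return A list of class `symbioseqSimConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             nHostGenes = 5000L,
                             nSymbiontGenes = 1755L,
                             replicates = 3L,
                             degFraction = 0.1,
                             degLog2fc = 3,
                             nbDispersion = 0.05,
                             baseMeanMeanlog = log(200),
                             baseMeanSdlog = 1,
                             baseMeanConstant = NULL,
                             libSizeRange = c(0.8, 1.25),
                             goEnrichFactor = 10,
                             goTermsPerGene = 2L,
                             goAnnotatedFraction = 0.8,
                             plantedCog = "M",
                             cogEnrichFactor = 4,
                             zeroFraction = 378 / 1755,
                             symbiontDepth = 150000L,
                             nGenomes = 13L,
                             coreFraction = 0.6,
                             nHgtGenes = 6L,
                             nHitQueries = 300L,
                             ingroupTaxid = 988779L) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$degFraction >= 0, cfg$degFraction <= 1,
    cfg$zeroFraction >= 0, cfg$zeroFraction < 1,
    cfg$goAnnotatedFraction >= 0, cfg$goAnnotatedFraction <= 1,
    cfg$replicates >= 2, cfg$nGenomes >= 2,
    cfg$nbDispersion > 0, cfg$coreFraction >= 0, cfg$coreFraction <= 1,
    cfg$nHgtGenes <= cfg$nHitQueries, cfg$nHitQueries <= cfg$nSymbiontGenes
  )
  class(cfg) <- "symbioseqSimConfig"
  cfg
}

#' Simulate the host count matrix with planted differential expression
#'
#' Negative-binomial counts for a two-condition, replicated design. A
#' configured fraction of genes carries a planted log2 fold change (half
#' up, half down in the symbiont-positive condition relative to the
#' symbiont-negative reference); per-sample library-size multipliers are
#' applied on top.
#'
#' @param config A [simulationConfig()].
#' @return List with `counts` (a [HostCountSet-class], reference
#'   `"Mminus"`), `truth` (data frame `gene`, `is_de`, `log2fc`) and
#'   `lib_sizes`.
#' @export
simulateHostCounts <- function(config) {
  set.seed(stageSeed(config$seed, "host"))
  n <- config$nHostGenes
  genes <- sprintf("PPRIM_%05d", seq_len(n))
  base <- if (!is.null(config$baseMeanConstant)) {
    rep(config$baseMeanConstant, n)
  } else {
    stats::rlnorm(n, config$baseMeanMeanlog, config$baseMeanSdlog)
  }
  nDe <- round(config$degFraction * n)
  deIdx <- sample.int(n, nDe)
  lfc <- numeric(n)
  if (nDe > 0L) {
    signs <- rep(c(1, -1), length.out = nDe)
    lfc[deIdx] <- signs * config$degLog2fc
  }
  reps <- config$replicates
  condition <- rep(c("Mminus", "Mplus"), each = reps)
  samples <- paste0(condition, "_", rep(seq_len(reps), 2))
  libs <- stats::runif(2 * reps, config$libSizeRange[1], config$libSizeRange[2])
  mu <- cbind(
    matrix(base, n, reps),                 # reference condition
    matrix(base * 2^lfc, n, reps)          # symbiont-positive condition
  )
  mu <- sweep(mu, 2, libs, "*")
  counts <- matrix(
    stats::rnbinom(n * 2 * reps, mu = as.vector(mu), size = 1 / config$nbDispersion),
    nrow = n, dimnames = list(genes, samples)
  )
  list(
    counts = HostCountSet(counts, condition, reference = "Mminus"),
    truth = data.frame(gene = genes, is_de = lfc != 0, log2fc = lfc,
                       stringsAsFactors = FALSE),
    lib_sizes = stats::setNames(libs, samples)
  )
}

## Deterministic toy GO graph: per namespace a root, 2 level-1, 3 level-2,
## 5 level-3 and 3 level-4 terms, with a couple of multi-parent terms.
.toyGoDag <- function() {
  nsNames <- c(BP = "biological_process", MF = "molecular_function",
               CC = "cellular_component")
  terms <- list(); parents <- list()
  idn <- 0L
  mkId <- function() {
    idn <<- idn + 1L
    sprintf("GO:%07d", idn)
  }
  for (k in names(nsNames)) {
    root <- mkId()
    l1 <- c(mkId(), mkId())
    l2 <- c(mkId(), mkId(), mkId())
    l3 <- replicate(5, mkId())
    l4 <- c(mkId(), mkId(), mkId())
    ids <- c(root, l1, l2, l3, l4)
    terms[[k]] <- data.frame(
      id = ids,
      name = paste0(k, "_term_", seq_along(ids)),
      namespace = nsNames[[k]], stringsAsFactors = FALSE
    )
    p <- list()
    p[[root]] <- character(0)
    p[[l1[1]]] <- root; p[[l1[2]]] <- root
    p[[l2[1]]] <- l1            # two parents
    p[[l2[2]]] <- l1[1]; p[[l2[3]]] <- l1[2]
    p[[l3[1]]] <- l2[1]; p[[l3[2]]] <- l2[1]; p[[l3[3]]] <- l2[2]
    p[[l3[4]]] <- l2[3]; p[[l3[5]]] <- c(l2[2], l2[3])
    p[[l4[1]]] <- l3[1]
    p[[l4[2]]] <- c(l3[2], l3[3])
    p[[l4[3]]] <- l3[5]
    parents <- c(parents, p)
  }
  GoOntology(do.call(rbind, terms), parents)
}

#' Simulate a toy GO ontology and annotations with a planted enrichment
#'
#' Builds a small three-namespace `is_a` DAG (42 terms, levels 0-4) and
#' annotates host genes to level-3/4 terms. One level-3 biological-process
#' term is planted at `goEnrichFactor` times its baseline frequency among
#' the supplied up-regulated genes.
#'
#' @param config A [simulationConfig()].
#' @param genes All host gene identifiers.
#' @param upGenes Genes in which the planted term is over-represented.
#' @return List with `dag` ([GoOntology-class]), `annotations` (`gene`,
#'   `term`) and `planted_term`.
#' @export
simulateGoWorld <- function(config, genes, upGenes = character(0)) {
  set.seed(stageSeed(config$seed, "go"))
  dag <- .toyGoDag()
  lv <- .goLevels(dag)
  pool <- names(lv)[lv %in% c(3, 4)]
  bp <- dag@terms$id[dag@terms$namespace == "biological_process"]
  plantedTerm <- intersect(pool[lv[pool] == 3], bp)[1L]
  annotated <- sort(sample(genes, round(config$goAnnotatedFraction * length(genes))))
  isUp <- annotated %in% upGenes
  k <- config$goTermsPerGene
  baseW <- stats::setNames(rep(1, length(pool)), pool)
  rows <- lapply(seq_along(annotated), function(i) {
    w <- baseW
    if (isUp[i]) w[plantedTerm] <- w[plantedTerm] * config$goEnrichFactor
    sample(pool, k, prob = w)
  })
  list(
    dag = dag,
    annotations = data.frame(
      gene = rep(annotated, each = k),
      term = unlist(rows, use.names = FALSE), stringsAsFactors = FALSE
    ),
    planted_term = plantedTerm
  )
}

#' Simulate the symbiont transcriptome, annotation and pangenome
#'
#' Draws log-normal TPM targets for a configured fraction of active genes
#' (the rest are planted inactive), samples per-replicate read counts
#' multinomially at the configured depth, assigns COG letters with the
#' planted letter over-represented among active genes, builds a
#' presence/absence matrix realizing planted core / soft-core / shell /
#' cloud labels (active genes lean towards conserved partitions, inactive
#' ones towards the cloud), lays the genes out on one contig with the
#' planted HGT genes consecutive (all but the last on the same strand),
#' and emits assembly-quality summaries for 21 genomes of which exactly
#' the `nGenomes` used in the matrix pass the quality filter.
#'
#' @param config A [simulationConfig()].
#' @return List with `genes`, `lengths`, `counts` (gene x replicate
#'   matrix), `cog` (`gene`, `category` rows), `cog_table` (`gene`, `cog`
#'   collapsed), `pangenome` (presence/absence data frame),
#'   `gene_families`, `quality`, `loci` (GRanges), `hgt_genes`, and
#'   `truth` (planted activity, COG letter, refined partition labels).
#' @export
simulateSymbiont <- function(config) {
  set.seed(stageSeed(config$seed, "symbiont"))
  n <- config$nSymbiontGenes
  genes <- sprintf("MPOLY_%04d", seq_len(n))
  lens <- pmax(100, round(stats::rlnorm(n, log(900), 0.4)))
  nZero <- round(config$zeroFraction * n)
  zeroIdx <- sample.int(n, nZero)
  target <- stats::rlnorm(n, 0, 1.2)
  target[zeroIdx] <- 0
  active <- target > 0

  ## per-replicate multinomial read sampling, probabilities ~ target * length
  prob <- target * lens
  prob <- prob / sum(prob)
  counts <- vapply(seq_len(config$replicates), function(r) {
    as.vector(stats::rmultinom(1, config$symbiontDepth, prob))
  }, numeric(n))
  dimnames(counts) <- list(genes, paste0("rep", seq_len(config$replicates)))

  ## COG letters; planted letter over-represented among active genes
  cogPool <- c("C", "D", "E", "F", "G", "H", "I", "J", "K", "L", "M", "N",
               "O", "P", "Q", "S", "T", "U", "V")
  w <- stats::setNames(rep(1, length(cogPool)), cogPool)
  wActive <- w; wActive[config$plantedCog] <- config$cogEnrichFactor
  cogLetter <- character(n)
  cogLetter[active] <- sample(cogPool, sum(active), replace = TRUE, prob = wActive)
  cogLetter[!active] <- sample(cogPool, sum(!active), replace = TRUE, prob = w)
  ## a tenth of the genes carry a second letter
  second <- sample.int(n, round(0.1 * n))
  extra <- vapply(second, function(i) {
    sample(setdiff(cogPool, cogLetter[i]), 1)
  }, character(1))
  cogString <- cogLetter
  cogString[second] <- paste0(cogLetter[second], extra)
  cogRows <- data.frame(
    gene = c(genes, genes[second]),
    category = c(cogLetter, extra), stringsAsFactors = FALSE
  )
  cogRows <- cogRows[order(cogRows$gene, cogRows$category), ]

  ## pangenome: partition leaning on activity, then presence realizing it
  pPartAct <- c(persistent = 0.70, shell = 0.12, cloud = 0.18)
  pPartIna <- c(persistent = 0.30, shell = 0.15, cloud = 0.55)
  partition <- character(n)
  partition[active] <- sample(names(pPartAct), sum(active), TRUE, pPartAct)
  partition[!active] <- sample(names(pPartIna), sum(!active), TRUE, pPartIna)
  nOther <- config$nGenomes - 1L
  pres <- matrix(FALSE, n, config$nGenomes)
  pres[, 1L] <- TRUE                     # focal genome
  refined <- partition
  for (i in seq_len(n)) {
    if (partition[i] == "persistent") {
      if (stats::runif(1) < config$coreFraction) {
        pres[i, -1L] <- TRUE
        refined[i] <- "core"
      } else {
        miss <- sample.int(nOther, sample(1:3, 1))
        pres[i, -1L] <- TRUE
        pres[i, 1L + miss] <- FALSE
        refined[i] <- "soft_core"
      }
    } else if (partition[i] == "shell") {
      pres[i, -1L] <- stats::runif(nOther) < 0.4
      if (all(pres[i, -1L])) pres[i, 1L + 1L] <- FALSE
    } else {
      pres[i, -1L] <- stats::runif(nOther) < 0.05
      if (all(pres[i, -1L])) pres[i, 1L + 1L] <- FALSE
    }
  }
  genomeNames <- c("LgJac", sprintf("MPOL%02d", seq_len(nOther)))
  families <- paste0("fam_", genes)
  pangenome <- data.frame(family = families, partition = partition,
                          stringsAsFactors = FALSE)
  pangenome[genomeNames] <- as.data.frame(pres * 1L)

  ## quality summaries: the nGenomes used pass, 8 extra genomes fail
  nFail <- 8L
  quality <- data.frame(
    genome = c(genomeNames, sprintf("MPOLX%02d", seq_len(nFail))),
    complete_single = c(stats::runif(config$nGenomes, 85, 99),
                        stats::runif(nFail, 40, 79)),
    duplicated = c(stats::runif(config$nGenomes, 0, 1.5),
                   stats::runif(nFail, 2.5, 6)),
    stringsAsFactors = FALSE
  )

  ## loci on one contig; HGT genes consecutive, pattern + + + + + -
  hgtStart <- min(101L, n - config$nHgtGenes + 1L)
  hgtGenes <- genes[hgtStart:(hgtStart + config$nHgtGenes - 1L)]
  strand <- sample(c("+", "-"), n, replace = TRUE)
  strand[hgtStart:(hgtStart + config$nHgtGenes - 2L)] <- "+"
  strand[hgtStart + config$nHgtGenes - 1L] <- "-"
  starts <- cumsum(c(1, lens[-n] + 200))
  loci <- GenomicRanges::GRanges(
    seqnames = "contig_1",
    ranges = IRanges::IRanges(start = starts, width = lens),
    strand = strand
  )
  names(loci) <- genes
  loci$type <- "gene"
  loci$ID <- genes

  list(
    genes = genes, lengths = stats::setNames(lens, genes), counts = counts,
    cog = cogRows,
    cog_table = data.frame(gene = genes, cog = cogString, stringsAsFactors = FALSE),
    pangenome = pangenome,
    gene_families = data.frame(gene = genes, family = families,
                               stringsAsFactors = FALSE),
    quality = quality, loci = loci, hgt_genes = hgtGenes,
    truth = list(
      inactive_genes = genes[zeroIdx], planted_cog = config$plantedCog,
      refined = stats::setNames(refined, families), hgt_genes = hgtGenes
    )
  )
}

#' Simulate taxon-labelled homology hits with planted HGT profiles
#'
#' Vertical genes receive ingroup hits at least as strong as any outgroup
#' hit (Alien Index <= 0); planted HGT genes receive only strong outgroup
#' hits (best E <= 1e-60) plus at most a weak ingroup hit, guaranteeing a
#' planted Alien Index above 45.
#'
#' @param config A [simulationConfig()].
#' @param genes Symbiont gene identifiers.
#' @param hgtGenes Genes planted as horizontally transferred.
#' @return List with `hits` (as [readBlastHits()] would return) and
#'   `truth` (`gene`, `is_hgt`, `planted_ai`).
#' @export
simulateHits <- function(config, genes, hgtGenes) {
  set.seed(stageSeed(config$seed, "hits"))
  stopifnot(all(hgtGenes %in% genes))
  queries <- union(hgtGenes,
                   sample(setdiff(genes, hgtGenes),
                          config$nHitQueries - length(hgtGenes)))
  queries <- sort(queries)
  isHgt <- queries %in% hgtGenes
  eps <- 1e-200
  rows <- list()
  bestIn <- bestOut <- numeric(length(queries))
  for (i in seq_along(queries)) {
    q <- queries[i]
    if (isHgt[i]) {
      bOut <- 10^-stats::runif(1, 60, 150)
      bIn <- if (stats::runif(1) < 0.5) 1 else 10^-stats::runif(1, 0, 5)
    } else {
      bIn <- 10^-stats::runif(1, 20, 120)
      bOut <- min(1, bIn * 10^stats::runif(1, 2, 40))
      if (stats::runif(1) < 0.15) bOut <- 1   # no outgroup hit at all
    }
    bestIn[i] <- bIn
    bestOut[i] <- bOut
    mkRow <- function(subject, evalue, taxids) {
      sprintfRow <- data.frame(
        qseqid = q, sseqid = subject, pident = round(stats::runif(1, 30, 95), 1),
        length = sample(80:400, 1), mismatch = sample(5:120, 1),
        gapopen = sample(0:5, 1), qstart = 1L, qend = sample(80:400, 1),
        sstart = 1L, send = sample(80:400, 1),
        evalue = evalue, bitscore = round(stats::runif(1, 50, 900), 1),
        stringsAsFactors = FALSE
      )
      sprintfRow$staxids <- list(as.integer(taxids))
      sprintfRow
    }
    outTax <- function() sample(setdiff(1000:99999, config$ingroupTaxid), 1)
    if (bIn < 1) {
      rows[[length(rows) + 1L]] <- mkRow(paste0("in_", q), bIn, config$ingroupTaxid)
      ## a weaker ingroup hit, sometimes multi-taxid
      rows[[length(rows) + 1L]] <- mkRow(
        paste0("in2_", q), min(1, bIn * 10^stats::runif(1, 1, 5)),
        c(config$ingroupTaxid, outTax())
      )
    }
    if (bOut < 1) {
      rows[[length(rows) + 1L]] <- mkRow(paste0("out_", q), bOut, outTax())
      rows[[length(rows) + 1L]] <- mkRow(
        paste0("out2_", q), min(1, bOut * 10^stats::runif(1, 1, 5)), outTax()
      )
    }
  }
  hits <- do.call(rbind, rows)
  list(
    hits = hits,
    truth = data.frame(
      gene = queries, is_hgt = isHgt,
      planted_ai = log(bestIn + eps) - log(bestOut + eps),
      stringsAsFactors = FALSE
    )
  )
}

#' Simulate per-gene trimmed protein alignments
#'
#' Six biotin-pathway-like gene alignments over a panel of organisms; a
#' few organisms are present in fewer than three genes so the
#' minimum-gene taxon filter has something to discard.
#'
#' @param config A [simulationConfig()].
#' @return Named list of [Biostrings::AAStringSet] alignments.
#' @export
simulateAlignments <- function(config) {
  set.seed(stageSeed(config$seed, "alignments"))
  aaAlphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  geneNames <- c("bioA", "bioB", "bioD", "bioF", "bioH", "bioC")
  orgs <- sprintf("org%02d", 1:12)
  membership <- matrix(stats::runif(length(orgs) * length(geneNames)) < 0.85,
                       nrow = length(orgs),
                       dimnames = list(orgs, geneNames))
  membership[1:3, ] <- TRUE
  membership["org11", ] <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  membership["org12", ] <- c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  out <- lapply(geneNames, function(g) {
    width <- sample(40:80, 1)
    present <- orgs[membership[, g]]
    seqs <- vapply(present, function(o) {
      paste(sample(aaAlphabet, width, replace = TRUE), collapse = "")
    }, character(1))
    Biostrings::AAStringSet(seqs)
  })
  names(out) <- geneNames
  out
}

#' Run every generator under one configuration
#'
#' @param config A [simulationConfig()].
#' @return List with components `config`, `host`, `go`, `symbiont`,
#'   `hits`, `alignments`.
#' @export
simulateAll <- function(config = simulationConfig()) {
  host <- simulateHostCounts(config)
  ## the GO world plants its term among truly up-regulated genes
  upTruth <- host$truth$gene[host$truth$is_de & host$truth$log2fc > 0]
  go <- simulateGoWorld(config, host$truth$gene, upGenes = upTruth)
  symbiont <- simulateSymbiont(config)
  hits <- simulateHits(config, symbiont$genes, symbiont$hgt_genes)
  alignments <- simulateAlignments(config)
  list(config = config, host = host, go = go, symbiont = symbiont,
       hits = hits, alignments = alignments)
}

#' Write a simulated data set to disk in the pipeline's input formats
#'
#' Emits every format the pipeline reads: count and annotation TSVs, an
#' OBO ontology, a GFF3 gene map, a 13-column homology-hit table, FASTA
#' alignments and a ground-truth JSON.
#'
#' @param sim A list from [simulateAll()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$config
  hdr <- list(seed = cfg$seed, generator = "symbioseq-synthetic")
  cts <- SummarizedExperiment::assay(sim$host$counts, "counts")
  writeTsv(data.frame(gene = rownames(cts), cts, check.names = FALSE),
           file.path(dir, "host_counts.tsv"), params = hdr)
  writeTsv(data.frame(
    sample = colnames(cts),
    condition = SummarizedExperiment::colData(sim$host$counts)$condition
  ), file.path(dir, "samples.tsv"), params = hdr)
  writeOBO(sim$go$dag, file.path(dir, "go.obo"))
  writeTsv(sim$go$annotations, file.path(dir, "go_annotation.tsv"), params = hdr)
  writeTsv(
    data.frame(gene = sim$symbiont$genes,
               effective_length = unname(sim$symbiont$lengths),
               sim$symbiont$counts, check.names = FALSE),
    file.path(dir, "symbiont_counts.tsv"), params = hdr
  )
  writeTsv(sim$symbiont$cog_table, file.path(dir, "cog.tsv"), params = hdr)
  writeTsv(sim$symbiont$pangenome, file.path(dir, "pangenome.tsv"), params = hdr)
  writeTsv(sim$symbiont$gene_families, file.path(dir, "gene_families.tsv"),
           params = hdr)
  writeTsv(sim$symbiont$quality, file.path(dir, "busco.tsv"), params = hdr)
  hits <- sim$hits$hits
  hitLines <- apply(cbind(
    hits$qseqid, hits$sseqid, hits$pident, hits$length, hits$mismatch,
    hits$gapopen, hits$qstart, hits$qend, hits$sstart, hits$send,
    format(hits$evalue, scientific = TRUE, digits = 3, trim = TRUE),
    hits$bitscore,
    vapply(hits$staxids, paste, character(1), collapse = ";")
  ), 1, paste, collapse = "\t")
  writeLines(hitLines, file.path(dir, "hits.tsv"))
  rtracklayer::export(sim$symbiont$loci, file.path(dir, "loci.gff3"),
                      format = "gff3")
  alnDir <- file.path(dir, "alignments")
  dir.create(alnDir, showWarnings = FALSE)
  for (g in names(sim$alignments)) {
    Biostrings::writeXStringSet(sim$alignments[[g]],
                                file.path(alnDir, paste0(g, ".faa")))
  }
  truth <- list(
    seed = cfg$seed,
    host_de = sim$host$truth,
    planted_go_term = sim$go$planted_term,
    symbiont_inactive = sim$symbiont$truth$inactive_genes,
    planted_cog = sim$symbiont$truth$planted_cog,
    refined_partitions = as.list(sim$symbiont$truth$refined),
    hgt_genes = sim$symbiont$truth$hgt_genes,
    hit_truth = sim$hits$truth
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
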