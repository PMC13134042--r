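## small custom DAG: root -> x1 -> x2 (-> p2) ; a long chain to p4; term T
## has parents at levels 2 and 4
mixedDag <- function() {
  ids <- c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004",
           "GO:0000005", "GO:0000006", "GO:0000007")
  # 1 root; 2,3 chain to level 2 (term 3); 4,5,6 chain to level 4 (term 6,
  # via 2->4->5->6); 7 has parents 3 (level 2) and 6 (level 4)
  parents <- list(
    "GO:0000001" = character(0),
    "GO:0000002" = "GO:0000001",
    "GO:0000003" = "GO:0000002",
    "GO:0000004" = "GO:0000002",
    "GO:0000005" = "GO:0000004",
    "GO:0000006" = "GO:0000005",
    "GO:0000007" = c("GO:0000003", "GO:0000006")
  )
  terms <- data.frame(id = ids, name = ids, namespace = "biological_process",
                      stringsAsFactors = FALSE)
  GoOntology(terms, parents)
}

test_that("term levels are shortest-path is_a distances from the root", {
  chain <- chainDag(3)
  ids <- chain@terms$id
  expect_equal(termLevel(chain, ids[1]), 0L)
  expect_equal(termLevel(chain, ids[4]), 3L)
  dag <- mixedDag()
  # parents at levels 2 and 4: min parent level + 1 = 3
  expect_equal(termLevel(dag, "GO:0000007"), 3L)
  expect_equal(termLevel(dag, "GO:0000007", rule = "longest"), 5L)
  expect_error(termLevel(dag, "GO:9999999"), "unknown")
})

test_that("cyclic or disconnected ontologies are rejected", {
  terms <- data.frame(id = c("a", "b", "c"), name = c("a", "b", "c"),
                      namespace = "biological_process")
  expect_error(GoOntology(terms, list(a = character(0), b = "c", c = "b")),
               "reach|cycle")
})

test_that("annotations map to fixed-level ancestors as specified", {
  dag <- mixedDag()
  # term at the level maps to itself
  ann <- data.frame(gene = "g1", term = "GO:0000007")
  out <- mapToLevel(dag, ann, 3L)
  expect_equal(out$term, "GO:0000007")
  # a deep term with two distinct level-3 ancestors yields two rows:
  # add a level-5 child of 7 (level 3) wired also under 6's child...
  ids <- c(dag@terms$id, "GO:0000008", "GO:0000009")
  parents <- c(dag@parents, list(
    "GO:0000008" = "GO:0000005",                     # level 4 via chain
    "GO:0000009" = c("GO:0000007", "GO:0000008")     # levels 3+1=4? see below
  ))
  terms <- data.frame(id = ids, name = ids, namespace = "biological_process")
  dag2 <- GoOntology(terms, parents)
  # GO:0000009 has ancestors GO:0000007 (level 3) and, via GO:0000008,
  # GO:0000005 (level 3): two distinct level-3 ancestors
  out2 <- mapToLevel(dag2, data.frame(gene = "g1", term = "GO:0000009"), 3L)
  expect_setequal(out2$term, c("GO:0000007", "GO:0000005"))
  expect_equal(nrow(out2), 2L)
  # a shallow term has no level-3 representative
  out3 <- mapToLevel(dag, data.frame(gene = "g1", term = "GO:0000002"), 3L)
  expect_equal(nrow(out3), 0L)
  # native mode keeps only terms already at the level
  out4 <- mapToLevel(dag2, data.frame(gene = "g1", term = "GO:0000009"), 3L,
                     mode = "native")
  expect_equal(nrow(out4), 0L)
})

test_that("level mapping is idempotent and matches a matrix-closure oracle", {
  cfg <- simulationConfig(seed = 13, nHostGenes = 120)
  world <- simulateGoWorld(cfg, sprintf("PPRIM_%05d", 1:120))
  dag <- world$dag
  ann <- world$annotations
  for (L in c(3L, 4L)) {
    lev <- mapToLevel(dag, ann, L)
    again <- mapToLevel(dag, lev, L)
    expect_equal(lev[order(lev$gene, lev$term), c("gene", "term")],
                 again[order(again$gene, again$term), c("gene", "term")])
    ## oracle: reachability by boolean matrix closure, levels by BFS powers
    ids <- dag@terms$id
    A <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
    for (t in ids) A[t, dag@parents[[t]]] <- TRUE
    reach <- A
    repeat {
      nxt <- reach | (reach %*% A > 0)
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    roots <- dag@roots
    lvl <- rep(NA_integer_, length(ids)); names(lvl) <- ids
    lvl[roots] <- 0L
    d <- 0L
    M <- diag(length(ids)) > 0
    dimnames(M) <- list(ids, ids)
    while (any(is.na(lvl))) {
      d <- d + 1L
      stopifnot(d <= length(ids))
      M <- (M %*% A > 0)
      dimnames(M) <- list(ids, ids)
      hit <- names(which(apply(M[, roots, drop = FALSE], 1, any)))
      lvl[hit[is.na(lvl[hit])]] <- d
    }
    expected <- unique(do.call(rbind, lapply(seq_len(nrow(ann)), function(i) {
      t <- ann$term[i]
      reps <- if (lvl[t] == L) t else ids[reach[t, ] & lvl == L]
      if (length(reps) == 0) return(NULL)
      data.frame(gene = ann$gene[i], term = reps)
    })))
    expect_equal(nrow(lev), nrow(expected))
    expect_setequal(paste(lev$gene, lev$term),
                    paste(expected$gene, expected$term))
  }
})

test_that("OBO files round-trip through the reader and writer", {
  cfg <- simulationConfig(seed = 17, nHostGenes = 50)
  dag <- simulateGoWorld(cfg, sprintf("PPRIM_%05d", 1:50))$dag
  path <- withr::local_tempfile(fileext = ".obo")
  writeOBO(dag, path)
  back <- readOBO(path)
  expect_equal(goTerms(back), goTerms(dag))
  expect_equal(back@parents, dag@parents)
  expect_equal(back@roots, dag@roots)
})

test_that("obsolete terms and non-is_a relationships are skipped", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: live", "namespace: biological_process",
    "is_a: GO:0000001 ! root",
    "relationship: part_of GO:0000001", "",
    "[Term]", "id: GO:0000003", "name: dead", "namespace: biological_process",
    "is_a: GO:0000001", "is_obsolete: true", ""
  ), path)
  dag <- readOBO(path)
  expect_setequal(goTerms(dag)$id, c("GO:0000001", "GO:0000002"))
  expect_equal(dag@parents[["GO:0000002"]], "GO:0000001")
})

test_that("GO enrichment flags a planted term and respects null subsampling", {
  cfg <- simulationConfig(seed = 23, nHostGenes = 1500, goEnrichFactor = 10)
  genes <- sprintf("PPRIM_%05d", 1:1500)
  up <- sample(genes, 150)
  world <- simulateGoWorld(cfg, genes, upGenes = up)
  lev <- mapToLevel(world$dag, world$annotations, 3L)
  bp <- lev[lev$namespace == "biological_process", ]
  fore <- bp[bp$gene %in% up, ]
  res <- goEnrichment(fore, bp, "biological_process", 3L)
  expect_true(res$enriched[res$category == world$planted_term])
  ## a random subsample of the background is not enriched
  set.seed(101)
  null <- bp[bp$gene %in% sample(unique(bp$gene), 150), ]
  res0 <- goEnrichment(null, bp, "biological_process", 3L)
  expect_false(any(res0$enriched))
  ## empty foreground gives an empty result
  res1 <- suppressWarnings(
    goEnrichment(bp[0, ], bp, "biological_process", 3L)
  )
  expect_equal(nrow(res1), 0L)
  ## namespace mismatch rejected
  expect_error(goEnrichment(fore, bp, "molecular_function", 3L), "namespace")
})

test_that("enrichment is invariant under gene relabelling", {
  cfg <- simulationConfig(seed = 29, nHostGenes = 300)
  genes <- sprintf("PPRIM_%05d", 1:300)
  up <- genes[1:40]
  world <- simulateGoWorld(cfg, genes, upGenes = up)
  lev <- mapToLevel(world$dag, world$annotations, 3L)
  bp <- lev[lev$namespace == "biological_process", ]
  res1 <- goEnrichment(bp[bp$gene %in% up, ], bp, "biological_process", 3L)
  relabel <- setNames(paste0("X", seq_along(genes)), genes)
  bp2 <- bp; bp2$gene <- unname(relabel[bp$gene])
  res2 <- goEnrichment(bp2[bp2$gene %in% relabel[up], ], bp2,
                       "biological_process", 3L)
  expect_equal(res1$p_raw, res2$p_raw)
  expect_equal(res1$enriched, res2$enriched)
})

test_that("the full direction x namespace x level analysis is assembled", {
  cfg <- simulationConfig(seed = 31, nHostGenes = 600)
  genes <- sprintf("PPRIM_%05d", 1:600)
  up <- sample(genes, 60); down <- sample(setdiff(genes, up), 60)
  world <- simulateGoWorld(cfg, genes, upGenes = up)
  res <- hostGoEnrichment(world$dag, world$annotations, up, down)
  expect_true(all(res$direction %in% c("up", "down")))
  expect_setequal(unique(res$namespace),
                  c("biological_process", "molecular_function", "cellular_component"))
  expect_setequal(unique(res$level), c(3L, 4L))
  expect_true(res$enriched[res$direction == "up" & res$level == 3 &
                             res$category == world$planted_term])
})
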