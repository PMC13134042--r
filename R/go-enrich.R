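#' Gene Ontology subgraph
#'
#' An S4 container for a parsed GO ontology restricted to `is_a` edges:
#' term table (id, name, namespace), a child-to-parents adjacency list, and
#' one root per namespace. Obsolete terms are dropped at parse time and
#' relationship types other than `is_a` (e.g. `part_of`) are ignored, which
#' matches analyses driven by the go-basic release.
#'
#' @slot terms data.frame with columns `id`, `name`, `namespace`.
#' @slot parents named list: term id -> character vector of `is_a` parents.
#' @slot roots named character: namespace -> root term id.
#' @export
setClass("GoOntology", representation(
  terms = "data.frame", parents = "list", roots = "character"
))

setValidity("GoOntology", function(object) {
  msg <- NULL
  if (!all(c("id", "name", "namespace") %in% names(object@terms))) {
    msg <- c(msg, "terms must have columns id, name, namespace")
  }
  ids <- object@terms$id
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate term ids")
  if (!all(unlist(object@parents) %in% ids)) {
    msg <- c(msg, "a parent edge points outside the term set")
  }
  ## acyclicity + root reachability via the level computation
  lv <- tryCatch(.goLevels(object), error = function(e) conditionMessage(e))
  if (is.character(lv)) {
    msg <- c(msg, lv)
  } else if (any(is.na(lv))) {
    msg <- c(msg, "some terms cannot reach their namespace root via is_a")
  }
  if (is.null(msg)) TRUE else msg
})

#' @export
setMethod("show", "GoOntology", function(object) {
  ns <- table(object@terms$namespace)
  cat("GoOntology:", nrow(object@terms), "terms\n")
  cat("  namespaces:", paste(sprintf("%s (%d)", names(ns), ns), collapse = ", "), "\n")
  cat("  roots     :", paste(names(object@roots), object@roots, sep = "=",
                             collapse = ", "), "\n")
})

#' @describeIn GoOntology term table accessor.
#' @param object A `GoOntology`.
#' @export
setGeneric("goTerms", function(object) standardGeneric("goTerms"))

#' @export
setMethod("goTerms", "GoOntology", function(object) object@terms)

#' Build a GoOntology from term and edge tables
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param parents Named list mapping each term id to its `is_a` parent ids
#'   (roots map to `character(0)`).
#' @return A validated [GoOntology-class].
#' @export
GoOntology <- function(terms, parents) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  parents <- parents[terms$id]
  names(parents) <- terms$id
  parents[vapply(parents, is.null, logical(1))] <- list(character(0))
  rootIdx <- lengths(parents) == 0L
  roots <- terms$id[rootIdx]
  ns <- terms$namespace[rootIdx]
  if (anyDuplicated(ns)) {
    stop("more than one parentless term in a namespace")
  }
  names(roots) <- ns
  obj <- methods::new("GoOntology", terms = terms, parents = parents, roots = roots)
  methods::validObject(obj)
  obj
}

## Shortest-path (default) or longest-path is_a depth of every term from
## its namespace root; root depth 0. Breadth-first over child edges; a
## cycle leaves terms unreached after |V| rounds and is reported.
.goLevels <- function(dag, rule = c("shortest", "longest")) {
  rule <- match.arg(rule)
  ids <- dag@terms$id
  children <- split(
    rep(ids, lengths(dag@parents[ids])),
    unlist(dag@parents[ids], use.names = FALSE)
  )
  lv <- stats::setNames(rep(NA_real_, length(ids)), ids)
  lv[dag@roots] <- 0
  frontier <- unname(dag@roots)
  rounds <- 0L
  agg <- if (rule == "shortest") pmin else pmax
  repeat {
    rounds <- rounds + 1L
    if (rounds > length(ids) + 1L) stop("cycle detected in is_a graph")
    nxt <- character(0)
    for (t in frontier) {
      for (ch in children[[t]]) {
        cand <- lv[[t]] + 1
        cur <- lv[[ch]]
        if (is.na(cur) || agg(cur, cand) != cur) {
          lv[[ch]] <- if (is.na(cur)) cand else agg(cur, cand)
          nxt <- c(nxt, ch)
        }
      }
    }
    if (length(nxt) == 0L) break
    frontier <- unique(nxt)
  }
  lv
}

#' Hierarchy level of a GO term
#'
#' The `is_a` distance of a term from its namespace root, with the root at
#' level 0. By default the shortest path is used; the longest-path
#' convention is available as a switch.
#'
#' @param dag A [GoOntology-class].
#' @param term Term id (vectorised).
#' @param rule `"shortest"` (default) or `"longest"` path to the root.
#' @return Integer level(s).
#' @export
termLevel <- function(dag, term, rule = c("shortest", "longest")) {
  rule <- match.arg(rule)
  if (!all(term %in% dag@terms$id)) {
    stop("unknown term(s): ", paste(setdiff(term, dag@terms$id), collapse = ", "))
  }
  lv <- .goLevels(dag, rule)
  as.integer(lv[term])
}

## All is_a ancestors of a term (transitive, excluding the term itself).
.goAncestors <- function(dag, term) {
  seen <- character(0)
  frontier <- dag@parents[[term]]
  while (length(frontier) > 0L) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(dag@parents[frontier], use.names = FALSE))
  }
  seen
}

#' Flatten GO annotations to a fixed hierarchy level
#'
#' Each annotated term is replaced by its level-`level` representatives:
#' itself if it already sits at that level, otherwise all of its `is_a`
#' ancestors at that level (`mode = "up"`, the default). Terms shallower
#' than the target level contribute nothing, duplicate (gene, term) rows
#' are collapsed, and genes left with no mapped term drop out. With
#' `mode = "native"` only terms whose own level equals the target are kept.
#'
#' @param dag A [GoOntology-class].
#' @param annotations Data frame with columns `gene` and `term`
#'   (one row per GO assignment).
#' @param level Target hierarchy level (3 or 4 in the standard analysis).
#' @param mode `"up"` (map deeper terms to level ancestors) or `"native"`
#'   (keep only terms natively at the level).
#' @param rule Level convention passed to [termLevel()].
#' @return Data frame `gene`, `term`, `namespace`, `level` with one row per
#'   distinct (gene, mapped term) pair.
#' @export
mapToLevel <- function(dag, annotations, level, mode = c("up", "native"),
                       rule = c("shortest", "longest")) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  stopifnot(all(c("gene", "term") %in% names(annotations)))
  terms <- unique(as.character(annotations$term))
  if (!all(terms %in% dag@terms$id)) {
    stop("annotations reference unknown term(s): ",
         paste(utils::head(setdiff(terms, dag@terms$id), 5), collapse = ", "))
  }
  lv <- .goLevels(dag, rule)
  mapped <- lapply(terms, function(t) {
    if (lv[[t]] == level) return(t)
    if (mode == "native") return(character(0))
    anc <- .goAncestors(dag, t)
    anc[lv[anc] == level]
  })
  names(mapped) <- terms
  rows <- do.call(rbind, lapply(seq_len(nrow(annotations)), function(i) {
    tgt <- mapped[[as.character(annotations$term[i])]]
    if (length(tgt) == 0L) return(NULL)
    data.frame(gene = annotations$gene[i], term = tgt, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    return(data.frame(gene = character(0), term = character(0),
                      namespace = character(0), level = integer(0),
                      stringsAsFactors = FALSE))
  }
  rows <- unique(rows)
  rows$namespace <- dag@terms$namespace[match(rows$term, dag@terms$id)]
  rows$level <- as.integer(level)
  rows <- rows[order(rows$gene, rows$term), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' GO-term enrichment at one namespace and level
#'
#' One-sided Fisher tests over the expanded (gene, term) rows of a leveled
#' annotation, treating multi-term genes as that many separate genes, with
#' one BH correction across the terms of this call. The standard full
#' analysis is 12 such independent calls: 2 regulation directions x 3
#' namespaces x 2 levels.
#'
#' @param leveledFore Leveled annotation rows ([mapToLevel()]) of the
#'   foreground (e.g. up-regulated) genes.
#' @param leveledBack Leveled annotation rows of the background gene set;
#'   the foreground genes must be a subset of the background genes.
#' @param namespace Expected namespace; the rows of both inputs must all
#'   belong to it.
#' @param level Expected level of both inputs.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return Enrichment table as from [enrichCategories()], with `category`
#'   holding GO term ids.
#' @export
goEnrichment <- function(leveledFore, leveledBack, namespace, level,
                         alpha = 0.05) {
  for (x in list(leveledFore, leveledBack)) {
    if (nrow(x) > 0L && (!all(x$namespace == namespace) || !all(x$level == level))) {
      stop("leveled rows do not all match namespace '", namespace,
           "' at level ", level)
    }
  }
  foreGenes <- unique(leveledFore$gene)
  backGenes <- unique(leveledBack$gene)
  if (!all(foreGenes %in% backGenes)) {
    stop("foreground genes must be a subset of the background genes")
  }
  if (length(foreGenes) == 0L) {
    return(enrichCategories(character(0), backGenes,
                            data.frame(gene = leveledBack$gene,
                                       category = leveledBack$term),
                            alpha = alpha))
  }
  enrichCategories(foreGenes, backGenes,
                   data.frame(gene = leveledBack$gene,
                              category = leveledBack$term,
                              stringsAsFactors = FALSE),
                   alpha = alpha)
}

#' Full GO enrichment over directions, namespaces and levels
#'
#' Runs [goEnrichment()] for each regulation direction (up, down), each
#' namespace present in the ontology, and each requested level, each as an
#' independent call with its own BH correction.
#'
#' @param dag A [GoOntology-class].
#' @param annotations Gene-to-term assignment table (`gene`, `term`).
#' @param upGenes,downGenes Character vectors of DEG identifiers.
#' @param backgroundGenes Background gene set (default: all annotated
#'   genes).
#' @param levels Hierarchy levels to analyse (default `c(3, 4)`).
#' @param alpha Significance threshold.
#' @param mode,rule Passed to [mapToLevel()].
#' @return One data frame combining all calls, with `direction`,
#'   `namespace` and `level` columns prepended to the enrichment columns.
#' @export
hostGoEnrichment <- function(dag, annotations, upGenes, downGenes,
                             backgroundGenes = unique(annotations$gene),
                             levels = c(3L, 4L), alpha = 0.05,
                             mode = "up", rule = "shortest") {
  ann <- annotations[annotations$gene %in% backgroundGenes, , drop = FALSE]
  out <- list()
  for (L in levels) {
    leveled <- mapToLevel(dag, ann, L, mode = mode, rule = rule)
    for (ns in sort(unique(dag@terms$namespace))) {
      lback <- leveled[leveled$namespace == ns, , drop = FALSE]
      for (dir in c("up", "down")) {
        genes <- if (dir == "up") upGenes else downGenes
        lfore <- lback[lback$gene %in% genes, , drop = FALSE]
        res <- suppressWarnings(
          goEnrichment(lfore, lback, namespace = ns, level = L, alpha = alpha)
        )
        if (nrow(res) > 0L) {
          res <- cbind(direction = dir, namespace = ns, level = L, res,
                       stringsAsFactors = FALSE)
          out[[length(out) + 1L]] <- res
        }
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

#' Read an OBO v1.2 flat file into a GoOntology
#'
#' Minimal reader for the go-basic flavour: `[Term]` stanzas with `id`,
#' `name`, `namespace`, `is_a` tags. Obsolete terms are skipped and only
#' `is_a` edges are retained.
#'
#' @param path Path to an OBO file.
#' @return A [GoOntology-class].
#' @export
readOBO <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) stop("no [Term] stanzas found in ", path)
  bounds <- c(starts, length(lines) + 1L)
  recs <- lapply(seq_along(starts), function(i) {
    chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    chunk <- chunk[!grepl("^\\[", chunk)]
    tagOf <- function(tag) {
      v <- sub(paste0("^", tag, ": "), "", grep(paste0("^", tag, ": "), chunk, value = TRUE))
      v
    }
    if (length(tagOf("is_obsolete")) > 0L && any(tagOf("is_obsolete") == "true")) {
      return(NULL)
    }
    id <- tagOf("id")
    if (length(id) == 0L) return(NULL)
    isa <- sub(" !.*$", "", tagOf("is_a"))
    list(id = id[1L], name = if (length(tagOf("name"))) tagOf("name")[1L] else id[1L],
         namespace = if (length(tagOf("namespace"))) tagOf("namespace")[1L] else NA_character_,
         is_a = isa)
  })
  recs <- Filter(Negate(is.null), recs)
  terms <- data.frame(
    id = vapply(recs, `[[`, character(1), "id"),
    name = vapply(recs, `[[`, character(1), "name"),
    namespace = vapply(recs, `[[`, character(1), "namespace"),
    stringsAsFactors = FALSE
  )
  parents <- lapply(recs, function(r) intersect(r$is_a, terms$id))
  names(parents) <- terms$id
  GoOntology(terms, parents)
}

#' Write a GoOntology as an OBO v1.2 flat file
#'
#' @param dag A [GoOntology-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeOBO <- function(dag, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag@terms))) {
    id <- dag@terms$id[i]
    writeLines(c(
      "[Term]",
      paste0("id: ", id),
      paste0("name: ", dag@terms$name[i]),
      paste0("namespace: ", dag@terms$namespace[i]),
      if (length(dag@parents[[id]]) > 0L)
        paste0("is_a: ", dag@parents[[id]]) else character(0),
      ""
    ), con)
  }
  invisible(path)
}
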