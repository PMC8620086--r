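#' @importFrom stats setNames
NULL

KB_ETYPES <- c("gene", "protein", "microRNA", "condition", "term")
GENE_LIKE <- c("gene", "protein", "microRNA")

#' Normalize a gene symbol
#'
#' Strips surrounding whitespace, upper-cases, and maps through an alias
#' table so that synonymous symbols (e.g. `G6PC` vs `G6PC1`, `GLUT2` vs
#' `SLC2A2`) collapse onto one canonical symbol. Literature-derived gene
#' lists routinely mix aliases between tables of the same article, so every
#' symbol entering the package passes through this function.
#'
#' @param raw character vector of raw symbols.
#' @param aliases named character vector mapping alias to canonical symbol
#'   (names are aliases, upper-case), e.g. `c(G6PC = "G6PC1")`. See
#'   [read_alias_table()] for the packaged default.
#' @return character vector of normalized symbols. Idempotent:
#'   `normalize_symbol(normalize_symbol(x))` equals `normalize_symbol(x)`
#'   provided the alias table maps onto canonical symbols only.
#' @examples
#' normalize_symbol(" tnf ")
#' normalize_symbol("g6pc", c(G6PC = "G6PC1"))
#' @export
normalize_symbol <- function(raw, aliases = NULL) {
  if (length(raw) == 0L) return(character(0))
  sym <- toupper(trimws(as.character(raw)))
  if (any(is.na(sym) | sym == "")) {
    stop("invalid gene symbol: empty or blank after stripping whitespace",
         call. = FALSE)
  }
  if (!is.null(aliases) && length(aliases) > 0L) {
    if (is.null(names(aliases))) {
      stop("alias table must be a named character vector (alias -> canonical)",
           call. = FALSE)
    }
    hit <- match(sym, toupper(names(aliases)))
    sym[!is.na(hit)] <- toupper(unname(aliases))[hit[!is.na(hit)]]
  }
  sym
}

#' Read an alias table
#'
#' Two-column TSV (`alias`, `canonical`). The packaged default resolves the
#' symbol conflicts present in the shipped fixtures (`G6PC` to `G6PC1`,
#' `GLUT2` to `SLC2A2`); users may extend it with their own file.
#'
#' @param path path to the TSV; defaults to the packaged table.
#' @return named character vector usable as `aliases` in [normalize_symbol()].
#' @export
read_alias_table <- function(path = system.file("extdata", "aliases.tsv",
                                                package = "condnet")) {
  df <- read_tsv_strict(path, c("alias", "canonical"), "alias table")
  setNames(toupper(trimws(df$canonical)), toupper(trimws(df$alias)))
}

#' Construct a knowledge base
#'
#' A typed directed multigraph of biological entities (genes/proteins,
#' microRNAs, conditions, terms) and literature-derived interactions.
#' Parallel edges (same source, target and relation recorded several times)
#' are retained in storage; analyses that need a simple graph collapse them
#' explicitly.
#'
#' @param entities data.frame with columns `id`, `name`, `etype`
#'   (one of gene, protein, microRNA, condition, term).
#' @param interactions data.frame with columns `source`, `target`, `rtype`
#'   and optionally `pmids` (semicolon-separated literature ids, uninterpreted).
#' @return object of class `knowledge_base`.
#' @export
knowledge_base <- function(entities, interactions) {
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  need_e <- c("id", "name", "etype")
  if (!all(need_e %in% names(entities))) {
    stop("entities must have columns id, name, etype", call. = FALSE)
  }
  if (!all(c("source", "target", "rtype") %in% names(interactions))) {
    stop("interactions must have columns source, target, rtype", call. = FALSE)
  }
  if (is.null(interactions$pmids)) interactions$pmids <- ""
  bad_t <- setdiff(unique(entities$etype), KB_ETYPES)
  if (length(bad_t) > 0L) {
    stop(sprintf("unknown entity type(s): %s (allowed: %s)",
                 paste(bad_t, collapse = ", "),
                 paste(KB_ETYPES, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(entities$id)) {
    stop(sprintf("duplicate entity id(s): %s",
                 paste(unique(entities$id[duplicated(entities$id)]),
                       collapse = ", ")), call. = FALSE)
  }
  dangle <- !(interactions$source %in% entities$id &
              interactions$target %in% entities$id)
  if (any(dangle)) {
    i <- which(dangle)[1L]
    stop(sprintf(
      "referential integrity violated: interaction row %d (%s -> %s, %s) references an unknown entity",
      i, interactions$source[i], interactions$target[i],
      interactions$rtype[i]), call. = FALSE)
  }
  structure(list(entities = entities[, c("id", "name", "etype")],
                 interactions = interactions[, c("source", "target",
                                                 "rtype", "pmids")]),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  tab <- table(x$entities$etype)
  cat(sprintf("knowledge_base: %d entities (%s), %d interactions\n",
              nrow(x$entities),
              paste(sprintf("%s %s", tab, names(tab)), collapse = ", "),
              nrow(x$interactions)))
  invisible(x)
}

#' Read a knowledge base from node and edge tables
#'
#' Node TSV columns: `id`, `name`, `etype`; edge TSV columns: `source`,
#' `target`, `rtype`, `pmids` (semicolon-separated, may be empty). Gene-like
#' entity names are normalized through the alias table, and gene and protein
#' records carrying the same normalized symbol are merged into a single node
#' (a literature network reports "genes/proteins" as one network member);
#' edge endpoints are remapped accordingly.
#'
#' @param nodes_path,edges_path paths to the TSV files.
#' @param aliases named alias vector (see [read_alias_table()]); `NULL` for
#'   none.
#' @return `knowledge_base`.
#' @export
read_kb <- function(nodes_path, edges_path, aliases = NULL) {
  nodes <- read_tsv_strict(nodes_path, c("id", "name", "etype"), "node")
  edges <- read_tsv_strict(edges_path, c("source", "target", "rtype"), "edge")
  if (is.null(edges$pmids)) edges$pmids <- ""
  bad_t <- setdiff(unique(nodes$etype), KB_ETYPES)
  if (length(bad_t) > 0L) {
    stop(sprintf("unknown entity type(s) in %s: %s", nodes_path,
                 paste(bad_t, collapse = ", ")), call. = FALSE)
  }
  glike <- nodes$etype %in% GENE_LIKE
  nodes$name[glike] <- normalize_symbol(nodes$name[glike], aliases)

  # merge gene/protein (and duplicated gene-like) nodes sharing a symbol
  remap <- setNames(nodes$id, nodes$id)
  keyed <- nodes[glike, , drop = FALSE]
  if (nrow(keyed) > 0L) {
    first <- !duplicated(keyed$name)
    canon <- setNames(keyed$id[first], keyed$name[first])
    remap[keyed$id] <- canon[keyed$name]
  }
  keep <- rep(TRUE, nrow(nodes))
  keep[glike] <- !duplicated(nodes$name[glike])
  nodes <- nodes[keep, , drop = FALSE]
  # merged gene/protein nodes are reported as genes
  nodes$etype[nodes$etype == "protein"] <- "gene"

  miss <- !(edges$source %in% names(remap)) | !(edges$target %in% names(remap))
  if (any(miss)) {
    i <- which(miss)[1L]
    stop(sprintf(
      "referential integrity violated at %s row %d: edge %s -> %s references an absent node",
      edges_path, i, edges$source[i], edges$target[i]), call. = FALSE)
  }
  edges$source <- unname(remap[edges$source])
  edges$target <- unname(remap[edges$target])
  knowledge_base(nodes, edges)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. Members are normalized through the
#' alias table and de-duplicated.
#'
#' @param path GMT file.
#' @param aliases alias vector (see [normalize_symbol()]).
#' @return named list of character vectors (one element per set).
#' @export
read_gmt <- function(path, aliases = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(setNames(list(), character(0)))
  out <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("GMT format error at line %d of %s: fewer than 3 fields",
                   i, path), call. = FALSE)
    }
    nm[i] <- f[1L]
    members <- f[-(1:2)]
    members <- members[nzchar(trimws(members))]
    out[[i]] <- unique(normalize_symbol(members, aliases))
  }
  setNames(out, nm)
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Collapse interactions to the simple undirected projection
#'
#' Parallel typed edges between the same unordered pair collapse to one;
#' self-loops are dropped. This is the graph on which connectivity-style
#' metrics are computed.
#'
#' @param kb `knowledge_base`.
#' @param ids optional entity ids to restrict to (induced subgraph).
#' @return data.frame with columns `from`, `to` (from < to lexicographically)
#'   and `multiplicity` (number of parallel stored links).
#' @export
simple_projection <- function(kb, ids = NULL) {
  e <- kb$interactions
  if (!is.null(ids)) {
    e <- e[e$source %in% ids & e$target %in% ids, , drop = FALSE]
  }
  e <- e[e$source != e$target, , drop = FALSE]
  if (nrow(e) == 0L) {
    return(data.frame(from = character(0), to = character(0),
                      multiplicity = integer(0), stringsAsFactors = FALSE))
  }
  a <- pmin(e$source, e$target)
  b <- pmax(e$source, e$target)
  key <- paste(a, b, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(from = vapply(parts, `[`, "", 1L),
                    to = vapply(parts, `[`, "", 2L),
                    multiplicity = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

#' Write a network in SIF format
#'
#' One line per simple edge, `source<TAB>relation<TAB>target`, in
#' deterministic lexicographic order. Parallel typed links collapse to one
#' line whose relation is the lexicographically first of their types.
#'
#' @param net a `condition_network` (see [extract_condition_network()]) or a
#'   data.frame with columns `from`, `to` and optionally `rtype`.
#' @param path output file.
#' @export
write_sif <- function(net, path) {
  edges <- if (inherits(net, "condition_network")) net$gene_gene_edges else
    as.data.frame(net, stringsAsFactors = FALSE)
  if (is.null(edges$rtype)) edges$rtype <- rep("interacts", nrow(edges))
  if (nrow(edges) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  lines <- sprintf("%s\t%s\t%s", a, edges$rtype, b)
  lines <- sort(unique(lines))
  writeLines(lines, path)
  invisible(path)
}

#' Read a SIF file back to a simple edge data.frame
#' @param path SIF file.
#' @return data.frame with columns `from`, `rtype`, `to`.
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) stop("SIF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(from = character(0), rtype = character(0),
                      to = character(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(f, length, 0L) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("SIF format error at line %d of %s", bad[1L], path),
         call. = FALSE)
  }
  data.frame(from = vapply(f, `[`, "", 1L),
             rtype = vapply(f, `[`, "", 2L),
             to = vapply(f, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' Read a flat term-to-gene annotation table
#'
#' TSV with columns `term_id`, `term_name`, `gene`; one gene per row. No
#' ontology propagation is performed: the annotation is taken as given.
#'
#' @param path TSV path.
#' @param aliases alias vector for symbol normalization.
#' @return named list term -> character vector of genes; term names carried
#'   in attribute `term_names`.
#' @export
read_annotation <- function(path, aliases = NULL) {
  df <- read_tsv_strict(path, c("term_id", "term_name", "gene"), "annotation")
  df$gene <- normalize_symbol(df$gene, aliases)
  sets <- split(df$gene, df$term_id)
  sets <- lapply(sets, unique)
  nm <- df$term_name[!duplicated(df$term_id)]
  names(nm) <- df$term_id[!duplicated(df$term_id)]
  attr(sets, "term_names") <- nm[names(sets)]
  sets
}
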