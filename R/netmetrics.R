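#' Extract the associative network of a condition
#'
#' The condition network contains every gene-like entity linked to the
#' condition by at least one stored interaction (in either direction),
#' together with the interactions among those genes. Gene-gene edges are
#' reported as the simple undirected projection (parallel typed links
#' collapsed, multiplicity retained; self-loops dropped).
#'
#' @param kb `knowledge_base`.
#' @param condition_id entity id of a condition node.
#' @return object of class `condition_network` with elements
#'   `condition_id`, `members` (gene symbols), `gene_gene_edges`
#'   (data.frame `from`, `to`, `multiplicity`, symbols), `gene_condition_links`
#'   (named integer: parallel link count per member), and `empty` flag.
#' @export
extract_condition_network <- function(kb, condition_id) {
  ent <- kb$entities
  row <- ent[ent$id == condition_id, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop("unknown condition id: ", condition_id, call. = FALSE)
  }
  if (row$etype != "condition") {
    stop(sprintf("entity %s has type %s, not condition", condition_id,
                 row$etype), call. = FALSE)
  }
  glike_ids <- ent$id[ent$etype %in% GENE_LIKE]
  e <- kb$interactions
  cond_e <- e[(e$source == condition_id & e$target %in% glike_ids) |
              (e$target == condition_id & e$source %in% glike_ids), ,
              drop = FALSE]
  partner <- ifelse(cond_e$source == condition_id, cond_e$target,
                    cond_e$source)
  member_ids <- sort(unique(partner))
  empty <- length(member_ids) == 0L
  if (empty) {
    warning(sprintf("condition %s has no linked genes; returning empty network",
                    condition_id), call. = FALSE)
  }
  id2sym <- stats::setNames(ent$name, ent$id)
  links <- table(factor(partner, levels = member_ids))
  gcl <- stats::setNames(as.integer(links), unname(id2sym[member_ids]))

  gg <- simple_projection(kb, ids = member_ids)
  if (nrow(gg) > 0L) {
    gg$from <- unname(id2sym[gg$from])
    gg$to <- unname(id2sym[gg$to])
    # re-canonicalize on symbols and drop symbol-level self loops
    a <- pmin(gg$from, gg$to); b <- pmax(gg$from, gg$to)
    gg$from <- a; gg$to <- b
    gg <- gg[gg$from != gg$to, , drop = FALSE]
    gg <- gg[order(gg$from, gg$to), , drop = FALSE]
    rownames(gg) <- NULL
  }
  structure(list(condition_id = condition_id,
                 members = sort(unname(id2sym[member_ids])),
                 member_ids = member_ids,
                 gene_gene_edges = gg,
                 gene_condition_links = gcl,
                 empty = empty),
            class = "condition_network")
}

#' @export
print.condition_network <- function(x, ...) {
  cat(sprintf("condition_network '%s': %d genes, %d gene-gene edges\n",
              x$condition_id, length(x$members), nrow(x$gene_gene_edges)))
  invisible(x)
}

cn_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$gene_gene_edges[, c("from", "to"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = net$members, stringsAsFactors = FALSE))
}

#' Betweenness centrality of condition-network genes
#'
#' Computed on the simple undirected unweighted gene-gene graph (condition
#' node excluded, self-loops excluded), unnormalized, with unordered pairs
#' counted once and fractional credit split equally among equally short
#' paths. Disconnected components are handled natively; degree-0 and
#' degree-1 genes score 0.
#'
#' @param net `condition_network`.
#' @return named numeric vector, one entry per member gene.
#' @export
betweenness_centrality <- function(net) {
  if (length(net$members) == 0L) return(stats::setNames(numeric(0), character(0)))
  g <- cn_igraph(net)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  b[net$members]
}

#' Cross-talk specificity of condition-network genes
#'
#' For gene i, `K` counts the stored links (parallel typed links included,
#' self-loops excluded) incident to i whose other endpoint is inside the
#' condition network or is the condition node itself, and `M` counts all
#' stored links of i in the whole knowledge base. CTS = K/M lies in (0, 1]:
#' values near 1 mark genes whose literature links are specific to the
#' analyzed network, values near 0 mark promiscuous global hubs.
#'
#' @param net `condition_network`.
#' @param kb the `knowledge_base` the network was extracted from.
#' @return data.frame with columns `gene`, `K`, `neighbor_degree`
#'   (distinct-neighbor count in the simple gene-gene projection), `M`, `CTS`.
#' @export
cross_talk_specificity <- function(net, kb) {
  members <- net$members
  if (length(members) == 0L) {
    return(data.frame(gene = character(0), K = integer(0),
                      neighbor_degree = integer(0), M = integer(0),
                      CTS = numeric(0), stringsAsFactors = FALSE))
  }
  ent <- kb$entities
  id2sym <- stats::setNames(ent$name, ent$id)
  member_ids <- net$member_ids
  cond <- net$condition_id
  e <- kb$interactions
  e <- e[e$source != e$target, , drop = FALSE]  # self-loops out of metrics

  inside <- c(member_ids, cond)
  src_m <- e$source %in% member_ids
  tgt_m <- e$target %in% member_ids

  # one occurrence per (stored link, member endpoint); links between two
  # members appear once for each of them
  ends_gene <- c(e$source[src_m], e$target[tgt_m])
  ends_other <- c(e$target[src_m], e$source[tgt_m])
  # M: every stored link incident to the gene anywhere in the kb
  M <- as.integer(table(factor(ends_gene, levels = member_ids)))
  # K: links whose other endpoint is in the network or is the condition
  K <- as.integer(table(factor(ends_gene[ends_other %in% inside],
                               levels = member_ids)))
  if (any(M == 0L)) {
    stop("internal consistency error: network member with zero global links",
         call. = FALSE)
  }
  syms <- unname(id2sym[member_ids])
  nd <- integer(length(members))
  names(nd) <- members
  if (nrow(net$gene_gene_edges) > 0L) {
    dtab <- table(factor(c(net$gene_gene_edges$from, net$gene_gene_edges$to),
                         levels = members))
    nd[] <- as.integer(dtab)
  }
  out <- data.frame(gene = syms, K = K,
                    neighbor_degree = unname(nd[syms]),
                    M = M, CTS = K / M, stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full per-gene metric table for a condition network
#'
#' Combines connectivity (`K`, with parallel typed links and the
#' gene-condition links counted), distinct-neighbor degree, unnormalized
#' betweenness centrality, global link count `M` and cross-talk specificity
#' `CTS`, sorted by CTS descending.
#'
#' @inheritParams cross_talk_specificity
#' @return data.frame with columns `gene`, `K`, `neighbor_degree`,
#'   `betweenness`, `M`, `CTS`.
#' @export
node_metrics <- function(net, kb) {
  cts <- cross_talk_specificity(net, kb)
  b <- betweenness_centrality(net)
  cts$betweenness <- unname(b[cts$gene])
  cts <- cts[, c("gene", "K", "neighbor_degree", "betweenness", "M", "CTS")]
  cts <- cts[order(-cts$CTS, cts$gene), , drop = FALSE]
  rownames(cts) <- NULL
  cts
}

#' Rank genes by a metric
#'
#' @param metrics data.frame as returned by [node_metrics()] (needs `gene`
#'   plus the requested key column).
#' @param key one of `"K"` (connectivity), `"B"` (betweenness), `"CTS"`.
#' @param n number of genes to return.
#' @return character vector of gene symbols, descending by key, ties broken
#'   lexicographically; length `min(n, nrow(metrics))`.
#' @export
rank_nodes <- function(metrics, key = c("K", "B", "CTS"), n = 10L) {
  key <- match.arg(key)
  if (nrow(metrics) == 0L) stop("metrics table is empty", call. = FALSE)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  col <- switch(key, K = "K", B = "betweenness", CTS = "CTS")
  if (is.null(metrics[[col]])) {
    stop("metrics table lacks column ", col, call. = FALSE)
  }
  ord <- order(-metrics[[col]], metrics$gene)
  metrics$gene[ord][seq_len(min(n, nrow(metrics)))]
}

#' Write the metric table as TSV
#' @param metrics data.frame from [node_metrics()].
#' @param path output path.
#' @export
write_metrics <- function(metrics, path) {
  write_tsv_plain(metrics, path)
  invisible(path)
}
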