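# Independent oracles used to validate the package's metrics and statistics.
# Deliberately naive implementations: exhaustive enumeration, no shared code
# with the package internals.

# Brute-force betweenness: enumerate ALL simple paths per unordered pair by
# depth-first search, keep the shortest ones, split one unit of credit per
# pair equally across them, and sum credit for intermediate vertices.
brute_betweenness <- function(nodes, edges) {
  adj <- setNames(lapply(nodes, function(v) character(0)), nodes)
  if (nrow(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      a <- edges$from[i]; b <- edges$to[i]
      if (a == b) next
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        out[[length(out) + 1L]] <<- path
        return(invisible())
      }
      for (w in adj[[v]]) if (!(w %in% path)) walk(c(path, w))
    }
    walk(s)
    out
  }
  b <- setNames(numeric(length(nodes)), nodes)
  n <- length(nodes)
  if (n < 2L) return(b)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    paths <- all_paths(nodes[i], nodes[j])
    if (length(paths) == 0L) next
    lens <- vapply(paths, length, 0L)
    short <- paths[lens == min(lens)]
    for (p in short) {
      inner <- p[-c(1L, length(p))]
      if (length(inner) > 0L) b[inner] <- b[inner] + 1 / length(short)
    }
  }
  b
}

# total (pair, intermediate) shortest-path credit, for conservation checks
brute_total_credit <- function(nodes, edges) sum(brute_betweenness(nodes, edges))

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from a
# universe of N items of which the first K are marked, count draws with at
# least k marked.
enum_hypergeom_tail <- function(k, K, n, N) {
  if (n == 0L) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Erdos-Renyi style random simple graph as an edge data.frame
random_edges <- function(n_nodes, p = 0.4) {
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  data.frame(from = pairs[1L, keep], to = pairs[2L, keep],
             stringsAsFactors = FALSE)
}

# small knowledge base from explicit edge triples; conditions inferred from
# ids starting with "cond"
toy_kb <- function(edges, extra_nodes = character(0)) {
  ids <- unique(c(edges$source, edges$target, extra_nodes))
  etype <- ifelse(grepl("^cond", ids), "condition", "gene")
  if (is.null(edges$rtype)) edges$rtype <- "ASSOCIATION"
  if (is.null(edges$pmids)) edges$pmids <- ""
  knowledge_base(data.frame(id = ids, name = ids, etype = etype,
                            stringsAsFactors = FALSE),
                 edges)
}

# condition network over the given edge list, condition linked to members
toy_condition_kb <- function(members, gene_edges = NULL,
                             cond = "cond1", rtype = "ASSOCIATION") {
  ce <- data.frame(source = members, target = cond, rtype = rtype,
                   pmids = "", stringsAsFactors = FALSE)
  e <- if (is.null(gene_edges) || nrow(gene_edges) == 0L) ce else {
    if (is.null(gene_edges$rtype)) gene_edges$rtype <- rep(rtype,
                                                           nrow(gene_edges))
    gene_edges$pmids <- rep("", nrow(gene_edges))
    rbind(ce, gene_edges[, c("source", "target", "rtype", "pmids")])
  }
  toy_kb(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
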