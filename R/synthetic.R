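GENE_CLASS_RTYPE <- data.frame(
  class = c("UP", "DOWN", "CAUSAL", "PROTECTIVE", "SNP_RISK", "OTHER"),
  rtype = c("UPREGULATES", "DOWNREGULATES", "CAUSES", "PROTECTS_AGAINST",
            "SNP_RISK", "ASSOCIATION"),
  direction = c("condition_to_gene", "condition_to_gene",
                "gene_to_condition", "gene_to_condition",
                "gene_to_condition", "gene_to_condition"),
  stringsAsFactors = FALSE)

#' Specification of a synthetic knowledge base
#'
#' Parameter record for the seeded generator. The defaults emulate the
#' published five-condition comparison the package validates against: one
#' focus network of 141 genes matched against comparator networks of 494,
#' 424, 685 and 130 genes, a 14-gene core shared by all five, and focus
#' overlaps of 47, 50, 62 and 22 genes; the global graph is a
#' preferential-attachment network of 2000 genes (3 edges per new node),
#' which gives the heavy-tailed degree distribution literature networks
#' show.
#'
#' @param n_genes number of genes in the global network.
#' @param m edges attached by each new node (preferential attachment).
#' @param n_conditions number of condition modules.
#' @param module_sizes integer vector, one size per condition.
#' @param core_size genes shared by all condition modules.
#' @param focus_overlaps planted overlap (core included) between the first
#'   condition's module and each of the others; `NULL` for independent
#'   modules (random overlap).
#' @param n_terms number of background annotation terms.
#' @param term_size_range integer length-2: uniform range of term sizes.
#' @param planted_term_fraction fraction in (0, 1] of each module covered by
#'   its planted enriched term.
#' @param planted_term_pad random non-module genes padded onto each planted
#'   term.
#' @param class_weights sampling weights over the six link classes for
#'   gene-condition edges; must sum to 1.
#' @param gg_rtype_weights named weights over gene-gene relation labels;
#'   must sum to 1.
#' @param seed integer seed driving every random draw.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000L, m = 3L, n_conditions = 5L,
                           module_sizes = c(141L, 494L, 424L, 685L, 130L),
                           core_size = 14L,
                           focus_overlaps = c(47L, 50L, 62L, 22L),
                           n_terms = 50L, term_size_range = c(10L, 40L),
                           planted_term_fraction = 0.8,
                           planted_term_pad = 5L,
                           class_weights = c(UP = 0.30, DOWN = 0.12,
                                             CAUSAL = 0.11,
                                             PROTECTIVE = 0.16,
                                             SNP_RISK = 0.18, OTHER = 0.13),
                           gg_rtype_weights = c(PPI = 0.5, ASSOCIATION = 0.3,
                                                UPREGULATES = 0.1,
                                                DOWNREGULATES = 0.1),
                           seed = 1L) {
  if (n_genes <= m || m < 1L) {
    stop("require n_genes > m >= 1", call. = FALSE)
  }
  if (length(module_sizes) != n_conditions) {
    stop("module_sizes must have one entry per condition", call. = FALSE)
  }
  if (core_size > min(module_sizes)) {
    stop("core_size must not exceed the smallest module", call. = FALSE)
  }
  if (any(module_sizes > n_genes)) {
    stop("module sizes must not exceed n_genes", call. = FALSE)
  }
  if (!is.null(focus_overlaps)) {
    if (length(focus_overlaps) != n_conditions - 1L) {
      stop("focus_overlaps must have one entry per non-focus condition",
           call. = FALSE)
    }
    if (any(focus_overlaps < core_size)) {
      stop("each focus overlap must be at least core_size", call. = FALSE)
    }
    if (core_size + sum(focus_overlaps - core_size) > module_sizes[1L]) {
      stop("planted overlaps exceed the focus module size", call. = FALSE)
    }
  }
  if (planted_term_fraction <= 0 || planted_term_fraction > 1) {
    stop("planted_term_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (abs(sum(class_weights) - 1) > 1e-8 ||
      abs(sum(gg_rtype_weights) - 1) > 1e-8) {
    stop("class_weights and gg_rtype_weights must each sum to 1",
         call. = FALSE)
  }
  if (!setequal(names(class_weights), LINK_CLASSES)) {
    stop("class_weights must be named by the six link classes",
         call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), m = as.integer(m),
                 n_conditions = as.integer(n_conditions),
                 module_sizes = as.integer(module_sizes),
                 core_size = as.integer(core_size),
                 focus_overlaps = if (is.null(focus_overlaps)) NULL else
                   as.integer(focus_overlaps),
                 n_terms = as.integer(n_terms),
                 term_size_range = as.integer(term_size_range),
                 planted_term_fraction = planted_term_fraction,
                 planted_term_pad = as.integer(planted_term_pad),
                 class_weights = class_weights,
                 gg_rtype_weights = gg_rtype_weights,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate the global gene-gene network
#'
#' Preferential-attachment growth: each new gene attaches `m` edges to
#' existing genes with probability proportional to current degree, yielding
#' the heavy-tailed degree distribution typical of literature-derived
#' interaction networks. Relation labels are sampled from
#' `gg_rtype_weights`. Deterministic for a fixed seed.
#'
#' @param n_genes,m,seed see [synthetic_spec()].
#' @param gg_rtype_weights named sampling weights over relation labels.
#' @return `knowledge_base` containing only gene entities.
#' @export
generate_global_network <- function(n_genes, m, seed,
                                    gg_rtype_weights = c(PPI = 0.5,
                                                         ASSOCIATION = 0.3,
                                                         UPREGULATES = 0.1,
                                                         DOWNREGULATES = 0.1)) {
  if (n_genes <= m || m < 1L) stop("require n_genes > m >= 1", call. = FALSE)
  with_seed(seed, {
    g <- igraph::sample_pa(n_genes, power = 1, m = m, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    syms <- sprintf("G%04d", seq_len(n_genes))
    rt <- sample(names(gg_rtype_weights), nrow(el), replace = TRUE,
                 prob = gg_rtype_weights)
    entities <- data.frame(id = syms, name = syms, etype = "gene",
                           stringsAsFactors = FALSE)
    interactions <- data.frame(source = syms[el[, 1L]],
                               target = syms[el[, 2L]],
                               rtype = rt, pmids = "",
                               stringsAsFactors = FALSE)
    knowledge_base(entities, interactions)
  })
}

kb_gene_degree <- function(kb) {
  genes <- kb$entities$id[kb$entities$etype %in% GENE_LIKE]
  e <- kb$interactions
  e <- e[e$source %in% genes & e$target %in% genes & e$source != e$target, ,
         drop = FALSE]
  tab <- table(factor(c(e$source, e$target), levels = genes))
  stats::setNames(as.integer(tab), genes)
}

#' Plant condition modules into a knowledge base
#'
#' Core genes are drawn first and linked to every condition; the remaining
#' module members are drawn without replacement with probability
#' proportional to (degree + 1), emulating the literature bias toward hubs.
#' When `focus_overlaps` is given, the extra genes shared between the focus
#' module and each comparator are drawn disjointly so the planted pairwise
#' intersections are exact; with `focus_overlaps = NULL` modules are drawn
#' independently. Each gene-condition edge is typed by a link class sampled
#' from `class_weights`, so the class assignment is planted too.
#'
#' @param kb `knowledge_base` of genes (see [generate_global_network()]).
#' @param spec `synthetic_spec`.
#' @param seed seed for the planting draws.
#' @return list with elements `kb` (conditions and gene-condition edges
#'   added) and `truth` (`synthetic_truth`: `modules`, `core`,
#'   `class_assignment`, `condition_ids`, `spec`).
#' @export
plant_conditions <- function(kb, spec, seed = spec$seed + 1L) {
  genes <- kb$entities$id[kb$entities$etype %in% GENE_LIKE]
  if (spec$n_genes > length(genes)) {
    stop("spec expects more genes than the knowledge base holds",
         call. = FALSE)
  }
  deg <- kb_gene_degree(kb)
  cond_ids <- sprintf("COND%d", seq_len(spec$n_conditions))
  with_seed(seed, {
    w <- deg + 1
    draw <- function(pool, size) {
      if (size > length(pool)) {
        stop("infeasible module sizes: gene pool exhausted", call. = FALSE)
      }
      if (size == 0L) return(character(0))
      sample(pool, size, prob = w[pool])
    }
    pool <- genes
    core <- draw(pool, spec$core_size)
    pool <- setdiff(pool, core)
    modules <- vector("list", spec$n_conditions)
    if (is.null(spec$focus_overlaps)) {
      for (j in seq_len(spec$n_conditions)) {
        extra <- draw(pool, spec$module_sizes[j] - spec$core_size)
        modules[[j]] <- c(core, extra)  # independent: pool not consumed
      }
    } else {
      extras <- vector("list", spec$n_conditions - 1L)
      for (j in seq_len(spec$n_conditions - 1L)) {
        extras[[j]] <- draw(pool, spec$focus_overlaps[j] - spec$core_size)
        pool <- setdiff(pool, extras[[j]])
      }
      excl1 <- draw(pool, spec$module_sizes[1L] - spec$core_size -
                      sum(lengths(extras)))
      pool <- setdiff(pool, excl1)
      modules[[1L]] <- c(core, unlist(extras), excl1)
      for (j in seq_len(spec$n_conditions - 1L)) {
        exclj <- draw(pool, spec$module_sizes[j + 1L] -
                        spec$focus_overlaps[j])
        pool <- setdiff(pool, exclj)
        modules[[j + 1L]] <- c(core, extras[[j]], exclj)
      }
    }
    names(modules) <- cond_ids

    # type the gene-condition links, recording the planted classes
    rows <- list()
    class_assignment <- vector("list", spec$n_conditions)
    names(class_assignment) <- cond_ids
    for (j in seq_len(spec$n_conditions)) {
      mod <- modules[[j]]
      cls <- sample(names(spec$class_weights), length(mod), replace = TRUE,
                    prob = spec$class_weights)
      map <- GENE_CLASS_RTYPE[match(cls, GENE_CLASS_RTYPE$class), ]
      src <- ifelse(map$direction == "condition_to_gene", cond_ids[j], mod)
      tgt <- ifelse(map$direction == "condition_to_gene", mod, cond_ids[j])
      rows[[j]] <- data.frame(source = src, target = tgt, rtype = map$rtype,
                              pmids = "", stringsAsFactors = FALSE)
      class_assignment[[j]] <- stats::setNames(as.list(cls), mod)
    }
    cond_ent <- data.frame(id = cond_ids, name = cond_ids,
                           etype = "condition", stringsAsFactors = FALSE)
    kb2 <- knowledge_base(rbind(kb$entities, cond_ent),
                          rbind(kb$interactions, do.call(rbind, rows)))
    truth <- structure(list(modules = lapply(modules, sort),
                            core = sort(core),
                            class_assignment = class_assignment,
                            condition_ids = cond_ids, spec = spec),
                       class = "synthetic_truth")
    list(kb = kb2, truth = truth)
  })
}

#' Plant annotation terms
#'
#' Generates `n_terms` background terms of sizes uniform in
#' `term_size_range` over random genes, plus one planted enriched term per
#' condition containing `planted_term_fraction` of that condition's module
#' (padded with `planted_term_pad` random non-module genes).
#'
#' @param kb `knowledge_base` (genes provide the annotation universe).
#' @param truth `synthetic_truth` from [plant_conditions()].
#' @param seed seed for the annotation draws.
#' @return list: `annotation` (named list term -> genes) and `truth` with
#'   `planted_terms` (named character vector condition id -> term id) added.
#' @export
plant_annotations <- function(kb, truth, seed = truth$spec$seed + 2L) {
  spec <- truth$spec
  if (spec$planted_term_fraction <= 0 || spec$planted_term_fraction > 1) {
    stop("planted_term_fraction must lie in (0, 1]", call. = FALSE)
  }
  genes <- kb$entities$id[kb$entities$etype %in% GENE_LIKE]
  with_seed(seed, {
    annotation <- list()
    for (t in seq_len(spec$n_terms)) {
      size <- sample(seq(spec$term_size_range[1L], spec$term_size_range[2L]),
                     1L)
      annotation[[sprintf("T%03d", t)]] <- sort(sample(genes, size))
    }
    planted <- character(0)
    for (cid in truth$condition_ids) {
      mod <- truth$modules[[cid]]
      n_in <- max(1L, round(spec$planted_term_fraction * length(mod)))
      inside <- sample(mod, n_in)
      pad <- sample(setdiff(genes, mod), spec$planted_term_pad)
      tid <- paste0("PLANTED_", cid)
      annotation[[tid]] <- sort(c(inside, pad))
      planted[cid] <- tid
    }
    truth$planted_terms <- planted
    list(annotation = annotation, truth = truth)
  })
}

#' Generate a complete synthetic bundle
#'
#' Runs the three planting stages under seeds derived from `spec$seed` and
#' returns the knowledge base, annotation map and ground truth together.
#'
#' @param spec `synthetic_spec`.
#' @return list with `kb`, `annotation`, `truth`.
#' @export
generate_synthetic_bundle <- function(spec = synthetic_spec()) {
  kb <- generate_global_network(spec$n_genes, spec$m, spec$seed,
                                spec$gg_rtype_weights)
  planted <- plant_conditions(kb, spec, seed = spec$seed + 1L)
  ann <- plant_annotations(planted$kb, planted$truth,
                           seed = spec$seed + 2L)
  list(kb = planted$kb, annotation = ann$annotation, truth = ann$truth)
}

#' Write a synthetic bundle to disk
#'
#' Emits the node/edge TSV dialect of [read_kb()], one GMT of the planted
#' modules, the annotation TSV of [read_annotation()], and the ground truth
#' as JSON.
#'
#' @param bundle list from [generate_synthetic_bundle()].
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_plain(bundle$kb$entities, file.path(dir, "nodes.tsv"))
  write_tsv_plain(bundle$kb$interactions, file.path(dir, "edges.tsv"))
  write_gmt(bundle$truth$modules, file.path(dir, "modules.gmt"))
  ann <- bundle$annotation
  df <- data.frame(term_id = rep(names(ann), lengths(ann)),
                   term_name = rep(names(ann), lengths(ann)),
                   gene = unlist(ann, use.names = FALSE),
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, file.path(dir, "annotation.tsv"))
  truth <- bundle$truth
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Synthesize a knowledge base from a class assignment
#'
#' Inverse of [classify_condition_links()] for round-trip testing: builds a
#' minimal knowledge base whose gene-condition edges encode exactly the
#' given multi-label assignment (one typed edge per gene-class pair; OTHER
#' becomes a plain ASSOCIATION link).
#'
#' @param assignment named list gene -> character vector of classes.
#' @param condition_id id for the condition entity.
#' @return `knowledge_base`.
#' @export
kb_from_class_assignment <- function(assignment, condition_id = "COND1") {
  genes <- names(assignment)
  rows <- list()
  for (g in genes) {
    for (cl in assignment[[g]]) {
      map <- GENE_CLASS_RTYPE[GENE_CLASS_RTYPE$class == cl, ]
      if (nrow(map) == 0L) stop("unknown class: ", cl, call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        source = if (map$direction == "condition_to_gene") condition_id else g,
        target = if (map$direction == "condition_to_gene") g else condition_id,
        rtype = map$rtype, pmids = "", stringsAsFactors = FALSE)
    }
  }
  entities <- data.frame(id = c(genes, condition_id),
                         name = c(genes, condition_id),
                         etype = c(rep("gene", length(genes)), "condition"),
                         stringsAsFactors = FALSE)
  knowledge_base(entities, do.call(rbind, rows))
}
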