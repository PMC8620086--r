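REPORT_SCHEMA_VERSION <- "1.0"

#' Pipeline run configuration
#'
#' Two modes are supported. Knowledge-base mode (`nodes` + `edges` given):
#' condition networks are extracted, per-gene metrics computed for the
#' focus condition, link classes assigned, and the set-level comparisons
#' run on the extracted memberships. Set-only mode (`sets_gmt` given): the
#' comparisons (overlap matrix, Venn partition, mutual core, optional term
#' enrichment) run directly on the supplied gene sets — the degraded mode
#' for users who have curated lists but no graph.
#'
#' @param focus condition entity id (kb mode) or set name (sets mode).
#' @param nodes,edges node/edge TSV paths ([read_kb()] dialect).
#' @param sets_gmt GMT of named gene sets (sets mode).
#' @param annotation optional annotation TSV ([read_annotation()] dialect).
#' @param comparators character vector of condition ids / set names to
#'   compare against; defaults to every other condition/set.
#' @param background_N background universe size; defaults to the number of
#'   gene entities in the knowledge base (kb mode); required in sets mode.
#' @param alpha significance threshold (default 0.01).
#' @param method `"bonferroni"` or `"BH"`.
#' @param aliases_path optional alias TSV; defaults to the packaged table.
#' @param seed integer recorded in the report (the pipeline itself is
#'   deterministic).
#' @param outdir output directory for the JSON report and TSV side files.
#' @return object of class `run_config`.
#' @export
run_config <- function(focus, nodes = NULL, edges = NULL, sets_gmt = NULL,
                       annotation = NULL, comparators = NULL,
                       background_N = NULL, alpha = 0.01,
                       method = c("bonferroni", "BH"), aliases_path = NULL,
                       seed = 1L, outdir = tempfile("condnet_run")) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  kb_mode <- !is.null(nodes) || !is.null(edges)
  if (kb_mode && (is.null(nodes) || is.null(edges))) {
    stop("knowledge-base mode needs both nodes and edges paths",
         call. = FALSE)
  }
  if (!kb_mode && is.null(sets_gmt)) {
    stop("supply either nodes+edges or sets_gmt", call. = FALSE)
  }
  for (p in c(nodes, edges, sets_gmt, annotation, aliases_path)) {
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  }
  if (!kb_mode && is.null(background_N)) {
    stop("set-only mode needs an explicit background_N", call. = FALSE)
  }
  structure(list(focus = focus, nodes = nodes, edges = edges,
                 sets_gmt = sets_gmt, annotation = annotation,
                 comparators = comparators, background_N = background_N,
                 alpha = alpha, method = method,
                 aliases_path = aliases_path, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the comparative network pipeline
#'
#' Executes every analysis stage the configuration allows and writes a
#' versioned JSON report plus TSV side files into `config$outdir`. Reruns
#' with identical inputs produce byte-identical reports; on any stage
#' error the partially written output directory is removed.
#'
#' @param config `run_config`.
#' @return the report, invisibly also written to
#'   `file.path(config$outdir, "report.json")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  aliases <- if (is.null(config$aliases_path)) read_alias_table() else
    read_alias_table(config$aliases_path)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  created <- character(0)
  on_fail <- function(e) {
    unlink(created)
    stop(e)
  }
  emit <- function(fun, obj, file) {
    path <- file.path(config$outdir, file)
    fun(obj, path)
    created <<- c(created, path)
  }

  tryCatch({
    # the output location is not a semantic input: reports must be
    # byte-identical wherever they are written
    cfg_rec <- unclass(config)
    cfg_rec$outdir <- NULL
    report <- list(schema_version = REPORT_SCHEMA_VERSION,
                   tool = paste0("condnet ",
                                 as.character(utils::packageVersion("condnet"))),
                   config = cfg_rec)
    report$config_hash <- config_hash(
      jsonlite::toJSON(cfg_rec, auto_unbox = TRUE, null = "null"))

    kb_mode <- !is.null(config$nodes)
    if (kb_mode) {
      kb <- stage("read_kb", read_kb(config$nodes, config$edges, aliases))
      cond_ids <- kb$entities$id[kb$entities$etype == "condition"]
      comparators <- config$comparators %||%
        sort(setdiff(cond_ids, config$focus))
      N <- config$background_N %||%
        sum(kb$entities$etype %in% GENE_LIKE)
      nets <- stage("extract", {
        ids <- c(config$focus, comparators)
        stats::setNames(lapply(ids, extract_condition_network, kb = kb), ids)
      })
      sets <- lapply(nets, function(n) n$members)
      metrics <- stage("metrics", node_metrics(nets[[config$focus]], kb))
      emit(write_metrics, metrics, "focus_metrics.tsv")
      emit(write_sif, nets[[config$focus]], "focus_network.sif")
      report$focus_metrics_top <- list(
        by_connectivity = rank_nodes(metrics, "K", 15L),
        by_betweenness = rank_nodes(metrics, "B", 15L),
        by_cts = rank_nodes(metrics, "CTS", 10L))
      cls <- stage("classify", {
        stats::setNames(lapply(names(nets), classify_condition_links,
                               kb = kb), names(nets))
      })
      emit(write_classification, cls[[config$focus]],
           "focus_classification.tsv")
      report$class_counts <- lapply(cls, function(x)
        as.list(class_counts(x)))
      if (length(comparators) >= 1L) {
        ct <- stage("crosstab", cross_classification(cls[[config$focus]],
                                                     cls[[comparators[1L]]]))
        emit(write_cross_table, ct, "cross_table.tsv")
        report$cross_table_sizes <- lapply(ct$cells, length)
      }
    } else {
      sets <- stage("read_sets", read_gmt(config$sets_gmt, aliases))
      if (!(config$focus %in% names(sets))) {
        stop("focus set not found in GMT: ", config$focus, call. = FALSE)
      }
      comparators <- config$comparators %||%
        sort(setdiff(names(sets), config$focus))
      sets <- sets[c(config$focus, comparators)]
      N <- config$background_N
    }

    report$network_sizes <- lapply(sets, length)
    if (length(comparators) >= 1L) {
      om <- stage("overlap", overlap_matrix(sets[[config$focus]],
                                            sets[comparators], N,
                                            alpha = config$alpha))
      emit(write_tsv_plain, as.data.frame(om), "overlap_matrix.tsv")
      report$overlap_matrix <- lapply(seq_len(nrow(om)), function(i)
        list(comparator = om$comparator[i], k = om$k[i], K = om$K[i],
             n = om$n[i], N = om$N[i], log10_p = om$log10_p[i]))
    }
    if (length(sets) >= 2L && length(sets) <= 6L) {
      vp <- stage("venn", venn_partition(sets))
      emit(write_venn, vp, "venn_partition.tsv")
      report$venn_sizes <- as.list(vp$sizes)
      report$mutual_genes <- mutual_genes(sets)
    }
    if (!is.null(config$annotation)) {
      ann <- stage("read_annotation",
                   read_annotation(config$annotation, aliases))
      background <- sort(unique(c(unlist(sets, use.names = FALSE),
                                  unlist(ann, use.names = FALSE))))
      enr <- stage("enrich", {
        lapply(sets, term_enrichment, annotation = ann,
               background = background, alpha = config$alpha,
               method = config$method)
      })
      for (nm in names(enr)) {
        emit(write_enrichment, enr[[nm]],
             sprintf("enrichment_%s.tsv", gsub("[^A-Za-z0-9_.-]", "_", nm)))
      }
      shared <- stage("shared_terms",
                      shared_enriched_terms(enr, alpha = config$alpha))
      report$shared_terms <- shared$label
      report$significant_terms <- lapply(enr, function(r)
        r$label[r$significant])
    }

    path <- file.path(config$outdir, "report.json")
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    created <- c(created, path)
    invisible(report)
  }, error = on_fail)
}

#' Render a human-readable pipeline summary
#'
#' Deterministic plain-text rendering of a report: tool version, config
#' hash, network sizes, top-ranked genes, class counts in fixed class
#' order, overlaps and shared terms.
#'
#' @param report list returned by [run_pipeline()].
#' @return character vector of lines.
#' @export
render_summary <- function(report) {
  lines <- c(sprintf("%s report (schema %s, config %s)",
                     report$tool %||% "condnet",
                     report$schema_version %||% "?",
                     report$config_hash %||% "?"))
  if (!is.null(report$network_sizes)) {
    lines <- c(lines, "network sizes:",
               sprintf("  %s: %d", names(report$network_sizes),
                       unlist(report$network_sizes)))
  }
  if (!is.null(report$focus_metrics_top)) {
    lines <- c(lines,
               sprintf("top by connectivity: %s",
                       paste(report$focus_metrics_top$by_connectivity,
                             collapse = ", ")),
               sprintf("top by betweenness: %s",
                       paste(report$focus_metrics_top$by_betweenness,
                             collapse = ", ")),
               sprintf("top by CTS: %s",
                       paste(report$focus_metrics_top$by_cts,
                             collapse = ", ")))
  }
  if (!is.null(report$class_counts)) {
    for (nm in names(report$class_counts)) {
      cc <- report$class_counts[[nm]]
      lines <- c(lines, sprintf("link classes %s: %s", nm,
                                paste(sprintf("%s=%d", LINK_CLASSES,
                                              unlist(cc[LINK_CLASSES])),
                                      collapse = " ")))
    }
  }
  if (!is.null(report$overlap_matrix)) {
    for (cell in report$overlap_matrix) {
      lines <- c(lines, sprintf("overlap %s: k=%d (K=%d, n=%d, N=%d) log10p=%.2f",
                                cell$comparator, cell$k, cell$K, cell$n,
                                cell$N, cell$log10_p))
    }
  }
  if (!is.null(report$mutual_genes)) {
    lines <- c(lines, sprintf("mutual genes (%d): %s",
                              length(report$mutual_genes),
                              paste(report$mutual_genes, collapse = ", ")))
  }
  if (!is.null(report$shared_terms)) {
    lines <- c(lines, sprintf("terms enriched in every set (%d): %s",
                              length(report$shared_terms),
                              paste(report$shared_terms, collapse = ", ")))
  }
  lines
}
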