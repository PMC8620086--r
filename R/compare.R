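#' Disjoint Venn partition of 2-6 gene sets
#'
#' Every gene of the union is assigned to exactly one region, keyed by its
#' membership bitmask over the declared set order (e.g. `"10110"` for a gene
#' present in sets 1, 3 and 4 of five). Bitmask keys serialize any diagram
#' up to six-way without drawing it.
#'
#' @param sets named list of 2-6 character vectors.
#' @return object of class `venn_partition`: `set_names`, `regions` (named
#'   list bitmask -> sorted gene vector; only non-empty regions present),
#'   `sizes`.
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be a named list of gene vectors", call. = FALSE)
  }
  if (length(sets) < 2L || length(sets) > 6L) {
    stop("venn_partition requires between 2 and 6 sets", call. = FALSE)
  }
  sets <- lapply(sets, unique)
  univ <- sort(unique(unlist(sets, use.names = FALSE)))
  if (length(univ) == 0L) {
    return(structure(list(set_names = names(sets), regions = list(),
                          sizes = integer(0)), class = "venn_partition"))
  }
  member <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) member <- matrix(member, nrow = 1L)
  mask <- apply(member, 1L, function(r) paste(as.integer(r), collapse = ""))
  regions <- split(univ, mask)
  regions <- lapply(regions, sort)
  regions <- regions[order(names(regions), decreasing = TRUE)]
  structure(list(set_names = names(sets), regions = regions,
                 sizes = vapply(regions, length, 0L)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("venn_partition of %d sets (%s): %d non-empty regions, union %d\n",
              length(x$set_names), paste(x$set_names, collapse = ", "),
              length(x$regions), sum(x$sizes)))
  invisible(x)
}

#' Genes mutual to all sets
#'
#' The intersection of every input set; identical to the all-ones Venn
#' region.
#'
#' @param sets named or unnamed list of at least two character vectors.
#' @return sorted character vector.
#' @export
mutual_genes <- function(sets) {
  if (length(sets) < 2L) stop("mutual_genes requires >= 2 sets", call. = FALSE)
  sort(Reduce(intersect, lapply(sets, unique)))
}

#' Terms enriched simultaneously across conditions
#'
#' Keeps the terms whose corrected p-value clears `alpha` in every
#' per-condition enrichment table, sorted by their worst (largest) corrected
#' p ascending.
#'
#' @param per_condition_results list of data.frames as returned by
#'   [term_enrichment()].
#' @param alpha corrected-p threshold (default 0.01).
#' @return data.frame with columns `label`, `max_p_corrected`.
#' @export
shared_enriched_terms <- function(per_condition_results, alpha = 0.01) {
  if (length(per_condition_results) == 0L) {
    stop("no enrichment result lists supplied", call. = FALSE)
  }
  sig <- lapply(per_condition_results, function(r) {
    if (is.null(r$p_corrected)) {
      stop("result list lacks corrected p-values", call. = FALSE)
    }
    r[r$p_corrected < alpha, c("label", "p_corrected"), drop = FALSE]
  })
  shared <- Reduce(intersect, lapply(sig, function(r) r$label))
  if (length(shared) == 0L) {
    return(data.frame(label = character(0), max_p_corrected = numeric(0),
                      stringsAsFactors = FALSE))
  }
  worst <- vapply(shared, function(t)
    max(vapply(sig, function(r) r$p_corrected[match(t, r$label)], 0)),
    numeric(1))
  out <- data.frame(label = shared, max_p_corrected = unname(worst),
                    stringsAsFactors = FALSE)
  out <- out[order(out$max_p_corrected, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap matrix of a focus gene set against comparators
#'
#' One hypergeometric overrepresentation test per comparator set, with the
#' shared genes attached.
#'
#' @param focus character vector (the query network's genes).
#' @param comparators named list of character vectors.
#' @param N background universe size.
#' @param alpha threshold passed through to each cell.
#' @return data.frame of class `overlap_matrix`, one row per comparator:
#'   `comparator`, `k`, `K`, `n`, `N`, `log10_p`, `p_raw`, `genes`
#'   (semicolon-joined overlap).
#' @export
overlap_matrix <- function(focus, comparators, N, alpha = 0.01) {
  if (!is.list(comparators) || is.null(names(comparators))) {
    stop("comparators must be a named list", call. = FALSE)
  }
  rows <- lapply(names(comparators), function(nm) {
    r <- overlap_overrepresentation(focus, comparators[[nm]], N, label = nm,
                                    alpha = alpha)
    data.frame(comparator = nm, k = r$k, K = r$K, n = r$n, N = r$N,
               log10_p = r$log10_p, p_raw = r$p_raw,
               genes = paste(r$genes, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("overlap_matrix", class(out))
  out
}

#' Write a Venn partition as TSV
#' @param vp `venn_partition`.
#' @param path output path.
#' @export
write_venn <- function(vp, path) {
  df <- data.frame(bitmask = names(vp$regions),
                   size = unname(vp$sizes),
                   genes = vapply(vp$regions, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
  invisible(path)
}
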