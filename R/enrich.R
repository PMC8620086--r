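#' Log-space upper tail of the hypergeometric distribution
#'
#' Exact log10 of P(X >= k) for X ~ Hypergeometric(N, K, n): the probability
#' of drawing at least `k` marked items when `n` items are drawn without
#' replacement from a universe of `N` items of which `K` are marked. Terms
#' are evaluated as log-gamma sums and combined by log-sum-exp, so tails far
#' below the smallest double (p ~ 1e-300 and beyond) remain finite and
#' accurate in log-space.
#'
#' @param k overlap count (number of marked items drawn), `0 <= k <= min(K, n)`.
#' @param K number of marked items in the universe.
#' @param n number of items drawn.
#' @param N universe size.
#' @return log10 of P(X >= k), a non-positive real (0 when the event is the
#'   whole support).
#' @examples
#' 10^hypergeom_tail(3, 5, 4, 10)  # 55/210
#' @export
hypergeom_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L,
            length(N) == 1L)
  if (k < 0) stop("domain error: k >= 0 violated", call. = FALSE)
  if (K > N) stop("domain error: K <= N violated", call. = FALSE)
  if (n > N) stop("domain error: n <= N violated", call. = FALSE)
  if (k > min(K, n)) stop("domain error: k <= min(K, n) violated",
                          call. = FALSE)
  lo <- max(0, K + n - N)  # smallest attainable overlap
  if (k <= lo) return(0)
  i <- seq.int(k, min(K, n))
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  logsumexp(logp) / log(10)
}

log10p_to_p <- function(log10_p) pmin(1, 10^log10_p)

#' Bonferroni correction
#'
#' @param p_list raw p-values in (0, 1].
#' @param m number of tests; must be at least `length(p_list)`.
#' @return `pmin(1, m * p_list)`.
#' @export
bonferroni <- function(p_list, m = length(p_list)) {
  if (length(p_list) == 0L) return(numeric(0))
  if (any(p_list <= 0 | p_list > 1)) {
    stop("domain error: p-values must lie in (0, 1]", call. = FALSE)
  }
  if (m < length(p_list)) {
    stop("m must be >= length(p_list)", call. = FALSE)
  }
  pmin(1, m * p_list)
}

new_enrichment_result <- function(label, k, K, n, N, log10_p, m = 1L,
                                  alpha = 0.01, genes = character(0),
                                  method = "bonferroni") {
  p_raw <- log10p_to_p(log10_p)
  p_corr <- if (identical(method, "bonferroni")) min(1, m * p_raw) else p_raw
  structure(list(label = label, k = k, K = K, n = n, N = N,
                 log10_p = log10_p, p_raw = p_raw, p_corrected = p_corr,
                 significant = p_corr < alpha, genes = sort(genes)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment '%s': k=%d K=%d n=%d N=%d  p=%.3g (corrected %.3g)%s\n",
    x$label, x$k, x$K, x$n, x$N, x$p_raw, x$p_corrected,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Overrepresentation of one gene set within another
#'
#' Hypergeometric upper-tail test of the overlap between a query set and a
#' reference set drawn from a background of `N` genes: the chance of sharing
#' at least the observed number of genes if the two sets were independent
#' draws.
#'
#' @param query,reference character vectors of (normalized) gene symbols.
#' @param N background universe size; must be at least the size of the union.
#' @param label label carried into the result (defaults to "overlap").
#' @param alpha significance threshold applied to the (uncorrected, m = 1)
#'   p-value.
#' @return `enrichment_result` with the overlap members attached as `$genes`.
#' @export
overlap_overrepresentation <- function(query, reference, N,
                                       label = "overlap", alpha = 0.01) {
  query <- unique(query); reference <- unique(reference)
  u <- length(union(query, reference))
  if (N < u) {
    stop(sprintf("domain error: background N=%d smaller than union size %d",
                 N, u), call. = FALSE)
  }
  ov <- intersect(query, reference)
  lp <- hypergeom_tail(length(ov), length(query), length(reference), N)
  new_enrichment_result(label, length(ov), length(query), length(reference),
                        N, lp, m = 1L, alpha = alpha, genes = ov)
}

#' Term enrichment of a query gene set
#'
#' One hypergeometric upper-tail test per annotation term, corrected for
#' multiple testing. Annotated genes outside the background are dropped
#' (their count is reported via `message`); the number of tests `m` is the
#' number of terms carrying at least one query gene, the convention of
#' common enrichment tools.
#'
#' @param query character vector of genes; must be a subset of `background`.
#' @param annotation named list mapping term id to its annotated genes.
#' @param background character vector: the gene universe.
#' @param alpha family-wise significance threshold on corrected p
#'   (default 0.01).
#' @param method `"bonferroni"` (default) or `"BH"`
#'   (Benjamini-Hochberg via [stats::p.adjust()]).
#' @param ease if `TRUE`, apply the EASE-style conservative variant that
#'   decrements the observed overlap by one before taking the tail
#'   (off by default).
#' @return data.frame, one row per tested term, sorted by raw p ascending:
#'   columns `label`, `k`, `K`, `n`, `N`, `log10_p`, `p_raw`, `p_corrected`,
#'   `significant`, `genes` (semicolon-joined overlap).
#' @export
term_enrichment <- function(query, annotation, background, alpha = 0.01,
                            method = c("bonferroni", "BH"), ease = FALSE) {
  method <- match.arg(method)
  query <- unique(query)
  if (length(query) == 0L) stop("query gene set is empty", call. = FALSE)
  background <- unique(background)
  if (!all(query %in% background)) {
    stop(sprintf("query genes outside background: %s",
                 paste(utils::head(setdiff(query, background), 5L),
                       collapse = ", ")), call. = FALSE)
  }
  if (length(annotation) == 0L) {
    return(data.frame(label = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), log10_p = numeric(0),
                      p_raw = numeric(0), p_corrected = numeric(0),
                      significant = logical(0), genes = character(0),
                      stringsAsFactors = FALSE))
  }
  N <- length(background)
  ann <- lapply(annotation, function(g) unique(g))
  dropped <- sum(vapply(ann, function(g) sum(!(g %in% background)), 0L))
  if (dropped > 0L) {
    message(sprintf("term_enrichment: dropped %d annotated gene record(s) outside the background",
                    dropped))
    ann <- lapply(ann, function(g) g[g %in% background])
  }
  ov <- lapply(ann, function(g) intersect(query, g))
  tested <- vapply(ov, length, 0L) >= 1L
  m <- sum(tested)
  if (m == 0L) {
    return(term_enrichment(query, list(), background, alpha, method))
  }
  labels <- names(ann)[tested]
  rows <- lapply(which(tested), function(i) {
    k <- length(ov[[i]]); n <- length(ann[[i]])
    k_eff <- if (ease) max(k - 1L, 0L) else k
    lp <- hypergeom_tail(k_eff, length(query), n, N)
    data.frame(label = names(ann)[i], k = k, K = length(query), n = n, N = N,
               log10_p = lp, p_raw = log10p_to_p(lp),
               genes = paste(sort(ov[[i]]), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_corrected <- if (method == "bonferroni") {
    bonferroni(res$p_raw, m)
  } else {
    stats::p.adjust(res$p_raw, method = "BH")
  }
  res$significant <- res$p_corrected < alpha
  res <- res[order(res$p_raw, res$label),
             c("label", "k", "K", "n", "N", "log10_p", "p_raw",
               "p_corrected", "significant", "genes")]
  rownames(res) <- NULL
  res
}

#' Sensitivity of an overlap p-value to the background size
#'
#' Literature knowledge bases rarely state their gene universe; this maps
#' the assumption space by recomputing the overlap tail over a grid of
#' background sizes. For a fixed positive overlap the log10 p decreases
#' strictly as the background grows.
#'
#' @param query,reference gene sets as in [overlap_overrepresentation()].
#' @param N_grid integer vector of background sizes, each at least the union
#'   size.
#' @return data.frame with columns `N`, `log10_p`.
#' @export
background_sensitivity <- function(query, reference, N_grid) {
  query <- unique(query); reference <- unique(reference)
  u <- length(union(query, reference))
  if (any(N_grid < u)) {
    stop(sprintf("domain error: background N=%d smaller than union size %d",
                 min(N_grid), u), call. = FALSE)
  }
  k <- length(intersect(query, reference))
  data.frame(N = as.integer(N_grid),
             log10_p = vapply(N_grid, function(N)
               hypergeom_tail(k, length(query), length(reference), N),
               numeric(1)))
}

#' Write an enrichment result table as TSV
#' @param res data.frame from [term_enrichment()] or rows assembled from
#'   [overlap_overrepresentation()] results.
#' @param path output path.
#' @export
write_enrichment <- function(res, path) {
  write_tsv_plain(res, path)
  invisible(path)
}
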