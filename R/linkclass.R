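LINK_CLASSES <- c("UP", "DOWN", "CAUSAL", "PROTECTIVE", "SNP_RISK", "OTHER")

#' Default relation-type rulemap for gene-condition link classification
#'
#' Maps a stored relation label plus its direction relative to the condition
#' to one of the six curated link-pattern classes: expression up- or
#' down-regulated by the condition, condition-inducing (causal) molecules,
#' protective/counterregulatory molecules, SNP risk associations, and other
#' links. Direction is `"condition_to_gene"` or `"gene_to_condition"`.
#'
#' @return data.frame with columns `rtype`, `direction`, `class`.
#' @export
default_rulemap <- function() {
  data.frame(
    rtype = c("UPREGULATES", "DOWNREGULATES", "CAUSES",
              "PROTECTS_AGAINST", "SNP_RISK"),
    direction = c("condition_to_gene", "condition_to_gene",
                  "gene_to_condition", "gene_to_condition",
                  "gene_to_condition"),
    class = c("UP", "DOWN", "CAUSAL", "PROTECTIVE", "SNP_RISK"),
    stringsAsFactors = FALSE)
}

#' Read a rulemap from TSV
#' @param path TSV with columns `rtype`, `direction`, `class`.
#' @return rulemap data.frame.
#' @export
read_rulemap <- function(path) {
  df <- read_tsv_strict(path, c("rtype", "direction", "class"), "rulemap")
  bad <- setdiff(unique(df$class), LINK_CLASSES)
  if (length(bad) > 0L) {
    stop("rulemap contains unknown class(es): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}

new_link_classification <- function(condition_id, assignment) {
  assignment <- assignment[order(names(assignment))]
  structure(list(condition_id = condition_id, assignment = assignment),
            class = "link_classification")
}

#' Build a classification from per-class gene lists
#'
#' Convenience constructor for externally curated classifications (for
#' example the packaged table transcriptions): takes a named list mapping
#' class to gene vector and inverts it into the per-gene multi-label
#' assignment.
#'
#' @param class_sets named list; names must be among
#'   UP, DOWN, CAUSAL, PROTECTIVE, SNP_RISK, OTHER.
#' @param condition_id label carried on the object.
#' @return `link_classification`.
#' @export
as_link_classification <- function(class_sets, condition_id = "condition") {
  bad <- setdiff(names(class_sets), LINK_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  genes <- sort(unique(unlist(class_sets, use.names = FALSE)))
  assignment <- lapply(genes, function(g) {
    cls <- names(class_sets)[vapply(class_sets, function(s) g %in% s,
                                    logical(1))]
    intersect(LINK_CLASSES, cls)  # fixed class order
  })
  names(assignment) <- genes
  new_link_classification(condition_id, assignment)
}

#' Classify a condition's gene links by relation-type rules
#'
#' Replaces manual curation of gene-condition link patterns with a
#' declarative rulemap: each stored gene-condition interaction is matched on
#' its relation label and direction; matched classes accumulate per gene
#' (multi-label: a gene reported both up- and down-regulated keeps both
#' classes). Genes none of whose condition links match any rule (e.g. plain
#' ASSOCIATION or PPI records) fall into `OTHER`; `OTHER` is never combined
#' with a substantive class. Relation labels absent from the rulemap are
#' reported via `message` once per label.
#'
#' @param kb `knowledge_base`.
#' @param condition_id condition entity id.
#' @param rulemap data.frame as from [default_rulemap()].
#' @return `link_classification`: `condition_id` plus `assignment`, a named
#'   list gene -> character vector of classes.
#' @export
classify_condition_links <- function(kb, condition_id,
                                     rulemap = default_rulemap()) {
  net <- extract_condition_network(kb, condition_id)
  ent <- kb$entities
  id2sym <- stats::setNames(ent$name, ent$id)
  e <- kb$interactions
  cond_e <- e[(e$source == condition_id & e$target %in% net$member_ids) |
              (e$target == condition_id & e$source %in% net$member_ids), ,
              drop = FALSE]
  gene_id <- ifelse(cond_e$source == condition_id, cond_e$target,
                    cond_e$source)
  direction <- ifelse(cond_e$source == condition_id,
                      "condition_to_gene", "gene_to_condition")
  key <- paste(cond_e$rtype, direction)
  rk <- paste(rulemap$rtype, rulemap$direction)
  cls <- rulemap$class[match(key, rk)]
  unmatched <- unique(cond_e$rtype[is.na(cls)])
  if (length(unmatched) > 0L) {
    message("classify_condition_links: relation label(s) not in rulemap, contributing OTHER: ",
            paste(sort(unmatched), collapse = ", "))
  }
  assignment <- lapply(net$member_ids, function(gid) {
    got <- unique(cls[gene_id == gid & !is.na(cls)])
    if (length(got) == 0L) "OTHER" else intersect(LINK_CLASSES, got)
  })
  names(assignment) <- unname(id2sym[net$member_ids])
  new_link_classification(condition_id, assignment)
}

#' @export
print.link_classification <- function(x, ...) {
  cat(sprintf("link_classification '%s': %d genes\n", x$condition_id,
              length(x$assignment)))
  cc <- class_counts(x)
  cat(paste(sprintf("  %s: %d", names(cc), cc), collapse = "\n"), "\n")
  invisible(x)
}

#' Per-class gene counts of a classification
#'
#' Multi-label counting: a gene carrying two classes counts once in each.
#'
#' @param cls `link_classification`.
#' @return named integer vector over the six classes in fixed order.
#' @export
class_counts <- function(cls) {
  stopifnot(inherits(cls, "link_classification"))
  lab <- unlist(cls$assignment, use.names = FALSE)
  tab <- table(factor(lab, levels = LINK_CLASSES))
  stats::setNames(as.integer(tab), LINK_CLASSES)
}

#' Class membership of a classification
#' @param cls `link_classification`.
#' @param class one of the six class labels.
#' @return sorted character vector of genes carrying the class.
#' @export
class_members <- function(cls, class) {
  class <- match.arg(class, LINK_CLASSES)
  sort(names(cls$assignment)[vapply(cls$assignment,
                                    function(a) class %in% a, logical(1))])
}

#' Cross-classification of two conditions' link patterns
#'
#' For the genes present in both classifications, builds the contingency
#' table whose cell (i, j) holds the genes carrying class i for condition A
#' and class j for condition B; multi-label genes appear in several cells.
#'
#' @param clsA,clsB `link_classification` objects.
#' @return object of class `cross_table`: `row_condition`, `col_condition`,
#'   `classes`, and `cells`, a named list `"ROW|COL"` -> gene vector.
#' @export
cross_classification <- function(clsA, clsB) {
  shared <- intersect(names(clsA$assignment), names(clsB$assignment))
  cells <- list()
  for (ra in LINK_CLASSES) for (cb in LINK_CLASSES) {
    g <- shared[vapply(shared, function(x)
      ra %in% clsA$assignment[[x]] && cb %in% clsB$assignment[[x]],
      logical(1))]
    cells[[paste(ra, cb, sep = "|")]] <- sort(g)
  }
  structure(list(row_condition = clsA$condition_id,
                 col_condition = clsB$condition_id,
                 classes = LINK_CLASSES, cells = cells),
            class = "cross_table")
}

#' Decompose a cross-classification table into its two classifications
#'
#' Inverse of [cross_classification()]: recovers the per-gene row-condition
#' and column-condition class assignments from the cell memberships. The
#' recomposition `cross_classification(row, col)` reproduces the original
#' table exactly whenever each gene's cell memberships form the full
#' rectangle of its row and column classes (true of any table produced by
#' [cross_classification()]).
#'
#' @param ct `cross_table`.
#' @return list with `link_classification` elements `row` and `col`.
#' @export
cross_table_classifications <- function(ct) {
  genes <- sort(unique(unlist(ct$cells, use.names = FALSE)))
  parts <- strsplit(names(ct$cells), "|", fixed = TRUE)
  rows <- vapply(parts, `[`, "", 1L)
  cols <- vapply(parts, `[`, "", 2L)
  pick <- function(labels) {
    a <- lapply(genes, function(g) {
      got <- unique(labels[vapply(ct$cells, function(cell) g %in% cell,
                                  logical(1))])
      intersect(LINK_CLASSES, got)
    })
    names(a) <- genes
    a
  }
  list(row = new_link_classification(ct$row_condition, pick(rows)),
       col = new_link_classification(ct$col_condition, pick(cols)))
}

#' Extract one cell of a cross-classification table
#' @param ct `cross_table`.
#' @param row_class,col_class class labels.
#' @return sorted character vector of genes.
#' @export
cross_cell <- function(ct, row_class, col_class) {
  row_class <- match.arg(row_class, LINK_CLASSES)
  col_class <- match.arg(col_class, LINK_CLASSES)
  ct$cells[[paste(row_class, col_class, sep = "|")]] %||% character(0)
}

#' @export
print.cross_table <- function(x, ...) {
  sizes <- matrix(vapply(x$cells, length, 0L), nrow = length(x$classes),
                  byrow = TRUE, dimnames = list(x$classes, x$classes))
  cat(sprintf("cross_table %s x %s (cell sizes):\n", x$row_condition,
              x$col_condition))
  print(sizes)
  invisible(x)
}

#' Write a classification as TSV
#' @param cls `link_classification`.
#' @param path output path.
#' @export
write_classification <- function(cls, path) {
  df <- data.frame(gene = names(cls$assignment),
                   classes = vapply(cls$assignment, paste, "",
                                    collapse = ","),
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
  invisible(path)
}

#' Write a cross-classification table as TSV
#' @param ct `cross_table`.
#' @param path output path.
#' @export
write_cross_table <- function(ct, path) {
  parts <- strsplit(names(ct$cells), "|", fixed = TRUE)
  df <- data.frame(row_class = vapply(parts, `[`, "", 1L),
                   col_class = vapply(parts, `[`, "", 2L),
                   n = vapply(ct$cells, length, 0L),
                   genes = vapply(ct$cells, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
  invisible(path)
}
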