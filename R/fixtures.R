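fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "condnet")
  if (!nzchar(p)) stop("packaged fixture file missing: ", file, call. = FALSE)
  p
}

FIXTURE_REGISTRY <- c(
  table1 = "the ten molecule-category gene sets of the focus network",
  table2 = "the six link-pattern class gene sets of the focus condition",
  table5 = "the 4x4 cross-classification cells against the comparator condition",
  mutual14 = "the 14 genes mutual to all five compared networks",
  endothelial = "the microvascular-endothelium genes present in the focus network",
  top_cts10 = "the ten genes with the highest cross-talk specificity",
  hubs = "the seven junction genes with the highest connectivity/betweenness",
  aliases = "the packaged alias table")

#' Load a packaged fixture
#'
#' Machine-readable transcriptions of the published hypoglycemia-network
#' tables and in-text gene lists, normalized through the packaged alias
#' table. Registry names: `table1` (named list of 10 category sets),
#' `table2` (named list of 6 link-class sets), `table5` (`cross_table` of
#' the hypoglycemia-by-Alzheimer link classes), `mutual14`, `endothelial`,
#' `top_cts10`, `hubs` (character vectors), `aliases` (named vector).
#'
#' @param name registry name.
#' @return the transcribed, normalized object.
#' @export
load_fixture <- function(name) {
  if (!(name %in% names(FIXTURE_REGISTRY))) {
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(FIXTURE_REGISTRY), collapse = ", ")),
         call. = FALSE)
  }
  al <- read_alias_table(fixture_path("aliases.tsv"))
  switch(name,
    aliases = al,
    table1 = read_gmt(fixture_path("table1_categories.gmt"), al),
    table2 = read_gmt(fixture_path("table2_link_classes.gmt"), al),
    table5 = load_table5(al),
    {
      lists <- read_gmt(fixture_path("reported_lists.gmt"), al)
      key <- c(mutual14 = "mutual14", endothelial = "endothelial_in_network",
               top_cts10 = "top_cts10", hubs = "hub_genes")[[name]]
      lists[[key]]
    })
}

load_table5 <- function(aliases) {
  df <- read_tsv_strict(fixture_path("table5_cells.tsv"),
                        c("row_class", "col_class", "genes"),
                        "cross-table fixture")
  cells <- list()
  for (ra in LINK_CLASSES) for (cb in LINK_CLASSES) {
    cells[[paste(ra, cb, sep = "|")]] <- character(0)
  }
  for (i in seq_len(nrow(df))) {
    g <- df$genes[i]
    g <- if (is.na(g) || !nzchar(trimws(g))) character(0) else
      normalize_symbol(strsplit(g, ";", fixed = TRUE)[[1L]], aliases)
    cells[[paste(df$row_class[i], df$col_class[i], sep = "|")]] <- sort(g)
  }
  structure(list(row_condition = "hypoglycemia",
                 col_condition = "alzheimer_disease",
                 classes = LINK_CLASSES, cells = cells),
            class = "cross_table")
}

#' Verify the packaged fixtures' internal consistency
#'
#' Checks the transcription invariants that tie the fixtures together:
#' the ten category sets have the printed sizes and their union the printed
#' network size (one symbol appears in two categories); every link-class
#' gene, mutual gene, endothelial gene, top-CTS gene and hub gene belongs
#' to the network union after alias normalization. Violations are report
#' content, not errors, so a transcription bug is pinpointed rather than
#' thrown.
#'
#' @param bundle optional named list overriding loaded fixtures (used to
#'   test the verifier itself); any of `table1`, `table2`, `mutual14`,
#'   `endothelial`, `top_cts10`, `hubs`, `table5`.
#' @return list with elements `ok` (logical) and `violations`
#'   (character vector, empty when consistent).
#' @export
verify_fixture_invariants <- function(bundle = list()) {
  fx <- function(name) bundle[[name]] %||% load_fixture(name)
  v <- character(0)
  t1 <- fx("table1")
  expected_sizes <- c(Hormones = 14L, Cytokines_and_growth_factors = 12L,
                      Receptors = 19L, Enzymes = 38L, Transporters = 19L,
                      Transcription_factors = 12L, Neuropeptides = 7L,
                      Structural_proteins = 2L, Other_proteins = 17L,
                      MicroRNAs = 2L)
  for (nm in names(expected_sizes)) {
    got <- length(t1[[nm]] %||% character(0))
    if (got != expected_sizes[[nm]]) {
      v <- c(v, sprintf("category %s has %d genes, expected %d", nm, got,
                        expected_sizes[[nm]]))
    }
  }
  univ <- sort(unique(unlist(t1, use.names = FALSE)))
  if (length(univ) != sum(expected_sizes) - 1L) {
    v <- c(v, sprintf("network union has %d genes, expected %d (one cross-category duplicate)",
                      length(univ), sum(expected_sizes) - 1L))
  }
  dup <- unlist(t1, use.names = FALSE)
  dup <- unique(dup[duplicated(dup)])
  if (!identical(dup, "NR3C1")) {
    v <- c(v, sprintf("cross-category duplicate(s) [%s], expected exactly NR3C1",
                      paste(dup, collapse = ", ")))
  }
  check_subset <- function(set, label) {
    out <- setdiff(set, univ)
    if (length(out) > 0L) {
      sprintf("%s gene(s) outside the network union: %s", label,
              paste(out, collapse = ", "))
    } else character(0)
  }
  t2 <- fx("table2")
  v <- c(v, check_subset(unlist(t2, use.names = FALSE), "link-class"))
  v <- c(v, check_subset(fx("mutual14"), "mutual-core"))
  if (length(fx("mutual14")) != 14L) {
    v <- c(v, sprintf("mutual core has %d genes, expected 14",
                      length(fx("mutual14"))))
  }
  v <- c(v, check_subset(fx("endothelial"), "endothelial"))
  v <- c(v, check_subset(fx("top_cts10"), "top-CTS"))
  v <- c(v, check_subset(fx("hubs"), "hub"))
  t5 <- if (!is.null(bundle$table5)) bundle$table5 else load_fixture("table5")
  v <- c(v, check_subset(unlist(t5$cells, use.names = FALSE),
                         "cross-table"))
  list(ok = length(v) == 0L, violations = v)
}
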