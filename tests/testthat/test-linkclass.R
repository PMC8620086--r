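test_that("relation-type rules assign the documented classes, multi-label included", {
  e <- data.frame(
    source = c("cond1", "cond1", "cond1", "g2", "g3"),
    target = c("g1", "g2", "g2", "cond1", "cond1"),
    rtype = c("UPREGULATES", "UPREGULATES", "DOWNREGULATES", "CAUSES",
              "ASSOCIATION"),
    pmids = "")
  kb <- toy_kb(e)
  cls <- classify_condition_links(kb, "cond1")
  expect_equal(cls$assignment$g1, "UP")
  expect_equal(cls$assignment$g2, c("UP", "DOWN", "CAUSAL"))
  expect_equal(cls$assignment$g3, "OTHER")
})

test_that("unmapped relation labels are logged and contribute OTHER only as fallback", {
  e <- data.frame(source = c("g1", "cond1", "g2"),
                  target = c("cond1", "g1", "cond1"),
                  rtype = c("WEIRD_LINK", "UPREGULATES", "PPI"),
                  pmids = "")
  kb <- toy_kb(e)
  expect_message(cls <- classify_condition_links(kb, "cond1"),
                 "WEIRD_LINK")
  # g1 has a substantive class, so its unmapped link does not add OTHER
  expect_equal(cls$assignment$g1, "UP")
  expect_equal(cls$assignment$g2, "OTHER")
})

test_that("every member gets a class and OTHER never coexists with a substantive class", {
  b <- generate_synthetic_bundle(synthetic_spec(
    n_genes = 150, m = 2, n_conditions = 2, module_sizes = c(40, 30),
    core_size = 5, focus_overlaps = 10, n_terms = 3, seed = 9))
  suppressMessages(cls <- classify_condition_links(b$kb, "COND1"))
  net <- extract_condition_network(b$kb, "COND1")
  expect_setequal(names(cls$assignment), net$members)
  expect_true(all(lengths(cls$assignment) >= 1))
  has_other <- vapply(cls$assignment, function(a) "OTHER" %in% a, logical(1))
  expect_true(all(lengths(cls$assignment)[has_other] == 1))
})

test_that("classification is invariant to edge input order", {
  e <- data.frame(
    source = c("cond1", "g2", "cond1", "g3"),
    target = c("g1", "cond1", "g2", "cond1"),
    rtype = c("UPREGULATES", "PROTECTS_AGAINST", "DOWNREGULATES",
              "SNP_RISK"),
    pmids = "")
  kb1 <- toy_kb(e)
  kb2 <- toy_kb(e[rev(seq_len(nrow(e))), ])
  expect_identical(classify_condition_links(kb1, "cond1")$assignment,
                   classify_condition_links(kb2, "cond1")$assignment)
})

test_that("class counts use multi-membership semantics", {
  cls <- as_link_classification(list(UP = c("g1", "g2"), DOWN = "g2"))
  cc <- class_counts(cls)
  expect_equal(unname(cc["UP"]), 2L)
  expect_equal(unname(cc["DOWN"]), 1L)
  expect_equal(sum(cc), 3L)
  expect_length(cls$assignment, 2L)

  empty <- as_link_classification(list(UP = character(0)))
  expect_equal(sum(class_counts(empty)), 0L)

  expect_error(as_link_classification(list(BOGUS = "g1")), "unknown class")
})

test_that("round-trip: a knowledge base synthesized from an assignment classifies back to it", {
  set.seed(21)
  for (rep in 1:10) {
    genes <- sprintf("g%02d", 1:12)
    assignment <- lapply(genes, function(g)
      sort(sample(c("UP", "DOWN", "CAUSAL", "PROTECTIVE", "SNP_RISK"),
                  sample(1:2, 1))))
    names(assignment) <- genes
    # a few pure-OTHER genes
    assignment[["g13"]] <- "OTHER"
    kb <- kb_from_class_assignment(assignment, "COND1")
    suppressMessages(got <- classify_condition_links(kb, "COND1")$assignment)
    want <- lapply(assignment, function(a) intersect(
      c("UP", "DOWN", "CAUSAL", "PROTECTIVE", "SNP_RISK", "OTHER"), a))
    expect_identical(got[names(want)], want)
  }
})

test_that("cross-classification restricts to shared genes and respects multi-labels", {
  a <- as_link_classification(list(UP = c("g1", "g2"), DOWN = "g2"),
                              "condA")
  b <- as_link_classification(list(UP = "g1", SNP_RISK = c("g2", "g9")),
                              "condB")
  ct <- cross_classification(a, b)
  expect_equal(cross_cell(ct, "UP", "UP"), "g1")
  expect_equal(cross_cell(ct, "UP", "SNP_RISK"), "g2")
  expect_equal(cross_cell(ct, "DOWN", "SNP_RISK"), "g2")
  expect_length(cross_cell(ct, "DOWN", "UP"), 0)

  disjoint <- cross_classification(
    as_link_classification(list(UP = "x")),
    as_link_classification(list(UP = "y")))
  expect_true(all(lengths(disjoint$cells) == 0))
})

test_that("decomposing and recomposing the transcribed cross-table reproduces every printed cell", {
  t5 <- load_fixture("table5")
  cls <- cross_table_classifications(t5)
  expect_s3_class(cls$row, "link_classification")
  # VEGFA is the transcription's only multi-row gene: up- and down-regulated
  # on both sides
  expect_equal(cls$row$assignment$VEGFA, c("UP", "DOWN"))
  expect_equal(cls$col$assignment$VEGFA, c("UP", "DOWN"))
  recomposed <- cross_classification(cls$row, cls$col)
  expect_equal(recomposed$cells, t5$cells)
})
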