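test_that("condition-network extraction keeps exactly the condition-linked genes", {
  kb <- toy_kb(data.frame(source = c("cond1", "cond1", "g1", "g2"),
                          target = c("g1", "g2", "g2", "g3"),
                          rtype = "ASSOCIATION", pmids = ""))
  net <- extract_condition_network(kb, "cond1")
  expect_setequal(net$members, c("g1", "g2"))
  expect_equal(nrow(net$gene_gene_edges), 1)
  expect_false("g3" %in% net$members)

  kb1 <- toy_kb(data.frame(source = "cond1", target = "g1",
                           rtype = "CAUSES", pmids = ""))
  net1 <- extract_condition_network(kb1, "cond1")
  expect_equal(net1$members, "g1")
  expect_equal(nrow(net1$gene_gene_edges), 0)

  expect_error(extract_condition_network(kb, "nope"), "unknown condition")
  expect_error(extract_condition_network(kb, "g1"), "not condition")

  kb_empty <- toy_kb(data.frame(source = "g1", target = "g2",
                                rtype = "PPI", pmids = ""),
                     extra_nodes = "cond9")
  expect_warning(net0 <- extract_condition_network(kb_empty, "cond9"),
                 "no linked genes")
  expect_true(net0$empty)
  expect_length(net0$members, 0)
})

make_net <- function(edges, members = NULL) {
  members <- members %||% unique(c(edges$from, edges$to))
  kb <- toy_condition_kb(members,
                         data.frame(source = edges$from, target = edges$to))
  extract_condition_network(kb, "cond1")
}

test_that("betweenness matches hand-derived values on canonical small graphs", {
  path3 <- make_net(data.frame(from = c("A", "B"), to = c("B", "C")))
  b <- betweenness_centrality(path3)
  expect_equal(unname(b[c("A", "B", "C")]), c(0, 1, 0))

  star <- make_net(data.frame(from = "ctr", to = c("L1", "L2", "L3", "L4")))
  b <- betweenness_centrality(star)
  expect_equal(unname(b["ctr"]), 6)  # C(4,2) leaf pairs
  expect_equal(unname(b[c("L1", "L2", "L3", "L4")]), rep(0, 4))

  # 4-cycle: each pair of opposite vertices has two equal shortest paths,
  # each crediting its single intermediate 1/2 (value frozen from the
  # brute-force path-enumeration oracle)
  cyc <- make_net(data.frame(from = c("A", "B", "C", "D"),
                             to = c("B", "C", "D", "A")))
  b <- betweenness_centrality(cyc)
  expect_equal(unname(b[c("A", "B", "C", "D")]), rep(0.5, 4))
  nodes <- c("A", "B", "C", "D")
  oracle <- brute_betweenness(nodes, data.frame(
    from = c("A", "B", "C", "D"), to = c("B", "C", "D", "A")))
  expect_equal(b[nodes], oracle[nodes])
})

test_that("betweenness agrees with the brute-force oracle on random graphs, including credit conservation", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(3:8, 1)
    edges <- random_edges(n, p = stats::runif(1, 0.25, 0.8))
    nodes <- LETTERS[seq_len(n)]
    net <- make_net(edges, members = nodes)
    b <- betweenness_centrality(net)
    oracle <- brute_betweenness(nodes, edges)
    expect_equal(b[nodes], oracle[nodes], tolerance = 1e-12)
    expect_equal(sum(b), brute_total_credit(nodes, edges), tolerance = 1e-12)
  }
})

test_that("cross-talk specificity counts links inside the network against all global links", {
  # g1's links all inside (to g2 and the condition) -> CTS 1;
  # g2 additionally touches outside genes o1..o3
  e <- data.frame(
    source = c("g1", "g2", "cond1", "cond1", "g2", "g2", "g2"),
    target = c("g2", "g1", "g1", "g2", "o1", "o2", "o3"),
    rtype = "ASSOCIATION", pmids = "")
  kb <- toy_kb(e)
  net <- extract_condition_network(kb, "cond1")
  cts <- cross_talk_specificity(net, kb)
  g1 <- cts[cts$gene == "g1", ]
  g2 <- cts[cts$gene == "g2", ]
  expect_equal(g1$K, 3)  # two parallel g1-g2 links + condition link
  expect_equal(g1$M, 3)
  expect_equal(g1$CTS, 1.0)
  expect_equal(g2$K, 3)
  expect_equal(g2$M, 6)
  expect_equal(g2$CTS, 0.5)
  expect_equal(g1$neighbor_degree, 1)  # parallel links, one neighbor

  # direct formula case: K=4, M=10 -> 0.4
  e2 <- data.frame(
    source = c(rep("g1", 3), "cond1", rep("g1", 6)),
    target = c(rep("g2", 3), "g1", paste0("o", 1:6)),
    rtype = "PPI", pmids = "")
  e2 <- rbind(e2, data.frame(source = "cond1", target = "g2",
                             rtype = "PPI", pmids = ""))
  kb2 <- toy_kb(e2)
  cts2 <- cross_talk_specificity(extract_condition_network(kb2, "cond1"), kb2)
  expect_equal(cts2$CTS[cts2$gene == "g1"], 0.4)
})

test_that("CTS lies in (0,1] and is invariant under whole-KB duplication", {
  b <- generate_synthetic_bundle(synthetic_spec(
    n_genes = 120, m = 2, n_conditions = 2, module_sizes = c(25, 30),
    core_size = 4, focus_overlaps = 8, n_terms = 5, seed = 3))
  kb <- b$kb
  net <- extract_condition_network(kb, "COND1")
  cts <- cross_talk_specificity(net, kb)
  expect_true(all(cts$CTS > 0 & cts$CTS <= 1))
  expect_true(all(cts$K <= cts$M))

  kb2 <- knowledge_base(kb$entities, rbind(kb$interactions, kb$interactions))
  cts2 <- cross_talk_specificity(extract_condition_network(kb2, "COND1"), kb2)
  expect_equal(cts2$CTS, cts$CTS)
  expect_equal(cts2$K, 2L * cts$K)
})

test_that("extract -> metrics pipeline is deterministic", {
  b <- generate_synthetic_bundle(synthetic_spec(
    n_genes = 100, m = 2, n_conditions = 1, module_sizes = 20,
    core_size = 0, focus_overlaps = NULL, n_terms = 3, seed = 5))
  m1 <- node_metrics(extract_condition_network(b$kb, "COND1"), b$kb)
  m2 <- node_metrics(extract_condition_network(b$kb, "COND1"), b$kb)
  expect_identical(m1, m2)
})

test_that("rank_nodes sorts descending with lexicographic tie-breaks", {
  m <- data.frame(gene = c("A", "B"), K = c(3, 5), betweenness = c(1, 1),
                  CTS = c(0.2, 0.2))
  expect_equal(rank_nodes(m, "K", 1), "B")
  expect_equal(rank_nodes(m, "CTS", 2), c("A", "B"))
  expect_equal(rank_nodes(m, "K", 10), c("B", "A"))
  expect_error(rank_nodes(m[0, ], "K", 1), "empty")
})

test_that("a planted dominant hub ranks first by connectivity and betweenness", {
  # star of 50 leaves plus a sparse ring among leaves keeps every other
  # node at degree <= 5
  leaves <- sprintf("L%02d", 1:50)
  edges <- data.frame(from = "HUB", to = leaves)
  ring <- data.frame(from = leaves, to = c(leaves[-1], leaves[1]))
  net <- make_net(rbind(edges, ring))
  m <- node_metrics(net, toy_condition_kb(
    c("HUB", leaves), data.frame(source = c(edges$from, ring$from),
                                 target = c(edges$to, ring$to))))
  expect_equal(rank_nodes(m, "K", 1), "HUB")
  expect_equal(rank_nodes(m, "B", 1), "HUB")
})
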