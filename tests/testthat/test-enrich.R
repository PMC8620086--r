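test_that("hypergeometric tail matches enumeration-derived values on small cases", {
  expect_equal(hypergeom_tail(0, 5, 4, 10), 0)           # whole support
  expect_equal(10^hypergeom_tail(3, 5, 4, 10), 55 / 210) # enumeration: 210 draws, 55 with >= 3 marked
  expect_equal(10^hypergeom_tail(5, 5, 5, 100), 1 / choose(100, 5))
  # forced overlap: drawing all N items makes k = K certain
  expect_equal(hypergeom_tail(5, 5, 10, 10), 0)

  expect_error(hypergeom_tail(6, 5, 10, 20), "k <= min")
  expect_error(hypergeom_tail(1, 25, 10, 20), "K <= N")
  expect_error(hypergeom_tail(1, 5, 30, 20), "n <= N")
  expect_error(hypergeom_tail(-1, 5, 10, 20), "k >= 0")
})

test_that("hypergeometric tail agrees with exhaustive draw enumeration and with phyper", {
  set.seed(7)
  for (rep in 1:40) {
    N <- sample(2:12, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    p_pkg <- 10^hypergeom_tail(k, K, n, N)
    p_enum <- enum_hypergeom_tail(k, K, n, N)
    expect_equal(p_pkg, p_enum, tolerance = 1e-10)
  }
  for (rep in 1:40) {
    N <- sample(50:5000, 1); K <- sample(1:(N %/% 2), 1)
    n <- sample(1:(N %/% 2), 1); k <- sample(0:min(K, n), 1)
    got <- hypergeom_tail(k, K, n, N)
    ref <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                         log.p = TRUE) / log(10)
    expect_lt(abs(got - ref), 1e-9 * max(1, abs(ref)))
  }
})

test_that("tail probability is monotone in k and symmetric in K and n", {
  for (par in list(c(8, 5, 12), c(50, 30, 100), c(141, 494, 20000))) {
    K <- par[1]; n <- par[2]; N <- par[3]
    tails <- vapply(0:min(K, n), hypergeom_tail, numeric(1),
                    K = K, n = n, N = N)
    expect_true(all(diff(tails) <= 1e-12))
    for (k in c(0, 1, min(K, n) %/% 2, min(K, n))) {
      expect_equal(hypergeom_tail(k, K, n, N), hypergeom_tail(k, n, K, N),
                   tolerance = 1e-10)
    }
  }
})

test_that("log-space evaluation stays finite far below double underflow", {
  lp <- hypergeom_tail(141, 141, 141, 20000)
  expect_true(is.finite(lp))
  expect_lt(lp, -300)
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.004, 10), 0.04)
  expect_equal(bonferroni(0.5, 3), 1.0)
  expect_equal(bonferroni(1e-20, 100), 1e-18)
  expect_equal(bonferroni(c(0.01, 0.2), 5), c(0.05, 1.0))
  expect_error(bonferroni(0, 3), "domain error")
  expect_error(bonferroni(1.2, 3), "domain error")
  expect_error(bonferroni(c(0.1, 0.2), 1), "m must be")
})

test_that("overlap overrepresentation covers degenerate and forced cases", {
  r0 <- overlap_overrepresentation(c("A", "B"), c("C", "D"), 100)
  expect_equal(r0$k, 0)
  expect_equal(r0$p_raw, 1)

  # query inside reference with the background equal to the reference:
  # every draw is maximal, so the tail is the whole support
  r1 <- overlap_overrepresentation(c("A", "B"), LETTERS[1:10], 10)
  expect_equal(r1$k, 2)
  expect_equal(r1$p_raw, 1)

  expect_error(overlap_overrepresentation(LETTERS[1:5], LETTERS[3:8], 7),
               "smaller than union")
  r2 <- overlap_overrepresentation(LETTERS[1:5], LETTERS[3:8], 26)
  expect_equal(r2$genes, c("C", "D", "E"))
})

test_that("term enrichment applies the tested-terms convention and ranks the planted term first", {
  # one term identical to the query over a background equal to the query
  r <- term_enrichment(c("A", "B"), list(T1 = c("A", "B")),
                       background = c("A", "B"))
  expect_equal(r$p_raw, 1)

  # second term without query genes is not tested (m = 1)
  r2 <- term_enrichment(c("A", "B"), list(T1 = c("A", "B"), T2 = c("C")),
                        background = c("A", "B", "C"))
  expect_equal(nrow(r2), 1)
  expect_equal(r2$label, "T1")

  # planted term: 20/20 query genes inside a 25-gene term, background 1000
  bg <- sprintf("G%04d", 1:1000)
  query <- bg[1:20]
  ann <- list(PLANTED = c(query, bg[900:904]),
              NOISE1 = bg[10:60], NOISE2 = bg[500:540])
  r3 <- term_enrichment(query, ann, bg, alpha = 0.01)
  expect_equal(r3$label[1], "PLANTED")
  expect_true(r3$significant[1])
  expect_equal(r3$k[1], 20)
  # cross-check the planted p against the survival-function route
  expect_equal(r3$log10_p[1],
               stats::phyper(19, 20, 980, 25, lower.tail = FALSE,
                             log.p = TRUE) / log(10), tolerance = 1e-9)

  expect_error(term_enrichment(character(0), ann, bg), "empty")
  expect_equal(nrow(term_enrichment(query, list(), bg)), 0)
  expect_error(term_enrichment(c("ZZZ"), ann, bg), "outside background")
})

test_that("EASE variant is more conservative and BH is available", {
  bg <- sprintf("G%03d", 1:200)
  query <- bg[1:15]
  ann <- list(T1 = bg[1:30], T2 = bg[10:80], T3 = bg[100:150])
  plain <- term_enrichment(query, ann, bg)
  ease <- term_enrichment(query, ann, bg, ease = TRUE)
  expect_true(all(ease$p_raw[match(plain$label, ease$label)] >= plain$p_raw))
  bh <- term_enrichment(query, ann, bg, method = "BH")
  expect_equal(bh$p_corrected,
               stats::p.adjust(bh$p_raw, "BH"))
})

test_that("overlap p-values sharpen monotonically as the background grows", {
  expect_equal(background_sensitivity(c("A"), c("B"), c(10, 100))$log10_p,
               c(0, 0))
  bs <- background_sensitivity(LETTERS[1:5], LETTERS[4:8], c(20, 200))
  expect_lt(bs$log10_p[2], bs$log10_p[1])
  # k=2, K=5, n=5: enumeration oracle at both backgrounds
  expect_equal(10^bs$log10_p[1], enum_hypergeom_tail(2, 5, 5, 20),
               tolerance = 1e-12)

  t1 <- unique(unlist(load_fixture("table1")))
  grid <- c(1000, 3162, 10000, 31623, 100000)
  curve <- background_sensitivity(t1[1:50], t1[30:141], grid)
  expect_true(all(diff(curve$log10_p) < 0))
})
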