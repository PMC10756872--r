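test_that("PPI expansion adds one-hop neighbors above the score threshold", {
  genes5 <- c("MAST4", "ITGA6", "PITX2", "CACNA1S", "CDON")
  edges <- data.frame(gene_a = c("MAST4", "PITX2", "X"),
                      gene_b = c("X", "Y", "Z"),
                      combined_score = c(800, 650, 800))
  g <- ppiGraph(edges, minScore = 700)
  exp <- expandGeneSet(genes5, g)
  expect_true(all(genes5 %in% exp))
  expect_true("X" %in% exp)       # edge at 800 kept
  expect_false("Y" %in% exp)      # 650 < 700 dropped
  expect_false("Z" %in% exp)      # neighbor-of-neighbor excluded (one hop)
  # empty network leaves the query unchanged
  expect_setequal(expandGeneSet(genes5, NULL), genes5)
  # expansion of the expanded set may grow (documented one-hop behavior)
  expect_true("Z" %in% expandGeneSet(exp, g))
  expect_error(ppiGraph(data.frame(gene_a = "A", gene_b = "B",
                                   combined_score = 1200)), "0-1000")
  expect_error(ppiGraph(data.frame(gene_a = "A", gene_b = "A",
                                   combined_score = 900)), "self-loop")
})

test_that("hypergeometric p matches exhaustive draw enumeration", {
  expect_equal(hypergeomTest(LETTERS[1:5], LETTERS[1:5], LETTERS[1:5]), 1)
  expect_equal(hypergeomTest(LETTERS[1:5], LETTERS[6:10], LETTERS[1:20]), 1)
  # universe 20, term 5, query 5, overlap 4
  u <- sprintf("g%02d", 1:20)
  term <- u[1:5]
  query <- c(u[1:4], u[10])
  p <- hypergeomTest(term, query, u)
  expect_equal(p, hyperEnumOracle(1:5, 5, 20, 4), tolerance = 1e-12)
  # a few random small configurations against the enumeration oracle
  set.seed(3)
  for (i in 1:10) {
    N <- sample(8:14, 1)
    uu <- sprintf("x%02d", 1:N)
    m <- sample(2:(N - 1), 1)
    q <- sample(2:5, 1)
    tt <- sample(uu, m)
    qq <- sample(uu, q)
    k <- length(intersect(tt, qq))
    expect_equal(hypergeomTest(tt, qq, uu),
                 hyperEnumOracle(match(tt, uu), q, N, k),
                 tolerance = 1e-12)
  }
  expect_error(hypergeomTest("A", "A", character()), "empty universe")
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(adjustPvalues(0.03), 0.03)
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustPvalues(c(0.005, 0.01, 0.04)), c(0.015, 0.015, 0.04))
  expect_equal(adjustPvalues(rep(1, 5)), rep(1, 5))
  set.seed(5)
  p <- runif(30)
  adj <- adjustPvalues(p)
  expect_equal(adj, bhOracle(p))
  expect_true(all(adj >= p))
  # adjusted p is monotone in raw-p rank
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(adjustPvalues(c(0.5, 1.2)))
})

test_that("enrichment ranks a perfectly matching term first and flags padj", {
  u <- sprintf("g%03d", 1:200)
  query <- u[1:8]
  sets <- list("HIT:1" = u[1:8], "MISS:1" = u[51:70],
               "PART:1" = c(u[1:3], u[100:110]))
  res <- enrichTerms(query, sets, universe = u, padjThreshold = 0.01)
  expect_equal(res$term_id[1], "HIT:1")
  expect_true(res$significant[1])
  expect_equal(res$overlap[res$term_id == "HIT:1"], 8)
  expect_equal(res$term_size[res$term_id == "MISS:1"], 20)
  expect_true(all(res$p_adj >= res$p_value - 1e-12))
  expect_equal(res$significant, res$p_adj < 0.01)
  expect_equal(attr(res, "adjust_method"), "BH")
  # empty query: nothing significant, all p = 1
  res0 <- enrichTerms(character(), sets, universe = u)
  expect_true(all(res0$p_value == 1) && !any(res0$significant))
})

test_that("fixture enrichment ranks calcium-channel and adhesion terms on top", {
  ts <- taTermSets()
  query <- expandGeneSet(variants(taFixture())$gene,
                         ppiGraph(taPpiEdges(), 700))
  res <- enrichTerms(query, ts$sets, source = ts$source)
  top <- res$term_id[1:5]
  expect_true("GO:0005891" %in% top)  # voltage-gated calcium channel complex
  expect_true(any(c("KEGG:04510", "GO:0007155") %in% top))  # focal adhesion
  expect_true(all(res$p_value[match(top, res$term_id)] < 0.05))
  # background-only terms rank below the biology terms
  expect_gt(match("KEGG:00000", res$term_id), 5)
})

test_that("random queries give roughly nominal raw-p false-positive rates", {
  set.seed(17)
  universe <- sprintf("G%04d", 1:2000)
  frac <- replicate(200, {
    terms <- lapply(1:30, function(i) sample(universe, sample(400:800, 1)))
    q <- sample(universe, 250)
    mean(vapply(terms, hypergeomTest, numeric(1), queryGenes = q,
                universe = universe) < 0.05)
  })
  expect_gt(mean(frac), 0.02)
  expect_lt(mean(frac), 0.08)
})
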