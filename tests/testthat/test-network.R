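test_that("PPI edges apply the inclusive 0.45 threshold with dedup and self-drop", {
  rec <- data.frame(gene_a = c("A", "A", "A", "B", "C"),
                    gene_b = c("B", "A", "B", "A", "D"),
                    miscore = c(0.5, 0.9, 0.7, 0.45, 0.3),
                    stringsAsFactors = FALSE)
  g <- ppi_edges(rec)
  el <- igraph::as_edgelist(g)
  expect_identical(nrow(el), 1L)           # A-B only; C-D below threshold
  expect_identical(sort(el[1, ]), c("A", "B"))
  expect_equal(igraph::E(g)$miscore, 0.7)  # max over duplicates either way
  expect_identical(ppi_edges(data.frame(gene_a = "A", gene_b = "B",
                                        miscore = 0.45)) |> igraph::ecount(), 1)
  expect_error(ppi_edges(data.frame(gene_a = "A", gene_b = "B", miscore = 1.2)),
               "malformed")
})

toy_evidence <- function() {
  graph_from_pairs(c("n1", "n2", "k1", "k2", "k3"),
                   list(c("n1", "k1"), c("n2", "k1"), c("n1", "n2"),
                        c("n1", "k2")))
}

test_that("functional network reproduces the hand-enumerated toy fixture", {
  net <- build_functional_network(novel = c("n1", "n2"),
                                  known = c("k1", "k2", "k3"),
                                  coexpr = toy_evidence())
  expect_identical(sort(igraph::V(net)$name), c("k1", "n1", "n2"))
  el <- igraph::as_edgelist(net)
  pairs <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  expect_identical(pairs, c("k1 n1", "k1 n2", "n1 n2"))
  labels <- igraph::vertex_attr(net, "label",
                                igraph::V(net)[c("k1", "n1", "n2")])
  expect_identical(labels, c("known", "novel", "novel"))
  deg <- novel_degree_table(net)
  expect_identical(deg$gene, c("n1", "n2"))
  expect_identical(deg$n_known_neighbors, c(1L, 1L))
})

test_that("known genes need two novel neighbors; provenance marks shared edges", {
  co <- graph_from_pairs(c("n1", "n2", "k1"), list(c("n1", "k1")))
  # k1 has one novel neighbor -> excluded, and n1 is left unconnected
  net1 <- build_functional_network("n1", "k1", coexpr = co)
  expect_equal(igraph::vcount(net1), 0)
  co2 <- graph_from_pairs(c("n1", "n2", "k1"),
                          list(c("n1", "k1"), c("n2", "k1")))
  net2 <- build_functional_network(c("n1", "n2"), "k1", coexpr = co2)
  expect_identical(sort(igraph::V(net2)$name), c("k1", "n1", "n2"))
  # an edge present in both evidence graphs is labelled "both"
  pp <- data.frame(gene_a = "n1", gene_b = "k1", miscore = 0.9)
  net3 <- build_functional_network(c("n1", "n2"), "k1", coexpr = co2,
                                   ppi = ppi_edges(pp))
  el <- igraph::as_edgelist(net3)
  prov <- igraph::E(net3)$provenance
  both <- prov[apply(el, 1, function(p) setequal(p, c("n1", "k1")))]
  expect_identical(both, "both")
})

test_that("degenerate networks: empty novel set and the known-leaf star", {
  co <- graph_from_pairs(c("k1", "k2"), list(c("k1", "k2")))
  expect_identical(igraph::vcount(
    build_functional_network(character(0), c("k1", "k2"), coexpr = co)), 0)
  # star: novel hub, five known leaves, each leaf touching only one novel
  star <- graph_from_pairs(c("n1", paste0("k", 1:5)),
                           lapply(paste0("k", 1:5), function(k) c("n1", k)))
  net <- build_functional_network("n1", paste0("k", 1:5), coexpr = star)
  expect_equal(igraph::vcount(net), 0)
  expect_identical(nrow(novel_degree_table(net)), 0L)
})

test_that("network construction is invariant to input row order and monotone", {
  set.seed(8)
  genes <- sprintf("g%02d", 1:20)
  novel <- genes[1:6]; known <- genes[7:20]
  rec <- expand.grid(gene_a = genes, gene_b = genes,
                     stringsAsFactors = FALSE)
  rec <- rec[rec$gene_a < rec$gene_b, ]
  rec$miscore <- runif(nrow(rec))
  g1 <- ppi_edges(rec)
  g2 <- ppi_edges(rec[sample(nrow(rec)), ])
  n1 <- build_functional_network(novel, known, ppi = g1)
  n2 <- build_functional_network(novel, known, ppi = g2)
  expect_identical(igraph::as_edgelist(n1), igraph::as_edgelist(n2))
  expect_identical(igraph::V(n1)$name, igraph::V(n2)$name)
  # removing a novel gene never adds network nodes
  n3 <- build_functional_network(novel[-1], known, ppi = g1)
  expect_true(all(igraph::V(n3)$name %in%
                    c(igraph::V(n1)$name[igraph::V(n1)$name != novel[1]])))
})

test_that("over-representation equals the enumeration oracle and edge cases", {
  bg <- sprintf("b%02d", 1:25)
  set.seed(3)
  for (rep in 1:20) {
    K <- sample(1:25, 1); n <- sample(1:25, 1)
    ann <- sample(bg, K); gs <- sample(bg, n)
    k <- length(intersect(gs, ann))
    res <- overrepresentation(gs, ann, bg)
    expect_equal(res$p, oracle_hyper_tail(k, 25, K, n), tolerance = 1e-12)
    expect_identical(res$overlap, k)
  }
  sat <- overrepresentation(bg, bg, bg)
  expect_equal(sat$p, 1)
  none <- overrepresentation(bg[1:5], bg[6:10], bg)
  expect_equal(none$p, 1)           # P(X >= 0) = 1
  expect_true(is.finite(none$odds_ratio))   # Haldane correction applied
  expect_error(overrepresentation("a", "a", character(0)), "background")
  expect_error(overrepresentation("zz", bg[1], bg), "subsets")
})
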