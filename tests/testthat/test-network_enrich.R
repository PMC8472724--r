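write_edges <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("load_network cleans loops and duplicates", {
  f <- write_edges(c("A\tB", "B\tA", "A\tA"))
  g <- suppressMessages(load_network(f))
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::vcount(g), 2L)
  empty <- suppressMessages(load_network(write_edges(character(0))))
  expect_equal(igraph::vcount(empty), 0L)
  sif <- write_edges(c("a\tpp\tb", "b\tpp\tc"))
  gs <- load_network(sif)
  expect_setequal(igraph::V(gs)$name, c("A", "B", "C"))  # upper-cased
  expect_error(load_network(write_edges(c("A\tB", "oops"))), "line 2")
})

test_that("handshake lemma holds on random edge files", {
  set.seed(91)
  for (i in 1:10) {
    e <- matrix(sample(LETTERS[1:15], 200L, replace = TRUE), ncol = 2L)
    f <- write_edges(apply(e, 1L, paste, collapse = "\t"))
    g <- suppressMessages(load_network(f))
    expect_equal(sum(igraph::degree(g)), 2L * igraph::ecount(g))
  }
})

test_that("induced_subnetwork matches the brute-force edge filter", {
  f <- write_edges(c("A\tB", "B\tC", "C\tA"))
  tri <- load_network(f)
  sub <- induced_subnetwork(tri, c("A", "B"))
  expect_equal(sub$n_nodes, 2L)
  expect_equal(sub$n_edges, 1L)
  none <- induced_subnetwork(tri, c("X", "Y"))
  expect_equal(none$n_nodes, 0L)
  expect_equal(none$n_query_unmatched, 2L)

  set.seed(14)
  for (i in 1:40) {
    nodes <- sprintf("N%02d", 1:20)
    e <- unique(t(apply(matrix(sample(nodes, 120L, replace = TRUE),
                               ncol = 2L), 1L, sort)))
    e <- e[e[, 1L] != e[, 2L], , drop = FALSE]
    g <- igraph::simplify(igraph::graph_from_edgelist(e, directed = FALSE))
    q <- sample(nodes, sample(2:12, 1L))
    sub <- induced_subnetwork(g, q)
    expect_equal(edge_key(sub$graph),
                 oracle_subgraph_edges(igraph::as_edgelist(g), q))
  }
})

test_that("induced_subnetwork is idempotent and can drop isolated nodes", {
  f <- write_edges(c("A\tB", "C\tD"))
  g <- load_network(f)
  s1 <- induced_subnetwork(g, c("A", "B", "C"))
  s2 <- induced_subnetwork(s1$graph, c("A", "B", "C"))
  expect_equal(edge_key(s1$graph), edge_key(s2$graph))
  expect_equal(s1$n_nodes, 3L)
  kept <- induced_subnetwork(g, c("A", "B", "C"), drop_isolated = TRUE)
  expect_equal(kept$n_nodes, 2L)
})

test_that("color_by_state attaches aspc columns, flags and missing markers", {
  f <- write_edges(c("A\tB", "B\tC"))
  g <- load_network(f)
  px <- structure(list(cohort = "Wt", aspc = c(A = 20, B = 5), n_runs = 1L,
                       identified = c("A", "B")), class = "cohort_profile")
  py <- structure(list(cohort = "Ho", aspc = c(A = 5, B = 5), n_runs = 1L,
                       identified = c("A", "B")), class = "cohort_profile")
  rep_ <- compare_pair(px, py)
  sub <- induced_subnetwork(g, c("A", "B", "C"))
  attrs <- color_by_state(sub, list(px, py), list(rep_))
  expect_equal(nrow(attrs), sub$n_nodes)
  expect_equal(attrs$state[attrs$node == "A"], "up_in_Wt")
  expect_equal(attrs$state[attrs$node == "B"], "unchanged")
  expect_equal(attrs$state[attrs$node == "C"], "missing")
})

test_that("hypergeometric p matches exhaustive enumeration", {
  terms <- data.frame(gene = paste0("G", 1:5), term = "T1")
  universe <- paste0("G", 1:10)
  res <- hypergeom_enrich(c("G1", "G2"), universe, terms, alpha = 0.5)
  expect_equal(res$p_value, 10 / 45, tolerance = 1e-12)
  expect_equal(res$k, 2L)
  expect_equal(res$K, 5L)

  set.seed(101)
  for (i in 1:30) {
    N <- sample(8:30, 1L)
    uni <- sprintf("g%02d", seq_len(N))
    K <- sample(1:N, 1L)
    terms <- data.frame(gene = uni[seq_len(K)], term = "T")
    n <- sample(1:N, 1L)
    q <- sample(uni, n)
    res <- hypergeom_enrich(q, uni, terms, alpha = 1)
    k <- sum(q %in% terms$gene)
    if (k == 0) expect_equal(res$p_value, 1.0)
    else expect_equal(res$p_value, oracle_hyper_tail(k, K, n, N),
                      tolerance = 1e-10)
  }
})

test_that("BH correction reproduces the hand step-up and stays monotone", {
  # three terms engineered to give p = .01/.02/.03 is cumbersome with
  # hypergeometric inputs; check the BH layer through p.adjust semantics
  # on the output of a multi-term enrichment instead
  set.seed(7)
  uni <- sprintf("g%02d", 1:24)
  terms <- do.call(rbind, lapply(1:6, function(t)
    data.frame(gene = sample(uni, 8L), term = paste0("T", t))))
  q <- sample(uni, 10L)
  res <- hypergeom_enrich(q, uni, terms, alpha = 0.05)
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
  expect_true(!is.unsorted(res$q_value))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
})

test_that("hypergeom_enrich validates the query and handles empty terms", {
  expect_error(hypergeom_enrich("X", c("A", "B"),
                                data.frame(gene = "A", term = "T")),
               "subset")
  res <- hypergeom_enrich("A", c("A", "B"),
                          data.frame(gene = character(0),
                                     term = character(0)))
  expect_equal(nrow(res), 0L)
})
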