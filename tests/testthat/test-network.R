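# Residue-interaction graph construction and eigenvector centrality.

test_that("the sequence-gap rule admits |i-j| >= 2 and non-zero weights only", {
  tab <- data.frame(res_i = c(10L, 10L, 10L), res_j = c(11L, 12L, 14L),
                    chain_i = "A", chain_j = "A", freq = c(0.9, 0.9, 0))
  g <- build_graph(tab, min_sequence_gap = 2L)
  key <- paste(g$edges$res_i, g$edges$res_j)
  expect_false("10 11" %in% key)  # immediate neighbor excluded
  expect_true("10 12" %in% key)
  expect_false("10 14" %in% key)  # zero frequency: no edge
  expect_equal(g$edges$freq[key == "10 12"], 0.9)
  # inter-chain pairs are always eligible
  tab2 <- data.frame(res_i = 10L, res_j = 11L, chain_i = "A", chain_j = "B",
                     freq = 0.5)
  expect_equal(nrow(build_graph(tab2)$edges), 1L)
})

test_that("closed forms hold: complete graphs are uniform, stars split 1/sqrt(2) vs 1/sqrt(6)", {
  n <- 5L
  W <- matrix(0.7, n, n); diag(W) <- 0
  s <- eigenvector_centrality(graph_from_adjacency(W))
  expect_lt(max(abs(s - 1 / sqrt(n))), 1e-10)
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  s2 <- eigenvector_centrality(graph_from_adjacency(star))
  expect_lt(abs(s2[1] - 1 / sqrt(2)), 1e-10)
  expect_lt(max(abs(s2[2:4] - 1 / sqrt(6))), 1e-10)
})

test_that("centrality matches a dense eigensolver on random weighted graphs", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    W <- random_weighted_graph(n)
    s <- eigenvector_centrality(graph_from_adjacency(W))
    e <- eigen(W, symmetric = TRUE)
    ref <- abs(e$vectors[, 1])
    expect_lt(max(abs(as.numeric(s) - ref)), 1e-8)
    expect_true(all(s >= 0))  # Perron sign convention
    lam <- attr(s, "eigenvalue")
    expect_lt(abs(lam - e$values[1]), 1e-8)
  }
})

test_that("centrality is invariant to global edge-weight scaling", {
  set.seed(17)
  W <- random_weighted_graph(20)
  s1 <- eigenvector_centrality(graph_from_adjacency(W))
  s2 <- eigenvector_centrality(graph_from_adjacency(0.25 * W))
  expect_lt(max(abs(as.numeric(s1) - as.numeric(s2))), 1e-9)
})

test_that("isolated nodes score zero and do not perturb the main component", {
  set.seed(19)
  W <- random_weighted_graph(15)
  Wbig <- rbind(cbind(W, 0), 0)  # append an isolated node
  s <- eigenvector_centrality(graph_from_adjacency(W))
  sbig <- eigenvector_centrality(graph_from_adjacency(Wbig))
  expect_equal(as.numeric(sbig[16]), 0)
  expect_lt(max(abs(as.numeric(sbig[1:15]) - as.numeric(s))), 1e-9)
  expect_error(eigenvector_centrality(build_graph(
    data.frame(res_i = integer(), res_j = integer(), chain_i = character(),
               chain_j = character(), freq = numeric()))), regexp = "empty")
})

test_that("centrality agrees with igraph on a weighted graph", {
  skip_if_not_installed("igraph")
  set.seed(23)
  W <- random_weighted_graph(30)
  s <- eigenvector_centrality(graph_from_adjacency(W))
  ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE)
  ref <- igraph::eigen_centrality(ig)$vector
  ref <- ref / sqrt(sum(ref^2))  # rescale igraph's max-1 convention to L2
  expect_lt(max(abs(as.numeric(s) - ref)), 1e-6)
})

test_that("strengthening a hub's edges strictly raises its score", {
  set.seed(29)
  W <- random_weighted_graph(25)
  hub <- 12L
  W2 <- W
  nb <- which(W[hub, ] > 0)
  W2[hub, nb] <- W2[nb, hub] <- pmin(1, W[hub, nb] + 0.4)
  s1 <- eigenvector_centrality(graph_from_adjacency(W))
  s2 <- eigenvector_centrality(graph_from_adjacency(W2))
  expect_gt(as.numeric(s2[hub]), as.numeric(s1[hub]))
})

test_that("bootstrap centrality reduces to the plain computation and reports spread", {
  spec <- quick_spec(frames_per_trajectory = 30L)
  m <- generate_condition(spec, "A")
  cf1 <- bootstrap_frequencies(m, bootstrap_plan(1L, 30L, FALSE), 4.5,
                               selection_spec(chain = "R"))
  cb <- centrality_with_bootstrap(cf1)
  s <- eigenvector_centrality(build_graph(cf1))
  expect_equal(cb$score, as.numeric(s), tolerance = 1e-12)
  expect_true(all(cb$spread == 0))  # single sample: zero diagnostic spread
  cf4 <- bootstrap_frequencies(m, bootstrap_plan(4L, 30L, FALSE, seed = 2L),
                               4.5, selection_spec(chain = "R"))
  cb4 <- centrality_with_bootstrap(cf4)  # identical samples: zero spread
  expect_lt(max(cb4$spread), 1e-12)
})

test_that("condition comparison reproduces published-table arithmetic", {
  s1 <- setNames(c(0.202, 0.165), c("R:114", "R:70"))
  s2 <- setNames(c(0.167, 0.186), c("R:114", "R:70"))
  tab <- compare_conditions(s1, s2, highlight = 0.005)
  expect_equal(tab$signed_diff[tab$resid == 114], 0.035)
  expect_equal(tab$abs_diff[tab$resid == 114], 0.035)
  expect_equal(tab$signed_diff[tab$resid == 70], -0.021)
  expect_equal(tab$abs_diff[tab$resid == 70], 0.021)
  expect_true(all(tab$highlighted))
  # identity comparison: nothing highlighted
  t0 <- compare_conditions(s1, s1)
  expect_true(all(t0$signed_diff == 0))
  expect_false(any(t0$highlighted))
  # highlight is strict: a difference equal to the threshold is not flagged
  te <- compare_conditions(setNames(0.105, "R:1"), setNames(0.100, "R:1"),
                           highlight = 0.005)
  expect_false(te$highlighted)
  # node-universe mismatch errors
  expect_error(compare_conditions(s1, setNames(0.1, "R:99")),
               regexp = "universes")
  # min-score filter keeps residues scoring >= 0.10 in either condition
  tf <- compare_conditions(setNames(c(0.05, 0.12), c("R:1", "R:2")),
                           setNames(c(0.06, 0.01), c("R:1", "R:2")),
                           min_score = 0.10)
  expect_identical(tf$resid, 2L)
})
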