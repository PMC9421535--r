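test_that("LD=1 network matches brute-force Levenshtein on toy cases", {
  g <- build_ld1_network(c("CARW", "CARY", "CTRW"))
  expect_equal(graph_edge_keys(g),
               sort(c("CARW--CARY", "CARW--CTRW")))
  expect_equal(graph_edge_keys(build_ld1_network(c("CAR", "CARW"))),
               "CAR--CARW")
  expect_equal(igraph::ecount(build_ld1_network("CARW")), 0)
})

test_that("hashed LD=1 network is edge-identical to the brute-force oracle", {
  withr::with_seed(42, {
    for (i in 1:10) {
      seqs <- random_peptides(sample(20:200, 1))
      expect_identical(graph_edge_keys(build_ld1_network(seqs)),
                       brute_force_ld1_edges(seqs))
    }
  })
})

test_that("architecture summaries match hand enumeration", {
  # edgeless graph: all nodes unconnected, hub scores defined as 0
  g0 <- igraph::make_empty_graph(10, directed = FALSE)
  igraph::V(g0)$name <- paste0("s", 1:10)
  s0 <- architecture_summary(g0)
  expect_equal(s0$frac_unconnected, 1)
  expect_equal(s0$frac_largest, 0.1)
  expect_equal(s0$mean_hub_score, 0)

  # complete graph K4: symmetric, every hub score 1
  s4 <- architecture_summary(igraph::make_full_graph(4))
  expect_equal(s4$frac_largest, 1)
  expect_equal(s4$mean_hub_score, 1)
  expect_equal(s4$frac_unconnected, 0)

  # path P3: degrees (1, 2, 1), cumulative distribution (0, 2/3, 1)
  p3 <- igraph::make_graph(~ a - b, b - c)
  s3 <- architecture_summary(p3)
  expect_equal(unname(s3$cum_degree), c(0, 2 / 3, 1))
})

test_that("architecture similarity combines four components as stated", {
  g <- build_ld1_network(c("CARW", "CARY", "CTRW"))
  s <- architecture_summary(g)
  expect_equal(architecture_similarity(s, s), 1)

  s_shift <- s
  s_shift$mean_hub_score <- s$mean_hub_score - 1
  expect_equal(architecture_similarity(s, s_shift), 0.75)

  # P3 vs K3: each component computed independently
  sp <- architecture_summary(igraph::make_graph(~ a - b, b - c))
  sk <- architecture_summary(igraph::make_full_graph(3))
  # hub-score oracle: Perron-Frobenius eigenvector of the adjacency matrix
  # (unique and positive on a connected graph), max-normalized
  eig_hub <- function(adj) {
    e <- eigen(adj)
    v <- abs(e$vectors[, which.max(e$values)])
    mean(v / max(v))
  }
  adj_p <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  adj_k <- matrix(1, 3, 3) - diag(3)
  expect_equal(sp$mean_hub_score, eig_hub(adj_p), tolerance = 1e-6)
  expect_equal(sk$mean_hub_score, eig_hub(adj_k), tolerance = 1e-6)
  cd_p <- c(0, 2 / 3, 1)  # degrees (1,2,1)
  cd_k <- c(0, 0, 1)      # degrees (2,2,2)
  manual <- mean(c(max(0, cor(cd_p, cd_k)),
                   1 - abs(eig_hub(adj_p) - eig_hub(adj_k)),
                   1 - abs(0 - 0),
                   1 - abs(1 - 1)))
  expect_equal(architecture_similarity(sp, sk), manual, tolerance = 1e-6)
})

test_that("hub scores peak at the star center and are deterministic", {
  star <- igraph::make_star(9, mode = "undirected")
  hs <- airrnet:::ld1_hub_scores(star)
  expect_equal(unname(hs[1]), 1)       # center carries the maximal score
  expect_true(all(hs[-1] < 1))
  expect_equal(unname(hs[-1]), rep(unname(hs[2]), 8), tolerance = 1e-9)
  expect_identical(airrnet:::ld1_hub_scores(star), hs)  # rerun identical
  # matches the dense eigenvector oracle on a connected graph
  A <- as.matrix(igraph::as_adjacency_matrix(star))
  e <- eigen(A)
  v <- abs(e$vectors[, which.max(e$values)])
  expect_equal(unname(hs), v / max(v), tolerance = 1e-6)
})

test_that("degree distributions are compared on padded union support", {
  # star S5 (maxdeg 4) vs single edge pair (maxdeg 1)
  star <- architecture_summary(igraph::make_star(5, mode = "undirected"))
  pair <- architecture_summary(igraph::make_graph(~ a - b))
  k <- max(length(star$cum_degree), length(pair$cum_degree))
  pad <- function(v) c(v, rep(1, k - length(v)))
  manual1 <- max(0, cor(pad(unname(star$cum_degree)),
                        pad(unname(pair$cum_degree))))
  got <- architecture_similarity(star, pair)
  manual <- mean(c(manual1,
                   1 - abs(star$mean_hub_score - pair$mean_hub_score),
                   1 - abs(star$frac_unconnected - pair$frac_unconnected),
                   1 - abs(star$frac_largest - pair$frac_largest)))
  expect_equal(got, manual, tolerance = 1e-12)
})
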