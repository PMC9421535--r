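panel_3 <- function() {
  list(a = small_sim(21, n = 150), b = small_sim(22, n = 150),
       c = small_sim(23, n = 150))
}

test_that("feature matrices are symmetric with unit diagonal in [0,1]", {
  mats <- feature_matrices(panel_3())
  expect_named(mats, c("germline", "diversity", "aa_freq", "architecture",
                       "convergence", "kmer"))
  for (m in mats) {
    expect_equal(bare(m), t(bare(m)), tolerance = 1e-12)
    expect_equal(unname(diag(m)), rep(1, 3))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("identical repertoires give an all-ones matrix for every feature", {
  r <- small_sim(31, n = 120)
  mats <- feature_matrices(list(x = r, y = r))
  for (m in mats) expect_equal(bare(m), matrix(1, 2, 2,
                                                  dimnames = dimnames(m)))
})

test_that("germline similarity is zero by definition across species", {
  hs <- small_sim(41, n = 120)
  mm <- simulate_repertoire(sim_config(species = "mouse", n_sequences = 120,
                                       subsample_to = 120, seed = 42,
                                       label = "m"))
  g <- feature_matrix(list(h = hs, m = mm), "germline")
  expect_equal(g["h", "m"], 0)
  expect_equal(g["h", "h"], 1)
})

test_that("condensation aggregates cellwise with min <= mean <= max", {
  m1 <- new_similarity(matrix(c(1, 0.4, 0.4, 1), 2,
                              dimnames = list(c("a", "b"), c("a", "b"))),
                       feature = "f1")
  m2 <- new_similarity(matrix(c(1, 0.8, 0.8, 1), 2,
                              dimnames = list(c("a", "b"), c("a", "b"))),
                       feature = "f2")
  expect_equal(condense(list(m1, m2), "mean")["a", "b"], 0.6)
  expect_equal(condense(list(m1, m2), "max")["a", "b"], 0.8)
  expect_equal(condense(list(m1, m2), "min")["a", "b"], 0.4)

  expect_equal(bare(condense(list(m1, m1, m1), "mean")), bare(m1))

  mats <- feature_matrices(panel_3())
  lo <- condense(mats, "min"); mid <- condense(mats, "mean")
  hi <- condense(mats, "max")
  expect_true(all(lo <= mid + 1e-12) && all(mid <= hi + 1e-12))
  # mean condensation commutes with input order permutation
  expect_equal(bare(condense(rev(mats), "mean")), bare(mid))

  m3 <- new_similarity(matrix(1, 2, 2, dimnames = list(c("b", "a"),
                                                       c("b", "a"))),
                       feature = "f3")
  expect_error(condense(list(m1, m3)), class = "airrnet_input_error")
})

test_that("edge thresholding keeps quantile-defined top weights with ties", {
  ids <- paste0("r", 1:5)
  w <- matrix(0.5, 5, 5, dimnames = list(ids, ids))
  diag(w) <- 1
  m_eq <- new_similarity(w, "composite")
  expect_equal(nrow(threshold_edges(m_eq, 0.25)), 10)  # all tied, all kept

  vals <- seq(0.1, 1, by = 0.1)
  w2 <- matrix(0, 5, 5, dimnames = list(ids, ids))
  w2[upper.tri(w2)] <- vals
  w2 <- w2 + t(w2); diag(w2) <- 1
  m <- new_similarity(w2, "composite")
  got <- threshold_edges(m, 0.25)
  # linear-interpolation 75th percentile of 0.1..1.0 is 0.775
  expect_setequal(got$weight, c(0.8, 0.9, 1.0))
  expect_equal(nrow(threshold_edges(m, 1)), 10)

  # nesting across cutoffs
  e25 <- threshold_edges(m, 0.25); e50 <- threshold_edges(m, 0.5)
  e75 <- threshold_edges(m, 0.75)
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(e25) %in% key(e50)))
  expect_true(all(key(e50) %in% key(e75)))
})

test_that("local similarity normalizes node strengths over the subgraph", {
  ids <- c("A", "B", "C")
  w <- matrix(0, 3, 3, dimnames = list(ids, ids))
  w["A", "B"] <- w["B", "A"] <- 0.8
  w["A", "C"] <- w["C", "A"] <- 0.4
  w["B", "C"] <- w["C", "B"] <- 0.2
  diag(w) <- 1
  m <- new_similarity(w, "composite")
  ls <- local_similarity(m)
  expect_equal(ls$strength, c(1.2, 1.0, 0.6))
  expect_equal(ls$local, c(0.42857, 0.35714, 0.21429), tolerance = 1e-4)
  expect_equal(sum(ls$local), 1, tolerance = 1e-9)
  expect_equal(ls$scaled, ls$local / 3)

  # equal weights: each local similarity is 1/3
  weq <- matrix(0.5, 3, 3, dimnames = list(ids, ids)); diag(weq) <- 1
  expect_equal(local_similarity(new_similarity(weq, "x"))$local,
               rep(1 / 3, 3))

  # invariant to nodes outside the subgraph
  ids4 <- c(ids, "D")
  w4 <- matrix(0.9, 4, 4, dimnames = list(ids4, ids4))
  w4[ids, ids] <- w; diag(w4) <- 1
  expect_equal(local_similarity(new_similarity(w4, "x"), ids)$local,
               ls$local)

  wz <- matrix(0, 3, 3, dimnames = list(ids, ids)); diag(wz) <- 1
  expect_error(local_similarity(new_similarity(wz, "x")),
               class = "airrnet_input_error")
})

test_that("reference repertoire maximizes local similarity with ties by id", {
  ids <- c("hub", "x1", "x2", "x3")
  w <- matrix(0.1, 4, 4, dimnames = list(ids, ids))
  w["hub", ] <- w[, "hub"] <- 0.9
  diag(w) <- 1
  expect_equal(reference_repertoire(new_similarity(w, "x")), "hub")

  weq <- matrix(0.5, 3, 3,
                dimnames = list(c("b", "a", "c"), c("b", "a", "c")))
  diag(weq) <- 1
  expect_equal(reference_repertoire(new_similarity(weq, "x")), "a")

  # brute-force row-sum check on a simulated cohort matrix
  mats <- feature_matrices(panel_3())
  comp <- condense(mats)
  sub <- unclass(comp); diag(sub) <- 0
  expect_equal(reference_repertoire(comp),
               rownames(comp)[which.max(rowSums(sub))])
})

test_that("compare_to_reference is a per-feature lookup", {
  mats <- feature_matrices(panel_3())
  tab <- compare_to_reference(mats, "a", c("b", "c"))
  expect_equal(tab$query, c("b", "c"))
  for (f in names(mats)) {
    expect_equal(tab[[f]], unname(unclass(mats[[f]])[c("b", "c"), "a"]))
  }
  self <- compare_to_reference(mats, "a", "a")
  expect_true(all(as.numeric(self[1, -1]) == 1))
  expect_error(compare_to_reference(mats, "zz"),
               class = "airrnet_input_error")
})
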