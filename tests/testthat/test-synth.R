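test_that("segment libraries are deterministic and well formed", {
  lib <- segment_library("human", "TRB")
  expect_identical(lib, segment_library("human", "TRB"))
  expect_true(nrow(lib$v) >= 8 && nrow(lib$v) <= 12)
  expect_true(nrow(lib$d) >= 2 && nrow(lib$d) <= 4)
  expect_true(nrow(lib$j) >= 4 && nrow(lib$j) <= 6)
  for (seg in lib) {
    expect_equal(sum(seg$freq), 1, tolerance = 1e-12)
    expect_true(all(grepl("^[acgt]+$", seg$seq)))
    expect_true(all(nchar(seg$seq) >= 50 & nchar(seg$seq) <= 300))
  }
  expect_true(all(substr(lib$v$frag, 1, 3) == "tgt"))
  expect_false(identical(segment_library("mouse", "TRB")$v$frag,
                         lib$v$frag))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_sequences = 300, subsample_to = 250, seed = 5)
  r1 <- simulate_repertoire(cfg)
  r2 <- simulate_repertoire(cfg)
  expect_equal(tibble::as_tibble(r1), tibble::as_tibble(r2))
  r3 <- simulate_repertoire(sim_config(n_sequences = 300, subsample_to = 250,
                                       seed = 6))
  expect_false(identical(r1$junction, r3$junction))
})

test_that("simulated repertoires satisfy the repertoire invariants", {
  r <- small_sim(77, n = 400)
  expect_equal(sum(r$clone_freq), 1, tolerance = 1e-9)
  expect_false(any(grepl("\\*", r$junction_aa)))
  expect_true(all(nchar(r$junction) %% 3 == 0))
  expect_true(all(nchar(r$junction) == 3 * nchar(r$junction_aa)))
  expect_equal(anyDuplicated(paste(r$junction, r$v_call, r$j_call)), 0L)
  expect_identical(airrnet:::translate_nt(r$junction), r$junction_aa)
})

test_that("without insertions/deletions junction lengths are attainable", {
  # the V x D x J combination space is finite without junctional variation,
  # so request fewer clones than the number of attainable combinations
  r <- simulate_repertoire(sim_config(n_sequences = 100, subsample_to = 100,
                                      seed = 8, insertions = FALSE,
                                      deletions = FALSE))
  lib <- segment_library("human", "TRB")
  attainable <- unique(as.vector(outer(
    outer(nchar(lib$v$frag), nchar(lib$d$frag), "+"),
    nchar(lib$j$frag), "+")))
  expect_true(all(nchar(r$junction) %in% attainable))
})

test_that("steeper clone-count exponents lower the evenness profile", {
  for (seed in c(3, 14)) {
    flat <- simulate_repertoire(sim_config(n_sequences = 400,
                                           subsample_to = 400, seed = seed,
                                           clone_count_alpha = 0.5))
    steep <- simulate_repertoire(sim_config(n_sequences = 400,
                                            subsample_to = 400, seed = seed,
                                            clone_count_alpha = 2))
    expect_lt(mean(evenness_profile(steep)$evenness),
              mean(evenness_profile(flat)$evenness))
  }
})

test_that("motif implantation is probability-faithful and frame-preserving", {
  r <- small_sim(55, n = 2000)
  expect_equal(tibble::as_tibble(implant_motifs(r, "tacgcctac", 0,
                                                seed = 1)),
               tibble::as_tibble(r), ignore_attr = TRUE)

  forced <- implant_motifs(r, "tacgcctac", 1, seed = 2)
  long_enough <- nchar(forced$junction) >= 9
  expect_true(all(grepl("tacgcctac", forced$junction[long_enough],
                        fixed = TRUE)))
  expect_true(all(grepl("YAY", forced$junction_aa[long_enough], fixed = TRUE)))
  # implants land on codon boundaries
  pos <- regexpr("tacgcctac", forced$junction[long_enough], fixed = TRUE)
  expect_true(all((pos - 1) %% 3 == 0))

  # implanted-clone count within the binomial 99% interval
  p <- 0.025
  hit <- implant_motifs(r, "tacgcctac", p, seed = 3)
  n_implanted <- attr(hit, "implant_count")
  bounds <- qbinom(c(0.005, 0.995), nrow(r), p)
  expect_gte(n_implanted, bounds[1])
  expect_lte(n_implanted, bounds[2])
})

test_that("hub removal deletes top hub-score sequences deterministically", {
  r <- small_sim(66, n = 300)
  expect_identical(remove_hubs(r, 0), r)
  out <- remove_hubs(r, 0.05)
  n_unique <- length(unique(r$junction_aa))
  expect_equal(length(unique(out$junction_aa)),
               n_unique - ceiling(0.05 * n_unique))

  # star topology: each leaf differs from the center at a distinct position
  # (leaves are pairwise at distance 2), so the center is the unique hub
  star <- toy_repertoire(c("CAAAAAAW", "CYAAAAAW", "CAYAAAAW", "CAAYAAAW",
                           "CAAAYAAW", "CAAAAYAW", "CAAAAAYW", "CAAAAAAY"))
  g <- build_ld1_network(unique(star$junction_aa))
  expect_equal(igraph::ecount(g), 7)
  kept <- remove_hubs(star, 0.1)  # ceiling(0.1 * 8) = 1 sequence removed
  expect_false("CAAAAAAW" %in% kept$junction_aa)
  expect_equal(nrow(kept), 7)
})

codon_split <- function(x) {
  strsplit(gsub("(...)", "\\1 ", x), " ", fixed = TRUE)
}

test_that("synonymous swaps preserve amino-acid junctions exactly", {
  r <- small_sim(88, n = 500)
  expect_identical(synonymous_swap(r, 0, seed = 1), r)
  swapped <- synonymous_swap(r, 1, seed = 1)
  expect_setequal(swapped$junction_aa, r$junction_aa)
  expect_false(any(c("tat", "agt", "gtt") %in%
                     unlist(codon_split(swapped$junction))))

  one <- toy_repertoire("YSV")
  expect_equal(one$junction, "tatagtgtt")
  expect_equal(synonymous_swap(one, 1, seed = 1)$junction, "tacagcgtg")
})

test_that("panel generation derives seeds and manifests per replicate", {
  cfgs <- list(sim_config(n_sequences = 120, subsample_to = 100, seed = 10,
                          label = "a"),
               sim_config(n_sequences = 120, subsample_to = 100, seed = 50,
                          clone_count_alpha = 2, label = "b"))
  panel <- generate_panel(cfgs, replicates = 3)
  expect_length(panel, 6)
  manifest <- attr(panel, "manifest")
  expect_equal(nrow(manifest), 6)
  expect_equal(manifest$seed[manifest$config_label == "a"], 10:12)
  expect_true(all(sapply(panel, nrow) == 100))
  expect_false(identical(panel[["a_r1"]]$junction, panel[["a_r2"]]$junction))
  # replicates share their config hash (seed/label excluded); parameter
  # changes alter it
  expect_length(unique(manifest$config_hash[manifest$config_label == "a"]), 1)
  expect_length(unique(manifest$config_hash), 2)
})

test_that("synthetic expression matrices separate groups when effect is large", {
  m <- generate_expression(n_genes = 400, group_sizes = c(4, 4),
                           effect_size = 3, seed = 2)
  expect_equal(dim(m), c(400, 8))
  expect_identical(m, generate_expression(n_genes = 400,
                                          group_sizes = c(4, 4),
                                          effect_size = 3, seed = 2))
  sim <- expression_similarity(m, sd_threshold = 1)
  grp <- attr(m, "groups")
  same <- outer(grp, grp, "==") & upper.tri(sim)
  diff <- outer(grp, grp, "!=") & upper.tri(sim)
  expect_gt(mean(sim[same]), mean(sim[diff]))
})
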