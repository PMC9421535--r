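# Shared fixtures and independent oracles used across the test files.

# Reverse-translate an amino-acid string with a fixed codon choice so toy
# repertoires can be specified at the aa level.
aa_to_nt <- function(aa) {
  codon <- c(A = "gct", C = "tgt", D = "gat", E = "gaa", F = "ttt",
             G = "ggt", H = "cat", I = "att", K = "aaa", L = "ctt",
             M = "atg", N = "aat", P = "cct", Q = "caa", R = "aga",
             S = "agt", T = "act", V = "gtt", W = "tgg", Y = "tat",
             "*" = "taa")
  vapply(strsplit(aa, ""), function(ch) paste0(codon[ch], collapse = ""),
         character(1))
}

toy_repertoire <- function(aa, counts = NULL, v = NULL, j = NULL, d = NULL,
                           id = "toy", species = "human", receptor = "TRB",
                           cohort = "default") {
  n <- length(aa)
  new_repertoire(
    tibble::tibble(
      junction = aa_to_nt(aa),
      junction_aa = aa,
      v_call = v %||% rep("TRBV1*01", n),
      d_call = d %||% rep("TRBD1*01", n),
      j_call = j %||% rep("TRBJ1*01", n),
      duplicate_count = counts %||% rep(1L, n)),
    repertoire_id = id, species = species, receptor = receptor,
    cohort = cohort)
}

# Random peptide sets for network property tests.
random_peptides <- function(n, len_range = 4:10) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "K", "R", "S", "T", "W", "Y")
  unique(vapply(seq_len(n), function(i) {
    paste0(sample(aa, sample(len_range, 1), replace = TRUE), collapse = "")
  }, character(1)))
}

# Brute-force LD=1 edge set via base R's generalized Levenshtein distance.
brute_force_ld1_edges <- function(seqs) {
  d <- utils::adist(seqs, seqs)
  idx <- which(d == 1 & upper.tri(d), arr.ind = TRUE)
  if (nrow(idx) == 0) return(character(0))
  sort(paste(pmin(seqs[idx[, 1]], seqs[idx[, 2]]),
             pmax(seqs[idx[, 1]], seqs[idx[, 2]]), sep = "--"))
}

graph_edge_keys <- function(g) {
  if (igraph::ecount(g) == 0) return(character(0))
  el <- igraph::as_edgelist(g)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "--"))
}

# Strip similarity-object attributes down to the bare numeric matrix.
bare <- function(m) {
  m <- unclass(m)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

# A small simulated panel cached per test run (cheap configs).
small_sim <- function(seed, n = 300, ...) {
  simulate_repertoire(sim_config(n_sequences = n, subsample_to = n,
                                 seed = seed, label = paste0("s", seed), ...))
}
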