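# Bundled SYNTHETIC germline segment library
#
# A stand-in segment library generated deterministically in code (fixed
# internal seed, isolated from the user's RNG stream): per species/receptor
# combination, 8-12 V, 2-4 D and 4-6 J segments with junction-proximal
# fragments whose in-frame codons avoid stops, plus skewed baseline usage
# frequencies. These are NOT curated germline alleles; a user-supplied
# library with the same structure can be passed wherever `library` appears.

.airrnet_env <- new.env(parent = emptyenv())

NON_STOP_CODONS <- {
  nts <- c("a", "c", "g", "t")
  all3 <- as.vector(outer(as.vector(outer(nts, nts, paste0)), nts, paste0))
  setdiff(all3, c("taa", "tag", "tga"))
}

random_codon_seq <- function(n_codons, first = NULL) {
  body <- sample(NON_STOP_CODONS, n_codons - length(first), replace = TRUE)
  paste0(paste0(first, collapse = ""), paste0(body, collapse = ""))
}

build_segment_set <- function(prefix, n, lengths, first = NULL, gamma_shape) {
  frags <- vapply(seq_len(n), function(i) {
    L <- sample(lengths, 1)
    random_codon_seq(L / 3, first = first)
  }, character(1))
  # embed each junction fragment in a longer synthetic gene sequence
  full <- vapply(frags, function(f) {
    pad <- sample(NON_STOP_CODONS, sample(15:60, 1), replace = TRUE)
    paste0(paste0(pad, collapse = ""), f)
  }, character(1), USE.NAMES = FALSE)
  freq <- sort(stats::rgamma(n, shape = gamma_shape, rate = 1),
               decreasing = TRUE)
  freq <- freq / sum(freq)
  tibble::tibble(gene = paste0(prefix, seq_len(n)),
                 frag = unname(frags), seq = full, freq = freq)
}

#' Synthetic germline segment library for a species/receptor combination
#'
#' @param species `"human"` or `"mouse"`.
#' @param receptor `"TRB"` or `"IgH"`.
#' @return list with tibbles `v`, `d`, `j` (columns `gene`, `frag`, `seq`,
#'   `freq`), built deterministically per combination.
#' @export
segment_library <- function(species = c("human", "mouse"),
                            receptor = c("TRB", "IgH")) {
  species <- match.arg(species)
  receptor <- match.arg(receptor)
  key <- paste(species, receptor, sep = "_")
  if (!is.null(.airrnet_env[[key]])) return(.airrnet_env[[key]])
  combos <- c(human_TRB = 1L, human_IgH = 2L, mouse_TRB = 3L, mouse_IgH = 4L)
  nv <- c(human_TRB = 12L, human_IgH = 10L, mouse_TRB = 10L, mouse_IgH = 8L)
  nd <- c(human_TRB = 2L, human_IgH = 3L, mouse_TRB = 2L, mouse_IgH = 4L)
  nj <- c(human_TRB = 6L, human_IgH = 5L, mouse_TRB = 5L, mouse_IgH = 4L)
  locus <- if (receptor == "TRB") "TRB" else "IGH"
  sp_tag <- if (species == "human") "" else "m"
  lib <- withr::with_seed(78001 + combos[[key]], {
    list(
      v = build_segment_set(paste0(sp_tag, locus, "V"), nv[[key]],
                            lengths = c(15, 18, 21), first = "tgt",
                            gamma_shape = 1.2),
      d = build_segment_set(paste0(sp_tag, locus, "D"), nd[[key]],
                            lengths = c(6, 9, 12), gamma_shape = 2),
      j = build_segment_set(paste0(sp_tag, locus, "J"), nj[[key]],
                            lengths = c(12, 15, 18), gamma_shape = 1.5)
    )
  })
  .airrnet_env[[key]] <- lib
  lib
}

# Gene universe backing germline_usage() for simulated repertoires.
default_gene_universe <- function(species, receptor) {
  if (is.null(species) || is.null(receptor) ||
      !species %in% c("human", "mouse") || !receptor %in% c("TRB", "IgH")) {
    return(NULL)
  }
  lib <- segment_library(species, receptor)
  list(v = lib$v$gene, d = lib$d$gene, j = lib$j$gene)
}
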