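# 20 standard amino acids, fixed column order for all positional matrices.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# CDR3 amino-acid length range retained for positional analysis.
AA_LENGTH_RANGE <- 8:20

#' Positional amino-acid frequency profile
#'
#' For each CDR3 amino-acid length between 8 and 20 with at least one clone,
#' tabulates an L x 20 matrix of per-position relative amino-acid frequencies
#' over unique junctions. By default each unique sequence counts once,
#' unweighted by clone abundance; set `weight_by_count = TRUE` to weight by
#' `duplicate_count`.
#'
#' @param rep an `airr_repertoire`.
#' @param weight_by_count weight sequences by clonal abundance.
#' @return list of class `airr_aafreq` with elements `freq` (named list of
#'   matrices, one per length) and `n_seq` (sequence counts per length).
#' @export
positional_aa_frequencies <- function(rep, weight_by_count = FALSE) {
  if (weight_by_count) {
    w <- tapply(rep$duplicate_count, rep$junction_aa, sum)
    seqs <- names(w)
    w <- as.numeric(w)
  } else {
    seqs <- unique(rep$junction_aa)
    w <- rep(1, length(seqs))
  }
  lens <- nchar(seqs)
  keep <- lens %in% AA_LENGTH_RANGE
  freq <- list()
  n_seq <- integer(0)
  if (!any(keep)) {
    warn("no clone within the 8-20 aa length range; empty positional profile")
  } else {
    for (L in sort(unique(lens[keep]))) {
      idx <- which(lens == L)
      chars <- matrix(unlist(strsplit(seqs[idx], "")), ncol = L, byrow = TRUE)
      m <- matrix(0, nrow = L, ncol = length(AA_ALPHABET),
                  dimnames = list(NULL, AA_ALPHABET))
      for (pos in seq_len(L)) {
        tab <- tapply(w[idx], factor(chars[, pos], levels = AA_ALPHABET), sum)
        tab[is.na(tab)] <- 0
        m[pos, ] <- tab / sum(tab)
      }
      freq[[as.character(L)]] <- m
      n_seq[as.character(L)] <- length(idx)
    }
  }
  structure(list(freq = freq, n_seq = n_seq), class = "airr_aafreq")
}

#' Similarity between positional amino-acid frequency profiles
#'
#' For each CDR3 length present in both profiles the flattened L x 20
#' frequency matrices are Pearson-correlated (clipped at 0); the unweighted
#' mean over shared lengths is returned. Profiles sharing no length score 0.
#'
#' @param a,b `airr_aafreq` profiles.
#' @return similarity in `[0, 1]`.
#' @export
aa_freq_similarity <- function(a, b) {
  shared <- intersect(names(a$freq), names(b$freq))
  if (length(shared) == 0) {
    warn("no shared CDR3 length between positional profiles; similarity 0")
    return(0)
  }
  cors <- vapply(shared, function(L) {
    clipped_pearson(as.vector(a$freq[[L]]), as.vector(b$freq[[L]]))
  }, numeric(1))
  mean(cors)
}
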