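#' Gapped k-mer occurrence profile
#'
#' Counts occurrences of gapped nucleotide k-mer pairs (left k-mer, gap g,
#' right k-mer) for all gap sizes `g = 0..m` across the unique nucleotide
#' junctions of the repertoire, and normalizes by the grand total of gapped
#' k-mers found across all gap sizes (so short-gap pairs, being more
#' numerous, carry more weight). Pairs containing characters outside
#' `{a,c,g,t}` are dropped. Sequences shorter than `2k` contribute nothing.
#'
#' @param rep an `airr_repertoire`.
#' @param k k-mer length (default 3).
#' @param m maximal gap size (default 3).
#' @param weight_by_count weight sequences by clonal abundance instead of
#'   counting each unique junction once.
#' @return named numeric vector of class `airr_kmer` (keys
#'   `"left.gap.right"`), frequencies summing to 1; empty when no pair exists.
#' @export
#' @examples
#' # a single 6-nt junction yields one gapped pair at gap 0
gapped_kmer_profile <- function(rep, k = 3, m = 3, weight_by_count = FALSE) {
  if (weight_by_count) {
    w <- tapply(rep$duplicate_count, rep$junction, sum)
    seqs <- names(w)
    w <- as.numeric(w)
  } else {
    seqs <- unique(rep$junction)
    w <- rep(1, length(seqs))
  }
  counts <- count_gapped_kmers(seqs, w, k = k, m = m)
  if (length(counts) == 0) {
    warn("no gapped k-mer pair found (all sequences shorter than 2k?)")
    prof <- stats::setNames(numeric(0), character(0))
  } else {
    prof <- counts / sum(counts)
  }
  structure(prof, class = "airr_kmer", k = k, m = m)
}

# Weighted gapped k-mer pair counts over a set of sequences.
count_gapped_kmers <- function(seqs, w, k = 3, m = 3) {
  lens <- nchar(seqs)
  key_acc <- list()
  wt_acc <- list()
  maxL <- if (length(lens)) max(lens) else 0
  for (g in 0:m) {
    span <- 2 * k + g
    if (maxL < span) next
    for (start in seq_len(maxL - span + 1)) {
      idx <- which(lens >= start + span - 1)
      if (length(idx) == 0) next
      left <- substr(seqs[idx], start, start + k - 1)
      right <- substr(seqs[idx], start + k + g, start + span - 1)
      ok <- grepl("^[acgt]+$", left) & grepl("^[acgt]+$", right)
      if (!any(ok)) next
      key_acc[[length(key_acc) + 1L]] <- paste0(left[ok], ".", g, ".",
                                                right[ok])
      wt_acc[[length(wt_acc) + 1L]] <- w[idx][ok]
    }
  }
  if (length(key_acc) == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  dt <- data.table::data.table(pair = unlist(key_acc), w = unlist(wt_acc))
  agg <- dt[, list(w = sum(w)), by = "pair"]
  data.table::setorder(agg, pair)
  stats::setNames(agg$w, agg$pair)
}

#' Similarity between gapped k-mer profiles
#'
#' Pearson correlation over the union of keys (absent keys contribute
#' frequency 0), clipped below at 0. If either profile is empty the
#' similarity is 0 (with a warning when both are empty).
#'
#' @param a,b `airr_kmer` profiles.
#' @return similarity in `[0, 1]`.
#' @export
kmer_similarity <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) {
    warn("both gapped k-mer profiles empty; similarity 0")
    return(0)
  }
  if (length(a) == 0 || length(b) == 0) return(0)
  keys <- union(names(a), names(b))
  fill <- function(p) {
    out <- stats::setNames(numeric(length(keys)), keys)
    out[names(p)] <- as.numeric(p)
    out
  }
  clipped_pearson(fill(a), fill(b))
}
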