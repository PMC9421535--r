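#' Clonal overlap (convergence) between two repertoires
#'
#' Clones are defined at 100% identity of the CDR3 amino-acid sequence. The
#' overlap is `|X intersect Y| / min(|X|, |Y|) * 100`, where X and Y are the
#' sets of unique amino-acid junctions; the convergence similarity score is
#' this percentage divided by 100.
#'
#' @param a,b `airr_repertoire` objects (non-empty).
#' @return overlap percentage in `[0, 100]`.
#' @export
#' @examples
#' # |X| = 3, |Y| = 5, |X intersect Y| = 2 -> 66.67
clonal_overlap <- function(a, b) {
  x <- unique(a$junction_aa)
  y <- unique(b$junction_aa)
  if (length(x) == 0 || length(y) == 0) {
    abort("clonal overlap of an empty repertoire is undefined",
          class = "airrnet_empty_repertoire")
  }
  length(intersect(x, y)) / min(length(x), length(y)) * 100
}

#' @rdname clonal_overlap
#' @export
convergence_similarity <- function(a, b) clonal_overlap(a, b) / 100
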