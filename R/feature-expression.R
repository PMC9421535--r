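#' Gene-expression similarity between samples
#'
#' Applies a low-variation filter (keeps genes whose across-sample standard
#' deviation exceeds `sd_threshold`, default 1), then computes the pairwise
#' Pearson correlation between sample columns, clipped below at 0, with unit
#' diagonal.
#'
#' @param x genes x samples numeric matrix (see [read_expression()]).
#' @param sd_threshold minimal per-gene SD to retain a gene.
#' @return an `airr_similarity` matrix over samples (feature `"expression"`).
#' @export
expression_similarity <- function(x, sd_threshold = 1) {
  stopifnot(is.matrix(x), ncol(x) >= 2)
  sds <- apply(x, 1, stats::sd)
  keep <- x[sds > sd_threshold, , drop = FALSE]
  if (nrow(keep) < 2) {
    abort(sprintf(
      "fewer than 2 genes exceed SD threshold %.3g; lower `sd_threshold`",
      sd_threshold), class = "airrnet_input_error")
  }
  r <- stats::cor(keep)
  r[r < 0] <- 0
  diag(r) <- 1
  new_similarity(r, feature = "expression")
}
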