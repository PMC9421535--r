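#' Hill diversity of a clonal frequency distribution
#'
#' The Hill number of order `alpha` is `(sum p_i^alpha)^(1/(1-alpha))` for
#' `alpha != 1`, with the Shannon limit `exp(-sum p_i log p_i)` at
#' `alpha = 1`. At `alpha = 0` it equals species richness; for large `alpha`
#' it approaches `1 / max(p)`.
#'
#' @param freqs probability vector (non-negative, summing to 1 within 1e-6).
#' @param alpha non-negative order of the diversity index.
#' @return Hill diversity (`>= 1` for any proper distribution).
#' @export
#' @examples
#' hill_diversity(c(0.75, 0.25), 2) # 1 / 0.625 = 1.6
hill_diversity <- function(freqs, alpha) {
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-6) {
    abort("freqs must be a probability vector summing to 1",
          class = "airrnet_input_error")
  }
  stopifnot(is.finite(alpha), alpha >= 0)
  p <- freqs[freqs > 0]
  if (abs(alpha - 1) < 1e-12) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^alpha)^(1 / (1 - alpha))
  }
}

# Shared alpha grid: 0 to 10 in steps of 0.1 (101 points).
evenness_alpha_grid <- function() seq(0, 10, by = 0.1)

#' Evenness profile of a repertoire
#'
#' Hill diversity normalized by richness, evaluated on the alpha grid 0-10 in
#' steps of 0.1 (101 values), computed on nucleotide-level clones with
#' frequencies from `duplicate_count`. At `alpha = 1` this is the Shannon
#' evenness `exp(H)/S`. Values lie in `(0, 1]` and the profile is
#' non-increasing in alpha; a perfectly uniform repertoire gives all 1s.
#'
#' @param rep an `airr_repertoire`.
#' @return tibble of class `airr_evenness` with columns `alpha`, `evenness`.
#' @export
evenness_profile <- function(rep) {
  counts <- tapply(rep$duplicate_count, rep$junction, sum)
  p <- as.numeric(counts) / sum(counts)
  grid <- evenness_alpha_grid()
  if (length(p) == 1) {
    warn("single-clone repertoire: evenness profile is degenerate (all 1)")
    ev <- rep(1, length(grid))
  } else {
    richness <- length(p)
    ev <- vapply(grid, function(a) hill_diversity(p, a) / richness, numeric(1))
  }
  structure(tibble::tibble(alpha = grid, evenness = ev),
            class = c("airr_evenness", class(tibble::tibble())))
}

#' Similarity between two evenness profiles
#'
#' Pearson correlation of the two 101-point evenness vectors, clipped below
#' at 0; identical degenerate (constant) profiles score 1.
#'
#' @param a,b `airr_evenness` profiles on the same alpha grid.
#' @return similarity in `[0, 1]`.
#' @export
diversity_similarity <- function(a, b) {
  stopifnot(identical(a$alpha, b$alpha))
  clipped_pearson(a$evenness, b$evenness)
}
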