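#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a similarity matrix into a long pair table
#'
#' @param x an `airr_similarity` matrix.
#' @param upper_only keep each unordered pair once (upper triangle).
#' @param ... unused.
#' @return tibble with `from`, `to`, `feature`, `similarity`.
#' @export
tidy.airr_similarity <- function(x, upper_only = TRUE, ...) {
  ids <- rownames(x)
  idx <- if (upper_only) which(upper.tri(x), arr.ind = TRUE) else
    which(row(x) != col(x), arr.ind = TRUE)
  tibble::tibble(from = ids[idx[, 1]], to = ids[idx[, 2]],
                 feature = attr(x, "feature") %||% NA_character_,
                 similarity = unclass(x)[idx])
}

#' Summarize a similarity matrix
#'
#' @param x an `airr_similarity` matrix.
#' @param ... unused.
#' @return one-row tibble with the feature label, panel size and off-diagonal
#'   summary statistics.
#' @export
glance.airr_similarity <- function(x, ...) {
  w <- unclass(x)[upper.tri(x)]
  tibble::tibble(feature = attr(x, "feature") %||% NA_character_,
                 n_repertoires = nrow(x),
                 mean_similarity = mean(w),
                 min_similarity = min(w),
                 max_similarity = max(w))
}

#' Tidy an evenness profile
#'
#' @param x an `airr_evenness` profile.
#' @param ... unused.
#' @export
tidy.airr_evenness <- function(x, ...) tibble::as_tibble(x)
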