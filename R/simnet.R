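# Feature labels understood by the matrix builders.
REPERTOIRE_FEATURES <- c("germline", "diversity", "aa_freq", "architecture",
                         "convergence", "kmer")

#' Construct a similarity-matrix object
#'
#' A similarity matrix is a plain numeric matrix with repertoire ids as
#' dimnames plus the feature label and optional panel metadata as
#' attributes. Exposed so additional features (beyond the built-in six and
#' the expression feature) can be condensed into the composite network.
#'
#' @param m symmetric numeric matrix in `[0, 1]` with id dimnames.
#' @param feature feature label.
#' @param meta optional metadata tibble (columns `repertoire_id`, `species`,
#'   `receptor`, `cohort`).
#' @param extra internal: condensation bookkeeping.
#' @return an `airr_similarity` object.
#' @export
new_similarity <- function(m, feature, meta = NULL, extra = list()) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  structure(m, class = c("airr_similarity", "matrix", "array"),
            feature = feature, meta = meta, method = extra$method %||% NULL,
            features = extra$features %||% NULL)
}

#' @export
print.airr_similarity <- function(x, ...) {
  cat(sprintf("<airr_similarity> feature '%s', %d repertoires\n",
              attr(x, "feature"), nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))),
                   drop = FALSE])
  invisible(x)
}

#' Compute per-repertoire feature profiles
#'
#' Precomputes the per-repertoire summaries each feature's similarity score is
#' based on: evenness profile (diversity), positional amino-acid frequencies,
#' LD=1 network architecture summary, unique amino-acid junction set
#' (convergence), germline usage vectors, and the gapped k-mer profile.
#'
#' @param rep an `airr_repertoire`.
#' @param features subset of
#'   `c("germline","diversity","aa_freq","architecture","convergence","kmer")`.
#' @param universe optional germline gene universe, see [germline_usage()].
#' @param k,m gapped k-mer parameters.
#' @return named list of profiles (class `airr_profiles`).
#' @export
repertoire_profiles <- function(rep, features = REPERTOIRE_FEATURES,
                                universe = NULL, k = 3, m = 3) {
  features <- match.arg(features, REPERTOIRE_FEATURES, several.ok = TRUE)
  out <- list()
  if ("diversity" %in% features) out$diversity <- evenness_profile(rep)
  if ("aa_freq" %in% features) out$aa_freq <- positional_aa_frequencies(rep)
  if ("architecture" %in% features) {
    out$architecture <- architecture_summary(
      build_ld1_network(unique(rep$junction_aa)))
  }
  if ("convergence" %in% features) {
    out$convergence <- unique(rep$junction_aa)
  }
  if ("germline" %in% features) {
    out$germline <- germline_usage(rep, universe = universe)
  }
  if ("kmer" %in% features) out$kmer <- gapped_kmer_profile(rep, k = k, m = m)
  structure(out, class = "airr_profiles", meta = rep_metadata(rep))
}

# Pairwise similarity between two precomputed profile sets for one feature.
profile_similarity <- function(pa, pb, feature,
                               weights = c(v = 1, d = 1, j = 1, vj = 0)) {
  switch(feature,
    diversity = diversity_similarity(pa$diversity, pb$diversity),
    aa_freq = aa_freq_similarity(pa$aa_freq, pb$aa_freq),
    architecture = architecture_similarity(pa$architecture, pb$architecture),
    convergence = {
      x <- pa$convergence
      y <- pb$convergence
      length(intersect(x, y)) / min(length(x), length(y))
    },
    germline = germline_similarity(pa$germline, pb$germline,
                                   weights = weights),
    kmer = kmer_similarity(pa$kmer, pb$kmer),
    abort(sprintf("unknown feature '%s'", feature)))
}

#' Per-feature similarity matrices over a panel of repertoires
#'
#' Evaluates every repertoire pair with each feature's similarity operation,
#' yielding one n x n symmetric matrix in `[0, 1]` per feature with unit
#' diagonal. A pair raising a feature error scores 0 for that cell (the
#' degenerate contract), with a warning naming the pair.
#'
#' @param reps list of `airr_repertoire` objects (length >= 2); names are
#'   used as repertoire ids (defaulting to each repertoire's metadata id).
#' @inheritParams repertoire_profiles
#' @param weights germline component weights, see [germline_similarity()].
#' @return named list of `airr_similarity` matrices.
#' @export
feature_matrices <- function(reps, features = REPERTOIRE_FEATURES,
                             universe = NULL, k = 3, m = 3,
                             weights = c(v = 1, d = 1, j = 1, vj = 0)) {
  stopifnot(length(reps) >= 2)
  features <- match.arg(features, REPERTOIRE_FEATURES, several.ok = TRUE)
  meta <- purrr::map_dfr(reps, rep_metadata)
  ids <- names(reps) %||% meta$repertoire_id
  if (is.null(names(reps))) names(reps) <- ids
  meta$repertoire_id <- ids
  profiles <- purrr::map(reps, repertoire_profiles, features = features,
                         universe = universe, k = k, m = m)
  n <- length(reps)
  out <- purrr::map(features, function(f) {
    mat <- diag(nrow = n)
    dimnames(mat) <- list(ids, ids)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        val <- tryCatch(
          profile_similarity(profiles[[i]], profiles[[j]], f,
                             weights = weights),
          error = function(e) {
            warn(sprintf("feature '%s' failed for pair (%s, %s): %s",
                         f, ids[i], ids[j], conditionMessage(e)))
            0
          })
        mat[i, j] <- mat[j, i] <- val
      }
    }
    new_similarity(mat, feature = f, meta = meta)
  })
  stats::setNames(out, features)
}

#' @rdname feature_matrices
#' @param feature a single feature label.
#' @export
feature_matrix <- function(reps, feature, universe = NULL, k = 3, m = 3,
                           weights = c(v = 1, d = 1, j = 1, vj = 0)) {
  feature_matrices(reps, features = feature, universe = universe, k = k,
                   m = m, weights = weights)[[feature]]
}

#' Condense per-feature similarity matrices into a composite network
#'
#' Cellwise aggregation (default: arithmetic mean) of the per-feature
#' similarity matrices into a single composite similarity matrix. `min` and
#' `max` condensation are available as alternatives, and for any input
#' `min <= mean <= max` holds cellwise.
#'
#' @param matrices named list of `airr_similarity` matrices sharing id order.
#' @param method one of `"mean"`, `"max"`, `"min"`.
#' @return composite `airr_similarity` matrix (feature `"composite"`).
#' @export
condense <- function(matrices, method = c("mean", "max", "min")) {
  method <- match.arg(method)
  stopifnot(length(matrices) >= 1)
  ids <- rownames(matrices[[1]])
  for (m in matrices) {
    if (!identical(rownames(m), ids)) {
      abort("similarity matrices do not share repertoire id order",
            class = "airrnet_input_error")
    }
  }
  arr <- simplify2array(lapply(matrices, unclass))
  agg <- switch(method,
                mean = apply(arr, c(1, 2), mean),
                max = apply(arr, c(1, 2), max),
                min = apply(arr, c(1, 2), min))
  dimnames(agg) <- list(ids, ids)
  labels <- purrr::map_chr(matrices, ~ attr(.x, "feature") %||% "feature")
  new_similarity(agg, feature = "composite",
                 meta = attr(matrices[[1]], "meta"),
                 extra = list(method = method, features = unname(labels)))
}

#' Threshold a similarity network to its top edges
#'
#' Keeps the upper-triangle edges whose weight is at least the
#' `(1 - top_fraction)` linear-interpolation quantile of the off-diagonal
#' upper-triangle weights; ties at the quantile are all kept, so the edge set
#' at a smaller fraction is nested inside the one at a larger fraction.
#'
#' @param m an `airr_similarity` matrix.
#' @param top_fraction fraction of top edge weights to keep (e.g. 0.25, 0.5,
#'   0.75; 1 keeps the complete graph).
#' @return tibble with columns `from`, `to`, `weight`.
#' @export
threshold_edges <- function(m, top_fraction) {
  stopifnot(nrow(m) >= 2, top_fraction > 0, top_fraction <= 1)
  ids <- rownames(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- unclass(m)[ut]
  thr <- stats::quantile(w, probs = 1 - top_fraction, type = 7, names = FALSE)
  keep <- w >= thr
  tibble::tibble(from = ids[ut[keep, 1]], to = ids[ut[keep, 2]],
                 weight = w[keep])
}

#' Local similarity of repertoires within a subgraph
#'
#' The node strength of each repertoire within the subgraph (sum of edge
#' weights to the other subgraph members) divided by the sum of all node
#' strengths; local similarities over a subgraph sum to 1. The scaled value
#' divides additionally by the subgraph size so values are comparable across
#' subgraphs of different size.
#'
#' @param m an `airr_similarity` matrix.
#' @param ids subgraph member ids (subset of the matrix ids, length >= 2).
#' @return tibble of class `airr_local` with columns `id`, `strength`,
#'   `local`, `scaled`.
#' @export
local_similarity <- function(m, ids = rownames(m)) {
  stopifnot(length(ids) >= 2)
  if (!all(ids %in% rownames(m))) {
    abort("subgraph ids not all present in the similarity matrix",
          class = "airrnet_input_error")
  }
  sub <- unclass(m)[ids, ids, drop = FALSE]
  diag(sub) <- 0
  strength <- unname(rowSums(sub))
  tot <- sum(strength)
  if (tot <= 0) {
    abort("degenerate subgraph: all node strengths are 0",
          class = "airrnet_input_error")
  }
  structure(tibble::tibble(id = ids, strength = strength,
                           local = strength / tot,
                           scaled = strength / tot / length(ids)),
            class = c("airr_local", class(tibble::tibble())))
}

#' Most representative repertoire of a cohort
#'
#' Returns the cohort member with maximal local similarity (ties broken by
#' lexicographic id, deterministically).
#'
#' @inheritParams local_similarity
#' @export
reference_repertoire <- function(m, ids = rownames(m)) {
  ls <- local_similarity(m, ids)
  best <- ls$id[ls$local >= max(ls$local) - .EQ_TOL]
  sort(best)[1]
}

#' Per-feature similarity of query repertoires to a reference
#'
#' Looks up, for each query, its similarity to the reference repertoire in
#' every per-feature matrix, yielding the table behind radar-style one-to-many
#' comparisons.
#'
#' @param matrices named list of `airr_similarity` matrices.
#' @param ref reference repertoire id.
#' @param query_ids query ids (default: all non-reference ids).
#' @return tibble with `query` and one column per feature.
#' @export
compare_to_reference <- function(matrices, ref,
                                 query_ids = setdiff(rownames(matrices[[1]]),
                                                     ref)) {
  ids <- rownames(matrices[[1]])
  unknown <- setdiff(c(ref, query_ids), ids)
  if (length(unknown) > 0) {
    abort(sprintf("unknown repertoire id(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "airrnet_input_error")
  }
  cols <- purrr::map(matrices, ~ unname(unclass(.x)[query_ids, ref]))
  dplyr::bind_cols(tibble::tibble(query = query_ids),
                   tibble::as_tibble(cols))
}
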