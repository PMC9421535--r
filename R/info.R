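#' Normalized mutual information (redundancy) between two feature vectors
#'
#' Each vector is discretized by equal-frequency binning with
#' `floor(n^(1/3))` bins (minimum 2); the plug-in mutual information
#' `I(X;Y) = H(X) + H(Y) - H(X,Y)` of the joint histogram is divided by
#' `H(X) + H(Y)` (with `0/0` defined as 0). Under this normalizer the
#' redundancy of a variable with itself is 0.5, the effective maximum; 0
#' indicates independence. The estimate is symmetric in its arguments and
#' invariant under strictly monotone transforms.
#'
#' @param x,y numeric vectors of equal length (>= 10).
#' @param bins number of bins; default `max(2, floor(n^(1/3)))`.
#' @return one-row tibble of class `airr_mi` with columns `nmi`, `bins`, `n`.
#' @export
#' @examples
#' normalized_mi(1:100, (1:100)^2)$nmi # 0.5: identical after ranking
normalized_mi <- function(x, y, bins = NULL) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "airrnet_input_error")
  }
  n <- length(x)
  stopifnot(n >= 10)
  if (is.null(bins)) bins <- max(2L, floor(n^(1 / 3)))
  bx <- equal_freq_bin(x, bins)
  by <- equal_freq_bin(y, bins)
  hx <- plugin_entropy(table(bx))
  hy <- plugin_entropy(table(by))
  hxy <- plugin_entropy(table(bx, by))
  mi <- max(0, hx + hy - hxy)
  nmi <- if (hx + hy <= 0) 0 else mi / (hx + hy)
  structure(tibble::tibble(nmi = nmi, bins = as.integer(bins), n = n),
            class = c("airr_mi", class(tibble::tibble())))
}

# Equal-frequency discretization: breaks at interpolated quantiles.
equal_freq_bin <- function(x, bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               type = 7, names = FALSE))
  if (length(br) <= 2) {
    return(rep(1L, length(x)))
  }
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

plugin_entropy <- function(tab) {
  p <- as.numeric(tab) / sum(tab)
  p <- p[p > 0]
  -sum(p * log(p))
}

# Upper-triangle off-diagonal cells of a similarity matrix, in fixed order,
# with the mask of cross-species/receptor (zero-by-definition) pairs.
upper_cells <- function(m) {
  ut <- which(upper.tri(m), arr.ind = TRUE)
  vals <- unclass(m)[ut]
  meta <- attr(m, "meta")
  mask <- rep(FALSE, nrow(ut))
  if (!is.null(meta)) {
    sp <- meta$species[match(rownames(m), meta$repertoire_id)]
    rc <- meta$receptor[match(rownames(m), meta$repertoire_id)]
    mask <- sp[ut[, 1]] != sp[ut[, 2]] | rc[ut[, 1]] != rc[ut[, 2]]
  }
  list(values = vals, cross = mask)
}

#' Pairwise normalized mutual information between repertoire features
#'
#' For each pair of per-feature similarity matrices, the feature vectors are
#' the upper-triangle off-diagonal cells. Cells that are zero by definition in
#' the germline feature (cross-species or cross-receptor repertoire pairs)
#' are excluded from all features' vectors before estimation.
#'
#' @param matrices named list of `airr_similarity` matrices sharing id order.
#' @param exclude_cross_cells drop cross-species/receptor cells.
#' @return tibble with `feature_a`, `feature_b`, `nmi`, `bins`, `n_pairs`
#'   covering all ordered feature pairs (symmetric).
#' @export
feature_mi_matrix <- function(matrices, exclude_cross_cells = TRUE) {
  labs <- names(matrices) %||%
    purrr::map_chr(matrices, ~ attr(.x, "feature"))
  cells <- stats::setNames(purrr::map(matrices, upper_cells), labs)
  keep <- !cells[[1]]$cross
  if (!exclude_cross_cells) keep <- rep(TRUE, length(keep))
  if (sum(keep) < 10) {
    abort("fewer than 10 usable repertoire pairs for mutual information",
          class = "airrnet_input_error")
  }
  grid <- tidyr::expand_grid(feature_a = labs, feature_b = labs)
  grid$nmi <- NA_real_
  grid$bins <- NA_integer_
  grid$n_pairs <- sum(keep)
  for (r in seq_len(nrow(grid))) {
    a <- cells[[grid$feature_a[r]]]$values[keep]
    b <- cells[[grid$feature_b[r]]]$values[keep]
    est <- normalized_mi(a, b)
    grid$nmi[r] <- est$nmi
    grid$bins[r] <- est$bins
  }
  structure(grid, class = c("airr_mi_table", class(tibble::tibble())))
}

#' Feature-sufficiency curve
#'
#' Quantifies the diminishing information gained by adding features: for each
#' step `n -> n+1` and each of `n_perm` random feature orderings, the mean
#' absolute cellwise change of the mean-composite similarity matrix when the
#' `(n+1)`-th feature is appended, averaged over permutations. A saturating
#' (non-increasing) curve indicates that additional features add increasingly
#' less information.
#'
#' @param matrices named list of `airr_similarity` matrices sharing id order.
#' @param n_perm number of random feature orderings per step (default 500).
#' @param seed RNG seed for reproducibility.
#' @return tibble of class `airr_sufficiency` with columns `step` (the n of
#'   `n -> n+1`), `mean_abs_change`, `n_perm`, `seed`.
#' @export
sufficiency_analysis <- function(matrices, n_perm = 500, seed = NULL) {
  stopifnot(length(matrices) >= 2, n_perm > 0)
  nf <- length(matrices)
  vecs <- vapply(matrices, function(m) upper_cells(m)$values,
                 numeric(sum(upper.tri(matrices[[1]]))))
  steps <- seq_len(nf - 1)
  acc <- matrix(0, nrow = n_perm, ncol = length(steps))
  with_seed_or_current(seed, {
    for (p in seq_len(n_perm)) {
      ord <- sample.int(nf)
      run <- vecs[, ord, drop = FALSE]
      cum <- apply(run, 1, cumsum)  # nf x cells
      means <- sweep(cum, 1, seq_len(nf), "/")
      for (s in steps) {
        acc[p, s] <- mean(abs(means[s + 1, ] - means[s, ]))
      }
    }
  })
  structure(tibble::tibble(step = steps,
                           mean_abs_change = colMeans(acc),
                           n_perm = n_perm,
                           seed = seed %||% NA_integer_),
            class = c("airr_sufficiency", class(tibble::tibble())))
}
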