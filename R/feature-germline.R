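#' Germline V(D)J gene usage profile
#'
#' Relative frequencies of V, D and J germline genes across clones (each
#' clone counted once) over the gene universe of the species/receptor, plus
#' VJ pairing frequencies over the V x J product space. Allele suffixes
#' (`*01`) are stripped for usage counting. Genes in the universe but absent
#' from the repertoire carry frequency 0; genes observed but missing from a
#' supplied universe are added with a warning. Clones without a D annotation
#' are dropped from the D vector only.
#'
#' @param rep an `airr_repertoire`.
#' @param universe optional list with character vectors `v`, `d`, `j` naming
#'   the gene universe (allele-stripped). Defaults to the bundled synthetic
#'   universe for the repertoire's species/receptor when available, otherwise
#'   to the genes observed in the repertoire.
#' @return list of class `airr_germline` with frequency vectors `v`, `d`,
#'   `j`, `vj` and the repertoire's `species` and `receptor`.
#' @export
germline_usage <- function(rep, universe = NULL) {
  strip <- function(x) sub("\\*.*$", "", x)
  v <- strip(rep$v_call)
  d <- strip(rep$d_call)
  j <- strip(rep$j_call)
  d <- d[!is.na(d) & d != ""]
  if (is.null(universe)) {
    universe <- default_gene_universe(attr(rep, "species"),
                                      attr(rep, "receptor"))
  }
  if (is.null(universe)) {
    universe <- list(v = sort(unique(v)), d = sort(unique(d)),
                     j = sort(unique(j)))
  } else {
    for (seg in c("v", "d", "j")) {
      obs <- switch(seg, v = v, d = d, j = j)
      unknown <- setdiff(unique(obs), universe[[seg]])
      if (length(unknown) > 0) {
        warn(sprintf("gene(s) not in %s universe added: %s", toupper(seg),
                     paste(unknown, collapse = ", ")))
        universe[[seg]] <- sort(c(universe[[seg]], unknown))
      }
    }
  }
  freq_over <- function(obs, genes) {
    if (length(genes) == 0 || length(obs) == 0) {
      return(stats::setNames(numeric(length(genes)), genes))
    }
    tab <- table(factor(obs, levels = genes))
    as.numeric(tab) / length(obs) -> f
    stats::setNames(f, genes)
  }
  vj_obs <- paste(v, j, sep = "|")
  vj_universe <- as.vector(outer(universe$v, universe$j, paste, sep = "|"))
  structure(list(
    v = freq_over(v, universe$v),
    d = freq_over(d, universe$d),
    j = freq_over(j, universe$j),
    vj = freq_over(vj_obs, vj_universe),
    species = attr(rep, "species"),
    receptor = attr(rep, "receptor")
  ), class = "airr_germline")
}

#' Similarity between germline usage profiles
#'
#' Weighted mean of the clipped Pearson correlations of the V, D, J (and VJ
#' pairing) frequency vectors, with default weights `c(v=1, d=1, j=1, vj=0)`.
#' Pairs from different species or receptors score 0 by definition.
#' Components empty on either side are dropped and the weights renormalized.
#'
#' @param a,b `airr_germline` profiles.
#' @param weights named non-negative weights for `v`, `d`, `j`, `vj`.
#' @return similarity in `[0, 1]`.
#' @export
germline_similarity <- function(a, b,
                                weights = c(v = 1, d = 1, j = 1, vj = 0)) {
  stopifnot(all(weights >= 0), any(weights > 0))
  if (!identical(a$species, b$species) || !identical(a$receptor, b$receptor)) {
    return(0)
  }
  align <- function(x, y) {
    genes <- union(names(x), names(y))
    fill <- function(v) {
      out <- stats::setNames(numeric(length(genes)), genes)
      out[names(v)] <- v
      out
    }
    list(fill(x), fill(y))
  }
  comps <- numeric(0)
  used_w <- numeric(0)
  for (seg in names(weights)) {
    if (weights[[seg]] <= 0) next
    if (length(a[[seg]]) == 0 || length(b[[seg]]) == 0) next
    al <- align(a[[seg]], b[[seg]])
    comps <- c(comps, clipped_pearson(al[[1]], al[[2]]))
    used_w <- c(used_w, weights[[seg]])
  }
  if (length(comps) == 0) {
    abort("no non-empty germline component with positive weight",
          class = "airrnet_input_error")
  }
  sum(comps * used_w) / sum(used_w)
}
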