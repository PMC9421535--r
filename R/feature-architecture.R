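#' Build the Levenshtein-distance-1 sequence similarity network
#'
#' Nodes are unique amino-acid CDR3 sequences; an undirected edge connects two
#' sequences iff their Levenshtein distance is exactly 1 (one substitution,
#' insertion, or deletion). Edges are found by deletion-variant hashing: two
#' equal-length strings differing at exactly one position share the deletion
#' variant obtained by deleting that position, and an insertion/deletion pair
#' is detected when a deletion variant of the longer string equals the shorter
#' string. This is edge-identical to all-pairs Levenshtein comparison.
#'
#' @param sequences character vector of unique, non-empty amino-acid strings.
#' @return an [igraph::graph] with vertex names equal to `sequences`.
#' @export
#' @examples
#' igraph::ecount(build_ld1_network(c("CARW", "CARY", "CTRW"))) # 2
build_ld1_network <- function(sequences) {
  stopifnot(length(sequences) >= 1, !anyDuplicated(sequences),
            all(nchar(sequences) > 0))
  n <- length(sequences)
  lens <- nchar(sequences)
  maxL <- max(lens)
  rows <- vector("list", maxL)
  for (pos in seq_len(maxL)) {
    idx <- which(lens >= pos)
    if (length(idx) == 0) next
    s <- sequences[idx]
    rows[[pos]] <- data.table::data.table(
      variant = paste0(substr(s, 1, pos - 1), substr(s, pos + 1, lens[idx])),
      id = idx, pos = pos, len = lens[idx])
  }
  dt <- data.table::rbindlist(rows)
  # substitutions: same deletion variant at the same position, same length
  sub <- dt[dt, on = c("variant", "pos", "len"), allow.cartesian = TRUE,
            .(a = x.id, b = i.id)]
  sub <- sub[sub$a < sub$b, ]
  # single insertion/deletion: a deletion variant equals another sequence
  seqdt <- data.table::data.table(variant = sequences, sid = seq_len(n))
  indel <- dt[seqdt, on = "variant", nomatch = NULL, .(a = x.id, b = i.sid)]
  indel <- unique(data.table::data.table(a = pmin(indel$a, indel$b),
                                         b = pmax(indel$a, indel$b)))
  edges <- unique(data.table::rbindlist(list(sub, indel)))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = sequences)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$a, edges$b))
  }
  g
}

#' Summarize the architecture of a sequence-similarity network
#'
#' Four summaries: (i) the cumulative degree distribution over degrees
#' `0..maxdeg`; (ii) the mean hub centrality score (principal-eigenvector
#' scores computed once on the whole graph and normalized to max 1 — the
#' Kleinberg hub score for symmetric graphs; defined as all-0 on an edgeless
#' graph); (iii) the fraction of nodes in singleton components; and (iv) the
#' fraction of nodes in the largest connected component.
#'
#' @param graph an igraph object with at least one node.
#' @return list of class `airr_architecture` with elements `cum_degree`,
#'   `mean_hub_score`, `frac_unconnected`, `frac_largest`.
#' @export
architecture_summary <- function(graph) {
  n <- igraph::vcount(graph)
  stopifnot(n >= 1)
  deg <- igraph::degree(graph)
  maxdeg <- max(deg)
  cum_degree <- vapply(0:maxdeg, function(d) mean(deg <= d), numeric(1))
  names(cum_degree) <- 0:maxdeg
  hubs <- ld1_hub_scores(graph)
  comps <- igraph::components(graph)
  sizes <- comps$csize
  structure(list(
    cum_degree = cum_degree,
    mean_hub_score = mean(hubs),
    frac_unconnected = sum(sizes[sizes == 1]) / n,
    frac_largest = max(sizes) / n
  ), class = "airr_architecture")
}

# Hub centrality scores: the principal (Perron-Frobenius) eigenvector of the
# adjacency matrix, max-normalized — for a symmetric graph this equals the
# Kleinberg hub score wherever the HITS iteration is well defined. Computed
# by power iteration on A + I from a uniform start, which is deterministic
# even on bipartite components where the plain HITS eigenproblem is
# degenerate (ARPACK-based solvers return run-dependent vectors there).
# Edgeless graphs score 0 everywhere by convention.
ld1_hub_scores <- function(graph, tol = 1e-12, max_iter = 2000) {
  n <- igraph::vcount(graph)
  nm <- igraph::V(graph)$name %||% as.character(seq_len(n))
  if (igraph::ecount(graph) == 0) {
    return(stats::setNames(rep(0, n), nm))
  }
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  x <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    y <- x + as.numeric(A %*% x)
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < tol) {
      x <- y
      break
    }
    x <- y
  }
  stats::setNames(x / max(x), nm)
}

#' Similarity between two network-architecture summaries
#'
#' Mean of four components: Pearson correlation (clipped at 0) of the
#' cumulative degree distributions evaluated on the union degree support
#' (shorter distribution padded with trailing 1s), and `1 - |difference|` for
#' mean hub score, fraction unconnected, and fraction in the largest
#' component.
#'
#' @param a,b `airr_architecture` summaries.
#' @return similarity in `[0, 1]`.
#' @export
architecture_similarity <- function(a, b) {
  k <- max(length(a$cum_degree), length(b$cum_degree))
  pad <- function(v) c(v, rep(1, k - length(v)))
  comp1 <- clipped_pearson(pad(unname(a$cum_degree)),
                           pad(unname(b$cum_degree)))
  comp2 <- 1 - abs(a$mean_hub_score - b$mean_hub_score)
  comp3 <- 1 - abs(a$frac_unconnected - b$frac_unconnected)
  comp4 <- 1 - abs(a$frac_largest - b$frac_largest)
  mean(c(comp1, comp2, comp3, comp4))
}
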