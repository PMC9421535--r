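#' Configuration for the synthetic repertoire generator
#'
#' Captures the full parameterization of one simulated repertoire: species
#' and receptor (selecting the synthetic segment library), the number of
#' unique clones to generate, the clone-count power-law exponent controlling
#' clonal expansion, multiplicative log-normal noise on germline segment
#' frequencies, junctional insertion/deletion switches, the three
#' post-simulation perturbations (motif implantation, hub deletion,
#' synonymous-codon swap), the subsampling depth, and the seed.
#'
#' @param species,receptor segment library selector (`"human"`/`"mouse"`,
#'   `"TRB"`/`"IgH"`).
#' @param n_sequences number of unique clones to simulate (default 12,000).
#' @param clone_count_alpha power-law exponent of the clone-count
#'   distribution; larger values give steeper clonal expansion and lower
#'   evenness.
#' @param germline_noise_sd SD of the multiplicative log-normal perturbation
#'   applied to segment frequencies (0 disables).
#' @param insertions,deletions enable junctional N1/N2 insertions and
#'   geometric segment trimming.
#' @param motif_implants named numeric vector: names are nucleotide motifs
#'   (length divisible by 3), values the per-clone implantation probability.
#' @param hub_deletion_fraction fraction of top hub-score sequences to remove
#'   post-simulation (in `[0, 1)`).
#' @param codon_swap_fraction fraction of clones receiving synonymous codon
#'   swaps post-simulation (in `[0, 1]`).
#' @param subsample_to top-clone subsampling depth applied last
#'   (default 10,000).
#' @param seed integer RNG seed.
#' @param label optional repertoire id stem.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(species = "human", receptor = "TRB",
                       n_sequences = 12000, clone_count_alpha = 1,
                       germline_noise_sd = 0, insertions = TRUE,
                       deletions = TRUE, motif_implants = NULL,
                       hub_deletion_fraction = 0, codon_swap_fraction = 0,
                       subsample_to = 10000, seed = 1, label = NULL) {
  cfg <- list(species = species, receptor = receptor,
              n_sequences = as.integer(n_sequences),
              clone_count_alpha = clone_count_alpha,
              germline_noise_sd = germline_noise_sd,
              insertions = isTRUE(insertions), deletions = isTRUE(deletions),
              motif_implants = motif_implants,
              hub_deletion_fraction = hub_deletion_fraction,
              codon_swap_fraction = codon_swap_fraction,
              subsample_to = as.integer(subsample_to),
              seed = as.integer(seed), label = label)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) abort(sprintf("invalid sim_config field '%s': %s", field, msg),
                   class = "airrnet_config_error")
  }
  chk(cfg$species %in% c("human", "mouse"), "species", "must be human/mouse")
  chk(cfg$receptor %in% c("TRB", "IgH"), "receptor", "must be TRB/IgH")
  chk(cfg$n_sequences >= 1, "n_sequences", "must be positive")
  chk(is.numeric(cfg$clone_count_alpha) && cfg$clone_count_alpha >= 0,
      "clone_count_alpha", "must be >= 0")
  chk(cfg$germline_noise_sd >= 0, "germline_noise_sd", "must be >= 0")
  if (!is.null(cfg$motif_implants)) {
    chk(all(nchar(names(cfg$motif_implants)) %% 3 == 0), "motif_implants",
        "motif lengths must be divisible by 3")
    chk(all(cfg$motif_implants >= 0 & cfg$motif_implants <= 1),
        "motif_implants", "probabilities must be in [0, 1]")
  }
  chk(cfg$hub_deletion_fraction >= 0 && cfg$hub_deletion_fraction < 1,
      "hub_deletion_fraction", "must be in [0, 1)")
  chk(cfg$codon_swap_fraction >= 0 && cfg$codon_swap_fraction <= 1,
      "codon_swap_fraction", "must be in [0, 1]")
  chk(cfg$subsample_to >= 1, "subsample_to", "must be positive")
  invisible(cfg)
}

# Random a/c/g/t strings of the given lengths (vectorized).
random_nt_strings <- function(lens) {
  out <- character(length(lens))
  tot <- sum(lens)
  if (tot > 0) {
    chars <- sample(c("a", "c", "g", "t"), tot, replace = TRUE)
    out[lens > 0] <- vapply(split(chars, rep(seq_along(lens), lens)),
                            paste0, character(1), collapse = "")
  }
  out
}

# One batch of candidate clones under the (already noise-perturbed) segment
# frequencies. Junction = trimmed 3' V + N1 + trimmed D + N2 + trimmed 5' J,
# frame-corrected to a multiple of 3.
draw_clone_batch <- function(n, lib, fv, fd, fj, insertions, deletions,
                             ins_p = 0.25, ins_cap = 12, trim_p = 0.3) {
  vi <- sample.int(nrow(lib$v), n, replace = TRUE, prob = fv)
  di <- sample.int(nrow(lib$d), n, replace = TRUE, prob = fd)
  ji <- sample.int(nrow(lib$j), n, replace = TRUE, prob = fj)
  vfrag <- lib$v$frag[vi]
  dfrag <- lib$d$frag[di]
  jfrag <- lib$j$frag[ji]
  vl <- nchar(vfrag)
  dl <- nchar(dfrag)
  jl <- nchar(jfrag)
  if (deletions) {
    vtrim <- pmin(stats::rgeom(n, trim_p), vl - 3)
    d5 <- pmin(stats::rgeom(n, trim_p), dl)
    d3 <- pmin(stats::rgeom(n, trim_p), dl - d5)
    jtrim <- pmin(stats::rgeom(n, trim_p), jl - 3)
  } else {
    vtrim <- d5 <- d3 <- jtrim <- rep(0L, n)
  }
  vpart <- substr(vfrag, 1, vl - vtrim)
  dpart <- substr(dfrag, 1 + d5, dl - d3)
  jpart <- substr(jfrag, 1 + jtrim, jl)
  if (insertions) {
    n1 <- random_nt_strings(pmin(stats::rgeom(n, ins_p), ins_cap))
    n2 <- random_nt_strings(pmin(stats::rgeom(n, ins_p), ins_cap))
  } else {
    n1 <- n2 <- rep("", n)
  }
  head <- paste0(vpart, n1, dpart, n2)
  rem <- (nchar(head) + nchar(jpart)) %% 3
  if (any(rem > 0)) {
    if (insertions) {
      pad <- random_nt_strings(ifelse(rem > 0, 3 - rem, 0))
      head <- paste0(head, pad)
    } else {
      # without insertions, restore frame by trimming the J start further
      jpart <- substr(jpart, 1 + rem, nchar(jpart))
    }
  }
  tibble::tibble(
    junction = paste0(head, jpart),
    v_call = paste0(lib$v$gene[vi], "*01"),
    d_call = paste0(lib$d$gene[di], "*01"),
    j_call = paste0(lib$j$gene[ji], "*01"))
}

#' Simulate a synthetic repertoire
#'
#' Draws V/(D)/J segments per clone from noise-perturbed segment frequencies,
#' assembles nucleotide junctions with geometric trimming (when deletions are
#' enabled) and geometric-length random N1/N2 insertions (when insertions are
#' enabled), redraws clones whose junction translates with a stop codon
#' (batch redraw, capped at 100 rounds), deduplicates to `n_sequences` unique
#' clones, assigns clone counts from a rank-based discrete power law with
#' exponent `clone_count_alpha`, applies any configured post-simulation
#' perturbation (motif implantation, hub deletion, synonymous-codon swap),
#' and finally subsamples to the top `subsample_to` clones. Fully seeded:
#' identical configurations produce identical repertoires.
#'
#' @param cfg a [sim_config()].
#' @return an `airr_repertoire`.
#' @export
simulate_repertoire <- function(cfg) {
  validate_sim_config(cfg)
  lib <- segment_library(cfg$species, cfg$receptor)
  clones <- with_seed_or_current(cfg$seed, {
    fv <- perturb_freq(lib$v$freq, cfg$germline_noise_sd)
    fd <- perturb_freq(lib$d$freq, cfg$germline_noise_sd)
    fj <- perturb_freq(lib$j$freq, cfg$germline_noise_sd)
    acc <- NULL
    for (round in seq_len(100)) {
      need <- cfg$n_sequences - if (is.null(acc)) 0L else nrow(acc)
      if (need <= 0) break
      batch <- draw_clone_batch(ceiling(need * 1.2), lib, fv, fd, fj,
                                cfg$insertions, cfg$deletions)
      batch$junction_aa <- translate_nt(batch$junction)
      batch <- batch[!grepl("*", batch$junction_aa, fixed = TRUE), ,
                     drop = FALSE]
      acc <- rbind(acc, batch)
      acc <- acc[!duplicated(paste(acc$junction, acc$v_call, acc$j_call)), ,
                 drop = FALSE]
    }
    if (nrow(acc) < cfg$n_sequences) {
      abort("failed to generate enough unique stop-free clones",
            class = "airrnet_simulation_error")
    }
    acc <- acc[seq_len(cfg$n_sequences), , drop = FALSE]
    acc$duplicate_count <- power_law_counts(cfg$n_sequences,
                                            cfg$clone_count_alpha)
    acc
  })
  rep <- new_repertoire(clones,
                        repertoire_id = cfg$label %||%
                          sprintf("%s_%s_s%d", cfg$species, cfg$receptor,
                                  cfg$seed),
                        species = cfg$species, receptor = cfg$receptor,
                        cohort = cfg$label %||% "simulated")
  if (!is.null(cfg$motif_implants) && any(cfg$motif_implants > 0)) {
    rep <- implant_motifs(rep, names(cfg$motif_implants),
                          unname(cfg$motif_implants), seed = cfg$seed + 101L)
  }
  if (cfg$hub_deletion_fraction > 0) {
    rep <- remove_hubs(rep, fraction = cfg$hub_deletion_fraction)
  }
  if (cfg$codon_swap_fraction > 0) {
    rep <- synonymous_swap(rep, fraction = cfg$codon_swap_fraction,
                           seed = cfg$seed + 202L)
  }
  subsample_top(rep, n = cfg$subsample_to)
}

# Multiplicative log-normal noise on segment frequencies.
perturb_freq <- function(f, sd) {
  if (sd <= 0) return(f)
  g <- f * exp(stats::rnorm(length(f), 0, sd))
  g / sum(g)
}

# Rank-based discrete power law: count_i proportional to i^(-alpha), scaled
# so the most abundant clone dominates at large alpha and counts stay >= 1.
power_law_counts <- function(n, alpha) {
  p <- seq_len(n)^(-alpha)
  p <- p / sum(p)
  pmax(1L, as.integer(round(p * n * 10)))
}

#' Implant nucleotide motifs into clone junctions
#'
#' Per clone and motif, with the given probability a codon-aligned window of
#' the motif's length at a uniformly chosen codon offset is replaced by the
#' motif (frame preserved); the amino-acid junction is re-translated. Clones
#' shorter than the motif are skipped (counted in attribute
#' `implant_skipped`).
#'
#' @param rep an `airr_repertoire`.
#' @param motifs character vector of nucleotide motifs (length divisible
#'   by 3).
#' @param prob per-clone implantation probability, recycled over motifs.
#' @param seed RNG seed.
#' @return perturbed repertoire with attributes `implant_skipped` and
#'   `implant_count`.
#' @export
implant_motifs <- function(rep, motifs, prob, seed = NULL) {
  stopifnot(all(nchar(motifs) %% 3 == 0), all(prob >= 0 & prob <= 1))
  prob <- rep_len(prob, length(motifs))
  clones <- tibble::as_tibble(rep)
  skipped <- 0L
  implanted <- 0L
  clones <- with_seed_or_current(seed, {
    for (mi in seq_along(motifs)) {
      motif <- tolower(motifs[mi])
      L <- nchar(motif)
      hit <- stats::runif(nrow(clones)) < prob[mi]
      fits <- nchar(clones$junction) >= L
      skipped <- skipped + sum(hit & !fits)
      idx <- which(hit & fits)
      implanted <- implanted + length(idx)
      if (length(idx) == 0) next
      maxoff <- (nchar(clones$junction[idx]) - L) %/% 3
      off <- floor(stats::runif(length(idx)) * (maxoff + 1))
      start <- 3 * off + 1
      j <- clones$junction[idx]
      clones$junction[idx] <- paste0(
        substr(j, 1, start - 1), motif,
        substr(j, start + L, nchar(j)))
    }
    clones
  })
  clones$junction_aa <- translate_nt(clones$junction)
  out <- refresh_repertoire(clones, rep)
  attr(out, "implant_skipped") <- skipped
  attr(out, "implant_count") <- implanted
  out
}

#' Remove the top hub sequences from a repertoire
#'
#' Builds the LD=1 network over unique amino-acid junctions, scores nodes by
#' Kleinberg hub centrality, and removes the `ceiling(fraction * n)`
#' top-scoring sequences (ties broken by lexicographic junction,
#' deterministically) together with all clones carrying them.
#'
#' @param rep an `airr_repertoire`.
#' @param fraction fraction of sequences to remove (default 0.05).
#' @return perturbed repertoire.
#' @export
remove_hubs <- function(rep, fraction = 0.05) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(rep)
  seqs <- unique(rep$junction_aa)
  g <- build_ld1_network(seqs)
  hs <- ld1_hub_scores(g)
  n_rm <- ceiling(fraction * length(seqs))
  ord <- order(-hs, seqs)
  drop_set <- seqs[ord[seq_len(n_rm)]]
  keep <- !rep$junction_aa %in% drop_set
  refresh_repertoire(tibble::as_tibble(rep)[keep, , drop = FALSE], rep)
}

#' Replace codons with synonymous codons in a fraction of clones
#'
#' Uniformly selects `floor(fraction * n)` clones (seeded) and, within each,
#' replaces every codon-aligned occurrence of `tat` by `tac` (Tyr), `agt` by
#' `agc` (Ser) and `gtt` by `gtg` (Val). Amino-acid junctions are unchanged
#' by construction.
#'
#' @param rep an `airr_repertoire`.
#' @param fraction fraction of clones to modify (default 0.5).
#' @param seed RNG seed.
#' @return perturbed repertoire.
#' @export
synonymous_swap <- function(rep, fraction = 0.5, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  k <- floor(fraction * nrow(rep))
  if (k == 0) return(rep)
  clones <- tibble::as_tibble(rep)
  sel <- with_seed_or_current(seed, sample.int(nrow(clones), k))
  swap <- c(tat = "tac", agt = "agc", gtt = "gtg")
  j <- clones$junction[sel]
  codons <- strsplit(gsub("(...)", "\\1 ", j), " ", fixed = TRUE)
  clones$junction[sel] <- vapply(codons, function(cs) {
    hit <- cs %in% names(swap)
    cs[hit] <- swap[cs[hit]]
    paste0(cs, collapse = "")
  }, character(1))
  refresh_repertoire(clones, rep)
}
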