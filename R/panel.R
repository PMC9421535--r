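#' Generate a panel of simulated repertoires
#'
#' Simulates `replicates` repertoires per configuration with derived seeds
#' (the config's base seed plus the replicate index minus one), each
#' subsampled to its `subsample_to` depth. A manifest mapping repertoire ids
#' to configurations, seeds and perturbations is attached as attribute
#' `manifest`.
#'
#' @param configs list of [sim_config()] objects (each should carry a unique
#'   `label`).
#' @param replicates replicates per configuration (default 5).
#' @return named list of `airr_repertoire` objects with a `manifest` tibble
#'   attribute.
#' @export
generate_panel <- function(configs, replicates = 5) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  reps <- list()
  manifest <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    label <- cfg$label %||% sprintf("config%d", ci)
    for (r in seq_len(replicates)) {
      rcfg <- cfg
      rcfg$seed <- cfg$seed + (r - 1L)
      rcfg$label <- sprintf("%s_r%d", label, r)
      rep_i <- simulate_repertoire(rcfg)
      reps[[rcfg$label]] <- rep_i
      manifest[[length(manifest) + 1L]] <- tibble::tibble(
        repertoire_id = rcfg$label, config_label = label, replicate = r,
        species = cfg$species, receptor = cfg$receptor, seed = rcfg$seed,
        n_sequences = cfg$n_sequences,
        clone_count_alpha = cfg$clone_count_alpha,
        germline_noise_sd = cfg$germline_noise_sd,
        insertions = cfg$insertions, deletions = cfg$deletions,
        motif_implants = if (is.null(cfg$motif_implants)) "" else
          paste(names(cfg$motif_implants), cfg$motif_implants,
                sep = ":", collapse = ";"),
        hub_deletion_fraction = cfg$hub_deletion_fraction,
        codon_swap_fraction = cfg$codon_swap_fraction,
        subsample_to = cfg$subsample_to,
        config_hash = config_hash(unclass(cfg)[setdiff(names(cfg),
                                                       c("seed", "label"))]))
    }
  }
  structure(reps, manifest = dplyr::bind_rows(manifest))
}

#' Generate a synthetic gene-expression matrix with known group structure
#'
#' Per-gene baseline means with normal noise; a subset of genes receives
#' group-specific mean shifts of magnitude `effect_size`, producing
#' higher within-group than between-group sample correlation when the effect
#' is large. Intended as a ground-truth fixture for the expression feature.
#'
#' @param n_genes number of genes.
#' @param group_sizes integer vector of samples per group (>= 2 groups).
#' @param effect_size SD of the group-specific mean shifts on affected genes.
#' @param seed RNG seed.
#' @param frac_de fraction of genes with group-specific shifts.
#' @param noise_sd per-observation noise SD.
#' @return genes x samples matrix with a `groups` attribute (sample group
#'   labels).
#' @export
generate_expression <- function(n_genes = 500, group_sizes = c(3, 3),
                                effect_size = 2, seed = NULL, frac_de = 0.3,
                                noise_sd = 1) {
  stopifnot(length(group_sizes) >= 2, all(group_sizes >= 1))
  n_samples <- sum(group_sizes)
  groups <- rep(paste0("group", seq_along(group_sizes)), group_sizes)
  with_seed_or_current(seed, {
    base <- stats::rnorm(n_genes, 8, 2)
    de <- sample.int(n_genes, max(1, round(frac_de * n_genes)))
    shift <- matrix(0, n_genes, length(group_sizes))
    shift[de, ] <- stats::rnorm(length(de) * length(group_sizes),
                                0, effect_size)
    m <- matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                n_genes, n_samples) + base
    for (s in seq_len(n_samples)) {
      m[, s] <- m[, s] + shift[, match(groups[s], unique(groups))]
    }
    dimnames(m) <- list(paste0("gene", seq_len(n_genes)),
                        paste0(groups, "_s", stats::ave(seq_len(n_samples),
                                                        groups,
                                                        FUN = seq_along)))
    structure(m, groups = groups)
  })
}
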