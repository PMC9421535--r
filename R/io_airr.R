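#' Read an AIRR Rearrangement-style TSV into a repertoire
#'
#' Accepts AIRR-community column names as well as common legacy synonyms
#' (`cdr3`, `cdr3_aa`, `vGeneName`, `cloneCount`, ...) via a column-alias map.
#' Rows are standardized (nt junctions lower case, aa junctions upper case)
#' and deduplicated on (`junction`, `v_call`, `j_call`) with duplicate counts
#' summed. Unknown extra columns are carried through untouched.
#'
#' @param path path to a tab-separated rearrangement file. Lines starting with
#'   `#` are ignored.
#' @param repertoire_id,species,receptor,cohort sample metadata.
#' @return an [new_repertoire()] object.
#' @export
read_airr <- function(path, repertoire_id = basename(path),
                      species = "human", receptor = "TRB",
                      cohort = "default") {
  aliases <- list(
    junction = c("junction", "junction_nt", "cdr3", "cdr3_nt", "nseqcdr3",
                 "cdr3nt"),
    junction_aa = c("junction_aa", "cdr3_aa", "aaseqcdr3", "cdr3aa"),
    v_call = c("v_call", "vgenename", "v_gene", "vgene", "bestvgene"),
    d_call = c("d_call", "dgenename", "d_gene", "dgene"),
    j_call = c("j_call", "jgenename", "j_gene", "jgene", "bestjgene"),
    duplicate_count = c("duplicate_count", "clone_count", "clonecount",
                        "count", "reads", "consensus_count")
  )
  raw <- suppressMessages(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE)
  )
  if (nrow(raw) == 0) {
    abort(sprintf("empty repertoire file: %s", path),
          class = "airrnet_empty_repertoire")
  }
  lowered <- tolower(names(raw))
  for (canon in names(aliases)) {
    hit <- which(lowered %in% aliases[[canon]])
    if (length(hit) >= 1) names(raw)[hit[1]] <- canon
  }
  mandatory <- c("junction", "junction_aa", "v_call", "j_call")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("file %s is missing mandatory column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "airrnet_format_error")
  }
  if (!"duplicate_count" %in% names(raw)) raw$duplicate_count <- 1L
  if (!"d_call" %in% names(raw)) raw$d_call <- ""
  raw$d_call[is.na(raw$d_call)] <- ""
  new_repertoire(raw, repertoire_id = repertoire_id, species = species,
                 receptor = receptor, cohort = cohort)
}

#' Write a repertoire as a canonical AIRR TSV
#'
#' Column order is canonicalized (`junction`, `junction_aa`, `v_call`,
#' `d_call`, `j_call`, `duplicate_count`, extras); a read-write-read
#' round-trip reproduces the clone table exactly.
#'
#' @param rep an `airr_repertoire`.
#' @param path output path.
#' @param header optional `#` comment line(s) written before the table.
#' @export
write_airr <- function(rep, path, header = NULL) {
  out <- tibble::as_tibble(rep)
  out$clone_freq <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove clones whose amino-acid junction contains a stop codon
#'
#' Clones with `*` anywhere in `junction_aa` are dropped and clone frequencies
#' renormalized.
#'
#' @param rep an `airr_repertoire`.
#' @return filtered repertoire.
#' @export
filter_stop_codons <- function(rep) {
  keep <- !stringr::str_detect(rep$junction_aa, stringr::fixed("*"))
  if (!any(keep)) {
    abort("all clones contain stop codons", class = "airrnet_empty_repertoire")
  }
  if (all(keep)) return(rep)
  refresh_repertoire(tibble::as_tibble(rep)[keep, , drop = FALSE], rep)
}

#' Keep the top-n clones by abundance
#'
#' Retains the `n` clones of highest `duplicate_count`; ties at the boundary
#' are broken by lexicographic `junction` so the result is deterministic.
#' Frequencies are renormalized. When `n` is at least the repertoire size this
#' is the identity.
#'
#' @param rep an `airr_repertoire`.
#' @param n number of clones to keep (default 10,000).
#' @export
subsample_top <- function(rep, n = 10000) {
  stopifnot(n >= 1)
  if (nrow(rep) <= n) return(rep)
  ord <- order(-rep$duplicate_count, rep$junction)
  refresh_repertoire(tibble::as_tibble(rep)[ord[seq_len(n)], , drop = FALSE],
                     rep)
}

#' Standard preprocessing pipeline
#'
#' Applies the fixed preprocessing order used throughout: exclude stop-codon
#' clones, then subsample to the top-`n` clones by abundance.
#'
#' @inheritParams subsample_top
#' @export
prepare_repertoire <- function(rep, n = 10000) {
  subsample_top(filter_stop_codons(rep), n = n)
}

#' Read a genes x samples expression matrix from TSV
#'
#' @param path TSV with gene ids in the first column and one numeric column
#'   per sample.
#' @param transpose set `TRUE` when the file is samples x genes.
#' @return numeric matrix (genes x samples) with dimnames.
#' @export
read_expression <- function(path, transpose = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    bad <- which(is.na(suppressWarnings(as.numeric(col))))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value in %s at row %d, column '%s'",
                    path, bad[1], names(body)[j]),
            class = "airrnet_format_error")
    }
  }
  m <- as.matrix(body)
  mode(m) <- "numeric"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) {
    abort("sample ids are not unique", class = "airrnet_format_error")
  }
  if (transpose) m <- t(m)
  m
}

#' Read a panel of repertoires from a metadata table
#'
#' @param metadata data frame or CSV path with columns `repertoire_id`,
#'   `path`, `species`, `receptor`, `cohort`.
#' @param prepare apply [prepare_repertoire()] to each repertoire.
#' @param n subsampling depth when `prepare = TRUE`.
#' @return named list of repertoires.
#' @export
read_repertoires <- function(metadata, prepare = TRUE, n = 10000) {
  if (is.character(metadata)) {
    metadata <- utils::read.csv(metadata, comment.char = "#",
                                stringsAsFactors = FALSE)
  }
  needed <- c("repertoire_id", "path", "species", "receptor", "cohort")
  missing <- setdiff(needed, names(metadata))
  if (length(missing) > 0) {
    abort(sprintf("metadata is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "airrnet_format_error")
  }
  reps <- purrr::pmap(metadata[needed], function(repertoire_id, path, species,
                                                 receptor, cohort) {
    r <- read_airr(path, repertoire_id = repertoire_id, species = species,
                   receptor = receptor, cohort = cohort)
    if (prepare) r <- prepare_repertoire(r, n = n)
    r
  })
  names(reps) <- metadata$repertoire_id
  reps
}
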