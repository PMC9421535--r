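#' @importFrom rlang .data abort warn inform %||%
#' @import tibble
NULL

# data.table is used internally (deletion-variant hashing joins)
.datatable.aware <- TRUE

# Tolerance used wherever two frequency vectors are compared for exact equality
.EQ_TOL <- 1e-9

#' Pearson correlation mapped onto the [0, 1] similarity scale
#'
#' All per-feature similarity scores are Pearson correlations clipped below at
#' zero so that every feature lives on a common 0-1 scale. Zero-variance input
#' (including length-1 vectors) is resolved by the equality rule: if the two
#' vectors are elementwise identical the similarity is 1, otherwise 0 (with a
#' warning), which keeps self-similarity at 1 for degenerate profiles.
#'
#' @param x,y numeric vectors of equal length.
#' @param quiet suppress the zero-variance warning.
#' @return similarity in `[0, 1]`.
#' @keywords internal
clipped_pearson <- function(x, y, quiet = FALSE) {
  stopifnot(length(x) == length(y))
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (is.na(sx) || is.na(sy) || sx < .EQ_TOL || sy < .EQ_TOL) {
    if (all(abs(x - y) < .EQ_TOL)) {
      return(1)
    }
    if (!quiet) warn("zero-variance vector in similarity computation; returning 0")
    return(0)
  }
  max(0, stats::cor(x, y))
}

# Translate nucleotide junctions to amino acids. Input must be a multiple of 3.
translate_nt <- function(nt) {
  if (length(nt) == 0) return(character(0))
  out <- rep(NA_character_, length(nt))
  ok <- !is.na(nt) & nchar(nt) > 0 & nchar(nt) %% 3 == 0
  if (any(ok)) {
    out[ok] <- as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAStringSet(toupper(nt[ok])),
                            if.fuzzy.codon = "X")
    ))
  }
  out
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; with seed = NULL the current stream is used.
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Stable non-cryptographic hash (polynomial rolling hash over the deparsed
# object, modulo a Mersenne prime) used to tag output files with a short
# configuration fingerprint.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Comment header written at the top of every CSV/TSV artifact.
artifact_header <- function(seed = NULL, extra = NULL) {
  ver <- as.character(utils::packageVersion("airrnet"))
  parts <- c(sprintf("airrnet v%s", ver),
             if (!is.null(seed)) sprintf("seed=%s", seed),
             extra)
  paste0("# ", paste(parts, collapse = " "))
}

write_table_with_header <- function(df, path, seed = NULL, extra = NULL,
                                    delim = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(artifact_header(seed = seed, extra = extra), con)
  utils::write.table(df, con, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table_skip_header <- function(path, delim = ",") {
  utils::read.table(path, sep = delim, header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
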