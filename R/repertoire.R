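#' Construct a repertoire object
#'
#' A repertoire is a tibble with one row per clone (columns `junction`,
#' `junction_aa`, `v_call`, `d_call`, `j_call`, `duplicate_count`,
#' `clone_freq`) carrying sample-level metadata (`repertoire_id`, `species`,
#' `receptor`, `cohort`) as attributes. Clones are deduplicated on the
#' (`junction`, `v_call`, `j_call`) key with duplicate counts summed, and
#' `clone_freq` is (re)derived from `duplicate_count`.
#'
#' @param clones data frame with at least `junction`, `junction_aa`, `v_call`,
#'   `j_call`; `d_call` defaults to `""` and `duplicate_count` to 1.
#' @param repertoire_id,species,receptor,cohort sample metadata strings.
#' @return a tibble of class `airr_repertoire`.
#' @export
#' @examples
#' rep <- new_repertoire(
#'   tibble::tibble(
#'     junction = c("tgtgcaagatgg", "tgtactagatgg"),
#'     junction_aa = c("CARW", "CTRW"),
#'     v_call = "TRBV1*01", j_call = "TRBJ1*01",
#'     duplicate_count = c(3L, 1L)),
#'   repertoire_id = "toy", species = "human", receptor = "TRB")
new_repertoire <- function(clones, repertoire_id = "rep",
                           species = "human", receptor = "TRB",
                           cohort = "default") {
  clones <- tibble::as_tibble(clones)
  needed <- c("junction", "junction_aa", "v_call", "j_call")
  missing <- setdiff(needed, names(clones))
  if (length(missing) > 0) {
    abort(sprintf("repertoire is missing mandatory column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "airrnet_format_error")
  }
  if (nrow(clones) == 0) {
    abort("repertoire contains no clones", class = "airrnet_empty_repertoire")
  }
  if (!"d_call" %in% names(clones)) clones$d_call <- ""
  if (!"duplicate_count" %in% names(clones)) clones$duplicate_count <- 1L
  clones$junction <- tolower(clones$junction)
  clones$junction_aa <- toupper(clones$junction_aa)
  clones$duplicate_count <- as.integer(clones$duplicate_count)
  if (any(is.na(clones$duplicate_count)) || any(clones$duplicate_count < 1)) {
    abort("duplicate_count must be a positive integer",
          class = "airrnet_format_error")
  }
  extra <- setdiff(names(clones),
                   c("junction", "junction_aa", "v_call", "d_call", "j_call",
                     "duplicate_count", "clone_freq"))
  clones <- clones |>
    dplyr::group_by(.data$junction, .data$v_call, .data$j_call) |>
    dplyr::summarise(
      junction_aa = dplyr::first(.data$junction_aa),
      d_call = dplyr::first(.data$d_call),
      duplicate_count = sum(.data$duplicate_count),
      dplyr::across(dplyr::all_of(extra), dplyr::first),
      .groups = "drop") |>
    dplyr::select(dplyr::all_of(c("junction", "junction_aa", "v_call",
                                  "d_call", "j_call", "duplicate_count")),
                  dplyr::all_of(extra)) |>
    dplyr::arrange(dplyr::desc(.data$duplicate_count), .data$junction)
  clones$clone_freq <- clones$duplicate_count / sum(clones$duplicate_count)
  structure(clones,
            class = c("airr_repertoire", class(tibble::tibble())),
            repertoire_id = repertoire_id, species = species,
            receptor = receptor, cohort = cohort)
}

# Rebuild clone_freq and reattach metadata after row filtering.
refresh_repertoire <- function(clones, template) {
  new_repertoire(clones,
                 repertoire_id = attr(template, "repertoire_id"),
                 species = attr(template, "species"),
                 receptor = attr(template, "receptor"),
                 cohort = attr(template, "cohort"))
}

#' Repertoire metadata
#'
#' @param rep an `airr_repertoire`.
#' @return one-row tibble with `repertoire_id`, `species`, `receptor`,
#'   `cohort` and the clone count.
#' @export
rep_metadata <- function(rep) {
  tibble::tibble(repertoire_id = attr(rep, "repertoire_id") %||% NA_character_,
                 species = attr(rep, "species") %||% NA_character_,
                 receptor = attr(rep, "receptor") %||% NA_character_,
                 cohort = attr(rep, "cohort") %||% NA_character_,
                 n_clones = nrow(rep))
}

#' @export
print.airr_repertoire <- function(x, ...) {
  m <- rep_metadata(x)
  cat(sprintf("<airr_repertoire> %s  [%s %s, cohort %s]  %d clones\n",
              m$repertoire_id, m$species, m$receptor, m$cohort, m$n_clones))
  NextMethod()
}

#' @export
glance.airr_repertoire <- function(x, ...) {
  m <- rep_metadata(x)
  m$total_count <- sum(x$duplicate_count)
  m$n_unique_aa <- length(unique(x$junction_aa))
  m
}

# Validate the internal frequency invariant; used by tests and assertions.
check_repertoire <- function(rep) {
  stopifnot(abs(sum(rep$clone_freq) - 1) < .EQ_TOL,
            all(rep$duplicate_count >= 1))
  invisible(rep)
}
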