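#' Build a table of SSR profiles
#'
#' An SSR profile is one sample's fingerprint: per panel marker, the set of
#' distinct allele fragment lengths (AFLs, integer bp) observed, stored
#' sorted ascending. An empty set records failed amplification (missing
#' data). Profiles are kept in a flat tibble -- one row per sample, the
#' usual identity metadata, and one list-column per marker -- so they pipe
#' straight into dplyr verbs.
#'
#' Single-peak (homozygous-looking) markers contribute ONE allele: allele
#' sets hold distinct variants, which is the convention the whole pipeline
#' (distances, binarisation, consensus) is built on.
#'
#' @param meta data frame with columns `sample_id` (unique), and optionally
#'   `tree_id`, `accession_id`, `location`, `cultivar_name_given`,
#'   `trueness_code` (integer 0-5 or NA for unassessed). Missing metadata
#'   columns are filled with `NA`.
#' @param alleles named list: for each panel marker, a list (one element per
#'   sample) of integer AFL vectors; or a list per sample of named lists.
#'   Vectors are deduplicated and sorted; `numeric(0)`/`NULL` means missing.
#' @param panel an [ssr_panel()].
#' @return A tibble of class `ssr_profiles` with attribute `panel`.
#' @export
ssr_profiles <- function(meta, alleles, panel) {
  stopifnot(inherits(panel, "ssr_panel"), is.data.frame(meta))
  meta <- tibble::as_tibble(meta)
  if (!"sample_id" %in% names(meta)) stop("`meta` needs a sample_id column", call. = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("tree_id", "accession_id", "location", "cultivar_name_given")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_character_
    meta[[col]] <- as.character(meta[[col]])
  }
  if (!"trueness_code" %in% names(meta)) meta$trueness_code <- NA_integer_
  meta$trueness_code <- validate_trueness(meta$trueness_code)

  n <- nrow(meta)
  out <- meta[, c("sample_id", "tree_id", "accession_id", "location",
                  "cultivar_name_given", "trueness_code")]
  for (mk in panel$marker) {
    col <- alleles[[mk]]
    if (is.null(col)) col <- rep(list(integer(0)), n)
    if (length(col) != n) stop("alleles for marker ", mk, " must have one entry per sample",
                               call. = FALSE)
    out[[mk]] <- unname(lapply(col, clean_allele_set, marker = mk))
  }
  new_ssr_profiles(out, panel)
}

new_ssr_profiles <- function(tbl, panel) {
  attr(tbl, "panel") <- panel
  class(tbl) <- unique(c("ssr_profiles", class(tbl)))
  tbl
}

# dedupe, sort, coerce to integer; integer(0) encodes missing
clean_allele_set <- function(x, marker = "?") {
  if (is.null(x) || length(x) == 0L) return(integer(0))
  x <- x[!is.na(x) & x != 0]
  if (length(x) == 0L) return(integer(0))
  xi <- as.integer(round(x))
  if (any(abs(x - xi) > 1e-8)) {
    stop("non-integer AFL at marker ", marker,
         ": configure an allele grid to snap decimal sizes", call. = FALSE)
  }
  xs <- sort(unique(xi))
  if (length(xs) > 4L) stop("more than 4 alleles at marker ", marker, call. = FALSE)
  xs
}

#' @export
print.ssr_profiles <- function(x, ...) {
  cat("<ssr_profiles> ", nrow(x), " samples x ",
      nrow(attr(x, "panel")), " markers\n", sep = "")
  NextMethod()
}

#' Panel attached to a profiles table
#' @param profiles an `ssr_profiles` tibble.
#' @return The `ssr_panel` the profiles were read against.
#' @export
profile_panel <- function(profiles) {
  p <- attr(profiles, "panel")
  if (is.null(p)) stop("object carries no panel attribute", call. = FALSE)
  p
}

# internal: list over markers of list over samples of allele vectors
allele_lists <- function(profiles, panel = profile_panel(profiles)) {
  stats::setNames(lapply(panel$marker, function(mk) profiles[[mk]]), panel$marker)
}

validate_trueness <- function(code) {
  code <- as.integer(code)
  bad <- !is.na(code) & !(code %in% 0:5)
  if (any(bad)) stop("trueness codes must be in 0..5 (NA = unassessed)", call. = FALSE)
  code
}

#' Trueness-to-type codes
#'
#' The genebank certainty codes for cultivar identity, combining pomological
#' and molecular evidence, with their labels and the desirability order used
#' when a group's code is compiled from its members
#' (1 over 5 over 2 over 3 over 4 over 0).
#'
#' @return A tibble with columns `code`, `label` and `desirability_rank`
#'   (1 = most desirable).
#' @export
trueness_codes <- function() {
  tibble::tibble(
    code = c(0L, 1L, 2L, 3L, 4L, 5L),
    label = c("deceased", "true-to-type", "true-to-type (group/mutant)",
              "not determined", "not assessed", "true-to-type with reservations"),
    desirability_rank = c(6L, 1L, 3L, 4L, 5L, 2L)
  )
}
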