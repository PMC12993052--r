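#' Define an SSR marker panel
#'
#' A marker panel is the ordered set of SSR loci a collection is genotyped at.
#' Its order is stable and defines column order in every table the package
#' writes. Each marker may carry the bp length of its repeat motif (used by
#' one of the tie-resolution rules) and an optional allele grid: the sorted
#' canonical fragment-length bins established from reference genotypes, used
#' to snap raw sizing calls onto integers.
#'
#' @param marker character vector of unique, non-empty marker names.
#' @param repeat_unit integer vector (or single value, recycled) of repeat
#'   motif lengths in bp; `NA` when unknown.
#' @param grid optional list of integer vectors, one per marker, each a
#'   strictly increasing set of allele-size bin centres in bp; `NULL` entries
#'   mean no grid is configured for that marker.
#' @return A tibble of class `ssr_panel` with columns `marker`,
#'   `repeat_unit` and list-column `grid`.
#' @examples
#' ssr_panel(c("CH02b10", "GD147"), repeat_unit = 2)
#' @export
ssr_panel <- function(marker, repeat_unit = NA_integer_, grid = NULL) {
  marker <- as.character(marker)
  if (length(marker) == 0L || anyNA(marker) || any(!nzchar(marker))) {
    stop("marker names must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(marker)) {
    stop("duplicate marker names in panel: ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "),
         call. = FALSE)
  }
  repeat_unit <- as.integer(repeat_unit)
  if (length(repeat_unit) == 1L) repeat_unit <- rep(repeat_unit, length(marker))
  if (length(repeat_unit) != length(marker)) {
    stop("`repeat_unit` must be length 1 or one per marker", call. = FALSE)
  }
  if (is.null(grid)) grid <- rep(list(NULL), length(marker))
  if (length(grid) != length(marker)) {
    stop("`grid` must have one entry per marker", call. = FALSE)
  }
  grid <- lapply(grid, function(g) {
    if (is.null(g) || length(g) == 0L) return(NULL)
    g <- as.integer(g)
    if (anyNA(g) || any(g <= 0L) || is.unsorted(g, strictly = TRUE)) {
      stop("allele grids must be strictly increasing positive integers",
           call. = FALSE)
    }
    g
  })
  out <- tibble::tibble(marker = marker, repeat_unit = repeat_unit, grid = grid)
  class(out) <- c("ssr_panel", class(out))
  out
}

#' The 17-marker GFG pear panel
#'
#' The ECPGR Malus/Pyrus marker set used for the German Fruit Genebank pear
#' collection. Repeat units default to 2 bp (dinucleotide motifs, typical of
#' these apple-derived CH/GD/EMPc loci); no allele grids are attached --
#' grids are collection-specific and can be supplied via [ssr_panel()] or a
#' panel file.
#'
#' @return An `ssr_panel` of the 17 markers.
#' @export
gfg_pear_panel <- function() {
  markers <- c("CH01d08", "CH01d09", "CH01f07a", "CH02b10", "CH03d12",
               "CH03g07", "CH04e03", "CH05c06", "EMPc11", "EMPc117",
               "GD147", "GD96", "CH_Vf1", "CH04c07", "CH05a02",
               "GD142", "NZ05g8")
  ssr_panel(markers, repeat_unit = 2L)
}

#' @export
print.ssr_panel <- function(x, ...) {
  cat("<ssr_panel> ", nrow(x), " markers\n", sep = "")
  NextMethod()
}

#' Read / write a plain-text panel file
#'
#' The panel file is a tab- or comma-separated table with columns `marker`,
#' `repeat_unit` and optional `grid` (comma-separated bp values inside the
#' cell, hence tab separation is the default).
#'
#' @param path file path.
#' @return `read_panel()` returns an `ssr_panel`; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("marker", "repeat_unit") %in% names(raw))) {
    stop("panel file needs columns `marker` and `repeat_unit`", call. = FALSE)
  }
  grid <- if ("grid" %in% names(raw)) {
    lapply(raw$grid, function(g) {
      if (is.na(g) || !nzchar(g)) NULL else as.integer(strsplit(g, ",")[[1]])
    })
  } else NULL
  ssr_panel(raw$marker, suppressWarnings(as.integer(raw$repeat_unit)), grid)
}

#' @rdname read_panel
#' @param panel an `ssr_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "ssr_panel"))
  out <- tibble::tibble(
    marker = panel$marker,
    repeat_unit = panel$repeat_unit,
    grid = vapply(panel$grid, function(g) {
      if (is.null(g)) "" else paste(g, collapse = ",")
    }, character(1))
  )
  readr::write_tsv(out, path)
  invisible(path)
}
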