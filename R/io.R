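META_COLS <- c("sample_id", "tree_id", "accession_id", "location",
               "cultivar_name_given", "trueness_code")

#' Read SSR profiles from tabular files
#'
#' Three dialects are supported:
#' * `"wide"`: one row per sample, one column per marker position named
#'   `<marker>_<k>` (e.g. `CH02b10_1`, `CH02b10_2`); blank, `NA` or `0`
#'   cells are missing. Metadata columns (`sample_id`, `tree_id`,
#'   `accession_id`, `location`, `cultivar_name_given`, `trueness_code`)
#'   pass through; any other column that is not a panel marker position is
#'   an error.
#' * `"long"`: one row per (sample, marker, allele) with columns
#'   `sample_id`, `marker`, `allele` and optional metadata; alleles are
#'   deduplicated and sorted, samples absent at a marker are missing there.
#' * `"gfg"`: sheet 1 of the published four-table representative-genotype
#'   layout (an `.xlsx` read via readxl, or the equivalent CSV); the
#'   molecular-group column becomes `sample_id`. Cells holding the literal
#'   review token `"CHECK"` are dropped with a warning.
#'
#' Decimal fragment sizes are only accepted for markers with an allele grid
#' configured in `panel`, in which case they are snapped with
#' [snap_to_grid()] at `grid_tolerance`; otherwise they raise an error.
#'
#' @param source a file path or a data frame already in the given layout.
#' @param panel an [ssr_panel()].
#' @param dialect `"wide"`, `"long"` or `"gfg"`.
#' @param grid_tolerance bp tolerance used when snapping decimal sizes onto
#'   a configured grid (default 1).
#' @param gfg_headers named list of header strings for the gfg dialect,
#'   see [gfg_headers()].
#' @return An `ssr_profiles` tibble.
#' @export
read_ssr_profiles <- function(source, panel, dialect = c("wide", "long", "gfg"),
                              grid_tolerance = 1L, gfg_headers = ssrcurate::gfg_headers()) {
  dialect <- match.arg(dialect)
  tbl <- load_table(source, dialect)
  switch(dialect,
         wide = parse_wide(tbl, panel, grid_tolerance),
         long = parse_long(tbl, panel, grid_tolerance),
         gfg = parse_gfg(tbl, panel, grid_tolerance, gfg_headers))
}

load_table <- function(source, dialect) {
  if (is.data.frame(source)) return(tibble::as_tibble(source))
  if (dialect == "gfg" && grepl("\\.xlsx?$", source, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx needs the readxl package", call. = FALSE)
    }
    return(readxl::read_excel(source, sheet = 1))
  }
  readr::read_csv(source, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

# "", NA, "0" -> missing; "CHECK" -> NA with warning; else numeric
parse_afl_cells <- function(x, where) {
  x <- as.character(x)
  x[x %in% c("", "NA", "0")] <- NA_character_
  n_check <- sum(x == "CHECK", na.rm = TRUE)
  if (n_check > 0) {
    warning(n_check, " unresolved CHECK cell(s) in ", where,
            " read as missing", call. = FALSE)
    x[x == "CHECK"] <- NA_character_
  }
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop("non-integer AFL value '", x[bad[1]], "' in ", where,
         " (row ", bad[1], ")", call. = FALSE)
  }
  out
}

snap_column <- function(vals, panel, mk, grid_tolerance, where) {
  frac <- !is.na(vals) & abs(vals - round(vals)) > 1e-8
  if (any(frac)) {
    g <- panel$grid[[match(mk, panel$marker)]]
    if (is.null(g)) {
      stop("decimal AFL at marker ", mk, " in ", where,
           " but no allele grid is configured", call. = FALSE)
    }
    snapped <- snap_to_grid(vals[frac], g, grid_tolerance)
    if (anyNA(snapped)) {
      warning(sum(is.na(snapped)), " AFL value(s) in ", where,
              " beyond grid tolerance, set to missing", call. = FALSE)
    }
    vals[frac] <- snapped
  }
  as.integer(round(vals))
}

grab_meta <- function(tbl) {
  if (!"sample_id" %in% names(tbl)) stop("missing `sample_id` column", call. = FALSE)
  meta <- tibble::tibble(sample_id = as.character(tbl$sample_id))
  for (col in setdiff(META_COLS, "sample_id")) {
    meta[[col]] <- if (col %in% names(tbl)) tbl[[col]] else NA
  }
  meta
}

parse_wide <- function(tbl, panel, grid_tolerance) {
  other <- setdiff(names(tbl), META_COLS)
  pos_marker <- sub("_[0-9]+$", "", other)
  unknown <- other[!(pos_marker %in% panel$marker)]
  if (length(unknown)) {
    stop("unknown marker column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  meta <- grab_meta(tbl)
  alleles <- lapply(panel$marker, function(mk) {
    cols <- other[pos_marker == mk]
    if (!length(cols)) return(rep(list(integer(0)), nrow(tbl)))
    mat <- sapply(cols, function(cn) {
      snap_column(parse_afl_cells(tbl[[cn]], paste0("column ", cn)),
                  panel, mk, grid_tolerance, paste0("column ", cn))
    })
    mat <- matrix(mat, nrow = nrow(tbl))
    lapply(seq_len(nrow(tbl)), function(i) {
      v <- mat[i, ]
      v[!is.na(v)]
    })
  })
  names(alleles) <- panel$marker
  ssr_profiles(meta, alleles, panel)
}

parse_long <- function(tbl, panel, grid_tolerance) {
  need <- c("sample_id", "marker", "allele")
  if (!all(need %in% names(tbl))) {
    stop("long dialect needs columns sample_id, marker, allele", call. = FALSE)
  }
  unknown <- setdiff(unique(tbl$marker), panel$marker)
  if (length(unknown)) {
    stop("unknown marker(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  first <- tbl[!duplicated(tbl$sample_id), , drop = FALSE]
  meta <- grab_meta(first)
  vals <- parse_afl_cells(tbl$allele, "column allele")
  ids <- meta$sample_id
  alleles <- lapply(panel$marker, function(mk) {
    sel <- tbl$marker == mk & !is.na(vals)
    v <- snap_column(vals[sel], panel, mk, grid_tolerance, paste0("marker ", mk))
    split_v <- split(v, factor(as.character(tbl$sample_id[sel]), levels = ids))
    lapply(split_v, function(x) x)
  })
  names(alleles) <- panel$marker
  ssr_profiles(meta, alleles, panel)
}

#' Default header strings for the published four-table layout
#'
#' The deposit's exact headers are configurable; these are the defaults the
#' writer uses and the reader expects.
#' @return Named list of header strings.
#' @export
gfg_headers <- function() {
  list(group = "molecular_group", cultivar = "cultivar_name",
       trueness = "trueness_to_type", sports = "sports", punq = "PUNQ",
       ploidy = "ploidy", retraceable = "retraceable_to_accession")
}

parse_gfg <- function(tbl, panel, grid_tolerance, headers) {
  if (!headers$group %in% names(tbl)) {
    stop("gfg sheet lacks the group column `", headers$group, "`", call. = FALSE)
  }
  tbl$sample_id <- tbl[[headers$group]]
  if (headers$cultivar %in% names(tbl)) {
    tbl$cultivar_name_given <- tbl[[headers$cultivar]]
  }
  if (headers$trueness %in% names(tbl)) {
    tbl$trueness_code <- suppressWarnings(as.integer(tbl[[headers$trueness]]))
  }
  keep <- names(tbl) %in% META_COLS |
    sub("_[0-9]+$", "", names(tbl)) %in% panel$marker
  parse_wide(tbl[, keep, drop = FALSE], panel, grid_tolerance)
}

#' Write SSR profiles
#'
#' @param profiles an `ssr_profiles` tibble.
#' @param path output CSV path.
#' @param dialect `"wide"` or `"long"` (see [read_ssr_profiles()]).
#' @return `path`, invisibly.
#' @export
write_ssr_profiles <- function(profiles, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  panel <- profile_panel(profiles)
  if (dialect == "long") {
    long <- tidyr::pivot_longer(tibble::as_tibble(profiles),
                                cols = dplyr::all_of(panel$marker),
                                names_to = "marker", values_to = "allele")
    long <- tidyr::unnest(long, "allele")
    readr::write_csv(long[, c(META_COLS, "marker", "allele")], path, na = "")
    return(invisible(path))
  }
  out <- tibble::as_tibble(profiles)[, META_COLS]
  for (mk in panel$marker) {
    k <- max(1L, max(lengths(profiles[[mk]])))
    for (p in seq_len(k)) {
      out[[paste0(mk, "_", p)]] <- vapply(profiles[[mk]], function(a) {
        if (length(a) >= p) a[p] else NA_integer_
      }, integer(1))
    }
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Snap a raw fragment size onto a marker's allele grid
#'
#' Fragment-analysis sizing drifts by fractions of a bp between runs; a
#' per-marker grid of canonical bin centres (established from reference
#' genotypes) standardises calls. A raw size is assigned to the nearest grid
#' value within `tolerance` bp; ties break toward the smaller grid value;
#' values farther than `tolerance` from every bin come back `NA` (unassigned)
#' and must be surfaced by the caller.
#'
#' @param x numeric vector of raw sizes in bp.
#' @param grid strictly increasing integer vector of bin centres.
#' @param tolerance non-negative bp tolerance (default 1).
#' @return Integer vector: snapped AFLs, `NA` where unassigned.
#' @examples
#' snap_to_grid(c(103.6, 102.0), c(100L, 104L, 108L), tolerance = 1)
#' @export
snap_to_grid <- function(x, grid, tolerance = 1L) {
  if (is.null(grid) || length(grid) == 0L) stop("empty allele grid", call. = FALSE)
  grid <- as.integer(grid)
  stopifnot(tolerance >= 0, !is.unsorted(grid, strictly = TRUE))
  vapply(as.numeric(x), function(v) {
    if (is.na(v)) return(NA_integer_)
    d <- abs(v - grid)
    i <- which.min(d)  # which.min takes the first (smaller) grid value on ties
    if (d[i] <= tolerance) grid[i] else NA_integer_
  }, integer(1))
}

#' Write the four-table representative-genotype dataset
#'
#' Emits the published deposit's four logical tables as four CSV files in
#' `dir`: (1) `representatives.csv` -- cultivar name, molecular group,
#' trueness-to-type, sports, PUNQ, ploidy, retraceability and the
#' per-marker-position AFLs, with unresolved positions carrying the literal
#' token `"CHECK"`; (2) `representatives_legend.csv`; (3)
#' `frequencies.csv` -- per-position frequency of the representative
#' variant plus the per-group average; (4) `frequencies_legend.csv`.
#'
#' @param reps an `ssr_representatives` tibble (see [consensus_genotypes()]).
#' @param panel the [ssr_panel()].
#' @param dir output directory (created if needed).
#' @param frequencies optional per-position frequency tibble from
#'   [variant_frequencies()]; omitted table 3 is written empty.
#' @param headers header strings, see [gfg_headers()].
#' @return Named character vector of the four paths, invisibly.
#' @export
write_representative_dataset <- function(reps, panel, dir,
                                         frequencies = NULL,
                                         headers = gfg_headers()) {
  stopifnot(inherits(reps, "ssr_representatives"))
  if (nrow(reps) == 0L) stop("no representative genotypes to write", call. = FALSE)
  missing_mk <- setdiff(panel$marker, names(reps))
  if (length(missing_mk)) {
    stop("representatives carry no consensus for marker(s): ",
         paste(missing_mk, collapse = ", "), call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  sheet1 <- tibble::tibble(
    !!headers$cultivar := reps$cultivar_name,
    !!headers$group := reps$group_id,
    !!headers$trueness := reps$trueness_code,
    !!headers$sports := vapply(reps$sports, paste, character(1), collapse = "; "),
    !!headers$punq := reps$punq,
    !!headers$ploidy := reps$ploidy,
    !!headers$retraceable := reps$retraceable
  )
  for (mk in panel$marker) {
    k <- max(1L, max(lengths(reps[[mk]])))
    for (p in seq_len(k)) {
      cells <- vapply(seq_len(nrow(reps)), function(i) {
        a <- reps[[mk]][[i]]
        if (length(a) < p) return("")
        if (!is.na(a[p])) return(as.character(a[p]))
        "CHECK"
      }, character(1))
      sheet1[[paste0(mk, "_", p)]] <- cells
    }
  }
  legend1 <- tibble::tibble(
    column = c(unlist(headers, use.names = FALSE), "<marker>_<position>"),
    meaning = c("curated cultivar name of the molecular group",
                "molecular group identifier (prefix + running number)",
                "trueness-to-type code, 0-5 (see trueness_codes())",
                "sports (mutants) of the cultivar held in the collection",
                "Pyrus UNiQue genotype code (externally assigned)",
                "ploidy level from flow cytometry (externally assigned)",
                "TRUE if the representative matches a measured member sample exactly",
                "allele fragment length in bp at the marker position; CHECK marks an unresolved tie")
  )
  if (is.null(frequencies)) {
    frequencies <- tibble::tibble(group_id = character(), marker = character(),
                                  position = integer(), afl = integer(),
                                  frequency = numeric())
  }
  avg <- dplyr::summarise(dplyr::group_by(frequencies, .data$group_id),
                          average_frequency = mean(.data$frequency), .groups = "drop")
  sheet3 <- dplyr::left_join(frequencies, avg, by = "group_id")
  legend3 <- tibble::tibble(
    column = c("group_id", "marker", "position", "afl", "frequency", "average_frequency"),
    meaning = c("molecular group identifier",
                "SSR marker name",
                "position index within the marker (alleles sorted ascending)",
                "representative allele fragment length (bp)",
                "fraction of amplified member samples carrying the representative AFL",
                "mean frequency over the group's resolved positions")
  )
  paths <- c(representatives = file.path(dir, "representatives.csv"),
             representatives_legend = file.path(dir, "representatives_legend.csv"),
             frequencies = file.path(dir, "frequencies.csv"),
             frequencies_legend = file.path(dir, "frequencies_legend.csv"))
  readr::write_csv(sheet1, paths[["representatives"]], na = "")
  readr::write_csv(legend1, paths[["representatives_legend"]], na = "")
  readr::write_csv(sheet3, paths[["frequencies"]], na = "")
  readr::write_csv(legend3, paths[["frequencies_legend"]], na = "")
  invisible(paths)
}
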