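#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a distance object into long pair form
#'
#' @param x an `ssr_dist` from [pairwise_distances()].
#' @param ... unused.
#' @return A tibble with one row per unordered sample pair: `sample_1`,
#'   `sample_2`, `distance` (`NA` for incomparable pairs).
#' @method tidy ssr_dist
#' @export
tidy.ssr_dist <- function(x, ...) {
  m <- x$matrix
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(sample_1 = x$sample_ids[idx[, 1]],
                 sample_2 = x$sample_ids[idx[, 2]],
                 distance = m[idx])
}

#' @rdname tidy.ssr_dist
#' @method glance ssr_dist
#' @export
glance.ssr_dist <- function(x, ...) {
  d <- x$matrix[upper.tri(x$matrix)]
  tibble::tibble(n_samples = length(x$sample_ids),
                 n_pairs = length(d),
                 n_incomparable = nrow(x$incomparable),
                 tolerance_bp = x$tolerance_bp,
                 mean_distance = mean(d, na.rm = TRUE),
                 min_distance = min(d, na.rm = TRUE))
}

#' Tidy / summarise a curation run
#'
#' `tidy()` returns one row per molecular group (size, cultivar name,
#' trueness, retraceability, average variant frequency, unresolved flags);
#' `glance()` returns the one-row run summary.
#'
#' @param x an `ssr_curation` from [run_ssr_curation()].
#' @param ... unused.
#' @method tidy ssr_curation
#' @export
tidy.ssr_curation <- function(x, ...) {
  sizes <- dplyr::count(x$groups, .data$group_id, name = "n_members")
  avg <- dplyr::summarise(dplyr::group_by(x$frequencies, .data$group_id),
                          average_frequency = mean(.data$frequency),
                          .groups = "drop")
  reps <- tibble::as_tibble(x$representatives)[
    , c("group_id", "cultivar_name", "trueness_code", "retraceable")]
  reps$n_unresolved_checks <- vapply(x$representatives$checks, nrow, integer(1))
  out <- dplyr::left_join(reps, sizes, by = "group_id")
  dplyr::left_join(out, avg, by = "group_id")
}

#' @rdname tidy.ssr_curation
#' @method glance ssr_curation
#' @export
glance.ssr_curation <- function(x, ...) {
  cnt <- x$manifest$counts
  tibble::tibble(n_samples = cnt$n_samples,
                 n_groups = cnt$n_groups,
                 n_retraceable = cnt$n_retraceable,
                 retraceable_fraction = cnt$n_retraceable / cnt$n_groups,
                 n_check_flags_unresolved = cnt$n_check_flags_unresolved,
                 n_incomparable_pairs = cnt$n_incomparable_pairs)
}
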