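#' Run the full curation pipeline
#'
#' One call from raw profiles to curated outputs: pairwise tolerance-aware
#' Dice distances, threshold clustering into named molecular groups,
#' majority-rule consensus with tie resolution, trueness propagation,
#' retraceability check, per-position variant frequencies and the
#' collection accounting table. Deterministic: identical inputs and
#' parameters give identical outputs.
#'
#' @param profiles an `ssr_profiles` tibble.
#' @param tolerance_bp allele-identity tolerance in bp (default 1).
#' @param cutoff molecular-group distance cut-off (default 0.2: 80-100%
#'   identity groups together).
#' @param prefix group-id prefix (default `"Pyr_"`).
#' @param linkage `"single"` (connected components, default) or
#'   `"complete"`.
#' @param panel the [ssr_panel()]; defaults to the profiles' panel.
#' @param ploidy,punq optional externally assigned metadata, named by
#'   group id (passed to [consensus_genotypes()]).
#' @return A list of class `ssr_curation`: `distances` (`ssr_dist`),
#'   `groups` (`ssr_groups`), `representatives` (`ssr_representatives`,
#'   with `retraceable` filled in), `resolution_log`, `retrace`,
#'   `frequencies`, `summary` (per-location accounting) and `manifest`
#'   (parameters, per-stage counts, warnings).
#' @export
run_ssr_curation <- function(profiles, tolerance_bp = 1L, cutoff = 0.2,
                             prefix = "Pyr_", linkage = "single",
                             panel = profile_panel(profiles),
                             ploidy = NULL, punq = NULL) {
  warnings_seen <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  dist <- pairwise_distances(profiles, tolerance_bp, panel)
  groups <- name_groups(threshold_cluster(dist, cutoff, linkage), prefix)
  reps <- collect(consensus_genotypes(profiles, groups, panel,
                                      ploidy = ploidy, punq = punq))
  retrace <- collect(retrace_representatives(reps, profiles, groups, panel))
  reps$retraceable <- retrace$retraceable[match(reps$group_id, retrace$group_id)]
  freqs <- collect(frequency_report(reps, profiles, groups, panel))
  summ <- collection_summary(profiles)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ssrcurate")),
    parameters = list(tolerance_bp = tolerance_bp, cutoff = cutoff,
                      prefix = prefix, linkage = linkage),
    counts = list(
      n_samples = nrow(profiles),
      n_markers = nrow(panel),
      n_groups = length(unique(groups$group_id)),
      n_incomparable_pairs = nrow(dist$incomparable),
      n_check_flags_unresolved = sum(vapply(reps$checks, nrow, integer(1))),
      n_retraceable = sum(retrace$retraceable, na.rm = TRUE),
      sum_group_sizes = nrow(groups)),
    warnings = warnings_seen)
  structure(list(distances = dist, groups = groups, representatives = reps,
                 resolution_log = attr(reps, "resolution_log"),
                 retrace = retrace, frequencies = freqs, summary = summ,
                 manifest = manifest),
            class = "ssr_curation")
}

#' @export
print.ssr_curation <- function(x, ...) {
  m <- x$manifest
  cat("<ssr_curation>\n",
      "  samples:            ", m$counts$n_samples, "\n",
      "  molecular groups:   ", m$counts$n_groups, "\n",
      "  retraceable:        ", m$counts$n_retraceable, "\n",
      "  unresolved CHECKs:  ", m$counts$n_check_flags_unresolved, "\n",
      "  warnings:           ", length(m$warnings), "\n", sep = "")
  invisible(x)
}

#' Write every artifact of a curation run
#'
#' Emits, under `dir`: `profiles_wide.csv`, `distances.csv` (labelled
#' square matrix), `groups.csv`, the four-table representative dataset
#' (see [write_representative_dataset()]), `consensus_log.csv`,
#' `retrace.csv`, `collection_summary.csv` and `manifest.json`.
#'
#' @param result an `ssr_curation` from [run_ssr_curation()].
#' @param profiles the input `ssr_profiles`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_curation_outputs <- function(result, profiles, dir) {
  stopifnot(inherits(result, "ssr_curation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  panel <- profile_panel(profiles)
  write_ssr_profiles(profiles, file.path(dir, "profiles_wide.csv"), "wide")
  dm <- tibble::as_tibble(result$distances$matrix, rownames = "sample_id")
  readr::write_csv(dm, file.path(dir, "distances.csv"), na = "")
  readr::write_csv(result$groups, file.path(dir, "groups.csv"))
  write_representative_dataset(result$representatives, panel, dir,
                               frequencies = result$frequencies)
  log_out <- result$resolution_log
  if (!is.null(log_out) && nrow(log_out)) {
    log_out$candidates <- vapply(log_out$candidates, paste, character(1), collapse = "|")
  } else {
    log_out <- tibble::tibble(group_id = character(), marker = character(),
                              position = integer(), candidates = character(),
                              rule = character(), chosen = integer())
  }
  readr::write_csv(log_out, file.path(dir, "consensus_log.csv"), na = "")
  readr::write_csv(result$retrace, file.path(dir, "retrace.csv"), na = "")
  readr::write_csv(result$summary, file.path(dir, "collection_summary.csv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
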